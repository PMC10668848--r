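# Shared fixture builders and independent oracles for the test suite.

# Tiny on-disk dataset: a few identities at 16 px, two days.
make_tiny_dataset <- function(dir, n_ids = 3, sigma_id = 2, per = 4,
                              days = 1:2, size = 16, seed = 11,
                              nuisance = nuisance_config(
                                rotation_range = 10, fog_level = 0.1,
                                partial_crop_prob = 0, occlusion_prob = 0,
                                noise_sd = 0.01)) {
  ids <- make_identities(n_ids, sigma_id, seed = seed)
  generate_dataset(ids, per, sessions = c("morning", "noon"),
                   nuisance = nuisance, out_dir = dir, seed = seed + 1,
                   days = days, size = size)
  read_manifest(file.path(dir, "manifest.csv"))
}

tiny_backbone <- function(size = 16, embed_dim = 16) {
  backbone_spec(input_size = size, embed_dim = embed_dim,
                channels = c(4, 8, 8, 8))
}

# Random score table shaped like score_test_set() output.
random_score_table <- function(n, n_classes = 3, seed = 1) {
  withr::with_seed(seed, {
    is_known <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    true_cls <- sample(paste0("id", seq_len(n_classes)), n, replace = TRUE)
    true_lab <- ifelse(is_known, true_cls,
                       paste0("unk", sample(3, n, replace = TRUE)))
    # duplicate some scores on purpose so ties are exercised
    sc <- round(stats::rnorm(n), 1)
    tibble::tibble(
      image_path = sprintf("img%03d.png", seq_len(n)),
      true_label = true_lab,
      is_known = is_known,
      known_score = sc,
      predicted_class = sample(paste0("id", seq_len(n_classes)), n,
                               replace = TRUE),
      predicted_index = 1L
    )
  })
}

# O(n^2) pairwise AUROC oracle (percent).
bf_auroc <- function(table) {
  k <- table$known_score[table$is_known]
  u <- table$known_score[!table$is_known]
  tot <- 0
  for (a in k) for (b in u) tot <- tot + (a > b) + 0.5 * (a == b)
  100 * tot / (length(k) * length(u))
}

# Brute-force OSCR oracle: explicit loop over all distinct thresholds with
# right-continuous step integration (percent).
bf_oscr <- function(table) {
  th <- sort(unique(table$known_score), decreasing = TRUE)
  nk <- sum(table$is_known)
  nu <- sum(!table$is_known)
  area <- 0
  prev_fpr <- 0
  for (s in th) {
    ccr <- 0
    fp <- 0
    for (i in seq_len(nrow(table))) {
      if (table$known_score[i] >= s) {
        if (table$is_known[i]) {
          if (table$predicted_class[i] == table$true_label[i]) ccr <- ccr + 1
        } else {
          fp <- fp + 1
        }
      }
    }
    ccr <- ccr / nk
    fpr <- fp / nu
    area <- area + ccr * (fpr - prev_fpr)
    prev_fpr <- fpr
  }
  100 * area
}

# Central finite-difference gradient of a scalar function of one array.
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Mean intra-class pairwise cosine similarity of feature rows.
intra_class_cosine <- function(features, labels) {
  fn <- features / pmax(sqrt(rowSums(features^2)), 1e-12)
  vals <- c()
  for (cl in unique(labels)) {
    rows <- fn[labels == cl, , drop = FALSE]
    if (nrow(rows) < 2) next
    cs <- tcrossprod(rows)
    vals <- c(vals, cs[upper.tri(cs)])
  }
  mean(vals)
}
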