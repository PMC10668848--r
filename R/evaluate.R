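#' Score a test set with a trained open-set model
#'
#' Embeds each test image, computes the combined distance to every
#' reciprocal point, and records the known-ness score
#' `max_k d(f(x), P_k)` (higher = more known-like; samples are rejected as
#' unknown when the distance to all reciprocal points falls below a
#' threshold) together with the closed-set prediction from the configured
#' head (AM-Softmax cosine argmax by default, maximum reciprocal-point
#' distance optionally). Ties in any argmax resolve to the lowest class
#' index.
#'
#' @param model An `osr_model` from [train()].
#' @param manifest Manifest tibble of test rows; by default all rows whose
#'   `day` differs from the model's training day (all rows if the manifest
#'   has a single day).
#' @param root Image root directory (defaults to the manifest attribute).
#' @param test_days Optional explicit day tags to evaluate on.
#' @return An `osr_scores` tibble: `image_path`, `true_label`, `is_known`,
#'   `known_score`, `predicted_class`, `predicted_index`.
#' @export
score_test_set <- function(model, manifest, root = attr(manifest, "root"),
                           test_days = NULL) {
  rows <- manifest
  if (!is.null(test_days)) {
    rows <- rows |> filter(.data$day %in% test_days)
  } else if ("day" %in% names(manifest) &&
             length(unique(manifest$day)) > 1) {
    rows <- rows |> filter(.data$day != model$config$train_day)
  }
  stop_if(nrow(rows) == 0, "no test rows selected")
  attr(rows, "root") <- root
  data <- load_images(rows, root = root)

  feats <- embed(data$x, model$spec, model$params)
  d <- arpl_distance(feats, model$points)
  stop_if(ncol(d) != length(model$classes),
          "class count mismatch between model state and distances")
  known_score <- apply(d, 1, max)
  pred_idx <- if (model$config$predict_from == "rp_distance") {
    apply(d, 1, which.max)
  } else {
    fn <- l2_normalize_rows(feats)
    wn <- normalize_cols(model$head$W)$Wn
    apply(fn %*% wn, 1, which.max)
  }
  structure(
    tibble(
      image_path = rows$image_path,
      true_label = rows$individual_id,
      is_known = rows$individual_id %in% model$known_ids,
      known_score = known_score,
      predicted_class = model$classes[pred_idx],
      predicted_index = pred_idx
    ),
    class = c("osr_scores", "tbl_df", "tbl", "data.frame"),
    known_ids = model$known_ids
  )
}

#' Threshold decision rule
#'
#' A sample is rejected as `"unknown"` iff its known-ness score falls below
#' `tau`; otherwise it receives its predicted known class.
#'
#' @param table An `osr_scores` tibble.
#' @param tau Rejection threshold on the known-ness score.
#' @return The table with a `decision` column appended.
#' @export
decide <- function(table, tau) {
  table |>
    mutate(decision = ifelse(.data$known_score < tau, "unknown",
                             .data$predicted_class))
}

check_two_sided <- function(table) {
  stop_if(sum(table$is_known) == 0 || sum(!table$is_known) == 0,
          "need at least one known and one unknown sample",
          class = "openherd_undefined_metric")
}

#' AUROC of known-vs-unknown discrimination (percent)
#'
#' All known individuals are pooled into one super-known class and all
#' unknowns into a super-unknown class; the AUROC is the probability that
#' a random known sample outscores a random unknown one (ties count 0.5),
#' computed threshold-free from ranks.
#'
#' @param table An `osr_scores` tibble with at least one known and one
#'   unknown sample.
#' @return Percent in \[0, 100\].
#' @export
auroc <- function(table) {
  check_two_sided(table)
  r <- rank(table$known_score)
  nk <- sum(table$is_known)
  nu <- sum(!table$is_known)
  100 * (sum(r[table$is_known]) - nk * (nk + 1) / 2) / (nk * nu)
}

oscr_points <- function(table) {
  th <- sort(unique(table$known_score), decreasing = TRUE)
  nk <- sum(table$is_known)
  nu <- sum(!table$is_known)
  correct <- table$is_known & table$predicted_class == table$true_label
  ccr <- vapply(th, function(s) sum(correct & table$known_score >= s) / nk,
                numeric(1))
  fpr <- vapply(th, function(s) sum(!table$is_known &
                                      table$known_score >= s) / nu,
                numeric(1))
  tibble(threshold = th, ccr = ccr, fpr = fpr)
}

#' Open-Set Classification Rate (OSCR, percent)
#'
#' Area under the curve of the Correct Classification Rate (fraction of
#' known samples scoring at or above a threshold *and* correctly
#' classified) against the False Positive Rate (fraction of unknown
#' samples scoring at or above the threshold), swept over all observed
#' scores. Right-continuous step integration by default; trapezoidal via
#' `method = "trapezoid"`.
#'
#' @inheritParams auroc
#' @param method `"step"` (default) or `"trapezoid"`.
#' @return Percent in \[0, 100\].
#' @export
oscr <- function(table, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  check_two_sided(table)
  pts <- oscr_points(table)
  dfpr <- diff(c(0, pts$fpr))
  if (method == "step") {
    100 * sum(pts$ccr * dfpr)
  } else {
    prev <- c(0, pts$ccr[-nrow(pts)])
    100 * sum((pts$ccr + prev) / 2 * dfpr)
  }
}

#' Closed-Set Accuracy (CSA, percent)
#'
#' Percent of known test samples whose predicted class equals their true
#' label; unknown samples are excluded.
#'
#' @inheritParams auroc
#' @export
csa <- function(table) {
  stop_if(sum(table$is_known) == 0, "no known samples",
          class = "openherd_undefined_metric")
  k <- table[table$is_known, ]
  100 * mean(k$predicted_class == k$true_label)
}

#' Closed-set accuracy, macro F1 and confusion matrix
#'
#' For an all-known experiment: overall accuracy, unweighted class-mean
#' (macro) F1, and the confusion matrix both as counts and row-normalized
#' percents (rows = true class).
#'
#' @param table An `osr_scores` tibble whose `true_label`s are all known
#'   classes.
#' @return List with `acc`, `f1`, `confusion` (counts), and
#'   `confusion_percent`.
#' @export
closed_set_report <- function(table) {
  stop_if(nrow(table) == 0, "empty score table")
  stop_if(!all(table$is_known), "closed_set_report needs an all-known table")
  classes <- sort(unique(c(table$true_label, table$predicted_class)))
  cm <- table(factor(table$true_label, levels = classes),
              factor(table$predicted_class, levels = classes))
  cm <- unclass(cm)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  f1 <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    denom <- 2 * tp + sum(cm[i, ]) - tp + sum(cm[, i]) - tp
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  rs <- rowSums(cm)
  pct <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/") * 100
  list(acc = acc, f1 = 100 * mean(f1), confusion = cm,
       confusion_percent = pct)
}

#' Openness of a recognition problem (percent)
#'
#' Two conventions are provided. `"ratio"`: `(1 - k_train / k_test) * 100`,
#' the simple individual-count ratio. `"sqrt"`:
#' `(1 - sqrt(2 * k_train / (k_test + k_target))) * 100`, the classical
#' square-root form. At 1 training individual and 7 unknowns
#' (`k_test = k_target = 8`) the sqrt form gives 64.64.
#'
#' @param k_train Number of individuals seen in training.
#' @param k_test Number of individuals in the test set (knowns + unknowns).
#' @param k_target Number of classes the recognizer must discriminate
#'   (defaults to `k_test`).
#' @param variant `"ratio"` or `"sqrt"`.
#' @return Percent.
#' @export
openness <- function(k_train, k_test, k_target = k_test,
                     variant = c("ratio", "sqrt")) {
  variant <- match.arg(variant)
  stop_if(any(k_train < 1) || any(k_train > k_test),
          "need 1 <= k_train <= k_test")
  if (variant == "ratio") {
    100 * (1 - k_train / k_test)
  } else {
    100 * (1 - sqrt(2 * k_train / (k_test + k_target)))
  }
}

#' Per-trial open-set metric report
#'
#' @param table An `osr_scores` tibble.
#' @return One-row tibble `csa`, `auroc`, `oscr` (percent).
#' @export
metric_report <- function(table) {
  tibble(csa = csa(table), auroc = auroc(table), oscr = oscr(table))
}

#' Aggregate per-trial metric reports
#'
#' @param reports Tibble of per-trial metric rows (numeric columns).
#' @param spread `"sd"` (sample standard deviation, default) or
#'   `"population"`.
#' @return An `osr_metrics` list: `per_trial` (the input, with a `trial`
#'   column) and `summary` (one row per metric: `mean`, `spread`,
#'   `spread_type`).
#' @export
aggregate_metrics <- function(reports, spread = c("sd", "population")) {
  spread <- match.arg(spread)
  stop_if(nrow(reports) == 0, "no reports to aggregate")
  num <- reports |> dplyr::select(dplyr::where(is.numeric), -dplyr::any_of("trial"))
  spread_fun <- function(x) {
    if (length(x) < 2) return(0)
    if (spread == "sd") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  spread_label <- spread
  summary <- tibble(
    metric = names(num),
    mean = unname(vapply(num, mean, numeric(1))),
    spread = unname(vapply(num, spread_fun, numeric(1))),
    spread_type = spread_label
  )
  per_trial <- reports
  if (!"trial" %in% names(per_trial)) {
    per_trial <- per_trial |> mutate(trial = dplyr::row_number(),
                                     .before = 1)
  }
  structure(list(per_trial = per_trial, summary = summary),
            class = "osr_metrics")
}

#' @export
print.osr_metrics <- function(x, ...) {
  cat(sprintf("<osr_metrics> %d trials (spread: %s)\n",
              nrow(x$per_trial), x$summary$spread_type[1]))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %6.2f +/- %.2f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$spread[i]))
  }
  invisible(x)
}

#' @rdname aggregate_metrics
#' @param x An `osr_metrics` object.
#' @param ... Unused.
#' @export
tidy.osr_metrics <- function(x, ...) x$per_trial

#' @rdname aggregate_metrics
#' @export
glance.osr_metrics <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(id_cols = "spread_type",
                       names_from = "metric",
                       values_from = c("mean", "spread"))
  wide
}

#' Export per-sample features with a 2-D projection
#'
#' Embeds the given manifest rows with a trained model and writes (or
#' returns) a table of raw embeddings together with their first two
#' principal components — the raw material for density or map-style
#' figures; no plotting is imposed.
#'
#' @param model An `osr_model`.
#' @param manifest Manifest tibble.
#' @param path Optional CSV path; when given, the table is written there.
#' @param root Image root directory.
#' @return Tibble with `image_path`, `individual_id`, `pc1`, `pc2`, and
#'   one `f<i>` column per embedding dimension (invisibly when `path` is
#'   given).
#' @export
export_features <- function(model, manifest, path = NULL,
                            root = attr(manifest, "root")) {
  attr(manifest, "root") <- root
  dat <- load_images(manifest, root = root)
  f <- embed(dat$x, model$spec, model$params)
  pc <- stats::prcomp(f, rank. = 2)
  out <- dplyr::bind_cols(
    tibble(image_path = manifest$image_path,
           individual_id = manifest$individual_id,
           pc1 = pc$x[, 1], pc2 = pc$x[, 2]),
    as_tibble(f, .name_repair = ~ sprintf("f%d", seq_along(.x)))
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' ROC and OSCR curve points
#'
#' @param table An `osr_scores` tibble.
#' @return Tibble of curve points (`threshold`, `tpr`/`ccr`, `fpr`).
#' @export
roc_curve <- function(table) {
  check_two_sided(table)
  th <- sort(unique(table$known_score), decreasing = TRUE)
  nk <- sum(table$is_known)
  nu <- sum(!table$is_known)
  tibble(
    threshold = th,
    tpr = vapply(th, function(s) sum(table$is_known &
                                       table$known_score >= s) / nk,
                 numeric(1)),
    fpr = vapply(th, function(s) sum(!table$is_known &
                                       table$known_score >= s) / nu,
                 numeric(1))
  )
}

#' @rdname roc_curve
#' @export
oscr_curve <- function(table) {
  check_two_sided(table)
  oscr_points(table)
}
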