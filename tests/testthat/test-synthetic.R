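# The procedural face generator: determinism, the identity-dispersion dial,
# nuisance rendering, and manifest bookkeeping.

test_that("make_identities is deterministic and draws distinct ids", {
  a <- make_identities(1, sigma_id = 0, seed = 7)
  b <- make_identities(1, sigma_id = 0, seed = 7)
  expect_identical(a$proto[[1]]$pattern_params, b$proto[[1]]$pattern_params)

  herd <- make_identities(17, sigma_id = 0.5, seed = 1)
  expect_equal(nrow(herd), 17)
  expect_equal(length(unique(herd$id)), 17)
  expect_error(make_identities(0, 1, seed = 1), "n_ids")
})

test_that("pairwise prototype distance grows with sigma_id", {
  mean_dist <- function(sigma) {
    d <- c()
    for (seed in 1:10) {   # 10 herds x C(5,2) pairs = 100 draws
      herd <- make_identities(5, sigma, seed = seed)
      for (i in 1:4) for (j in (i + 1):5) {
        d <- c(d, prototype_distance(herd$proto[[i]], herd$proto[[j]]))
      }
    }
    mean(d)
  }
  d_small <- mean_dist(0.1)
  d_mid <- mean_dist(0.5)
  d_big <- mean_dist(1.0)
  expect_gt(d_big, d_mid)
  expect_gt(d_mid, d_small)
  # sigma 0 collapses the herd onto one prototype
  herd0 <- make_identities(3, 0, seed = 2)
  expect_equal(prototype_distance(herd0$proto[[1]], herd0$proto[[2]]), 0)
})

test_that("render_sample honors the shape/value contract", {
  proto <- make_identities(1, 1, seed = 3)$proto[[1]]
  img <- render_sample(proto, nuisance_config(), size = 64, seed = 1)
  expect_equal(dim(img), c(64, 64))
  expect_true(all(img >= 0 & img <= 1))
  rgbimg <- render_sample(proto, nuisance_none(), size = 32, seed = 1,
                          rgb = TRUE)
  expect_equal(dim(rgbimg), c(32, 32, 3))
  expect_error(render_sample(proto, nuisance_none(), size = 8, seed = 1),
               "size")
})

test_that("degenerate nuisance renders are seed-independent", {
  proto <- make_identities(1, 1, seed = 4)$proto[[1]]
  a <- render_sample(proto, nuisance_none(), size = 32, seed = 1)
  b <- render_sample(proto, nuisance_none(), size = 32, seed = 999)
  expect_identical(a, b)
  # nondegenerate nuisance must actually vary with the seed
  nz <- nuisance_config()
  expect_false(identical(render_sample(proto, nz, size = 32, seed = 1),
                         render_sample(proto, nz, size = 32, seed = 2)))
})

test_that("occlusion overwrites one contiguous rectangle", {
  proto <- make_identities(1, 1, seed = 5)$proto[[1]]
  base <- render_sample(proto, nuisance_none(), size = 48, seed = 1)
  occ_cfg <- nuisance_config(rotation_range = 0,
                             illumination_range = c(1, 1), fog_level = 0,
                             partial_crop_prob = 0, occlusion_prob = 1,
                             scale_range = c(1, 1), noise_sd = 0)
  occ <- render_sample(proto, occ_cfg, size = 48, seed = 9)
  diff <- which(occ != base, arr.ind = TRUE)
  expect_gt(nrow(diff), 0)
  rows <- range(diff[, 1]); cols <- range(diff[, 2])
  # every changed pixel carries the occluder value, and the changed set
  # fills its bounding box (modulo pattern pixels that already equal it)
  expect_true(all(occ[diff] == 0.12))
  box <- occ[rows[1]:rows[2], cols[1]:cols[2]]
  expect_true(mean(box == 0.12) > 0.95)
})

test_that("generate_dataset writes a complete, deterministic dataset", {
  d1 <- withr::local_tempdir()
  ids <- make_identities(3, 1.5, seed = 6)
  man <- generate_dataset(ids, per_id_per_session = 2,
                          sessions = c("morning", "noon", "night"),
                          nuisance = nuisance_config(), out_dir = d1,
                          seed = 21, size = 16)
  expect_equal(nrow(man), 3 * 3 * 2)     # ids x sessions x per-session
  expect_equal(unname(table(man$individual_id)), rep(6L, 3),
               ignore_attr = TRUE)

  # round trip + manifest/file bijection
  man2 <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(as.data.frame(man2), as.data.frame(man), ignore_attr = TRUE)
  pngs <- list.files(d1, pattern = "\\.png$", recursive = TRUE)
  expect_setequal(pngs, man$image_path)

  # byte-identical regeneration under the same seed
  d2 <- withr::local_tempdir()
  generate_dataset(ids, 2, sessions = c("morning", "noon", "night"),
                   nuisance = nuisance_config(), out_dir = d2,
                   seed = 21, size = 16)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  h1 <- unname(tools::md5sum(file.path(d1, man$image_path[c(1, 9, 18)])))
  h2 <- unname(tools::md5sum(file.path(d2, man$image_path[c(1, 9, 18)])))
  expect_identical(h1, h2)

  # a different seed changes the images
  d3 <- withr::local_tempdir()
  generate_dataset(ids, 2, sessions = c("morning", "noon", "night"),
                   nuisance = nuisance_config(), out_dir = d3,
                   seed = 22, size = 16)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, man$image_path[1]))),
    unname(tools::md5sum(file.path(d3, man$image_path[1])))))
})

test_that("count_summary matches an independent group-by and sums rows", {
  d <- withr::local_tempdir()
  man <- make_tiny_dataset(d, n_ids = 3, per = 2, days = 1:2)
  cs <- count_summary(man, by = "day")
  ref <- table(man$individual_id, man$day)
  for (i in 1:3) {
    row <- cs[cs$individual_id == rownames(ref)[i], ]
    expect_equal(unname(unlist(row[, c("day_1", "day_2")])),
                 unname(ref[i, ]), ignore_attr = TRUE)
  }
  tot <- cs[cs$individual_id == "total", ]
  expect_equal(tot$day_1, sum(ref[, 1]))
  expect_equal(tot$day_2, sum(ref[, 2]))
})

test_that("raw-pixel separability increases with sigma_id", {
  # leave-one-out nearest-centroid accuracy on raw pixels, same seeds and
  # nuisance at three dispersion levels
  nc_accuracy <- function(sigma) {
    ids <- make_identities(5, sigma, seed = 31)
    d <- withr::local_tempdir()
    man <- generate_dataset(ids, per_id_per_session = 3,
                            sessions = c("a", "b"),
                            nuisance = nuisance_config(
                              rotation_range = 10, fog_level = 0.1,
                              partial_crop_prob = 0, occlusion_prob = 0,
                              noise_sd = 0.02),
                            out_dir = d, seed = 32, size = 16)
    dat <- load_images(read_manifest(file.path(d, "manifest.csv")))
    x <- matrix(aperm(dat$x, c(3, 1, 2)), nrow = dim(dat$x)[3])  # n x pixels
    y <- dat$labels
    correct <- 0
    for (i in seq_along(y)) {
      cent <- sapply(unique(y), function(cl) {
        colMeans(x[setdiff(which(y == cl), i), , drop = FALSE])
      })
      dists <- apply(cent, 2, function(cc) sum((x[i, ] - cc)^2))
      correct <- correct + (unique(y)[which.min(dists)] == y[i])
    }
    correct / length(y)
  }
  accs <- vapply(c(0.1, 0.7, 2.0), nc_accuracy, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
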