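#' Synthetic herd face-image generator
#'
#' Procedural generator emulating a herd of individually distinct but
#' visually similar animal faces, for testing open-set identification
#' pipelines without any real footage. Each identity is a point in a latent
#' pattern space: a Gabor-like base coat texture (two oriented sinusoid
#' components) plus a fixed number of elliptical facial markings whose
#' positions, shapes and contrasts are identity-specific. The
#' `sigma_id` dial scales how far identities scatter around the herd-average
#' pattern, i.e. how visually distinct individuals are: at `sigma_id = 0`
#' every animal looks identical, at large `sigma_id` a linear classifier on
#' raw pixels separates them easily.
#'
#' @param n_ids Number of identities to draw (>= 1).
#' @param sigma_id Nonnegative identity-dispersion parameter (unitless
#'   latent-space standard deviation multiplier).
#' @param seed Integer seed; the same seed reproduces the same prototypes.
#' @param n_markings Number of elliptical markings per face (default 6).
#'
#' @return A tibble with one row per identity: `id` (character label) and
#'   `proto` (list-column of prototype parameter objects).
#' @export
#' @examples
#' ids <- make_identities(3, sigma_id = 1, seed = 1)
#' img <- render_sample(ids$proto[[1]], nuisance_none(), size = 32, seed = 1)
#' range(img)
make_identities <- function(n_ids, sigma_id, seed, n_markings = 6L) {
  stop_if(!is.numeric(n_ids) || length(n_ids) != 1 || n_ids < 1,
          "`n_ids` must be a single integer >= 1")
  stop_if(!is.numeric(sigma_id) || sigma_id < 0,
          "`sigma_id` must be a nonnegative number")
  n_ids <- as.integer(n_ids)
  n_markings <- as.integer(n_markings)
  stop_if(n_markings < 1, "`n_markings` must be >= 1")

  protos <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_ids), function(i) {
      draw_prototype(sprintf("id%02d", i), sigma_id, n_markings)
    })
  })
  tibble(
    id = vapply(protos, `[[`, character(1), "id"),
    proto = protos
  )
}

# Herd-average pattern and per-parameter dispersion scales. The means define
# the "breed look"; sigma_id multiplies the scales to disperse identities.
proto_population <- function(n_markings) {
  ang <- 2 * pi * (seq_len(n_markings) - 1) / n_markings + pi / 7
  list(
    core_mean = c(freq1 = 3.5, theta1 = 0.4, phase1 = 0,
                  freq2 = 6.0, theta2 = -0.9, phase2 = 0,
                  amp = 0.20, base = 0.55),
    core_scale = c(freq1 = 0.8, theta1 = 0.5, phase1 = 1.2,
                   freq2 = 1.2, theta2 = 0.5, phase2 = 1.2,
                   amp = 0.04, base = 0.04),
    mark_mean = cbind(cx = 0.55 * cos(ang), cy = 0.5 * sin(ang),
                      rx = rep(0.16, n_markings), ry = rep(0.10, n_markings),
                      rot = ang,
                      contrast = 0.30 * (-1)^seq_len(n_markings)),
    mark_scale = cbind(cx = 0.12, cy = 0.12, rx = 0.035, ry = 0.025,
                       rot = 0.5, contrast = 0.12)[rep(1, n_markings), ,
                                                   drop = FALSE]
  )
}

draw_prototype <- function(id, sigma_id, n_markings) {
  pop <- proto_population(n_markings)
  core <- pop$core_mean + sigma_id * pop$core_scale * rnorm(length(pop$core_mean))
  mark <- pop$mark_mean + sigma_id * pop$mark_scale *
    matrix(rnorm(length(pop$mark_mean)), nrow = n_markings)
  # keep shape parameters physically meaningful
  core["freq1"] <- max(core["freq1"], 0.5)
  core["freq2"] <- max(core["freq2"], 0.5)
  mark[, "rx"] <- pmax(mark[, "rx"], 0.02)
  mark[, "ry"] <- pmax(mark[, "ry"], 0.02)
  structure(
    list(id = id, pattern_params = c(core, as.vector(mark)),
         core = core, markings = mark),
    class = "herd_prototype"
  )
}

#' @export
print.herd_prototype <- function(x, ...) {
  cat("<herd_prototype>", x$id, "-", nrow(x$markings), "markings\n")
  invisible(x)
}

#' Latent distance between two identity prototypes
#'
#' Euclidean distance in the generator's pattern-parameter space; its
#' expectation over random identity pairs grows monotonically with
#' `sigma_id`, which makes it the generator's own separability statistic.
#'
#' @param a,b Prototype objects from [make_identities()].
#' @return A single nonnegative number.
#' @export
prototype_distance <- function(a, b) {
  sqrt(sum((a$pattern_params - b$pattern_params)^2))
}

# Evaluate the noiseless analytic face pattern at continuous coordinates
# (u, v in [-1, 1]). Rendering through coordinates (rather than resampling
# pixels) keeps rotation/scale/crop free of interpolation artifacts.
eval_pattern <- function(proto, u, v) {
  p <- proto$core
  a1 <- u * cos(p["theta1"]) + v * sin(p["theta1"])
  a2 <- u * cos(p["theta2"]) + v * sin(p["theta2"])
  img <- p["base"] +
    p["amp"] * sin(2 * pi * p["freq1"] * a1 + p["phase1"]) +
    0.6 * p["amp"] * sin(2 * pi * p["freq2"] * a2 + p["phase2"])
  for (k in seq_len(nrow(proto$markings))) {
    m <- proto$markings[k, ]
    du <- u - m["cx"]
    dv <- v - m["cy"]
    ru <- du * cos(m["rot"]) + dv * sin(m["rot"])
    rv <- -du * sin(m["rot"]) + dv * cos(m["rot"])
    img <- img + m["contrast"] *
      exp(-0.5 * ((ru / m["rx"])^2 + (rv / m["ry"])^2))
  }
  # fixed head-shaped vignette shared by the whole herd
  mask <- exp(-((u / 1.05)^2 + (v / 0.95)^2)^3)
  clamp01(0.45 + (img - 0.45) * mask)
}

#' Nuisance (imaging-condition) configuration
#'
#' Controls the nuisance factors the generator layers over the identity
#' pattern: in-plane head rotation, multiplicative illumination,
#' fog (blur plus additive white haze), partially captured faces
#' (off-center zoomed crops), occlusion by a dark rectangle (e.g. a trough
#' bar or another animal), apparent head size, and pixel noise. Defaults
#' are the package's standing emulation of feeding-trough CCTV footage.
#'
#' @param rotation_range Maximum absolute in-plane rotation, degrees.
#' @param illumination_range Length-2 interval of multiplicative brightness.
#' @param fog_level Maximum per-image fog intensity in \[0, 1\].
#' @param partial_crop_prob Probability an image shows only part of the face.
#' @param occlusion_prob Probability of a rectangular occluder.
#' @param scale_range Length-2 interval of relative head size.
#' @param noise_sd Pixel-intensity Gaussian noise standard deviation.
#' @return A `herd_nuisance` list.
#' @export
nuisance_config <- function(rotation_range = 20,
                            illumination_range = c(0.75, 1.25),
                            fog_level = 0.25,
                            partial_crop_prob = 0.08,
                            occlusion_prob = 0.08,
                            scale_range = c(0.85, 1.15),
                            noise_sd = 0.02) {
  stop_if(rotation_range < 0, "`rotation_range` must be >= 0")
  stop_if(length(illumination_range) != 2 ||
            illumination_range[1] > illumination_range[2],
          "`illumination_range` must be an ordered length-2 interval")
  stop_if(fog_level < 0 || fog_level > 1, "`fog_level` must be in [0, 1]")
  stop_if(partial_crop_prob < 0 || partial_crop_prob > 1,
          "`partial_crop_prob` must be in [0, 1]")
  stop_if(occlusion_prob < 0 || occlusion_prob > 1,
          "`occlusion_prob` must be in [0, 1]")
  stop_if(length(scale_range) != 2 || scale_range[1] > scale_range[2] ||
            scale_range[1] <= 0,
          "`scale_range` must be an ordered positive length-2 interval")
  stop_if(noise_sd < 0, "`noise_sd` must be >= 0")
  structure(
    list(rotation_range = rotation_range,
         illumination_range = illumination_range,
         fog_level = fog_level,
         partial_crop_prob = partial_crop_prob,
         occlusion_prob = occlusion_prob,
         scale_range = scale_range,
         noise_sd = noise_sd),
    class = "herd_nuisance"
  )
}

#' @rdname nuisance_config
#' @details `nuisance_none()` is the degenerate configuration (no rotation,
#'   unit illumination, no fog, no crops/occlusion, unit scale, no noise);
#'   under it `render_sample()` returns the exact noiseless prototype
#'   rendering regardless of seed.
#' @export
nuisance_none <- function() {
  nuisance_config(rotation_range = 0, illumination_range = c(1, 1),
                  fog_level = 0, partial_crop_prob = 0, occlusion_prob = 0,
                  scale_range = c(1, 1), noise_sd = 0)
}

#' Render one face image for an identity under nuisance conditions
#'
#' @param proto A prototype from [make_identities()].
#' @param nuisance A [nuisance_config()] object.
#' @param size Image side length in pixels (>= 16).
#' @param seed Integer seed for the per-image nuisance draws.
#' @param rgb If `TRUE` return a `size x size x 3` array (the grayscale
#'   pattern with a subtle identity-independent coat tint), else a
#'   `size x size` matrix.
#' @return Numeric array with values in \[0, 1\].
#' @export
render_sample <- function(proto, nuisance, size = 64, seed = 1, rgb = FALSE) {
  stop_if(!inherits(proto, "herd_prototype"), "`proto` must be a herd_prototype")
  stop_if(!inherits(nuisance, "herd_nuisance"),
          "`nuisance` must come from nuisance_config()")
  stop_if(!is.numeric(size) || size < 16, "`size` must be >= 16")
  size <- as.integer(size)

  img <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    nz <- nuisance
    angle <- runif(1, -nz$rotation_range, nz$rotation_range) * pi / 180
    illum <- runif(1, nz$illumination_range[1], nz$illumination_range[2])
    fog <- runif(1, 0, nz$fog_level)
    scale <- runif(1, nz$scale_range[1], nz$scale_range[2])
    do_crop <- runif(1) < nz$partial_crop_prob
    crop_center <- runif(2, -0.4, 0.4)
    do_occl <- runif(1) < nz$occlusion_prob
    occl_box <- c(runif(2, 0.05, 0.6), runif(2, 0.2, 0.4))  # x0,y0,w,h (rel.)
    noise <- matrix(rnorm(size * size, 0, nz$noise_sd), size, size)

    ax <- seq(-1, 1, length.out = size)
    u0 <- matrix(ax, size, size, byrow = TRUE)
    v0 <- matrix(ax, size, size)
    if (do_crop) {  # zoom into an off-center sub-window: partial face
      u0 <- crop_center[1] + u0 * 0.55
      v0 <- crop_center[2] + v0 * 0.55
    }
    u <- (u0 * cos(angle) - v0 * sin(angle)) / scale
    v <- (u0 * sin(angle) + v0 * cos(angle)) / scale
    out <- eval_pattern(proto, u, v)
    if (do_occl) {
      i0 <- 1L + floor(occl_box[2] * (size - 1))
      j0 <- 1L + floor(occl_box[1] * (size - 1))
      i1 <- min(size, i0 + max(1L, floor(occl_box[4] * size)))
      j1 <- min(size, j0 + max(1L, floor(occl_box[3] * size)))
      out[i0:i1, j0:j1] <- 0.12
    }
    if (fog > 0) {
      out <- (1 - 0.35 * fog) * gaussian_blur(out, sigma = 2.5 * fog) +
        0.35 * fog
    }
    clamp01(out * illum + noise)
  })
  if (rgb) {
    img <- array(c(img * 1.0, img * 0.93, img * 0.85), dim = c(size, size, 3))
  }
  img
}

#' Generate an on-disk synthetic dataset with a CSV manifest
#'
#' Writes one PNG per (identity, day, session, replicate) and a manifest CSV
#' `image_path,individual_id,day,session` with paths relative to the
#' manifest's directory, mirroring the day/feeding-session bookkeeping of
#' trough-side herd footage (sessions default to morning/noon/night; one day
#' is typically used for training and the others held out for testing).
#'
#' @param ids Identity tibble from [make_identities()].
#' @param per_id_per_session Images per identity per session per day (>= 1).
#' @param sessions Character vector of session tags.
#' @param nuisance A [nuisance_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the full dataset is byte-reproducible.
#' @param days Integer vector of day tags (default a single day).
#' @param size Image side length in pixels.
#' @param rgb Write RGB images instead of grayscale.
#' @param session_illum Optional named numeric vector of per-session
#'   multiplicative illumination shifts (e.g. `c(night = 0.8)`); default
#'   none, i.e. sessions share one distribution.
#' @return The manifest as a tibble (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(ids, per_id_per_session,
                             sessions = c("morning", "noon", "night"),
                             nuisance = nuisance_config(),
                             out_dir, seed, days = 1L, size = 64,
                             rgb = FALSE, session_illum = NULL) {
  stop_if(!is.data.frame(ids) || !all(c("id", "proto") %in% names(ids)),
          "`ids` must be a tibble from make_identities()")
  stop_if(per_id_per_session < 1, "`per_id_per_session` must be >= 1")
  stop_if(length(sessions) == 0, "`sessions` must be nonempty")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'", out_dir),
          class = "openherd_io_error")
  }

  grid <- tidyr::expand_grid(
    individual_id = ids$id,
    day = as.integer(days),
    session = sessions,
    rep = seq_len(per_id_per_session)
  )
  grid$image_path <- sprintf("images/%s/d%d_%s_%03d.png",
                             grid$individual_id, grid$day, grid$session,
                             grid$rep)
  proto_by_id <- setNames(ids$proto, ids$id)

  for (d in unique(dirname(file.path(out_dir, grid$image_path)))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(nrow(grid))) {
    nz <- nuisance
    if (!is.null(session_illum) && grid$session[i] %in% names(session_illum)) {
      shift <- session_illum[[grid$session[i]]]
      nz$illumination_range <- nz$illumination_range * shift
    }
    img <- render_sample(proto_by_id[[grid$individual_id[i]]], nz,
                         size = size, seed = derive_seed(seed, i), rgb = rgb)
    png::writePNG(img, file.path(out_dir, grid$image_path[i]))
  }

  manifest <- grid[, c("image_path", "individual_id", "day", "session")]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- as_tibble(manifest)
  attr(manifest, "root") <- normalizePath(out_dir)
  manifest
}

#' Read and validate a dataset manifest
#'
#' @param path Path to a manifest CSV written by [generate_dataset()].
#' @param check_files If `TRUE` (default), error if any referenced image is
#'   missing.
#' @return Manifest tibble with an attribute `root` (the manifest directory)
#'   used to resolve relative image paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  stop_if(!file.exists(path), sprintf("manifest '%s' not found", path))
  m <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("image_path", "individual_id", "day", "session")
  stop_if(!all(need %in% names(m)),
          paste("manifest must have columns", paste(need, collapse = ", ")))
  root <- dirname(normalizePath(path))
  if (check_files) {
    missing <- !file.exists(file.path(root, m$image_path))
    stop_if(any(missing),
            sprintf("%d manifest images missing (first: %s)",
                    sum(missing), m$image_path[which(missing)[1]]))
  }
  attr(m, "root") <- root
  m
}

#' Per-individual image counts, one column per split
#'
#' Summarises a manifest into the bookkeeping table customary for herd
#' datasets: one row per individual, one count column per split (by default
#' the day tag), plus a `total` row.
#'
#' @param manifest Manifest tibble.
#' @param by Column to spread over (default `"day"`).
#' @return A tibble; last row is the column-wise total.
#' @export
count_summary <- function(manifest, by = "day") {
  stop_if(!by %in% names(manifest), sprintf("no column '%s' in manifest", by))
  wide <- manifest |>
    dplyr::count(.data$individual_id, .data[[by]]) |>
    tidyr::pivot_wider(names_from = all_of(by), values_from = "n",
                       values_fill = 0L, names_prefix = paste0(by, "_")) |>
    arrange(.data$individual_id)
  totals <- wide |>
    summarise(individual_id = "total",
              across(-"individual_id", \(x) sum(x)))
  bind_rows(wide, totals)
}

#' Load images referenced by a manifest into an array
#'
#' @param manifest Manifest tibble (needs the `root` attribute set by
#'   [read_manifest()], or pass `root`).
#' @param root Directory against which `image_path` is resolved.
#' @return List with `x` (array `size x size x n`) and `labels`
#'   (character vector of individual ids).
#' @export
load_images <- function(manifest, root = attr(manifest, "root")) {
  stop_if(is.null(root), "manifest has no root; pass `root`")
  n <- nrow(manifest)
  stop_if(n == 0, "empty manifest")
  first <- png::readPNG(file.path(root, manifest$image_path[1]))
  if (length(dim(first)) == 3) first <- first[, , 1]
  size <- nrow(first)
  x <- array(0, dim = c(size, size, n))
  x[, , 1] <- first
  if (n > 1) {
    for (i in 2:n) {
      img <- png::readPNG(file.path(root, manifest$image_path[i]))
      if (length(dim(img)) == 3) img <- img[, , 1]
      x[, , i] <- img
    }
  }
  list(x = x, labels = manifest$individual_id)
}
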