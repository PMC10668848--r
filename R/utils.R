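#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows count left_join n across all_of
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom stats rnorm runif setNames sd
NULL

# Mix a user seed with a stream counter into a valid 32-bit seed.
# Keeps every derived seed strictly below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483647
}

stop_if <- function(cond, msg, class = "openherd_invalid_argument") {
  if (isTRUE(cond)) abort(msg, class = class)
  invisible(NULL)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur on a single-channel image matrix.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2 * radius) - radius, 1L), n)  # replicate edges
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# Adam optimizer state for a named list of numeric arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Row-wise L2 normalization with a guard for zero rows.
l2_normalize_rows <- function(x, eps = 1e-12) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm < eps
  if (any(zero)) {
    warn("zero-norm vectors normalized to zero")
    nrm[zero] <- 1
  }
  x / nrm
}
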