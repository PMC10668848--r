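#' Feature-extractor specification
#'
#' The whole method is backbone-agnostic: training and evaluation only ever
#' see `f(x)`, a fixed-dimension embedding per image. The default
#' architecture is a desk-scale CNN of four conv(3x3) -> ReLU -> 2x2
#' average-pool blocks followed by a linear projection to `embed_dim`.
#' Externally trained extractors plug in through `forward_fn`: any function
#' `(images, params) -> n x embed_dim matrix` satisfies the contract and is
#' accepted unchanged by [train()] and [score_test_set()].
#'
#' @param input_size Image side length in pixels (must be divisible by 16
#'   for the default architecture).
#' @param embed_dim Embedding dimension (>= 2), default 128.
#' @param architecture Tag, default `"smallconv"`.
#' @param channels Per-block channel counts for the default CNN.
#' @param forward_fn Optional custom extractor function (see Details).
#' @return A `herd_backbone_spec` list.
#' @export
backbone_spec <- function(input_size = 64, embed_dim = 128,
                          architecture = "smallconv",
                          channels = c(8, 16, 32, 64),
                          forward_fn = NULL) {
  stop_if(embed_dim < 2, "`embed_dim` must be >= 2")
  if (architecture == "smallconv") {
    stop_if(input_size %% 16 != 0,
            "`input_size` must be divisible by 16 for the smallconv backbone")
    stop_if(length(channels) != 4, "`channels` must have 4 entries")
  }
  structure(
    list(input_size = as.integer(input_size),
         embed_dim = as.integer(embed_dim),
         architecture = architecture,
         channels = as.integer(channels),
         forward_fn = forward_fn),
    class = "herd_backbone_spec"
  )
}

#' Initialize backbone parameters
#'
#' He-scaled Gaussian weights, zero biases; deterministic given `seed`.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
backbone_init <- function(spec, seed = 1) {
  if (!is.null(spec$forward_fn)) return(list())
  ch <- c(1L, spec$channels)
  withr::with_seed(as.integer(seed), {
    params <- list()
    for (l in 1:4) {
      fan_in <- 9L * ch[l]
      params[[paste0("conv", l, "_w")]] <-
        matrix(rnorm(fan_in * ch[l + 1]) * sqrt(2 / fan_in), fan_in, ch[l + 1])
      params[[paste0("conv", l, "_b")]] <- numeric(ch[l + 1])
    }
    flat <- (spec$input_size / 16L)^2 * ch[5]
    params$fc_w <- matrix(rnorm(flat * spec$embed_dim) * sqrt(1 / flat),
                          flat, spec$embed_dim)
    params$fc_b <- numeric(spec$embed_dim)
    params
  })
}

# ---- conv plumbing (im2col) -------------------------------------------------
# Feature maps are arrays (H, W, C, N); the input batch is (H, W, N).

im2col3 <- function(xp, H, W) {
  cin <- dim(xp)[3]
  n <- dim(xp)[4]
  out <- matrix(0, H * W * n, 9L * cin)
  col <- 0L
  for (c in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        out[, col] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), c, ,
                                   drop = FALSE])
      }
    }
  }
  out
}

col2im3 <- function(dP, H, W, cin, n) {
  dxp <- array(0, dim = c(H + 2L, W + 2L, cin, n))
  col <- 0L
  for (c in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        dxp[di + seq_len(H), dj + seq_len(W), c, ] <-
          dxp[di + seq_len(H), dj + seq_len(W), c, , drop = FALSE] +
          array(dP[, col], dim = c(H, W, 1L, n))
      }
    }
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv_forward <- function(x, w, b) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; cin <- d[3]; n <- d[4]
  xp <- array(0, dim = c(H + 2L, W + 2L, cin, n))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  P <- im2col3(xp, H, W)
  om <- P %*% w
  om <- om + rep(b, each = nrow(om))
  cout <- ncol(w)
  out <- aperm(array(om, dim = c(H, W, n, cout)), c(1, 2, 4, 3))
  list(out = out, P = P, dims = c(H, W, cin, n, cout))
}

conv_backward <- function(dout, P, w, dims) {
  H <- dims[1]; W <- dims[2]; cin <- dims[3]; n <- dims[4]; cout <- dims[5]
  dm <- aperm(dout, c(1, 2, 4, 3))      # (H, W, N, Cout)
  dim(dm) <- c(H * W * n, cout)
  dw <- crossprod(P, dm)
  db <- colSums(dm)
  dP <- tcrossprod(dm, w)
  dx <- col2im3(dP, H, W, cin, n)
  list(dx = dx, dw = dw, db = db)
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
     x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(dy, dims) {
  dx <- array(0, dim = dims)
  io <- seq(1L, dims[1], by = 2L); jo <- seq(1L, dims[2], by = 2L)
  q <- dy / 4
  dx[io, jo, , ] <- q
  dx[io + 1L, jo, , ] <- q
  dx[io, jo + 1L, , ] <- q
  dx[io + 1L, jo + 1L, , ] <- q
  dx
}

backbone_forward <- function(params, spec, x, keep_cache = FALSE) {
  if (!is.null(spec$forward_fn)) {
    return(list(features = spec$forward_fn(x, params), cache = NULL))
  }
  d <- dim(x)
  stop_if(d[1] != spec$input_size || d[2] != spec$input_size,
          sprintf("images are %dx%d but the backbone expects %dx%d",
                  d[1], d[2], spec$input_size, spec$input_size))
  n <- if (length(d) == 3) d[3] else 1L
  h <- array(x, dim = c(d[1], d[2], 1L, n))
  cache <- list()
  for (l in 1:4) {
    cv <- conv_forward(h, params[[paste0("conv", l, "_w")]],
                       params[[paste0("conv", l, "_b")]])
    mask <- cv$out > 0
    h <- cv$out * mask
    pre_dims <- dim(h)
    hp <- avgpool2_forward(h)
    if (keep_cache) {
      cache[[l]] <- list(P = cv$P, dims = cv$dims, mask = mask,
                         pre_dims = pre_dims)
    }
    h <- hp
  }
  flat_dims <- dim(h)
  hf <- matrix(h, prod(flat_dims[1:3]), flat_dims[4])
  hf <- t(hf)                                   # n x flat
  feats <- hf %*% params$fc_w
  feats <- feats + rep(params$fc_b, each = nrow(feats))
  if (keep_cache) cache$flat <- list(hf = hf, flat_dims = flat_dims)
  list(features = feats, cache = cache)
}

backbone_backward <- function(params, spec, cache, dfeat) {
  grads <- list()
  grads$fc_w <- crossprod(cache$flat$hf, dfeat)
  grads$fc_b <- colSums(dfeat)
  dhf <- tcrossprod(dfeat, params$fc_w)         # n x flat
  fd <- cache$flat$flat_dims
  dh <- array(t(dhf), dim = fd)
  for (l in 4:1) {
    cc <- cache[[l]]
    dpre <- avgpool2_backward(dh, cc$pre_dims)
    dpre <- dpre * cc$mask
    cb <- conv_backward(dpre, cc$P, params[[paste0("conv", l, "_w")]],
                        cc$dims)
    grads[[paste0("conv", l, "_w")]] <- cb$dw
    grads[[paste0("conv", l, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

#' Embed a batch of images
#'
#' Runs the feature extractor in evaluation mode (deterministic: identical
#' weights and inputs give identical features).
#'
#' @param images A `size x size` matrix, a `size x size x n` array, or a
#'   list of matrices.
#' @param spec A [backbone_spec()].
#' @param params Parameters from [backbone_init()] or a trained model.
#' @param chunk Batch size used internally to bound memory.
#' @return An `n x embed_dim` matrix of features.
#' @export
embed <- function(images, spec, params, chunk = 128L) {
  if (is.list(images)) {
    images <- array(unlist(images),
                    dim = c(dim(images[[1]])[1], dim(images[[1]])[2],
                            length(images)))
  }
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  out <- matrix(0, n, spec$embed_dim)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- backbone_forward(params, spec,
                                   images[, , s:e, drop = FALSE])$features
  }
  stop_if(any(!is.finite(out)), "non-finite features produced")
  out
}
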