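#' Additive-margin softmax (AM-Softmax) classification head
#'
#' Cosine classifier over the known classes: both the feature vector and
#' each class weight column are unit-normalized, logits are
#' `s * cos(theta_c)`, and the additive margin `m` is subtracted from the
#' correct-class cosine only, which pushes same-class features into a
#' tighter angular cone and widens the gap between classes.
#'
#' @param embed_dim Feature dimension.
#' @param n_classes Number of known classes `C`.
#' @param s Scale hyperparameter (default 10).
#' @param m Additive margin (default 0.5).
#' @param seed Seed for the weight initialization.
#' @return A `herd_am_head` list with fields `W` (`embed_dim x C`), `s`,
#'   `m`, `C`.
#' @export
am_head <- function(embed_dim, n_classes, s = 10, m = 0.5, seed = 1) {
  stop_if(n_classes < 1, "`n_classes` must be >= 1")
  W <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(embed_dim * n_classes) * sqrt(1 / embed_dim),
           embed_dim, n_classes)
  })
  structure(list(W = W, s = s, m = m, C = as.integer(n_classes)),
            class = "herd_am_head")
}

normalize_cols <- function(W, eps = 1e-12) {
  nrm <- sqrt(colSums(W^2))
  zero <- nrm < eps
  if (any(zero)) {
    warn("zero-norm weight columns normalized to zero")
    nrm[zero] <- 1
  }
  list(Wn = sweep(W, 2, nrm, "/"), nrm = nrm)
}

check_labels <- function(labels, C, n) {
  stop_if(length(labels) != n, "one label per feature row required")
  stop_if(any(labels < 1 | labels > C | labels != floor(labels)),
          sprintf("labels must be integers in [1, %d]", C))
}

#' AM-Softmax loss
#'
#' Batch mean of the additive-margin softmax cross-entropy
#' `-log( exp(s (w_y.f - m)) / (exp(s (w_y.f - m)) + sum_{c != y} exp(s w_c.f)) )`
#' computed on unit-normalized features and weight columns. With `m = 0` it
#' reduces exactly to softmax cross-entropy on `s`-scaled cosine logits.
#'
#' @param features `n x embed_dim` matrix (unnormalized; normalization is
#'   part of the loss).
#' @param labels Integer class indices in `[1, C]`.
#' @param head A [am_head()].
#' @param grad If `TRUE` also return analytic gradients w.r.t. `features`
#'   and `head$W`.
#' @return Scalar loss, or (with `grad`) a list `loss`, `dfeatures`, `dW`.
#' @export
am_softmax_loss <- function(features, labels, head, grad = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  stop_if(n == 0, "empty batch")
  check_labels(labels, head$C, n)
  stop_if(ncol(features) != nrow(head$W),
          "feature dimension does not match head")

  eps <- 1e-12
  fn_nrm <- pmax(sqrt(rowSums(features^2)), eps)
  fn <- features / fn_nrm
  wc <- normalize_cols(head$W, eps)
  cosm <- fn %*% wc$Wn                              # n x C cosines
  logits <- head$s * cosm
  iy <- cbind(seq_len(n), labels)
  logits[iy] <- logits[iy] - head$s * head$m
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- mean(lse - logits[iy])
  if (!grad) return(loss)

  p <- exp(logits - lse)                            # softmax rows
  dlog <- p
  dlog[iy] <- dlog[iy] - 1
  dlog <- dlog * (head$s / n)
  dfn <- tcrossprod(dlog, wc$Wn)                    # n x D
  dfeatures <- (dfn - fn * rowSums(dfn * fn)) / fn_nrm
  dwn <- crossprod(fn, dlog)                        # D x C
  dW <- sweep(dwn - sweep(wc$Wn, 2, colSums(dwn * wc$Wn), "*"),
              2, wc$nrm, "/")
  list(loss = loss, dfeatures = dfeatures, dW = dW)
}

#' Reciprocal-point set for the known classes
#'
#' One learnable reciprocal point per known class plus a per-class
#' nonnegative margin `R` bounding (via the adversarial margin constraint)
#' how far a class's features may sit from its reciprocal point, and a
#' temperature `gamma` for turning distances into class probabilities.
#'
#' @param embed_dim Feature dimension.
#' @param n_classes Number of known classes `K`.
#' @param gamma Distance-softmax temperature (> 0), default 1.
#' @param seed Seed for the Gaussian point initialization (sd 0.1).
#' @return A `herd_points` list with fields `P` (`K x embed_dim`), `R`
#'   (length `K`, initialized at 0), `gamma`.
#' @export
reciprocal_points <- function(embed_dim, n_classes, gamma = 1, seed = 1) {
  stop_if(gamma <= 0, "`gamma` must be > 0")
  P <- withr::with_seed(as.integer(seed) + 1L, {
    matrix(rnorm(n_classes * embed_dim, sd = 0.1), n_classes, embed_dim)
  })
  structure(list(P = P, R = numeric(n_classes), gamma = gamma),
            class = "herd_points")
}

# Dimension-averaged squared Euclidean distance, n x K.
arpl_de <- function(features, points) {
  D <- ncol(features)
  stop_if(D != ncol(points$P),
          "feature dimension does not match reciprocal points")
  outer(rowSums(features^2), rep(1, nrow(points$P))) / D -
    2 * tcrossprod(features, points$P) / D +
    outer(rep(1, nrow(features)), rowSums(points$P^2)) / D
}

#' Combined reciprocal-point distance
#'
#' `d(f, P_k) = d_e(f, P_k) - f . P_k`, combining the dimension-averaged
#' squared Euclidean distance with the dot product. Larger values mean the
#' feature sits further into the open space claimed by class `k`'s
#' reciprocal point, i.e. looks more like a known sample of class `k`.
#'
#' @param features `n x embed_dim` matrix.
#' @param points A [reciprocal_points()] set.
#' @return `n x K` matrix of distances.
#' @export
arpl_distance <- function(features, points) {
  features <- as.matrix(features)
  de <- arpl_de(features, points)
  d <- de - tcrossprod(features, points$P)
  stop_if(any(!is.finite(d)), "non-finite distances")
  d
}

#' Class probabilities from reciprocal-point distances
#'
#' Softmax over `gamma * d`; the argmax matches the maximum-distance
#' known-class assignment rule.
#'
#' @param distances `n x K` matrix from [arpl_distance()].
#' @param gamma Temperature (> 0).
#' @return `n x K` row-stochastic matrix.
#' @export
arpl_class_probabilities <- function(distances, gamma = 1) {
  stop_if(!is.numeric(gamma) || gamma <= 0, "`gamma` must be > 0")
  z <- gamma * as.matrix(distances)
  mx <- apply(z, 1, max)
  e <- exp(z - mx)
  e / rowSums(e)
}

#' Adversarial margin constraint (AMC) loss
#'
#' Batch mean of `max(d_e(f(x), P_k) - R_k, 0)` where `k` is each sample's
#' own class: a hinge that caps how far a known class's features may drift
#' from its reciprocal point, bounding the open space left to unknowns.
#'
#' @inheritParams am_softmax_loss
#' @param points A [reciprocal_points()] set.
#' @param grad If `TRUE` also return gradients w.r.t. `features`,
#'   `points$P` and `points$R`.
#' @return Scalar loss, or a list `loss`, `dfeatures`, `dP`, `dR`.
#' @export
amc_loss <- function(features, labels, points, grad = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  K <- nrow(points$P)
  check_labels(labels, K, n)
  D <- ncol(features)
  stop_if(D != ncol(points$P),
          "feature dimension does not match reciprocal points")

  Pk <- points$P[labels, , drop = FALSE]
  diffs <- features - Pk
  dek <- rowSums(diffs^2) / D
  h <- dek - points$R[labels]
  active <- h > 0
  loss <- mean(pmax(h, 0))
  if (!grad) return(loss)

  coef <- ifelse(active, 2 / (D * n), 0)
  dfeatures <- diffs * coef
  dP <- matrix(0, K, D)
  dR <- numeric(K)
  if (any(active)) {
    contrib <- -diffs[active, , drop = FALSE] * coef[active]
    dP <- rowsum(contrib, group = labels[active], reorder = FALSE)
    dP_full <- matrix(0, K, D)
    dP_full[as.integer(rownames(dP)), ] <- dP
    dP <- dP_full
    tabs <- tabulate(labels[active], nbins = K)
    dR <- -tabs / n
  }
  list(loss = loss, dfeatures = dfeatures, dP = dP, dR = dR)
}

#' Reciprocal-point distance cross-entropy
#'
#' Softmax cross-entropy on the distance logits `gamma * d(f, P_k)`: the
#' classifier over known classes that the reciprocal-point framework pairs
#' with the margin constraint. It trains each class's features to sit at
#' maximal combined distance from their own reciprocal point relative to
#' the others, which is what gives the max-distance known-ness score and
#' the threshold rejection rule their known/unknown geometry.
#'
#' @inheritParams amc_loss
#' @return Scalar loss, or a list `loss`, `dfeatures`, `dP`.
#' @export
arpl_ce_loss <- function(features, labels, points, grad = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  K <- nrow(points$P)
  check_labels(labels, K, n)
  D <- ncol(features)
  stop_if(D != ncol(points$P),
          "feature dimension does not match reciprocal points")
  gamma <- points$gamma

  d <- arpl_distance(features, points)
  z <- gamma * d
  mx <- apply(z, 1, max)
  lse <- mx + log(rowSums(exp(z - mx)))
  iy <- cbind(seq_len(n), labels)
  loss <- mean(lse - z[iy])
  if (!grad) return(loss)

  p <- exp(z - lse)
  dd <- p
  dd[iy] <- dd[iy] - 1
  dd <- dd * (gamma / n)
  # d_ik = (|f_i|^2 - 2 f_i.P_k + |P_k|^2)/D - f_i.P_k
  sumdd <- rowSums(dd)
  dfeatures <- (2 / D) * features * sumdd - dd %*% (points$P * (2 / D + 1))
  dP <- (2 / D) * (points$P * colSums(dd) - crossprod(dd, features)) -
    crossprod(dd, features)
  list(loss = loss, dfeatures = dfeatures, dP = dP)
}

#' Joint objective: AM-Softmax plus weighted AMC
#'
#' @inheritParams amc_loss
#' @param head A [am_head()].
#' @param lambda_amc Nonnegative weight on the AMC term (default 0.1).
#' @param lambda_dce Nonnegative weight on the reciprocal-point distance
#'   cross-entropy ([arpl_ce_loss()]). Default 0 here (the bare AM + AMC
#'   composition); [train_config()] defaults it to 1 — see the methods
#'   vignette for why the distance classifier term is needed to train the
#'   open-set score geometry.
#' @return A `herd_loss_breakdown` list: `am_loss`, `amc_loss`, `dce_loss`,
#'   `total` (`= am_loss + lambda_amc * amc_loss + lambda_dce * dce_loss`),
#'   `lambda_amc`, `lambda_dce`; with `grad`, also `dfeatures`, `dW`,
#'   `dP`, `dR`.
#' @export
combined_loss <- function(features, labels, head, points,
                          lambda_amc = 0.1, lambda_dce = 0, grad = FALSE) {
  stop_if(lambda_amc < 0, "`lambda_amc` must be >= 0")
  stop_if(lambda_dce < 0, "`lambda_dce` must be >= 0")
  am <- am_softmax_loss(features, labels, head, grad = grad)
  amc <- amc_loss(features, labels, points, grad = grad)
  dce <- if (lambda_dce > 0) {
    arpl_ce_loss(features, labels, points, grad = grad)
  } else if (grad) {
    list(loss = 0, dfeatures = 0, dP = 0)
  } else 0
  if (!grad) {
    out <- list(am_loss = am, amc_loss = amc, dce_loss = dce,
                total = am + lambda_amc * amc + lambda_dce * dce,
                lambda_amc = lambda_amc, lambda_dce = lambda_dce)
  } else {
    out <- list(am_loss = am$loss, amc_loss = amc$loss, dce_loss = dce$loss,
                total = am$loss + lambda_amc * amc$loss +
                  lambda_dce * dce$loss,
                lambda_amc = lambda_amc, lambda_dce = lambda_dce,
                dfeatures = am$dfeatures + lambda_amc * amc$dfeatures +
                  lambda_dce * dce$dfeatures,
                dW = am$dW,
                dP = lambda_amc * amc$dP + lambda_dce * dce$dP,
                dR = lambda_amc * amc$dR)
  }
  stop_if(!all(is.finite(c(out$am_loss, out$amc_loss, out$total))),
          "non-finite loss")
  structure(out, class = "herd_loss_breakdown")
}

#' @export
print.herd_loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.4f = am %.4f + %.2f * amc %.4f + %.2f * dce %.4f\n",
              x$total, x$am_loss, x$lambda_amc, x$amc_loss,
              x$lambda_dce, x$dce_loss))
  invisible(x)
}
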