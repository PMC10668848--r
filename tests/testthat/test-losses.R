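# The AM-Softmax head, reciprocal-point distances, AMC hinge and the joint
# objective, checked against closed forms and independent scalar oracles.

test_that("am_softmax_loss matches hand-evaluated closed forms", {
  h <- am_head(2, 2, s = 1, m = 0)
  h$W <- cbind(c(1, 0), c(0, 1))
  f <- matrix(c(1, 0), 1)
  expect_equal(am_softmax_loss(f, 1L, h), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-10)
  h$m <- 0.5
  expect_equal(am_softmax_loss(f, 1L, h), -log(exp(0.5) / (exp(0.5) + 1)),
               tolerance = 1e-10)
  h$s <- 10
  expect_equal(am_softmax_loss(f, 1L, h), -log(exp(5) / (exp(5) + 1)),
               tolerance = 1e-10)
  # scale invariance of the normalized formulation
  expect_equal(am_softmax_loss(5 * f, 1L, h), am_softmax_loss(f, 1L, h))
})

test_that("m = 0 reduces to softmax cross-entropy on scaled cosine logits", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 7; D <- 6; C <- 4
      f <- matrix(rnorm(n * D), n)
      y <- sample(C, n, replace = TRUE)
      h <- am_head(D, C, s = 10, m = 0, seed = seed)
      fn <- f / sqrt(rowSums(f^2))
      wn <- apply(h$W, 2, function(w) w / sqrt(sum(w^2)))
      logits <- 10 * fn %*% wn
      ce <- mean(log(rowSums(exp(logits))) - logits[cbind(1:n, y)])
      expect_equal(am_softmax_loss(f, y, h), ce, tolerance = 1e-6)
    })
  }
})

test_that("am_softmax_loss is nondecreasing in the margin m", {
  withr::with_seed(3, {
    f <- matrix(rnorm(40), 8)
    y <- sample(3, 8, replace = TRUE)
    losses <- vapply(seq(0, 1, by = 0.1), function(m) {
      am_softmax_loss(f, y, am_head(5, 3, s = 10, m = m, seed = 1))
    }, numeric(1))
    expect_true(all(diff(losses) >= -1e-12))
  })
})

test_that("am_softmax_loss validates labels and dimensions", {
  h <- am_head(4, 3)
  f <- matrix(rnorm(8), 2)
  expect_error(am_softmax_loss(f, c(0L, 1L), h), "labels")
  expect_error(am_softmax_loss(f, c(1L, 4L), h), "labels")
  expect_error(am_softmax_loss(matrix(rnorm(10), 2), 1:2, h), "dimension")
  expect_error(am_softmax_loss(f[0, , drop = FALSE], integer(0), h), "empty")
})

test_that("arpl_distance matches its formula in special and random cases", {
  pts <- reciprocal_points(2, 3, seed = 4)
  # feature placed exactly at a reciprocal point: d = -dot
  f <- pts$P[2, , drop = FALSE]
  d <- arpl_distance(f, pts)
  expect_equal(d[1, 2], -sum(f * f), tolerance = 1e-12)
  # zero feature: d = |P_k|^2 / D for every k
  d0 <- arpl_distance(matrix(0, 1, 2), pts)
  expect_equal(as.vector(d0), rowSums(pts$P^2) / 2, tolerance = 1e-12)
  # random instance vs elementwise scalar-loop oracle
  withr::with_seed(9, {
    fmat <- matrix(rnorm(8), 4)
    dm <- arpl_distance(fmat, pts)
    for (i in 1:4) for (k in 1:3) {
      de <- sum((fmat[i, ] - pts$P[k, ])^2) / 2
      expect_equal(dm[i, k], de - sum(fmat[i, ] * pts$P[k, ]),
                   tolerance = 1e-12)
    }
  })
  expect_error(arpl_distance(matrix(0, 1, 5), pts), "dimension")
})

test_that("arpl_class_probabilities is a proper softmax over distances", {
  expect_equal(as.vector(arpl_class_probabilities(matrix(2, 1, 4))),
               rep(0.25, 4))
  expect_equal(as.vector(arpl_class_probabilities(matrix(c(1, 0), 1), 1)),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)), tolerance = 1e-12)
  big <- arpl_class_probabilities(matrix(c(100, 0, 0), 1), 1)
  expect_gt(big[1, 1], 0.999)
  withr::with_seed(2, {
    dm <- matrix(rnorm(50), 10)
    p <- arpl_class_probabilities(dm, gamma = 0.7)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
    expect_equal(apply(p, 1, which.max), apply(dm, 1, which.max))
  })
  expect_error(arpl_class_probabilities(matrix(1), gamma = 0), "gamma")
})

test_that("amc_loss is the batch-mean hinge on d_e with per-class margins", {
  D <- 2
  pts <- reciprocal_points(D, 2, seed = 1)
  pts$P <- matrix(0, 2, D)
  pts$R <- c(1, 1)
  # d_e = 0.5 (inside margin) -> 0 ; d_e = 1.5 -> 0.5
  f_in <- matrix(c(1, 0), 1)        # d_e = 1/2 = 0.5
  f_out <- matrix(c(sqrt(3), 0), 1) # d_e = 3/2 = 1.5
  expect_equal(amc_loss(f_in, 1L, pts), 0)
  expect_equal(amc_loss(f_out, 1L, pts), 0.5, tolerance = 1e-12)
  # batch with per-sample (d_e, R) = (2, 1), (0.5, 1) -> mean(1, 0) = 0.5
  fb <- rbind(c(2, 0), c(1, 0))     # d_e = 2 and 0.5
  expect_equal(amc_loss(fb, c(1L, 2L), pts), 0.5, tolerance = 1e-12)
  # hinge is zero iff every sample satisfies d_e <= R
  withr::with_seed(5, {
    fr <- matrix(rnorm(10), 5)
    y <- sample(2, 5, replace = TRUE)
    de <- vapply(1:5, function(i) sum((fr[i, ] - pts$P[y[i], ])^2) / D,
                 numeric(1))
    pts$R <- rep(max(de) + 0.1, 2)
    expect_equal(amc_loss(fr, y, pts), 0)
    pts$R <- rep(max(de) - 0.1, 2)
    expect_gt(amc_loss(fr, y, pts), 0)
  })
})

test_that("combined_loss recomposes from its component losses", {
  withr::with_seed(7, {
    f <- matrix(rnorm(24), 6)
    y <- sample(3, 6, replace = TRUE)
    h <- am_head(4, 3, seed = 2)
    pts <- reciprocal_points(4, 3, seed = 3)
    pts$R <- runif(3, 0.05, 0.3)
    lb0 <- combined_loss(f, y, h, pts, lambda_amc = 0)
    expect_equal(lb0$total, am_softmax_loss(f, y, h), tolerance = 1e-12)
    lb <- combined_loss(f, y, h, pts, lambda_amc = 0.7, lambda_dce = 0.3)
    expect_equal(lb$total,
                 am_softmax_loss(f, y, h) + 0.7 * amc_loss(f, y, pts) +
                   0.3 * arpl_ce_loss(f, y, pts),
                 tolerance = 1e-6)
    # inactive hinge: total collapses to the AM term (+ dce when enabled)
    pts$R <- rep(100, 3)
    lb1 <- combined_loss(f, y, h, pts, lambda_amc = 1)
    expect_equal(lb1$amc_loss, 0)
    expect_equal(lb1$total, lb1$am_loss)
  })
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(12, {
    n <- 5; D <- 4; C <- 3
    f <- matrix(rnorm(n * D), n)
    y <- sample(C, n, replace = TRUE)
    h <- am_head(D, C, seed = 5)
    pts <- reciprocal_points(D, C, seed = 6)
    pts$R <- runif(C, 0.1, 0.4)   # generic position, away from hinge kinks

    g <- combined_loss(f, y, h, pts, lambda_amc = 0.6, lambda_dce = 0.8,
                       grad = TRUE)
    tot <- function(ff, WW = h$W, PP = pts$P, RR = pts$R) {
      h2 <- h; h2$W <- WW
      p2 <- pts; p2$P <- PP; p2$R <- RR
      combined_loss(ff, y, h2, p2, lambda_amc = 0.6, lambda_dce = 0.8)$total
    }
    expect_equal(g$dfeatures, numeric_grad(function(x) tot(x), f),
                 tolerance = 1e-4)
    expect_equal(g$dW, numeric_grad(function(x) tot(f, WW = x), h$W),
                 tolerance = 1e-4)
    expect_equal(g$dP, numeric_grad(function(x) tot(f, PP = x), pts$P),
                 tolerance = 1e-4)
    expect_equal(as.vector(g$dR),
                 as.vector(numeric_grad(function(x) tot(f, RR = x), pts$R)),
                 tolerance = 1e-4)

    # AMC subgradient is exactly zero when every sample is inside its margin
    pts$R <- rep(100, C)
    gz <- amc_loss(f, y, pts, grad = TRUE)
    expect_equal(gz$loss, 0)
    expect_true(all(gz$dfeatures == 0) && all(gz$dP == 0) &&
                  all(gz$dR == 0))
  })
})
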