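test_that("bounded activation matches its closed form, knots included", {
  set.seed(10)
  x <- runif(1e4, -6, 6)
  oracle <- ifelse(x < -2, -1, ifelse(x >= 2, 1, x / 2))
  expect_identical(improved_activation(x), oracle)
  expect_equal(improved_activation(c(0, 1)), c(0, 0.5))
  expect_equal(improved_activation(c(3, -5)), c(1, -1))
  # continuity at the knots: value at 2 equals the left limit of x/2
  expect_equal(improved_activation(2), 1)
  expect_equal(improved_activation(2 - 1e-12), 1, tolerance = 1e-9)
  expect_equal(improved_activation(-2), -1)
  # bounded and nondecreasing
  xs <- sort(x)
  fx <- improved_activation(xs)
  expect_true(all(fx >= -1 & fx <= 1))
  expect_false(is.unsorted(fx))
})

test_that("branch scores are affine in the descriptor at evaluation", {
  pp <- pooling_params(channels = 4, m = 3, q = 2, delta = 0, hidden = 4,
                       exponents = c(1, 2, 4), seed = 1)
  # zero score layers give all-zero scores
  pz <- pp; pz$W_h[] <- 0; pz$b_h[] <- 0
  expect_equal(pooling_scores(c(1, -2, 0.5, 3), pz), c(0, 0, 0))
  # identity-like score layer reproduces the hand-computed affine map
  pi_ <- pp
  pi_$W_h <- diag(3)[, c(1:3, 1)] * 0; pi_$W_h[1, 1] <- 1; pi_$W_h[2, 2] <- 1
  pi_$W_h[3, 3] <- 1; pi_$b_h <- c(0.5, -0.5, 0)
  d <- c(0.2, -0.1, 0.3, 0.9)
  expect_equal(pooling_scores(d, pi_), c(0.2 + 0.5, -0.1 - 0.5, 0.3),
               tolerance = 1e-9)
  # evaluation mode is deterministic even with delta > 0
  pn <- pooling_params(channels = 4, m = 3, q = 2, delta = 0.3, hidden = 4,
                       exponents = c(1, 2, 4), seed = 2)
  expect_identical(pooling_scores(d, pn), pooling_scores(d, pn))
  expect_error(pooling_scores(c(1, NA, 0, 0), pp), "finite")
})

test_that("TOP-Q weights are a sparse softmax with exact zeros", {
  w <- topq_weights(c(2, 1, 0), 2)
  expect_equal(w, c(exp(2), exp(1), 0) / (exp(2) + exp(1)), tolerance = 1e-12)
  expect_identical(w[3], 0)
  expect_equal(topq_weights(rep(1.3, 4), 4), rep(0.25, 4))
  expect_equal(topq_weights(c(1, 3, 2), 1), c(0, 1, 0))
  set.seed(21)
  for (trial in 1:20) {
    m <- sample(2:8, 1)
    q <- sample(seq_len(m), 1)
    s <- rnorm(m)
    w <- topq_weights(s, q)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_equal(sum(w > 0), q)
    expect_equal(topq_weights(s + 7.3, q), w, tolerance = 1e-12)
  }
  # ties go to the lowest index
  expect_equal(topq_weights(c(1, 1, 1), 1), c(1, 0, 0))
  expect_error(topq_weights(c(1, 2), 3), "q must")
})

test_that("single-branch pooling collapses to plain average pooling", {
  set.seed(4)
  feats <- array(sample(-5:5, 2 * 3 * 4 * 4, replace = TRUE), c(2, 3, 4, 4))
  pp <- pooling_params(channels = 3, m = 1, q = 1, exponents = 1, seed = 1)
  got <- weighted_pool(feats, pp)
  want <- t(apply(feats, 1, function(s) apply(s, 1, mean)))
  expect_identical(got, want)
})

test_that("uniform weights average the branch aggregates", {
  set.seed(5)
  feats <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  pp <- pooling_params(channels = 3, m = 4, q = 4, delta = 0, seed = 1)
  pp$W_h[] <- 0; pp$b_h[] <- 0          # equal scores -> 1/m weights each
  got <- weighted_pool(feats, pp, return_weights = TRUE)
  expect_equal(attr(got, "weights"), matrix(0.25, 2, 4))
  for (s in 1:2) {
    xs <- aperm(feats[s, , , , drop = FALSE], c(3, 4, 2, 1))[, , , 1]
    aggs <- sapply(c(1, 2, 4, 8), function(p) {
      if (p == 1) apply(xs, 3, mean) else apply(abs(xs)^p, 3, mean)^(1 / p)
    })
    expect_equal(got[s, ], rowMeans(aggs), tolerance = 1e-12)
  }
})

test_that("pooling gradients match finite differences", {
  set.seed(3)
  feats <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  pp <- pooling_params(channels = 3, m = 4, q = 2, delta = 0.1, hidden = 5,
                       seed = 2)
  up <- matrix(rnorm(6), 2, 3)
  g <- weighted_pool_grad(feats, pp, up)
  expect_true(all(is.finite(g)))
  eps <- 1e-5
  num <- array(0, dim(feats))
  lossf <- function(xx) sum(weighted_pool(xx, pp) * up)
  for (i in seq_along(feats)) {
    xp <- feats; xp[i] <- xp[i] + eps
    xm <- feats; xm[i] <- xm[i] - eps
    num[i] <- (lossf(xp) - lossf(xm)) / (2 * eps)
  }
  expect_lt(max(abs(g - num)), 1e-4)
})

test_that("balance loss is the scaled usage CV, zero iff uniform", {
  uniform <- matrix(0.25, 8, 4)
  expect_identical(balance_loss(uniform, 1), 0)
  skewed <- matrix(c(1, 0, 0, 0), 8, 4, byrow = TRUE)
  expect_identical(balance_loss(skewed, 0), 0)
  expect_gt(balance_loss(skewed, 0.5), 0)
  # hand-computed case: usages (2, 1, 1)
  w <- matrix(c(0.5, 0.25, 0.25,
                0.5, 0.25, 0.25,
                0.5, 0.25, 0.25,
                0.5, 0.25, 0.25), 4, 3, byrow = TRUE)
  expect_equal(balance_loss(w, 1), 3 * 0.47140452079103173 / (4 / 3),
               tolerance = 1e-9)
  expect_equal(balance_loss(w, 1), 1.0606601717798214, tolerance = 1e-9)
  expect_warning(balance_loss(matrix(0, 3, 2), 1), "zero")
})

test_that("balance-loss gradients match finite differences", {
  set.seed(6)
  w <- matrix(runif(12), 4, 3); w <- w / rowSums(w)
  g <- fundusdr:::balance_loss_grad(w, 0.7)
  eps <- 1e-6
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(g[i], (balance_loss(wp, 0.7) - balance_loss(wm, 0.7)) /
                   (2 * eps), tolerance = 1e-5)
  }
})
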