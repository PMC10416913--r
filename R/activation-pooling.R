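# The trainable pooling components: bounded piecewise-linear activation,
# noisy branch scores, TOP-Q sparse softmax weights, generalized-mean branch
# aggregates, and the branch-usage balance loss.

#' Bounded piecewise-linear activation
#'
#' Elementwise \eqn{f(x) = x/2} for \eqn{-2 \le x < 2}, saturating at
#' \eqn{-1} below \eqn{-2} and \eqn{+1} from \eqn{2} upward. Continuous,
#' nondecreasing and bounded in [-1, 1]; used in place of ReLU throughout
#' the residual blocks and the pre-classifier dense layer.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape as `x`.
#' @export
improved_activation <- function(x) {
  if (anyNA(x)) stop("activation input must be finite", call. = FALSE)
  pmin(pmax(x / 2, -1), 1)
}

# derivative: 1/2 on the linear zone, 0 on the saturated zones
improved_activation_grad <- function(x) {
  0.5 * (x >= -2 & x < 2)
}

softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Pooling branch-score parameters
#'
#' Parameters of the trainable score head that weights the pooling branches:
#' a shared hidden ("prediction") layer mapping the global-average channel
#' descriptor to a latent code, and two linear maps producing per-branch
#' clean scores and noise scales. Branch k aggregates the feature map with
#' the generalized mean of exponent `exponents[k]` (exponent 1 is the plain
#' average; large exponents approach the max).
#'
#' @param channels number of feature-map channels the layer pools.
#' @param m number of branches (default 4).
#' @param q sparsity level: only the `q` best-scoring branches keep nonzero
#'   weight (default 2, `1 <= q <= m`).
#' @param delta nonnegative noise scale applied to the score perturbation
#'   during training (default 0.1).
#' @param hidden width of the shared hidden layer (default 16).
#' @param exponents generalized-mean exponents, length `m`
#'   (default 1, 2, 4, 8).
#' @param init_scale standard deviation of the random initial weights.
#' @param seed integer seed for initialization.
#' @return list of class `pooling_params` with weight matrices `W_p`, `b_p`
#'   (hidden layer), `W_h`, `b_h` (clean scores), `W_m`, `b_m` (noise
#'   scales) plus the hyperparameters.
#' @export
pooling_params <- function(channels, m = 4L, q = 2L, delta = 0.1,
                           hidden = 16L, exponents = c(1, 2, 4, 8),
                           init_scale = 0.1, seed = 1L) {
  m <- as.integer(m); q <- as.integer(q)
  if (q < 1L || q > m) stop("q must satisfy 1 <= q <= m", call. = FALSE)
  if (delta < 0) stop("delta must be nonnegative", call. = FALSE)
  if (length(exponents) != m) stop("need one exponent per branch", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  structure(list(
    channels = as.integer(channels), m = m, q = q, delta = delta,
    hidden = as.integer(hidden), exponents = as.numeric(exponents),
    W_p = matrix(stats::rnorm(hidden * channels, 0, init_scale), hidden, channels),
    b_p = numeric(hidden),
    W_h = matrix(stats::rnorm(m * hidden, 0, init_scale), m, hidden),
    b_h = numeric(m),
    W_m = matrix(stats::rnorm(m * hidden, 0, init_scale), m, hidden),
    b_m = numeric(m)
  ), class = "pooling_params")
}

#' Branch scores from a shared descriptor
#'
#' Computes the per-branch selection scores
#' \eqn{F_k = T^h_k(c) + \delta\,\varepsilon_k\,
#' \mathrm{softplus}(T^m_k(c))}, where \eqn{c} is the shared hidden-layer
#' descriptor, \eqn{T^h} and \eqn{T^m} are the two linear score maps and
#' \eqn{\varepsilon_k} is a standard-normal draw. The noise term is active
#' only during training (it encourages exploration across branches); at
#' evaluation it is dropped so scoring is deterministic.
#'
#' @param descriptor numeric vector of length `params$hidden` (the shared
#'   prediction-layer output).
#' @param params a [pooling_params()].
#' @param training logical; draw score noise?
#' @return numeric vector of `m` scores.
#' @export
pooling_scores <- function(descriptor, params, training = FALSE) {
  stopifnot(inherits(params, "pooling_params"))
  if (anyNA(descriptor) || any(!is.finite(descriptor)))
    stop("descriptor must be finite", call. = FALSE)
  h <- as.vector(params$W_h %*% descriptor + params$b_h)
  if (!training || params$delta == 0) return(h)
  m_raw <- as.vector(params$W_m %*% descriptor + params$b_m)
  h + params$delta * stats::rnorm(params$m) * softplus(m_raw)
}

#' TOP-Q sparse softmax weights
#'
#' Keeps the `q` largest scores and masks the rest to negative infinity
#' before the softmax, so exactly `q` weights are nonzero (bit-exact zeros
#' elsewhere) and the kept weights sum to 1. Ties are broken toward the
#' lowest branch index.
#'
#' @param scores numeric vector of branch scores.
#' @param q number of branches to keep, `1 <= q <= length(scores)`.
#' @return weight vector of the same length, summing to 1.
#' @examples
#' topq_weights(c(2, 1, 0), 2)  # c(e^2, e, 0) / (e^2 + e)
#' @export
topq_weights <- function(scores, q) {
  m <- length(scores)
  q <- as.integer(q)
  if (q < 1L || q > m) stop("q must satisfy 1 <= q <= m", call. = FALSE)
  kept <- order(-scores, seq_len(m))[seq_len(q)]
  w <- numeric(m)
  s <- scores[kept] - max(scores[kept])
  e <- exp(s)
  w[kept] <- e / sum(e)
  w
}

# generalized (power) mean over the spatial grid, per channel.
# x: H x W x C array; returns length-C vector. p = 1 is the plain average;
# p > 1 uses mean(|x|^p)^(1/p).
power_mean <- function(x, p) {
  if (p == 1) return(apply(x, 3, mean))
  apply(abs(x)^p, 3, mean)^(1 / p)
}

# gradient of power_mean wrt x given upstream da (length C)
power_mean_grad <- function(x, p, a, da) {
  hw <- dim(x)[1] * dim(x)[2]
  if (p == 1) {
    g <- array(0, dim(x))
    for (ch in seq_len(dim(x)[3])) g[, , ch] <- da[ch] / hw
    return(g)
  }
  g <- array(0, dim(x))
  for (ch in seq_len(dim(x)[3])) {
    if (a[ch] <= 0) next
    g[, , ch] <- da[ch] * abs(x[, , ch])^(p - 1) * sign(x[, , ch]) *
      a[ch]^(1 - p) / hw
  }
  g
}

# full forward pass of the trainable weighted pooling for one feature-map
# batch. x: H x W x N x C array. Returns pooled N x C matrix plus caches
# needed for the backward pass.
weighted_pool_forward <- function(x, params, training = FALSE) {
  dims <- dim(x)
  stopifnot(length(dims) == 4L, dims[4] == params$channels)
  n <- dims[3]; cc <- dims[4]; m <- params$m
  pooled <- matrix(0, n, cc)
  weights <- matrix(0, n, m)
  caches <- vector("list", n)
  for (s in seq_len(n)) {
    xs <- x[, , s, , drop = FALSE]
    dim(xs) <- dims[c(1, 2, 4)]
    gap <- apply(xs, 3, mean)
    pre_d <- as.vector(params$W_p %*% gap + params$b_p)
    d <- improved_activation(pre_d)
    h <- as.vector(params$W_h %*% d + params$b_h)
    noise <- numeric(m); sp <- numeric(m); m_raw <- numeric(m)
    scores <- h
    if (training && params$delta > 0) {
      m_raw <- as.vector(params$W_m %*% d + params$b_m)
      sp <- softplus(m_raw)
      noise <- stats::rnorm(m)
      scores <- h + params$delta * noise * sp
    }
    w <- topq_weights(scores, params$q)
    aggs <- vapply(seq_len(m),
                   function(k) power_mean(xs, params$exponents[k]),
                   numeric(cc))            # C x m
    pooled[s, ] <- as.vector(aggs %*% w)
    weights[s, ] <- w
    caches[[s]] <- list(xs = xs, gap = gap, pre_d = pre_d, d = d,
                        m_raw = m_raw, sp = sp, noise = noise,
                        w = w, aggs = aggs)
  }
  list(pooled = pooled, weights = weights, caches = caches)
}

# backward pass. dpooled: N x C; dweights: optional N x m extra gradient on
# the branch weights (e.g. from the balance loss). Returns dx plus parameter
# gradients.
weighted_pool_backward <- function(x, params, fwd, dpooled,
                                   dweights = NULL, training = FALSE) {
  dims <- dim(x)
  n <- dims[3]; cc <- dims[4]; m <- params$m
  dx <- array(0, dims)
  gW_p <- params$W_p * 0; gb_p <- params$b_p * 0
  gW_h <- params$W_h * 0; gb_h <- params$b_h * 0
  gW_m <- params$W_m * 0; gb_m <- params$b_m * 0
  for (s in seq_len(n)) {
    ca <- fwd$caches[[s]]
    dp <- dpooled[s, ]
    # pooled = aggs %*% w
    dw <- as.vector(t(ca$aggs) %*% dp)
    if (!is.null(dweights)) dw <- dw + dweights[s, ]
    daggs <- outer(dp, ca$w)               # C x m
    # softmax over the kept set
    kept <- which(ca$w > 0)
    dscores <- numeric(m)
    wk <- ca$w[kept]
    dscores[kept] <- wk * (dw[kept] - sum(wk * dw[kept]))
    # scores -> descriptor
    dd <- as.vector(t(params$W_h) %*% dscores)
    gW_h <- gW_h + outer(dscores, ca$d)
    gb_h <- gb_h + dscores
    if (training && params$delta > 0) {
      dsp <- params$delta * ca$noise * dscores
      dm_raw <- dsp * stats::plogis(ca$m_raw)
      dd <- dd + as.vector(t(params$W_m) %*% dm_raw)
      gW_m <- gW_m + outer(dm_raw, ca$d)
      gb_m <- gb_m + dm_raw
    }
    dpre <- dd * improved_activation_grad(ca$pre_d)
    dgap <- as.vector(t(params$W_p) %*% dpre)
    gW_p <- gW_p + outer(dpre, ca$gap)
    gb_p <- gb_p + dpre
    # feature gradients: branch aggregates + gap descriptor path
    dxs <- array(0, dims[c(1, 2, 4)])
    for (k in seq_len(m)) {
      if (all(daggs[, k] == 0)) next
      dxs <- dxs + power_mean_grad(ca$xs, params$exponents[k],
                                   ca$aggs[, k], daggs[, k])
    }
    hw <- dims[1] * dims[2]
    for (ch in seq_len(cc)) dxs[, , ch] <- dxs[, , ch] + dgap[ch] / hw
    dx[, , s, ] <- dxs
  }
  list(dx = dx, gW_p = gW_p, gb_p = gb_p, gW_h = gW_h, gb_h = gb_h,
       gW_m = gW_m, gb_m = gb_m)
}

#' Trainable TOP-Q weighted pooling
#'
#' Pools a batch of feature maps into one vector per sample: `m` candidate
#' aggregates (generalized means of the spatial grid with the exponents in
#' `params`) are scored by [pooling_scores()] from a shared global-average
#' descriptor, sparsified by [topq_weights()], and combined as the weighted
#' sum of aggregates. With `m = 1` this reduces exactly to global average
#' pooling.
#'
#' @param features numeric array with `N x C x H x W` semantics.
#' @param params a [pooling_params()] with `channels = C`.
#' @param training logical; enables score noise.
#' @param return_weights also return the `N x m` branch-weight matrix.
#' @return `N x C` matrix of pooled descriptors (with a `weights`
#'   attribute when `return_weights = TRUE`).
#' @export
weighted_pool <- function(features, params, training = FALSE,
                          return_weights = FALSE) {
  dims <- dim(features)
  if (length(dims) != 4L) stop("features must be an N x C x H x W array",
                               call. = FALSE)
  x <- aperm(features, c(3, 4, 1, 2))      # -> H x W x N x C
  fwd <- weighted_pool_forward(x, params, training)
  out <- fwd$pooled
  if (return_weights) attr(out, "weights") <- fwd$weights
  out
}

#' Gradient of the weighted pooling with respect to its features
#'
#' Analytic backward pass matching [weighted_pool()]; mainly used to verify
#' the layer against finite differences and to drive training.
#'
#' @param features `N x C x H x W` array.
#' @param params a [pooling_params()].
#' @param upstream `N x C` matrix of gradients on the pooled output.
#' @param training logical (must match the forward pass; noise is
#'   deterministic only when `FALSE`).
#' @return `N x C x H x W` array of feature gradients.
#' @export
weighted_pool_grad <- function(features, params, upstream, training = FALSE) {
  x <- aperm(features, c(3, 4, 1, 2))
  fwd <- weighted_pool_forward(x, params, training)
  bwd <- weighted_pool_backward(x, params, fwd, upstream, training = training)
  aperm(bwd$dx, c(3, 4, 1, 2))
}

#' Branch-usage balance loss
#'
#' Penalizes collapse of the TOP-Q gate onto few branches: with per-branch
#' usage \eqn{u_k = \sum_s w_k(Y_s)} over a mini-batch, the loss is
#' \eqn{3\beta \cdot S(u) / M(u)} — three times `beta` times the
#' coefficient of variation (population standard deviation over mean) of
#' the usages. Zero exactly when every branch is used equally.
#'
#' @param weights `N x m` matrix of branch weights, each row summing to 1.
#' @param beta nonnegative loss coefficient.
#' @return scalar loss.
#' @export
balance_loss <- function(weights, beta) {
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (beta == 0) return(0)
  u <- colSums(weights)
  mu <- mean(u)
  if (mu == 0) {
    warning("all branch usages are zero", call. = FALSE)
    return(0)
  }
  s <- sqrt(mean((u - mu)^2))
  3 * beta * s / mu
}

# gradient of balance_loss wrt the weight matrix (same for every row):
# d(3b s/mu)/du_k = 3b [ (u_k - mu)/(m s mu) - s/(m mu^2) ]
balance_loss_grad <- function(weights, beta) {
  n <- nrow(weights); m <- ncol(weights)
  g <- matrix(0, n, m)
  if (beta == 0) return(g)
  u <- colSums(weights)
  mu <- mean(u)
  s <- sqrt(mean((u - mu)^2))
  if (mu == 0 || s < 1e-12) return(g)
  du <- 3 * beta * ((u - mu) / (m * s * mu) - s / (m * mu^2))
  matrix(du, n, m, byrow = TRUE)
}
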