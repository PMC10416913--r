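# Minimal CNN framework: convolution (im2col), dense, activation, dropout
# and residual-block layers with hand-written backward passes, assembled
# into a residual grading network whose global pooling is the trainable
# TOP-Q weighted pool. Internal tensor layout is H x W x N x C: with the
# channel index outermost, the im2col patch matrix and its transpose
# scatter are plain reshapes, with no array permutations on the hot path.

# variance-preserving init for the x/2-slope bounded activation: the slope
# 1/2 quarters the variance per layer, so the weight variance is 4/fan_in
he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(4 / fan_in))

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

layer_conv <- function(cin, cout, kernel = 3L, stride = 1L) {
  k <- as.integer(kernel)
  W <- matrix(he_init(k * k * cin * cout, k * k * cin), k * k * cin, cout)
  new_layer("conv", cin = cin, cout = cout, k = k, stride = as.integer(stride),
            W = W, b = numeric(cout),
            vW = W * 0, vb = numeric(cout))
}

layer_dense <- function(din, dout) {
  W <- matrix(he_init(din * dout, din), din, dout)
  new_layer("dense", din = din, dout = dout, W = W, b = numeric(dout),
            vW = W * 0, vb = numeric(dout))
}

layer_act <- function() new_layer("act")
layer_dropout <- function(rate) new_layer("dropout", rate = rate)

layer_resblock <- function(channels, kernel = 3L) {
  new_layer("resblock",
            conv1 = layer_conv(channels, channels, kernel),
            conv2 = layer_conv(channels, channels, kernel))
}

layer_pool <- function(channels, pooling) {
  p <- do.call(pooling_params,
               c(list(channels = channels), pooling))
  new_layer("pool", params = p,
            vW_p = p$W_p * 0, vb_p = p$b_p * 0,
            vW_h = p$W_h * 0, vb_h = p$b_h * 0,
            vW_m = p$W_m * 0, vb_m = p$b_m * 0)
}

# ---- convolution via im2col -------------------------------------------------

# Patch matrix layout: rows run over (row, col, sample) of the output grid,
# columns over (channel within offset, offset). One block of C columns per
# kernel offset keeps the extraction/scatter loops at k^2 iterations.
im2col <- function(x, k, stride) {
  d <- dim(x)                               # H, W, N, C
  pad <- (k - 1L) %/% 2L
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  xp <- array(0, c(hp, wp, d[3], d[4]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
  h_out <- (d[1] + 2L * pad - k) %/% stride + 1L
  w_out <- (d[2] + 2L * pad - k) %/% stride + 1L
  rb <- seq(1L, by = stride, length.out = h_out)
  cb <- seq(1L, by = stride, length.out = w_out)
  nrows <- h_out * w_out * d[3]
  cols <- matrix(0, nrows, k * k * d[4])
  j <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    block <- xp[rb + dr, cb + dc, , , drop = FALSE]
    dim(block) <- c(nrows, d[4])
    cols[, j + seq_len(d[4])] <- block
    j <- j + d[4]
  }
  list(cols = cols, h_out = h_out, w_out = w_out, rb = rb, cb = cb,
       pad = pad, dims = d)
}

col2im <- function(dcols, meta, k, stride) {
  d <- meta$dims
  pad <- meta$pad
  dxp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  j <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    block <- dcols[, j + seq_len(d[4]), drop = FALSE]
    dim(block) <- c(meta$h_out, meta$w_out, d[3], d[4])
    dxp[meta$rb + dr, meta$cb + dc, , ] <-
      dxp[meta$rb + dr, meta$cb + dc, , , drop = FALSE] + block
    j <- j + d[4]
  }
  dxp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , , drop = FALSE]
}

conv_forward <- function(ly, x) {
  meta <- im2col(x, ly$k, ly$stride)
  out <- sweep(meta$cols %*% ly$W, 2L, ly$b, "+")
  n <- dim(x)[3]
  y <- array(out, c(meta$h_out, meta$w_out, n, ly$cout))
  list(y = y, cache = meta)
}

conv_backward <- function(ly, cache, dy) {
  n <- dim(dy)[3]
  dmat <- dy
  dim(dmat) <- c(cache$h_out * cache$w_out * n, ly$cout)
  ly$gW <- crossprod(cache$cols, dmat)
  ly$gb <- colSums(dmat)
  dcols <- tcrossprod(dmat, ly$W)
  col2im(dcols, cache, ly$k, ly$stride)
}

# ---- forward / backward over the layer list ---------------------------------

layer_forward <- function(ly, x, training, rng_noise) {
  switch(ly$type,
    conv = conv_forward(ly, x),
    act = list(y = improved_activation(x), cache = x),
    dropout = {
      if (training && ly$rate > 0) {
        mask <- array(stats::rbinom(length(x), 1L, 1 - ly$rate) /
                        (1 - ly$rate), dim(x))
        list(y = x * mask, cache = mask)
      } else list(y = x, cache = NULL)
    },
    dense = {
      y <- sweep(x %*% ly$W, 2L, ly$b, "+")
      list(y = y, cache = x)
    },
    resblock = {
      f1 <- conv_forward(ly$conv1, x)
      a1 <- improved_activation(f1$y)
      f2 <- conv_forward(ly$conv2, a1)
      pre <- x + f2$y
      list(y = improved_activation(pre),
           cache = list(f1 = f1, a1_pre = f1$y, f2 = f2, pre = pre))
    },
    pool = {
      fwd <- weighted_pool_forward(x, ly$params, training)
      list(y = fwd$pooled, cache = list(x = x, fwd = fwd))
    },
    stop("unknown layer type: ", ly$type)
  )
}

layer_backward <- function(ly, cache, dy, training, dweights = NULL) {
  switch(ly$type,
    conv = conv_backward(ly, cache, dy),
    act = dy * improved_activation_grad(cache),
    dropout = if (is.null(cache)) dy else dy * cache,
    dense = {
      ly$gW <- crossprod(cache, dy)
      ly$gb <- colSums(dy)
      tcrossprod(dy, ly$W)
    },
    resblock = {
      dpre <- dy * improved_activation_grad(cache$pre)
      da1 <- conv_backward(ly$conv2, cache$f2$cache, dpre)
      df1 <- da1 * improved_activation_grad(cache$a1_pre)
      dx <- conv_backward(ly$conv1, cache$f1$cache, df1)
      dx + dpre
    },
    pool = {
      bwd <- weighted_pool_backward(cache$x, ly$params, cache$fwd, dy,
                                    dweights = dweights, training = training)
      ly$g <- bwd[-1]
      bwd$dx
    }
  )
}

# ---- model ------------------------------------------------------------------

#' Grading network configuration
#'
#' @param depth `"tiny"` (3 residual blocks, 16/32/64 channels, 64x64
#'   inputs — sized so training runs on one CPU core in minutes) or
#'   `"resnet50"` (the full bottleneck 3-4-6-3 stack at 225x225).
#' @param input_size spatial input edge length; defaults to 64 for the tiny
#'   preset and 225 for resnet50.
#' @param n_classes number of severity grades (default 5).
#' @param dropout dropout rate before the classifier head (default 0.2).
#' @param kernel_size convolution kernel edge (default 3).
#' @param batch_size minibatch size (default 64).
#' @param epochs training epochs (default 1000).
#' @param learning_rate SGD step size (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param beta balance-loss coefficient (default 0.1).
#' @param pooling list of overrides for [pooling_params()] (m, q, delta,
#'   hidden, exponents).
#' @param seed integer seed for weight initialization.
#' @return list of class `model_config`.
#' @export
model_config <- function(depth = c("tiny", "resnet50"), input_size = NULL,
                         n_classes = 5L, dropout = 0.2, kernel_size = 3L,
                         batch_size = 64L, epochs = 1000L,
                         learning_rate = 0.001, momentum = 0.9,
                         beta = 0.1, pooling = list(), seed = 1L) {
  depth <- match.arg(depth)
  if (is.null(input_size)) input_size <- if (depth == "tiny") 64L else 225L
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  structure(list(depth = depth, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 kernel_size = as.integer(kernel_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 beta = beta, pooling = pooling, seed = as.integer(seed)),
            class = "model_config")
}

#' Build the grading network
#'
#' Assembles a residual CNN whose global pooling is the trainable TOP-Q
#' weighted pool, whose activations are the bounded piecewise-linear
#' activation, followed by a dense layer, dropout and a softmax head over
#' the severity grades. The `"tiny"` preset uses three residual blocks at
#' 16, 32 and 64 channels with stride-2 transitions from a 64x64 input;
#' `"resnet50"` assembles the full 3-4-6-3 bottleneck-free analogue at
#' 225x225 (deep preset, not intended for CPU-scale training).
#'
#' @param cfg a [model_config()].
#' @return list of class `grading_model` with the layer list and config.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  k <- cfg$kernel_size
  layers <- list()
  if (cfg$depth == "tiny") {
    widths <- c(16L, 32L, 64L)
    blocks_per <- 1L
  } else {
    widths <- c(64L, 128L, 256L, 512L)
    blocks_per <- 3L          # 3-4-6-3 compressed to uniform depth per stage
  }
  cin <- 1L
  for (w in widths) {
    layers <- c(layers, list(layer_conv(cin, w, k, stride = 2L), layer_act()))
    for (b in seq_len(blocks_per))
      layers <- c(layers, list(layer_resblock(w, k)))
    cin <- w
  }
  layers <- c(layers, list(layer_pool(cin, cfg$pooling)))
  head_width <- max(32L, cin %/% 2L)
  layers <- c(layers,
              list(layer_dense(cin, head_width), layer_act(),
                   layer_dropout(cfg$dropout),
                   layer_dense(head_width, cfg$n_classes)))
  structure(list(layers = layers, config = cfg, classes = DR_GRADES[seq_len(cfg$n_classes)]),
            class = "grading_model")
}

# run the network. x: H x W x 1 x N array (intensities already scaled to
# [0, 1] and centred). Returns logits plus per-layer caches and the branch
# weights from the pooling layer.
model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  pool_weights <- NULL
  for (i in seq_along(model$layers)) {
    f <- layer_forward(model$layers[[i]], x, training, NULL)
    caches[[i]] <- f$cache
    x <- f$y
    if (model$layers[[i]]$type == "pool") pool_weights <- f$cache$fwd$weights
  }
  list(logits = x, caches = caches, pool_weights = pool_weights)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# stack a list of grayscale matrices into the centred H x W x N x 1 input
prepare_batch <- function(images, size) {
  n <- length(images)
  x <- array(0, c(size, size, n, 1L))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (!all(dim(im) == c(size, size))) im <- resize_image(im, size, size)
    x[, , i, 1L] <- im / 255 - 0.5
  }
  x
}

#' Forward predictions of the grading network
#'
#' @param model a [build_model()] network (typically after [train_network()]).
#' @param images list of grayscale matrices on the 0-255 scale (resized to
#'   the model input size as needed).
#' @return list with `probabilities` (N x n_classes matrix) and `labels`
#'   (character grades).
#' @export
predict_network <- function(model, images) {
  stopifnot(inherits(model, "grading_model"))
  x <- prepare_batch(images, model$config$input_size)
  logits <- model_forward(model, x, training = FALSE)$logits
  p <- softmax_rows(logits)
  colnames(p) <- model$classes
  list(probabilities = p,
       labels = model$classes[max.col(p, ties.method = "first")])
}

#' Penultimate-layer feature vectors
#'
#' Extracts the activations of the dense layer preceding the classifier
#' head; these are the feature vectors consumed by the improved-SVM head.
#'
#' @param model a `grading_model`.
#' @param images list of grayscale matrices, 0-255 scale.
#' @return N x d feature matrix.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "grading_model"))
  x <- prepare_batch(images, model$config$input_size)
  # forward up to (and including) the activation after the first dense layer
  stop_at <- length(model$layers) - 2L      # before dropout + final dense
  for (i in seq_len(stop_at)) {
    f <- layer_forward(model$layers[[i]], x, FALSE, NULL)
    x <- f$y
  }
  x
}

# SGD + momentum update for every parameterized layer, from gradients left
# on the layer environments by the backward pass.
sgd_step <- function(model, lr, momentum) {
  upd <- function(ly) {
    if (ly$type %in% c("conv", "dense")) {
      ly$vW <- momentum * ly$vW - lr * ly$gW
      ly$vb <- momentum * ly$vb - lr * ly$gb
      ly$W <- ly$W + ly$vW
      ly$b <- ly$b + ly$vb
    } else if (ly$type == "resblock") {
      upd(ly$conv1); upd(ly$conv2)
    } else if (ly$type == "pool") {
      p <- ly$params
      for (nm in c("W_p", "b_p", "W_h", "b_h", "W_m", "b_m")) {
        v <- paste0("v", nm)
        assign(v, momentum * get(v, envir = ly) - lr * ly$g[[paste0("g", nm)]],
               envir = ly)
        p[[nm]] <- p[[nm]] + get(v, envir = ly)
      }
      ly$params <- p
    }
  }
  for (ly in model$layers) upd(ly)
  invisible(model)
}

#' Train the grading network
#'
#' Minimizes cross-entropy plus the branch-usage [balance_loss()] by
#' minibatch stochastic gradient descent with momentum. Deterministic for a
#' given `seed`: shuffling, dropout masks and pooling score noise all draw
#' from the one seeded stream.
#'
#' @param model a [build_model()] network; updated in place (layer
#'   parameters live in environments) and also returned.
#' @param images list of grayscale matrices, 0-255 scale.
#' @param labels character vector of grades (subset of the model's classes).
#' @param epochs,batch_size,learning_rate,momentum optional overrides of the
#'   model config.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return the model, with a `history` data.frame (epoch, loss,
#'   cross_entropy, balance, accuracy, usage_cv) attached as
#'   `model$history`.
#' @export
train_network <- function(model, images, labels, epochs = NULL,
                          batch_size = NULL, learning_rate = NULL,
                          momentum = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "grading_model"))
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  if (length(images) != length(labels))
    stop("images and labels must have equal length", call. = FALSE)
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  mom <- if (is.null(momentum)) cfg$momentum else momentum
  y <- match(labels, model$classes)
  if (anyNA(y)) stop("labels must be among: ",
                     paste(model$classes, collapse = ", "), call. = FALSE)
  x_all <- prepare_batch(images, cfg$input_size)
  n <- length(images)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  pool_idx <- which(vapply(model$layers, function(l) l$type, "") == "pool")
  n_branches <- model$layers[[pool_idx]]$params$m
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     cross_entropy = numeric(), balance = numeric(),
                     accuracy = numeric(), usage_cv = numeric())
  for (ep in seq_len(epochs)) {
    perm <- sample(n)
    ep_ce <- 0; ep_bal <- 0; ep_correct <- 0
    usage <- numeric(n_branches)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- x_all[, , idx, , drop = FALSE]
      yb <- y[idx]
      fw <- model_forward(model, xb, training = TRUE)
      p <- softmax_rows(fw$logits)
      nb <- length(idx)
      ce <- -mean(log(pmax(p[cbind(seq_len(nb), yb)], 1e-12)))
      bal <- balance_loss(fw$pool_weights, cfg$beta)
      ep_ce <- ep_ce + ce * nb
      ep_bal <- ep_bal + bal * nb
      ep_correct <- ep_correct + sum(max.col(p, ties.method = "first") == yb)
      usage <- usage + colSums(fw$pool_weights)
      # backward
      dy <- p
      dy[cbind(seq_len(nb), yb)] <- dy[cbind(seq_len(nb), yb)] - 1
      dy <- dy / nb
      dweights <- balance_loss_grad(fw$pool_weights, cfg$beta)
      for (i in rev(seq_along(model$layers))) {
        ly <- model$layers[[i]]
        dy <- layer_backward(ly, fw$caches[[i]], dy, TRUE,
                             dweights = if (ly$type == "pool") dweights)
      }
      sgd_step(model, lr, mom)
    }
    ucv <- if (mean(usage) > 0)
      sqrt(mean((usage - mean(usage))^2)) / mean(usage) else 0
    hist <- rbind(hist, data.frame(
      epoch = ep, loss = (ep_ce + ep_bal) / n, cross_entropy = ep_ce / n,
      balance = ep_bal / n, accuracy = ep_correct / n, usage_cv = ucv))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  usage CV %.3f",
                      ep, (ep_ce + ep_bal) / n, ep_correct / n, ucv))
  }
  model$history <- hist
  model
}
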