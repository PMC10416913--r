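# Multiclass linear SVM head: linear scoring of extracted feature vectors,
# Crammer-Singer hinge training by epoch-wise subgradient descent, argmax
# prediction with a fixed severity-order tie break.

#' Construct an SVM model
#'
#' @param weights n_classes x d matrix of per-class weight vectors.
#' @param biases length n_classes vector.
#' @param classes class labels, in tie-break order.
#' @return list of class `svm_model`.
#' @export
svm_model <- function(weights, biases, classes = DR_GRADES) {
  if (!is.matrix(weights) || nrow(weights) != length(biases) ||
      nrow(weights) != length(classes))
    stop("weights must be an n_classes x d matrix matching biases/classes",
         call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)) || any(!is.finite(biases)))
    stop("model parameters must be finite", call. = FALSE)
  structure(list(weights = weights, biases = biases, classes = classes),
            class = "svm_model")
}

#' Per-class linear scores
#'
#' \eqn{s_c = w_c \cdot p + b_c} for each class. `features` may be a single
#' vector or an N x d matrix.
#'
#' @param features feature vector of length d, or N x d matrix.
#' @param model an [svm_model()].
#' @return named score vector (or N x n_classes matrix).
#' @export
svm_scores <- function(features, model) {
  stopifnot(inherits(model, "svm_model"))
  if (is.vector(features)) features <- matrix(features, 1L)
  if (ncol(features) != ncol(model$weights))
    stop("feature length does not match the model", call. = FALSE)
  s <- sweep(features %*% t(model$weights), 2L, model$biases, "+")
  colnames(s) <- model$classes
  if (nrow(s) == 1L) return(drop(s))
  s
}

#' Predict severity grades from features
#'
#' Argmax of [svm_scores()]; exact ties go to the class earliest in the
#' model's class order (severity order NoDR < Mild < Moderate < Severe <
#' PDR by default).
#'
#' @param features feature vector or N x d matrix.
#' @param model an [svm_model()].
#' @return character vector of predicted grades.
#' @export
svm_predict <- function(features, model) {
  s <- svm_scores(features, model)
  if (is.vector(s)) s <- matrix(s, 1L)
  model$classes[max.col(s, ties.method = "first")]
}

#' Train the multiclass linear SVM head
#'
#' Minimizes the Crammer-Singer multiclass hinge loss with margin 1,
#' \eqn{\max_{c \ne y}(0, 1 + s_c - s_y)}, plus an L2 penalty
#' \eqn{\lambda/2 \|W\|^2}, by full-batch subgradient descent over `epochs`
#' passes. Deterministic given `seed` (used only for the initial weights).
#'
#' @param features N x d matrix of feature vectors.
#' @param labels character grades, at least two distinct classes.
#' @param classes class order (default the five severity grades).
#' @param epochs number of subgradient passes M (default 200).
#' @param learning_rate step size (default 0.1).
#' @param lambda L2 regularization strength (default 1e-4).
#' @param seed integer seed.
#' @return an [svm_model()] with a `loss_trace` attribute (regularized
#'   hinge loss per epoch).
#' @export
train_improved_svm <- function(features, labels, classes = DR_GRADES,
                               epochs = 200L, learning_rate = 0.1,
                               lambda = 1e-4, seed = 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (length(unique(labels)) < 2L)
    stop("training requires at least two classes", call. = FALSE)
  if (!all(labels %in% classes))
    stop("labels outside the class set", call. = FALSE)
  stopifnot(epochs >= 1L, learning_rate > 0)
  n <- nrow(features); d <- ncol(features); k <- length(classes)
  y <- match(labels, classes)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W <- matrix(stats::rnorm(k * d, 0, 0.01), k, d)
  b <- numeric(k)

  trace <- numeric(epochs)
  iy <- cbind(seq_len(n), y)
  for (ep in seq_len(epochs)) {
    s <- sweep(features %*% t(W), 2L, b, "+")       # N x k
    margins <- s - s[iy] + 1
    margins[iy] <- -Inf
    viol <- max.col(margins, ties.method = "first")
    vmax <- margins[cbind(seq_len(n), viol)]
    active <- vmax > 0
    trace[ep] <- mean(pmax(vmax, 0)) + lambda / 2 * sum(W^2)
    # subgradient: +x on the worst violating class, -x on the true class
    G <- matrix(0, n, k)
    G[cbind(which(active), viol[active])] <- 1
    G[cbind(which(active), y[active])] <- -1
    dW <- t(G) %*% features / n + lambda * W
    db <- colSums(G) / n
    W <- W - learning_rate * dW
    b <- b - learning_rate * db
  }
  out <- svm_model(W, b, classes)
  attr(out, "loss_trace") <- trace
  out
}

#' Serialize / load an SVM model as JSON
#'
#' @param model an [svm_model()].
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(list(weights = model$weights, biases = model$biases,
                            classes = model$classes),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  svm_model(o$weights, o$biases, o$classes)
}
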