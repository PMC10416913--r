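#' Artificial bee colony configuration
#'
#' Hyperparameters of the artificial bee colony (ABC) search over the beta
#' transform shapes (c, d). The identity transform (1, 1) is always seeded
#' into the initial colony when it lies inside the bounds, so the optimizer
#' can never do worse than leaving the image untouched.
#'
#' @param colony_size number of food sources (>= 2). Default 20.
#' @param scout_limit trials without improvement before a source is
#'   abandoned and re-scouted. Default 10.
#' @param max_cycles number of employed/onlooker/scout cycles. Default 30.
#' @param c_bounds,d_bounds closed positive search intervals. Default
#'   c(0.5, 10).
#' @param seed integer RNG seed used by [abc_optimize()].
#' @return list of class `abc_config`.
#' @export
abc_config <- function(colony_size = 20L, scout_limit = 10L, max_cycles = 30L,
                       c_bounds = c(0.5, 10), d_bounds = c(0.5, 10),
                       seed = 1L) {
  colony_size <- as.integer(colony_size)
  if (colony_size < 2L) stop("colony_size must be at least 2", call. = FALSE)
  stopifnot(length(c_bounds) == 2L, length(d_bounds) == 2L,
            c_bounds[1] > 0, d_bounds[1] > 0,
            c_bounds[1] <= c_bounds[2], d_bounds[1] <= d_bounds[2],
            scout_limit >= 1L, max_cycles >= 1L)
  structure(list(colony_size = colony_size,
                 scout_limit = as.integer(scout_limit),
                 max_cycles = as.integer(max_cycles),
                 c_bounds = as.numeric(c_bounds),
                 d_bounds = as.numeric(d_bounds),
                 seed = as.integer(seed)),
            class = "abc_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Select beta-transform shapes by artificial bee colony search
#'
#' Standard ABC (employed bees, fitness-proportional onlooker bees, scout
#' replacement after `scout_limit` stale trials) over the two-dimensional
#' (c, d) space, maximizing [compute_fitness()] of the transformed image.
#' Deterministic for a given `cfg$seed`. The best fitness over the run is
#' never below that of any initial food source, and (1, 1) is one of them
#' whenever the bounds allow, so the returned transform never scores below
#' the identity.
#'
#' @param img grayscale matrix to enhance.
#' @param cfg an [abc_config()].
#' @param fitness_args extra arguments passed to [compute_fitness()].
#' @return list of class `abc_result` with `c`, `d`, `fitness`,
#'   `report` (fitness report of the best transform) and `trace`
#'   (best-so-far fitness per cycle, nondecreasing).
#' @export
abc_optimize <- function(img, cfg = abc_config(), fitness_args = list()) {
  check_gray_image(img)
  stopifnot(inherits(cfg, "abc_config"))
  n <- cfg$colony_size
  lo <- c(cfg$c_bounds[1], cfg$d_bounds[1])
  hi <- c(cfg$c_bounds[2], cfg$d_bounds[2])

  eval_fit <- function(p) {
    rep <- do.call(compute_fitness,
                   c(list(img = beta_transform(img, p[1], p[2])), fitness_args))
    rep$fitness
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  # initial food sources; identity transform included when inside bounds
  pos <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
  if (all(lo <= 1) && all(hi >= 1)) pos[1, ] <- c(1, 1)
  fit <- apply(pos, 1, eval_fit)
  trials <- integer(n)

  best_i <- which.max(fit)
  best_p <- pos[best_i, ]
  best_f <- fit[best_i]
  trace <- numeric(cfg$max_cycles)

  try_move <- function(i) {
    k <- sample(setdiff(seq_len(n), i), 1L)
    j <- sample(1:2, 1L)
    cand <- pos[i, ]
    cand[j] <- clamp(cand[j] + stats::runif(1, -1, 1) * (pos[i, j] - pos[k, j]),
                     lo[j], hi[j])
    f <- eval_fit(cand)
    if (f > fit[i]) {
      pos[i, ] <<- cand; fit[i] <<- f; trials[i] <<- 0L
    } else trials[i] <<- trials[i] + 1L
  }

  for (cycle in seq_len(cfg$max_cycles)) {
    for (i in seq_len(n)) try_move(i)                       # employed bees
    # onlookers: fitness-proportional selection on shifted fitness
    w <- fit - min(fit) + 1e-12
    picks <- sample(seq_len(n), n, replace = TRUE, prob = w / sum(w))
    for (i in picks) try_move(i)
    # scouts
    stale <- which(trials >= cfg$scout_limit)
    for (i in stale) {
      pos[i, ] <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      fit[i] <- eval_fit(pos[i, ])
      trials[i] <- 0L
    }
    if (max(fit) > best_f) {
      best_i <- which.max(fit); best_f <- fit[best_i]; best_p <- pos[best_i, ]
    }
    trace[cycle] <- best_f
  }

  report <- do.call(compute_fitness,
                    c(list(img = beta_transform(img, best_p[1], best_p[2])),
                      fitness_args))
  structure(list(c = best_p[1], d = best_p[2], fitness = best_f,
                 report = report, trace = trace),
            class = "abc_result")
}

#' Enhance a fundus image
#'
#' Convenience composition: run [abc_optimize()] to pick (c, d), apply
#' [beta_transform()], and report the fitness of the result. RGB inputs are
#' enhanced on one channel — by default the green channel, which carries the
#' highest vessel/lesion contrast in fundus photography — with the other
#' channels passed through.
#'
#' @param img grayscale matrix or RGB array on the 0-255 scale.
#' @param cfg an [abc_config()].
#' @param channel for RGB inputs, `"green"` (default) enhances the green
#'   plane; `"luminance"` enhances the luma plane and rescales all three
#'   channels by the luma gain.
#' @param fitness_args extra arguments passed to [compute_fitness()].
#' @return list with `image` (enhanced, same dimensions as input), `params`
#'   (list with c, d), and `report` (fitness report).
#' @export
enhance <- function(img, cfg = abc_config(), channel = c("green", "luminance"),
                    fitness_args = list()) {
  channel <- match.arg(channel)
  if (is_rgb_image(img)) {
    if (channel == "green") {
      res <- enhance(img[, , 2], cfg, fitness_args = fitness_args)
      out <- img
      out[, , 2] <- res$image
      return(list(image = out, params = res$params, report = res$report))
    }
    luma <- to_gray(img)
    res <- enhance(luma, cfg, fitness_args = fitness_args)
    gain <- (res$image + 1) / (luma + 1)
    out <- img
    for (ch in 1:3) out[, , ch] <- quantize_gray(img[, , ch] * gain)
    return(list(image = out, params = res$params, report = res$report))
  }
  opt <- abc_optimize(img, cfg, fitness_args = fitness_args)
  enh <- beta_transform(img, opt$c, opt$d)
  list(image = enh, params = list(c = opt$c, d = opt$d), report = opt$report)
}
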