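# Seeded generator of schematic graded fundus images: a bright circular
# retina disc on a dark background, a dendritic dark vessel tree, and
# grade-dependent lesions (dark microaneurysm dots, larger dark haemorrhage
# blobs, bright irregular exudate patches). The goal is a five-way
# separable image distribution with fundus-like structure, not clinical
# realism.

#' Synthetic fundus generator configuration
#'
#' Lesion count ranges grow monotonically with severity so the grades are
#' statistically separable; NoDR images carry no lesions at all.
#'
#' @param size image edge length in pixels (default 128).
#' @param disc_intensity background retina-disc intensity (default 140).
#' @param vessel_count number of primary vessel branches (default 6).
#' @param vessel_width vessel stroke half-width in pixels (default 1.5).
#' @param micro_range,hemorrhage_range,exudate_range 5 x 2 matrices of
#'   per-grade lesion count ranges (rows NoDR..PDR, columns min/max);
#'   sensible monotone defaults are built in.
#' @param noise_sd additive Gaussian pixel noise (default 3).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(size = 128L, disc_intensity = 140,
                         vessel_count = 6L, vessel_width = 1.5,
                         micro_range = NULL, hemorrhage_range = NULL,
                         exudate_range = NULL, noise_sd = 3) {
  default_ranges <- function(r) matrix(r, 5, 2, byrow = TRUE)
  if (is.null(micro_range))
    micro_range <- default_ranges(c(0, 0, 2, 4, 6, 10, 12, 18, 20, 28))
  if (is.null(hemorrhage_range))
    hemorrhage_range <- default_ranges(c(0, 0, 0, 1, 2, 4, 5, 8, 9, 14))
  if (is.null(exudate_range))
    exudate_range <- default_ranges(c(0, 0, 0, 1, 1, 3, 4, 7, 8, 12))
  for (r in list(micro_range, hemorrhage_range, exudate_range)) {
    if (any(diff(r[, 1]) < 0) || any(diff(r[, 2]) < 0))
      stop("lesion count ranges must be nondecreasing in grade", call. = FALSE)
  }
  structure(list(size = as.integer(size), disc_intensity = disc_intensity,
                 vessel_count = as.integer(vessel_count),
                 vessel_width = vessel_width,
                 micro_range = micro_range,
                 hemorrhage_range = hemorrhage_range,
                 exudate_range = exudate_range,
                 noise_sd = noise_sd),
            class = "synth_config")
}

# stamp a filled disc of given radius and intensity delta, feathered edge
stamp_blob <- function(img, r0, c0, radius, delta, inside) {
  n <- nrow(img)
  rs <- max(1, floor(r0 - radius - 1)):min(n, ceiling(r0 + radius + 1))
  cs <- max(1, floor(c0 - radius - 1)):min(ncol(img), ceiling(c0 + radius + 1))
  dd <- outer(rs - r0, cs - c0, function(a, b) sqrt(a^2 + b^2))
  w <- pmax(0, pmin(1, radius + 0.5 - dd))
  img[rs, cs] <- img[rs, cs] + delta * w * inside[rs, cs]
  img
}

# draw a jagged dark vessel branch as a random walk of short strokes
draw_vessel <- function(img, r0, c0, angle, len, width, inside, depth = 0) {
  n <- nrow(img)
  r <- r0; c <- c0; a <- angle
  for (step in seq_len(len)) {
    a <- a + stats::rnorm(1, 0, 0.25)
    r2 <- r + 2.2 * sin(a)
    c2 <- c + 2.2 * cos(a)
    t <- seq(0, 1, length.out = 4)
    for (tt in t) {
      rr <- r + tt * (r2 - r); cc <- c + tt * (c2 - c)
      img <- stamp_blob(img, rr, cc, width, -45, inside)
    }
    r <- r2; c <- c2
    if (r < 2 || r > n - 1 || c < 2 || c > n - 1) break
    if (depth < 2 && stats::runif(1) < 0.06) {
      img <- draw_vessel(img, r, c, a + sample(c(-1, 1), 1) * 0.7,
                         max(4L, len %/% 2L), width * 0.75, inside,
                         depth + 1)
    }
  }
  img
}

#' Generate one synthetic graded fundus image
#'
#' Deterministic given `seed`. Returns the image together with a lesion
#' ledger (true counts by type) so downstream learnability checks have
#' ground truth.
#'
#' @param grade one of the five severity grades.
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `image` (grayscale matrix, 0-255), `grade`, and
#'   `lesions` (named counts: micro, hemorrhage, exudate).
#' @export
generate_fundus <- function(grade, cfg = synth_config(), seed = 1L) {
  gi <- match(grade, DR_GRADES)
  if (is.na(gi)) stop("unknown grade: ", grade, call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n <- cfg$size
  centre <- (n + 1) / 2
  radius <- n * 0.46
  dist <- outer(seq_len(n) - centre, seq_len(n) - centre,
                function(a, b) sqrt(a^2 + b^2))
  inside <- dist <= radius
  # retina disc with gentle radial falloff over a dark surround
  img <- matrix(8, n, n)
  img[inside] <- cfg$disc_intensity * (1 - 0.35 * (dist[inside] / radius)^2)
  # optic-disc-like bright region near the nasal side
  od_r <- centre + stats::rnorm(1, 0, n * 0.03)
  od_c <- centre + n * 0.28 + stats::rnorm(1, 0, n * 0.02)
  img <- stamp_blob(img, od_r, od_c, n * 0.07, 55, inside)

  # vessel tree fanning out from the optic-disc region
  for (v in seq_len(cfg$vessel_count)) {
    ang <- pi + (v - 1) * 2 * pi / cfg$vessel_count + stats::rnorm(1, 0, 0.2)
    img <- draw_vessel(img, od_r, od_c, ang, len = as.integer(n * 0.35),
                       width = cfg$vessel_width, inside = inside)
  }

  draw_count <- function(rng) {
    lo <- rng[gi, 1]; hi <- rng[gi, 2]
    if (hi <= 0) 0L else sample(lo:hi, 1L)
  }
  counts <- c(micro = draw_count(cfg$micro_range),
              hemorrhage = draw_count(cfg$hemorrhage_range),
              exudate = draw_count(cfg$exudate_range))
  rand_pos <- function() {
    repeat {
      r <- stats::runif(1, centre - radius * 0.85, centre + radius * 0.85)
      c <- stats::runif(1, centre - radius * 0.85, centre + radius * 0.85)
      if (dist[round(r), round(c)] <= radius * 0.88) return(c(r, c))
    }
  }
  for (i in seq_len(counts["micro"])) {
    p <- rand_pos()
    img <- stamp_blob(img, p[1], p[2], stats::runif(1, 1, 1.8), -60, inside)
  }
  for (i in seq_len(counts["hemorrhage"])) {
    p <- rand_pos()
    img <- stamp_blob(img, p[1], p[2], stats::runif(1, 2.5, 5), -70, inside)
  }
  for (i in seq_len(counts["exudate"])) {
    p <- rand_pos()
    # irregular bright patch: a cluster of small bright stamps
    for (j in seq_len(sample(3:6, 1L))) {
      img <- stamp_blob(img, p[1] + stats::rnorm(1, 0, 2),
                        p[2] + stats::rnorm(1, 0, 2),
                        stats::runif(1, 1.2, 2.5), 65, inside)
    }
  }
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
  list(image = quantize_gray(img), grade = grade, lesions = counts)
}

#' Generate a balanced synthetic dataset on disk
#'
#' Writes `5 * n_per_grade` PNG images plus a manifest CSV and a JSON
#' lesion ledger to `out_dir`. Byte-identical across runs with the same
#' seed and configuration.
#'
#' @param n_per_grade images per grade (>= 1).
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @param out_dir output directory (created if missing); when NULL no files
#'   are written and the images are returned in memory.
#' @return list with `manifest` (data.frame), `images` (named list of
#'   matrices), and `ledger` (per-image lesion counts).
#' @export
generate_dataset <- function(n_per_grade, cfg = synth_config(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(n_per_grade >= 1L)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list(); imgs <- list(); ledger <- list()
  i <- 0L
  for (g in DR_GRADES) {
    for (j in seq_len(n_per_grade)) {
      i <- i + 1L
      img_seed <- (seed * 10000L + i) %% .Machine$integer.max
      fx <- generate_fundus(g, cfg, seed = img_seed)
      id <- sprintf("synth_%s_%03d", tolower(g), j)
      rel <- paste0(id, ".png")
      if (!is.null(out_dir)) write_fundus(fx$image, file.path(out_dir, rel))
      recs[[i]] <- data.frame(image_id = id, path = rel, grade = g,
                              provenance = "original", stringsAsFactors = FALSE)
      imgs[[id]] <- fx$image
      ledger[[id]] <- as.list(fx$lesions)
    }
  }
  manifest <- do.call(rbind, recs)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    jsonlite::write_json(ledger, file.path(out_dir, "ledger.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, images = imgs, ledger = ledger)
}

#' Degrade image contrast (test fixture for enhancement)
#'
#' Blends every pixel toward the global mean by `1 - factor` and adds
#' Gaussian noise; `factor = 1` with `noise_sd = 0` is the identity.
#'
#' @param img grayscale matrix, 0-255 scale.
#' @param factor contrast retention factor in (0, 1].
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed for the noise.
#' @return degraded image, quantized to 8-bit.
#' @export
degrade_contrast <- function(img, factor, noise_sd = 0, seed = 1L) {
  check_gray_image(img)
  if (factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]", call. = FALSE)
  out <- mean(img) + factor * (img - mean(img))
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  }
  quantize_gray(out)
}
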