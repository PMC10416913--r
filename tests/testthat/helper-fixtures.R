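# Shared fixtures and straight-line oracles, deliberately independent of the
# package internals they are used to check.

ramp_image <- function(n = 64L) {
  matrix(rep(seq(0, 255, length.out = n), n), n, n)
}

checkerboard_image <- function(n = 32L) {
  255 * ((matrix(seq_len(n), n, n) + matrix(seq_len(n), n, n, byrow = TRUE)) %% 2)
}

random_image <- function(n = 16L, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# naive 2-D correlation with replicate (clamped) borders; pixel loops only
naive_filter <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (a in -kh:kh) for (b in -kw:kw) {
      ii <- min(max(i + a, 1L), n)
      jj <- min(max(j + b, 1L), m)
      acc <- acc + img[ii, jj] * kernel[a + kh + 1L, b + kw + 1L]
    }
    out[i, j] <- acc
  }
  out
}

naive_gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

naive_entropy <- function(img) {
  counts <- table(factor(round(img), levels = 0:255))
  q <- as.numeric(counts) / sum(counts)
  q <- q[q > 0]
  -sum(q * log2(q))
}

naive_psnr <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  mse <- s / length(a)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

# windowed SSIM recomputed with the naive filter
naive_ssim <- function(a, b) {
  g <- exp(-(-5:5)^2 / (2 * 1.5^2))
  w <- outer(g, g); w <- w / sum(w)
  a1 <- (0.01 * 255)^2; a2 <- (0.03 * 255)^2
  mx <- naive_filter(a, w); my <- naive_filter(b, w)
  vx <- naive_filter(a^2, w) - mx^2
  vy <- naive_filter(b^2, w) - my^2
  cxy <- naive_filter(a * b, w) - mx * my
  mean(((2 * mx * my + a1) * (2 * cxy + a2)) /
         ((mx^2 + my^2 + a1) * (vx + vy + a2)))
}

synthetic_grade_set <- function(n_per_grade, size = 64L, seed = 5L) {
  ds <- generate_dataset(n_per_grade, synth_config(size = size), seed = seed)
  list(images = unname(ds$images), labels = ds$manifest$grade,
       manifest = ds$manifest, ledger = ds$ledger)
}

# Table-style count fixtures used by the bookkeeping tests
aptos_counts <- c(NoDR = 1805, Mild = 370, Moderate = 999,
                  Severe = 193, PDR = 295)
aptos_ops <- c(NoDR = 0, Mild = 5, Moderate = 2, Severe = 9, PDR = 6)
kaggle_counts <- c(NoDR = 25810, Mild = 2443, Moderate = 5292,
                   Severe = 873, PDR = 708)
kaggle_ops <- c(NoDR = 0, Mild = 10, Moderate = 5, Severe = 29, PDR = 36)

counts_manifest <- function(counts) {
  grades <- rep(names(counts), counts)
  data.frame(image_id = sprintf("img%06d", seq_along(grades)),
             path = sprintf("img%06d.png", seq_along(grades)),
             grade = grades, provenance = "original",
             stringsAsFactors = FALSE)
}
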