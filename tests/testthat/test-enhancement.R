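test_that("beta transform fixes the endpoints and is the identity at c = d = 1", {
  levels <- matrix(rep(0:255, length.out = 256), 16, 16)
  expect_identical(beta_transform(levels, 1, 1), quantize_gray(levels))
  img <- ramp_image(16)
  out <- beta_transform(img, 3.7, 0.9)
  expect_equal(dim(out), dim(img))
  expect_equal(out[img == 0][1], 0)
  expect_equal(out[abs(img - 255) < 1e-9][1], 255)
})

test_that("beta transform matches closed forms and a numerical-integration oracle", {
  # I_v(2, 1) = v^2
  px <- matrix(128, 8, 8)
  expect_equal(beta_transform(px, 2, 1)[1, 1], round(255 * (128 / 255)^2))
  # symmetry: I_0.5(2, 2) = 0.5
  mid <- matrix(127.5, 8, 8)
  expect_equal(beta_transform(mid, 2, 2, quantize = FALSE)[1, 1], 127.5,
               tolerance = 1e-2)
  # numerical integration of the defining integral ratio
  oracle <- function(v, c, d) {
    num <- integrate(function(x) x^(c - 1) * (1 - x)^(d - 1), 0, v,
                     rel.tol = 1e-12)$value
    den <- integrate(function(x) x^(c - 1) * (1 - x)^(d - 1), 0, 1,
                     rel.tol = 1e-12)$value
    num / den
  }
  set.seed(42)
  grid <- data.frame(v = runif(50, 0.02, 0.98),
                     c = runif(50, 0.5, 6), d = runif(50, 0.5, 6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    img <- matrix(g$v * 255, 8, 8)
    got <- beta_transform(img, g$c, g$d, quantize = FALSE)[1, 1] / 255
    want <- oracle(round(g$v * 255) / 255, g$c, g$d)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("beta transform is monotone over a shape-parameter grid", {
  levels <- matrix(rep(0:255, length.out = 256), 16, 16)
  for (c in c(0.5, 1, 2, 5)) for (d in c(0.5, 1, 2, 5)) {
    out <- beta_transform(levels, c, d, quantize = FALSE)
    expect_false(is.unsorted(out[order(levels)]),
                 label = sprintf("monotone at c=%.1f d=%.1f", c, d))
  }
})

test_that("beta transform rejects invalid shape parameters", {
  img <- ramp_image(16)
  expect_error(beta_transform(img, 0, 1), "positive")
  expect_error(beta_transform(img, 1, -2), "positive")
  expect_error(beta_transform(img, NaN, 1), "positive")
})

test_that("image entropy matches the histogram limits", {
  expect_equal(image_entropy(matrix(7, 16, 16)), 0)
  expect_equal(image_entropy(matrix(c(0, 255), 16, 16)), 1)
  expect_equal(image_entropy(matrix(0:255, 16, 16)), 8)
  img <- random_image(32, seed = 3)
  expect_equal(image_entropy(img), naive_entropy(img), tolerance = 1e-12)
})

test_that("band-limited contrast is zero for flat images and tracks contrast", {
  expect_lt(local_contrast(matrix(100, 64, 64), 32), 1e-10)
  set.seed(8)
  img <- quantize_gray(128 + matrix(rnorm(64^2, 0, 20), 64, 64))
  boosted <- quantize_gray(mean(img) + 2 * (img - mean(img)))
  expect_gte(local_contrast(boosted, 32), local_contrast(img, 32))
  expect_error(local_contrast(ramp_image(16), 64), "fit inside")
})

test_that("single-block contrast equals a pixel-loop filter-and-divide oracle", {
  img <- matrix(60, 16, 16)
  img[, 9:16] <- 200   # step edge at the midline
  got <- local_contrast(img, block_size = 16)
  low <- naive_filter(img, naive_gaussian_kernel(2))
  fine <- naive_filter(img, naive_gaussian_kernel(1))
  want <- mean(abs(fine - low) / pmax(low, 1e-6))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("fitness report fields are internally consistent and comparable", {
  img <- checkerboard_image(32)
  rep <- compute_fitness(img)
  expect_s3_class(rep, "fitness_report")
  expect_lte(rep$edge_pixel_count, length(img))
  expect_gte(rep$entropy_bits, 0)
  expect_lte(rep$entropy_bits, 8)
  # combination formula recomputed straight-line from the report fields
  want <- log(log(rep$edge_intensity_sum)) *
    (rep$edge_pixel_count / length(img)) * rep$entropy_bits * rep$contrast
  expect_equal(rep$fitness, want, tolerance = 1e-12)
  # flat image: no edges -> sentinel
  expect_lt(compute_fitness(matrix(9, 32, 32))$fitness, -1e100)
  # washing out an image cuts its fitness
  faded <- quantize_gray(0.2 * img + 0.8 * 128)
  expect_gt(rep$fitness, compute_fitness(faded)$fitness)
})

test_that("fitness is invariant to transposition of a square image", {
  set.seed(11)
  fx <- generate_fundus("Moderate", synth_config(size = 64), seed = 21)
  a <- compute_fitness(fx$image)
  b <- compute_fitness(t(fx$image))
  expect_equal(a$fitness, b$fitness, tolerance = 1e-9)
  expect_equal(a$edge_pixel_count, b$edge_pixel_count)
})

test_that("the bee colony never does worse than the identity transform", {
  fx <- generate_fundus("Severe", synth_config(size = 64), seed = 9)
  degraded <- degrade_contrast(fx$image, 0.4, 2, seed = 4)
  cfg <- abc_config(colony_size = 5L, max_cycles = 4L, scout_limit = 4L,
                    seed = 13)
  opt <- abc_optimize(degraded, cfg)
  expect_gte(opt$fitness, compute_fitness(degraded)$fitness - 1e-12)
  expect_false(is.unsorted(opt$trace))
  # pinned bounds at the identity reproduce the input
  pin <- abc_config(colony_size = 2L, max_cycles = 1L,
                    c_bounds = c(1, 1), d_bounds = c(1, 1), seed = 1)
  res <- enhance(degraded, pin)
  expect_identical(res$image, quantize_gray(degraded))
})

test_that("bee colony search is deterministic given its seed", {
  fx <- generate_fundus("Mild", synth_config(size = 64), seed = 2)
  cfg <- abc_config(colony_size = 4L, max_cycles = 3L, seed = 33)
  a <- abc_optimize(fx$image, cfg)
  b <- abc_optimize(fx$image, cfg)
  expect_identical(c(a$c, a$d, a$fitness), c(b$c, b$d, b$fitness))
})

test_that("enhancement preserves dimensions and handles RGB on the green channel", {
  fx <- generate_fundus("Moderate", synth_config(size = 64), seed = 3)
  degraded <- degrade_contrast(fx$image, 0.5)
  cfg <- abc_config(colony_size = 4L, max_cycles = 3L, seed = 5)
  res <- enhance(degraded, cfg)
  expect_equal(dim(res$image), dim(degraded))
  expect_gte(res$report$fitness, compute_fitness(degraded)$fitness - 1e-12)
  rgb <- array(0, c(64, 64, 3))
  for (ch in 1:3) rgb[, , ch] <- degraded
  rres <- enhance(rgb, cfg)
  expect_equal(dim(rres$image), dim(rgb))
  expect_identical(rres$image[, , 1], degraded)  # red passed through
})
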