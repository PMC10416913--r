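test_that("augmentation plan arithmetic reproduces the per-grade balancing rows", {
  plan <- build_plan(aptos_counts, aptos_ops)
  expect_equal(plan$augmented[plan$grade == "Mild"], 1850)     # 370 x 5
  expect_equal(plan$augmented[plan$grade == "NoDR"], 1805)     # retained
  expect_equal(plan$augmented[plan$grade == "Moderate"], 1998) # 999 x 2
  expect_equal(attr(plan, "total"), 9160)
  kplan <- build_plan(kaggle_counts, kaggle_ops)
  expect_equal(kplan$augmented[kplan$grade == "Severe"], 25317) # 873 x 29
  expect_equal(attr(kplan, "total"), 127505)
  expect_error(build_plan(c(NoDR = -1, Mild = 0, Moderate = 0,
                            Severe = 0, PDR = 0),
                          aptos_ops), "nonnegative")
})

test_that("augmentation operators are deterministic, shape-preserving involutions", {
  img <- random_image(32, seed = 12)
  flip <- augment_op("horizontal_flip")
  expect_identical(apply_augmentation(apply_augmentation(img, flip), flip), img)
  expect_identical(apply_augmentation(img, augment_op("rotation", 0)), img)
  # a 0.25 shift on a 100-wide image moves content 25 columns right
  wide <- matrix(0, 16, 100); wide[8, 10] <- 255
  shifted <- apply_augmentation(wide, augment_op("horizontal_shift", 0.25))
  expect_equal(shifted[8, 35], 255)
  expect_equal(dim(apply_augmentation(img, augment_op("rotation", 37))),
               dim(img))
  rot <- apply_augmentation(img, augment_op("rotation", 90))
  expect_true(all(rot >= 0 & rot <= 255))
  expect_error(augment_op("zoom"), "unknown")
  expect_error(augment_op("rotation", 200), "degrees")
  expect_error(augment_op("horizontal_shift", 1.5), "fraction")
})

test_that("photometric ops move intensities the documented way", {
  img <- matrix(100, 16, 16)
  bright <- apply_augmentation(img, augment_op("brightness", 0.1))
  expect_equal(bright[1, 1], 100 + 25.5, tolerance = 1)
  img2 <- random_image(16, seed = 3)
  ctr <- apply_augmentation(img2, augment_op("contrast", 0.2))
  expect_gte(stats::sd(ctr), stats::sd(img2) * 0.99)
})

test_that("realizing a plan reproduces the augmented totals of both datasets", {
  for (fix in list(list(counts = aptos_counts, ops = aptos_ops, total = 9160),
                   list(counts = kaggle_counts, ops = kaggle_ops,
                        total = 127505))) {
    manifest <- counts_manifest(fix$counts)
    plan <- build_plan(fix$counts, fix$ops)
    out <- augment_dataset(manifest, plan, seed = 1)
    expect_equal(nrow(out), fix$total)
    got <- table(factor(out$grade, levels = plan$grade))
    expect_equal(as.integer(got), plan$augmented)
  }
  # zero-ops plan leaves the manifest unchanged
  manifest <- counts_manifest(c(NoDR = 4, Mild = 3, Moderate = 2,
                                Severe = 2, PDR = 1))
  plan0 <- build_plan(c(NoDR = 4, Mild = 3, Moderate = 2, Severe = 2, PDR = 1),
                      c(NoDR = 0, Mild = 0, Moderate = 0, Severe = 0, PDR = 0))
  expect_identical(augment_dataset(manifest, plan0, seed = 1), manifest)
})

test_that("augmented images written to disk are valid and deterministic", {
  dir <- withr::local_tempdir()
  src_dir <- file.path(dir, "src"); out1 <- file.path(dir, "a")
  out2 <- file.path(dir, "b")
  dir.create(src_dir)
  manifest <- data.frame(image_id = c("i1", "i2"),
                         path = c("i1.png", "i2.png"),
                         grade = c("Mild", "Mild"),
                         provenance = "original", stringsAsFactors = FALSE)
  for (p in manifest$path)
    write_fundus(random_image(32, seed = nchar(p)), file.path(src_dir, p))
  plan <- build_plan(c(NoDR = 0, Mild = 2, Moderate = 0, Severe = 0, PDR = 0),
                     c(NoDR = 0, Mild = 3, Moderate = 0, Severe = 0, PDR = 0))
  m1 <- augment_dataset(manifest, plan, seed = 7, image_dir = src_dir,
                        out_dir = out1)
  m2 <- augment_dataset(manifest, plan, seed = 7, image_dir = src_dir,
                        out_dir = out2)
  expect_equal(nrow(m1), 6)
  expect_identical(m1$image_id, m2$image_id)
  for (p in m1$path) {
    img <- read_fundus(file.path(out1, p))
    expect_true(all(img >= 0 & img <= 255))
    expect_identical(img, read_fundus(file.path(out2, p)))
  }
})

test_that("stratified split reproduces the per-grade 80:20 train counts", {
  plan <- build_plan(aptos_counts, aptos_ops)
  manifest <- counts_manifest(setNames(plan$augmented, plan$grade))
  sp <- split_dataset(manifest, 0.8, seed = 2)
  train_counts <- table(factor(sp$train$grade, levels = DR_GRADES))
  expect_equal(as.integer(train_counts), c(1444, 1480, 1598, 1390, 1416))
  expect_equal(nrow(sp$train), 7328)
  expect_equal(nrow(sp$test), 1832)
  test_counts <- table(factor(sp$test$grade, levels = DR_GRADES))
  expect_equal(as.integer(test_counts), c(361, 370, 400, 347, 354))
})

test_that("split is a stratified partition on random manifests", {
  set.seed(77)
  for (trial in 1:5) {
    counts <- setNames(sample(3:40, 5), DR_GRADES)
    manifest <- counts_manifest(counts)
    frac <- runif(1, 0.5, 0.9)
    sp <- split_dataset(manifest, frac, seed = trial)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(manifest))
    expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)
    expect_setequal(c(sp$train$image_id, sp$test$image_id), manifest$image_id)
    got <- table(factor(sp$train$grade, levels = DR_GRADES))
    want <- trunc(frac * counts + 0.5)   # round half away from zero
    expect_equal(as.integer(got), as.integer(want))
  }
  sp1 <- split_dataset(counts_manifest(c(NoDR = 9, Mild = 9, Moderate = 9,
                                         Severe = 9, PDR = 9)), 0.8, seed = 3)
  sp2 <- split_dataset(counts_manifest(c(NoDR = 9, Mild = 9, Moderate = 9,
                                         Severe = 9, PDR = 9)), 0.8, seed = 3)
  expect_identical(sp1, sp2)
})

test_that("manifests round-trip through CSV", {
  dir <- withr::local_tempdir()
  m <- counts_manifest(c(NoDR = 2, Mild = 1, Moderate = 1, Severe = 1, PDR = 1))
  p <- file.path(dir, "m.csv")
  write_manifest(m, p)
  expect_identical(read_manifest(p), m)
})
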