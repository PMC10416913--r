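# Class-balancing augmentation bookkeeping and stratified splitting.
# A dataset manifest is a data.frame with columns image_id, path, grade,
# provenance; grades use the standard five-level severity scale.

#' Diabetic retinopathy severity grades
#'
#' The five-level grading scale, in increasing severity order. This order is
#' also the tie-break order used by the SVM head's argmax.
#' @export
DR_GRADES <- c("NoDR", "Mild", "Moderate", "Severe", "PDR")

check_manifest <- function(manifest) {
  need <- c("image_id", "path", "grade", "provenance")
  if (!is.data.frame(manifest) || !all(need %in% names(manifest)))
    stop("manifest must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(manifest$grade %in% DR_GRADES))
    stop("manifest grades must be one of: ", paste(DR_GRADES, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$image_id))
    stop("manifest image_ids must be unique", call. = FALSE)
  invisible(manifest)
}

#' Build a class-balancing augmentation plan
#'
#' For each grade the augmented count is `original * max(operations, 1)`:
#' a grade with k >= 1 augmentation operations contributes k variants per
#' original (the originals themselves are replaced by their variants in the
#' balanced set), while a grade with 0 operations keeps its originals
#' untouched. This is the arithmetic that balances a skewed grade
#' distribution into roughly equal per-grade counts.
#'
#' @param original_counts named nonnegative integer vector (names = grades).
#' @param operations named nonnegative integer vector, same grades: number
#'   of augmentation operations applied per original image.
#' @return data.frame of class `augmentation_plan` with one row per grade
#'   (`grade`, `original`, `operations`, `augmented`) and an attached
#'   `total` attribute.
#' @examples
#' plan <- build_plan(c(NoDR = 1805, Mild = 370, Moderate = 999,
#'                      Severe = 193, PDR = 295),
#'                    c(NoDR = 0, Mild = 5, Moderate = 2,
#'                      Severe = 9, PDR = 6))
#' attr(plan, "total")  # 9160
#' @export
build_plan <- function(original_counts, operations) {
  grades <- names(original_counts)
  if (is.null(grades) || !setequal(grades, names(operations)))
    stop("original_counts and operations must be named by the same grades",
         call. = FALSE)
  operations <- operations[grades]
  if (any(original_counts < 0) || any(operations < 0))
    stop("counts and operations must be nonnegative", call. = FALSE)
  augmented <- as.integer(original_counts) * pmax(as.integer(operations), 1L)
  plan <- data.frame(grade = grades,
                     original = as.integer(original_counts),
                     operations = as.integer(operations),
                     augmented = augmented,
                     stringsAsFactors = FALSE)
  attr(plan, "total") <- sum(augmented)
  class(plan) <- c("augmentation_plan", "data.frame")
  plan
}

#' Construct an augmentation operation
#'
#' @param kind one of `"rotation"` (degrees in [0, 180]),
#'   `"horizontal_shift"` (fraction of width in [0, 1]),
#'   `"horizontal_flip"`, `"brightness"` (additive gain factor, e.g. 0.2
#'   brightens by 20%), `"contrast"` (scaling about the image mean, e.g.
#'   0.2 increases contrast by 20%).
#' @param magnitude operation strength; ignored for flips.
#' @param seed integer seed recorded with the op (used when magnitudes are
#'   drawn at random by [augment_dataset()]).
#' @return list of class `augment_op`.
#' @export
augment_op <- function(kind, magnitude = 0, seed = 0L) {
  kinds <- c("rotation", "horizontal_shift", "horizontal_flip",
             "brightness", "contrast")
  if (!kind %in% kinds)
    stop("unknown augmentation kind: ", kind, call. = FALSE)
  if (kind == "rotation" && (magnitude < 0 || magnitude > 180))
    stop("rotation angle must be in [0, 180] degrees", call. = FALSE)
  if (kind == "horizontal_shift" && (magnitude < 0 || magnitude > 1))
    stop("shift fraction must be in [0, 1]", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "augment_op")
}

# rotate about the image centre by `deg` degrees, bilinear resampling with
# mirror boundary fill (avoids the black corners a zero fill would create,
# which would distort edge-based fitness measures downstream).
rotate_reflect <- function(img, deg) {
  if (deg == 0) return(img)
  th <- deg * pi / 180
  n <- nrow(img); m <- ncol(img)
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  grid_r <- matrix(seq_len(n), n, m) - cr
  grid_c <- matrix(seq_len(m), n, m, byrow = TRUE) - cc
  src_r <- cos(th) * grid_r - sin(th) * grid_c + cr
  src_c <- sin(th) * grid_r + cos(th) * grid_c + cc
  matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c)), n, m)
}

shift_reflect <- function(img, fraction) {
  k <- round(fraction * ncol(img))
  if (k == 0) return(img)
  idx <- reflect_index(seq_len(ncol(img)) - k, ncol(img))
  img[, idx, drop = FALSE]
}

#' Apply one augmentation operation to an image
#'
#' Geometric operations preserve the image dimensions, filling uncovered
#' pixels by mirror reflection; photometric operations clamp back to
#' [0, 255]. Flipping is an involution; zero-magnitude rotation and shift
#' are identities.
#'
#' @param img grayscale matrix or RGB array, 0-255 scale.
#' @param op an [augment_op()].
#' @return augmented image, same dimensions and scale.
#' @export
apply_augmentation <- function(img, op) {
  stopifnot(inherits(op, "augment_op"))
  if (is_rgb_image(img)) {
    out <- img
    for (ch in 1:3) out[, , ch] <- apply_augmentation(img[, , ch], op)
    return(out)
  }
  switch(op$kind,
    rotation = if (op$magnitude == 0) img else
      quantize_gray(rotate_reflect(img, op$magnitude)),
    horizontal_shift = shift_reflect(img, op$magnitude),
    horizontal_flip = img[, rev(seq_len(ncol(img))), drop = FALSE],
    brightness = quantize_gray(img + op$magnitude * 255),
    contrast = quantize_gray(mean(img) + (1 + op$magnitude) * (img - mean(img)))
  )
}

# draw a random op of the given kind; rotation angles uniform on [0, 180],
# shifts uniform on [0, 0.3], brightness/contrast uniform on +/- 20%.
random_augment_op <- function(kind, seed) {
  mag <- switch(kind,
    rotation = stats::runif(1, 0, 180),
    horizontal_shift = stats::runif(1, 0, 0.3),
    horizontal_flip = 0,
    brightness = stats::runif(1, -0.2, 0.2),
    contrast = stats::runif(1, -0.2, 0.2))
  augment_op(kind, mag, seed)
}

#' Realize an augmentation plan over a manifest
#'
#' For every grade with k >= 1 operations, each original image yields k
#' augmented records (randomly drawn rotation / shift / flip / brightness /
#' contrast ops, deterministic given `seed`); grades with 0 operations keep
#' their original records. Per-grade output counts equal the plan's
#' `augmented` column. When `image_dir`/`out_dir` are given the augmented
#' images are actually computed and written as PNG; otherwise only the
#' bookkeeping records are produced (paths point at the planned outputs).
#'
#' @param manifest dataset manifest data.frame.
#' @param plan an [build_plan()] result consistent with the manifest counts.
#' @param seed integer seed.
#' @param image_dir,out_dir optional directories to read originals from and
#'   write augmented PNGs to.
#' @return augmented manifest data.frame.
#' @export
augment_dataset <- function(manifest, plan, seed = 1L,
                            image_dir = NULL, out_dir = NULL) {
  check_manifest(manifest)
  counts <- table(factor(manifest$grade, levels = plan$grade))
  if (!all(as.integer(counts) == plan$original))
    stop("plan original counts do not match the manifest", call. = FALSE)
  write_images <- !is.null(image_dir) && !is.null(out_dir)
  if (write_images) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c("rotation", "horizontal_shift", "horizontal_flip",
             "brightness", "contrast")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  out <- list()
  for (g in plan$grade) {
    k <- plan$operations[plan$grade == g]
    rows <- manifest[manifest$grade == g, , drop = FALSE]
    if (k == 0L || nrow(rows) == 0L) {
      out[[g]] <- rows
      next
    }
    recs <- vector("list", nrow(rows) * k)
    idx <- 1L
    for (r in seq_len(nrow(rows))) {
      src <- if (write_images) read_fundus(file.path(image_dir, rows$path[r]))
      for (v in seq_len(k)) {
        op <- random_augment_op(sample(kinds, 1L), seed)
        id <- sprintf("%s_aug%02d", rows$image_id[r], v)
        rel <- paste0(id, ".png")
        if (write_images)
          write_fundus(apply_augmentation(src, op), file.path(out_dir, rel))
        recs[[idx]] <- data.frame(image_id = id, path = rel, grade = g,
                                  provenance = "augmented",
                                  stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    out[[g]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratified train/test split
#'
#' Splits a manifest per grade: the train share is
#' `round(train_fraction * n_grade)` with round-half-away-from-zero, the
#' remainder goes to test. Record assignment within a grade is a seeded
#' uniform permutation; the two parts partition the input exactly.
#'
#' @param manifest dataset manifest data.frame.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` manifests.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  check_manifest(manifest)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train_idx <- logical(nrow(manifest))
  for (g in DR_GRADES) {
    rows <- which(manifest$grade == g)
    if (length(rows) == 0L) {
      warning("grade ", g, " has no records", call. = FALSE)
      next
    }
    n_train <- round_half_up(train_fraction * length(rows))
    perm <- sample(rows)
    train_idx[perm[seq_len(n_train)]] <- TRUE
  }
  list(train = manifest[train_idx, , drop = FALSE],
       test = manifest[!train_idx, , drop = FALSE])
}

# round-half-away-from-zero (base round() rounds halves to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Read / write a dataset manifest CSV
#'
#' @param path CSV path with columns image_id, path, grade, provenance.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
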