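# Synthetic paired-phantom simulator.
#
# Emulates the structure of paired short-axis / total-body PET acquisitions:
# the high-quality (HQ) slice is a noise-free activity map (background +
# elliptical organs + small high-contrast lesion discs); the low-quality (LQ)
# member is the same slice after resolution loss (Gaussian point-spread
# blur) and count-limited noise whose variance scales inversely with an
# effective-sensitivity factor (1 ~ total-body field of view, smaller values
# ~ shorter axial coverage), plus additive Gaussian electronic noise.

#' Phantom specification
#'
#' @param grid_size pixels per side of the square slice (>= 16).
#' @param n_organs number of elliptical activity regions (>= 1).
#' @param activity_range length-2 nonnegative `c(min, max)` of organ
#'   activities, `min < max`.
#' @param n_lesions number of small high-activity discs (>= 0).
#' @param lesion_contrast multiplicative lesion factor (> 1).
#' @param background_activity nonnegative background level.
#' @param seed RNG seed making the phantom reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L, n_organs = 5L,
                         activity_range = c(0.5, 1.5), n_lesions = 2L,
                         lesion_contrast = 3, background_activity = 0.1,
                         seed = 1L) {
  grid_size <- check_count(grid_size, "grid_size", min = 16L)
  n_organs <- check_count(n_organs, "n_organs", min = 1L)
  if (!is.numeric(activity_range) || length(activity_range) != 2L ||
      activity_range[1] < 0 || activity_range[1] >= activity_range[2])
    stopf("'activity_range' must be c(min, max) with 0 <= min < max")
  n_lesions <- check_count(n_lesions, "n_lesions", min = 0L)
  check_scalar(lesion_contrast, "lesion_contrast")
  if (lesion_contrast <= 1) stopf("'lesion_contrast' must be > 1")
  check_scalar(background_activity, "background_activity")
  if (background_activity < 0) stopf("'background_activity' must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(grid_size = grid_size, n_organs = n_organs,
                 activity_range = activity_range, n_lesions = n_lesions,
                 lesion_contrast = lesion_contrast,
                 background_activity = background_activity, seed = seed),
            class = "phantom_spec")
}

#' Degradation specification
#'
#' @param sensitivity effective-sensitivity factor in (0, 1]: 1 emulates the
#'   full total-body field of view; smaller values emulate shorter axial
#'   coverage (expected counts scale proportionally, so noise variance scales
#'   as 1/sensitivity).
#' @param psf_sigma_lq Gaussian point-spread blur width (pixels, >= 0)
#'   applied to the LQ branch.
#' @param count_scale expected photon count at unit activity and unit
#'   sensitivity (> 0).
#' @param gauss_sigma additive electronic-noise standard deviation (>= 0).
#' @param seed RNG seed for the noise draws.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(sensitivity = 1, psf_sigma_lq = 1,
                             count_scale = 50, gauss_sigma = 0.01,
                             seed = 1L) {
  check_scalar(sensitivity, "sensitivity")
  if (sensitivity <= 0 || sensitivity > 1)
    stopf("'sensitivity' must lie in (0, 1]")
  check_scalar(psf_sigma_lq, "psf_sigma_lq")
  if (psf_sigma_lq < 0) stopf("'psf_sigma_lq' must be >= 0")
  check_scalar(count_scale, "count_scale")
  if (count_scale <= 0) stopf("'count_scale' must be > 0")
  check_scalar(gauss_sigma, "gauss_sigma")
  if (gauss_sigma < 0) stopf("'gauss_sigma' must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(sensitivity = sensitivity, psf_sigma_lq = psf_sigma_lq,
                 count_scale = count_scale, gauss_sigma = gauss_sigma,
                 seed = seed), class = "degradation_spec")
}

#' Generate a high-quality ground-truth phantom slice
#'
#' Background plus `n_organs` ellipses with random centres, semi-axes,
#' orientations and activities, plus `n_lesions` discs whose value is
#' `lesion_contrast` times the local activity at their centre. Deterministic
#' for a given spec (same seed gives byte-identical output).
#'
#' @param spec a [phantom_spec()].
#' @return an [image_slice()] with nonnegative pixels and label
#'   `"synthetic"`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  n <- spec$grid_size
  with_seed(spec$seed, {
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    img <- matrix(spec$background_activity, n, n)
    for (i in seq_len(spec$n_organs)) {
      cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
      a <- stats::runif(1, n / 10, n / 3.5)
      b <- stats::runif(1, n / 10, n / 3.5)
      th <- stats::runif(1, 0, pi)
      act <- stats::runif(1, spec$activity_range[1], spec$activity_range[2])
      dx <- xs - cx; dy <- ys - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      img <- img + act * (u * u + v * v <= 1)
    }
    for (i in seq_len(spec$n_lesions)) {
      cx <- stats::runif(1, 2, n - 1); cy <- stats::runif(1, 2, n - 1)
      r <- stats::runif(1, max(1, n / 32), max(1.5, n / 16))
      local <- img[round(cy), round(cx)]
      mask <- (xs - cx)^2 + (ys - cy)^2 <= r * r
      img[mask] <- spec$lesion_contrast * local
    }
    image_slice(img, label = "synthetic")
  })
}

#' Degrade a high-quality slice into its low-quality counterpart
#'
#' `LQ = Poisson(s * c * blur(HQ)) / (s * c) + N(0, gauss_sigma)` with
#' `s = sensitivity` and `c = count_scale`: blur models resolution loss and
#' the scaled Poisson draw models count-limited acquisition, so lowering the
#' sensitivity raises the noise variance as `1/s`.
#'
#' @param hq an [image_slice()] (or matrix) with nonnegative pixels.
#' @param d a [degradation_spec()].
#' @return an [image_slice()] of identical dimensions; deterministic under
#'   `d$seed`.
#' @export
degrade <- function(hq, d) {
  if (!inherits(d, "degradation_spec")) stopf("'d' must be a degradation_spec")
  sl <- as_image_slice(hq)
  px <- sl$pixels
  if (any(px < 0)) stopf("degrade() requires a nonnegative input slice")
  blurred <- gaussian_blur2d(px, d$psf_sigma_lq)
  scale <- d$sensitivity * d$count_scale
  lq <- with_seed(d$seed, {
    counts <- stats::rpois(length(blurred), lambda = as.vector(blurred) * scale)
    out <- counts / scale + stats::rnorm(length(blurred), 0, d$gauss_sigma)
    matrix(out, nrow(px), ncol(px))
  })
  image_slice(lq, spacing = sl$spacing, label = sl$label)
}

#' Generate a paired dataset and split it into training and test sets
#'
#' Each pair's HQ slice comes from a phantom with its own derived seed and
#' the LQ member is degraded from that same HQ slice (pixel-aligned, no
#' cross-pair shuffling). Pairs are split 9:1 (train:test) under
#' `split_seed`.
#'
#' @param spec a [phantom_spec()]; per-pair seeds are derived from
#'   `spec$seed`.
#' @param d a [degradation_spec()]; per-pair noise seeds are derived from
#'   `d$seed`.
#' @param n_pairs number of pairs (>= 10 so the 9:1 split is nondegenerate).
#' @param split_seed seed of the random split.
#' @param groups optional grouping vector (length `n_pairs`, e.g. patient
#'   ids); when given, whole groups are assigned to the same side of the
#'   split. Default `NULL` splits by pair.
#' @return list with `train` and `test` (lists of [paired_sample()]),
#'   `test_idx`, and the generating specs.
#' @export
make_dataset <- function(spec, d, n_pairs, split_seed = 1L, groups = NULL) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (n_pairs < 10L) stopf("'n_pairs' must be >= 10 (9:1 split degenerate)")
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sp_i <- spec; sp_i$seed <- derive_seed(spec$seed, i)
    d_i <- d; d_i$seed <- derive_seed(d$seed, i, 7L)
    hq <- generate_phantom(sp_i)
    lq <- degrade(hq, d_i)
    pairs[[i]] <- paired_sample(lq, hq)
  }
  if (is.null(groups)) {
    n_test <- n_pairs %/% 10L
    test_idx <- sort(with_seed(split_seed, sample.int(n_pairs, n_test)))
  } else {
    if (length(groups) != n_pairs) stopf("'groups' must have length n_pairs")
    ug <- unique(groups)
    n_test_g <- max(1L, length(ug) %/% 10L)
    test_g <- with_seed(split_seed, sample(ug, n_test_g))
    test_idx <- sort(which(groups %in% test_g))
  }
  list(train = pairs[setdiff(seq_len(n_pairs), test_idx)],
       test = pairs[test_idx],
       test_idx = test_idx,
       phantom_spec = spec, degradation_spec = d, split_seed = split_seed)
}

#' Write a paired dataset as two NIfTI volumes plus a JSON manifest
#'
#' Slices are stacked along the third axis into `lq.nii.gz` and `hq.nii.gz`;
#' the manifest records the generating specs, seeds and split.
#'
#' @param dataset a dataset from [make_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_paired_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- c(dataset$train, dataset$test)
  write_volume(lapply(pairs, function(p) p$lq), file.path(dir, "lq.nii.gz"))
  write_volume(lapply(pairs, function(p) p$hq), file.path(dir, "hq.nii.gz"))
  n_train <- length(dataset$train)
  manifest <- list(
    phantom_spec = unclass(dataset$phantom_spec),
    degradation_spec = unclass(dataset$degradation_spec),
    split_seed = dataset$split_seed,
    n_pairs = length(pairs),
    train_slices = seq_len(n_train),
    test_slices = if (length(dataset$test)) n_train + seq_along(dataset$test) else integer(0),
    original_test_idx = dataset$test_idx)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a paired dataset written by [write_paired_dataset()]
#'
#' @param dir directory containing `lq.nii.gz`, `hq.nii.gz` and
#'   `manifest.json`.
#' @return list with `train`, `test` (lists of [paired_sample()]) and the
#'   parsed `manifest`.
#' @export
read_paired_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  lq <- read_volume(file.path(dir, "lq.nii.gz"))
  hq <- read_volume(file.path(dir, "hq.nii.gz"))
  pairs <- Map(paired_sample, lq, hq)
  list(train = pairs[man$train_slices],
       test = pairs[man$test_slices],
       manifest = man)
}
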