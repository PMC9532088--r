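#' Texture class specifications for the synthetic leaf generator
#'
#' Each synthetic class is an oriented quasi-periodic texture meant to mimic
#' the venation patterning that makes leaf surfaces separable by oriented
#' band-pass energy: a primary sinusoidal grating at a class-specific
#' (wavelength, orientation) pair, a weaker secondary grating at an offset
#' orientation (cross-venation), a smooth low-frequency illumination field, a
#' few dark blobs (specks/lesions), and white noise. Within-class variation
#' comes from orientation jitter, phase jitter, and random illumination.
#'
#' `default_class_specs()` assigns each class a distinct
#' (wavelength, orientation) pair drawn from the centers of a Log-Gabor bank,
#' so classes are separable in Log-Gabor energy space by construction: class
#' signal is deliberately placed where the filter bank is selective, which is
#' the mechanism the fused network is supposed to exploit. Wavelengths cycle
#' through the first `min(4, n_scales)` scales (so the default classes stay
#' resolvable on a 64-pixel image) and orientations advance once per cycle.
#'
#' @param n_classes Number of classes; at most `n_scales * n_orientations`.
#' @param params A [log_gabor_params()] object (default Table-style 8 x 10
#'   bank).
#' @param vein_contrast Amplitude of the primary grating (default 0.5).
#' @param blob_density Mean number of dark blobs per image (default 6).
#' @param noise_sd Additive Gaussian noise sd in intensity units
#'   (default 0.08).
#' @param jitter_sd_theta Orientation jitter sd in radians (default 0.05).
#' @param jitter_sd_px Phase jitter sd in pixels (default 2).
#' @return A tibble with one row per class: `class`, `vein_wavelength`,
#'   `base_orientation`, `secondary_orientation_offset`, `vein_contrast`,
#'   `blob_density`, `noise_sd`, `jitter_sd_theta`, `jitter_sd_px`.
#' @export
default_class_specs <- function(n_classes, params = log_gabor_params(),
                                vein_contrast = 0.5, blob_density = 6,
                                noise_sd = 0.08, jitter_sd_theta = 0.05,
                                jitter_sd_px = 2) {
  stopifnot(is_count(n_classes), inherits(params, "log_gabor_params"))
  if (n_classes > params$n_scales * params$n_orientations) {
    stop("n_classes exceeds the number of filters in the bank",
         call. = FALSE)
  }
  k <- min(4L, params$n_scales)
  idx <- seq_len(n_classes) - 1L
  scale_i <- (idx %% k) + 1L
  orient_i <- (idx %/% k) %% params$n_orientations + 1L
  if (anyDuplicated(cbind(scale_i, orient_i)) > 0) {
    # more classes than k * n_orientations: fall back to full enumeration
    all_pairs <- expand.grid(scale = seq_len(params$n_scales),
                             orientation = seq_len(params$n_orientations))
    scale_i <- all_pairs$scale[seq_len(n_classes)]
    orient_i <- all_pairs$orientation[seq_len(n_classes)]
  }
  tibble::tibble(
    class = seq_len(n_classes),
    vein_wavelength = lg_wavelengths(params)[scale_i],
    base_orientation = lg_orientations(params)[orient_i],
    secondary_orientation_offset = pi / 3,
    vein_contrast = vein_contrast,
    blob_density = blob_density,
    noise_sd = noise_sd,
    jitter_sd_theta = jitter_sd_theta,
    jitter_sd_px = jitter_sd_px
  )
}

#' Generate one synthetic leaf-texture image
#'
#' @param spec One row of a class-spec tibble (see [default_class_specs()]),
#'   as a list or single-row data frame.
#' @param size Image side length in pixels; must be at least twice the class
#'   wavelength so the texture is resolvable.
#' @param rng_seed Integer seed for this image's private RNG stream.
#' @return A `size` x `size` numeric matrix with values in `[0, 1]`.
#' @export
gen_image <- function(spec, size, rng_seed) {
  spec <- as.list(spec)
  lambda <- spec$vein_wavelength
  if (size < 2 * lambda) {
    stop("size must be >= 2 * vein_wavelength (texture unresolvable)",
         call. = FALSE)
  }
  withr::with_seed(as.integer(rng_seed), {
    theta <- spec$base_orientation + stats::rnorm(1, 0, spec$jitter_sd_theta)
    phase <- 2 * pi * stats::rnorm(1, 0, spec$jitter_sd_px) / lambda +
      stats::runif(1, 0, 2 * pi)
    xy <- seq_len(size) - 1
    X <- matrix(xy, size, size, byrow = TRUE) # x = column
    Y <- matrix(xy, size, size)               # y = row
    a <- spec$vein_contrast
    img <- 0.5 +
      0.5 * a * cos(2 * pi / lambda * (X * cos(theta) + Y * sin(theta)) + phase)
    # weaker cross-venation grating at the offset orientation
    theta2 <- theta + spec$secondary_orientation_offset
    phase2 <- stats::runif(1, 0, 2 * pi)
    img <- img + 0.2 * a *
      cos(2 * pi / lambda * (X * cos(theta2) + Y * sin(theta2)) + phase2)
    # smooth illumination field: one random low-frequency cosine
    ill_dir <- stats::runif(1, 0, 2 * pi)
    ill_ph <- stats::runif(1, 0, 2 * pi)
    img <- img + 0.1 *
      cos(2 * pi / size * (X * cos(ill_dir) + Y * sin(ill_dir)) + ill_ph)
    # dark blobs (specks)
    n_blob <- stats::rpois(1, spec$blob_density)
    if (n_blob > 0) {
      cx <- stats::runif(n_blob, 1, size)
      cy <- stats::runif(n_blob, 1, size)
      rad <- stats::runif(n_blob, 1.5, 3.5)
      for (b in seq_len(n_blob)) {
        d2 <- (X - cx[b])^2 + (Y - cy[b])^2
        img <- img - 0.2 * exp(-d2 / (2 * rad[b]^2))
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(size^2, 0, spec$noise_sd), size, size)
    }
    pmin(pmax(img, 0), 1)
  })
}

# Per-image seed derived from (dataset seed, class, index) so any subset of a
# dataset is stable under changes to the per-class count.
image_seed <- function(seed, class, index) {
  as.integer((as.double(seed) * 2654435761 + class * 97561 + index * 7919) %%
               2147483647)
}

#' Generate a labeled synthetic leaf-texture dataset
#'
#' Images are generated from per-image RNG streams derived from
#' `(seed, class, index)`, so two datasets with the same seed are
#' bit-identical and a dataset with a larger `n_per_class` contains the
#' smaller one's images as a per-class prefix.
#'
#' @param n_classes Number of texture classes (default 8).
#' @param n_per_class Images per class (default 50).
#' @param size Image side in pixels (default 64).
#' @param seed Integer master seed.
#' @param specs Optional class-spec tibble; defaults to
#'   [default_class_specs()].
#' @param params Bank parameters used for the default specs.
#' @return An object of class `leaf_dataset`: list with `data` (a tibble
#'   with columns `label`, `class_name`, `index`, and list-column `image`),
#'   `specs`, `seed`, `size`.
#' @examples
#' ds <- gen_dataset(3, 4, 32, seed = 1)
#' nrow(ds$data) # 12
#' @export
gen_dataset <- function(n_classes = 8, n_per_class = 50, size = 64, seed = 1,
                        specs = NULL, params = log_gabor_params()) {
  stopifnot(is_count(n_classes), is_count(n_per_class), is_count(size))
  if (is.null(specs)) specs <- default_class_specs(n_classes, params)
  stopifnot(nrow(specs) == n_classes)
  data <- tidyr::expand_grid(label = seq_len(n_classes),
                             index = seq_len(n_per_class))
  data$image <- purrr::map2(data$label, data$index, function(cl, i) {
    gen_image(specs[cl, ], size, image_seed(seed, cl, i))
  })
  data$class_name <- sprintf("class_%02d", data$label)
  structure(
    list(data = data[, c("label", "class_name", "index", "image")],
         specs = specs, seed = as.integer(seed), size = as.integer(size)),
    class = "leaf_dataset"
  )
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat("Synthetic leaf-texture dataset:", nrow(x$data), "images,",
      nrow(x$specs), "classes,", x$size, "x", x$size, "px, seed", x$seed, "\n")
  invisible(x)
}

#' Write / read a dataset as a directory-per-class PNG tree
#'
#' `write_dataset()` writes one PNG per image under class-named
#' subdirectories plus a `manifest.json` with the class specs, seed and size.
#' `read_dataset()` reads the tree back; labels are recovered from the
#' directory names and verified against the manifest.
#'
#' @param dataset A [gen_dataset()] result.
#' @param dir Output directory.
#' @param force Overwrite into an existing non-empty directory (default
#'   `FALSE`, refused).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `leaf_dataset`.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  stopifnot(inherits(dataset, "leaf_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory exists and is not empty; use force = TRUE", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(dataset$data))) {
    row <- dataset$data[i, ]
    cdir <- file.path(dir, row$class_name)
    dir.create(cdir, showWarnings = FALSE)
    png::writePNG(row$image[[1]],
                  file.path(cdir, sprintf("img_%04d.png", row$index)))
  }
  manifest <- list(seed = dataset$seed, size = dataset$size,
                   n_classes = nrow(dataset$specs),
                   n_per_class = max(dataset$data$index),
                   specs = dataset$specs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  rows <- purrr::map_dfr(seq_along(classes), function(ci) {
    files <- sort(list.files(file.path(dir, classes[ci]), pattern = "\\.png$",
                             full.names = TRUE))
    tibble::tibble(
      label = ci, class_name = classes[ci],
      index = seq_along(files),
      image = purrr::map(files, function(f) to_luminance(png::readPNG(f)))
    )
  })
  structure(
    list(data = rows, specs = tibble::as_tibble(manifest$specs),
         seed = as.integer(manifest$seed), size = as.integer(manifest$size)),
    class = "leaf_dataset"
  )
}
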