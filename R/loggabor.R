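#' Log-Gabor filter bank parameters
#'
#' Parameter set describing a 2-D Log-Gabor filter bank. A Log-Gabor filter is
#' a band-pass filter whose radial transfer function is Gaussian on a
#' logarithmic frequency axis, so it has exactly zero DC response and an
#' extended high-frequency tail. The bank is a grid of `n_scales` center
#' frequencies (a geometric sequence of wavelengths starting at
#' `min_wavelength` with ratio `scale_mult`) crossed with `n_orientations`
#' equally spaced orientations in `[0, pi)`.
#'
#' `sigma_on_f` is the ratio of the radial Gaussian's standard deviation to
#' the center frequency measured on the log axis, so the radial sigma used in
#' the transfer function is `abs(log(sigma_on_f))`; 0.65 gives filters of
#' roughly two octaves bandwidth. `angular_spread` is the ratio of the
#' orientation spacing `pi / n_orientations` to the angular Gaussian sigma.
#'
#' @param n_scales Number of filter scales (default 8).
#' @param n_orientations Number of filter orientations (default 10).
#' @param min_wavelength Wavelength in pixels of the highest-frequency scale
#'   (default 3; must be at least 2, the Nyquist limit).
#' @param scale_mult Ratio between wavelengths of successive scales
#'   (default 2).
#' @param sigma_on_f Radial bandwidth parameter in (0, 1) (default 0.65).
#' @param angular_spread Ratio of orientation spacing to angular sigma
#'   (default 1.5).
#' @return An object of class `log_gabor_params`.
#' @examples
#' p <- log_gabor_params()
#' p$n_scales * p$n_orientations # 80 filters
#' @export
log_gabor_params <- function(n_scales = 8, n_orientations = 10,
                             min_wavelength = 3, scale_mult = 2,
                             sigma_on_f = 0.65, angular_spread = 1.5) {
  stopifnot(
    "n_scales must be a positive count" = is_count(n_scales),
    "n_orientations must be a positive count" = is_count(n_orientations),
    "min_wavelength must be >= 2 (Nyquist)" =
      is.numeric(min_wavelength) && length(min_wavelength) == 1 &&
      min_wavelength >= 2,
    "scale_mult must be > 1" =
      is.numeric(scale_mult) && length(scale_mult) == 1 && scale_mult > 1,
    "sigma_on_f must be in (0, 1)" =
      is.numeric(sigma_on_f) && length(sigma_on_f) == 1 &&
      sigma_on_f > 0 && sigma_on_f < 1,
    "angular_spread must be > 0" =
      is.numeric(angular_spread) && length(angular_spread) == 1 &&
      angular_spread > 0
  )
  structure(
    list(
      n_scales = as.integer(n_scales),
      n_orientations = as.integer(n_orientations),
      min_wavelength = as.numeric(min_wavelength),
      scale_mult = as.numeric(scale_mult),
      sigma_on_f = as.numeric(sigma_on_f),
      angular_spread = as.numeric(angular_spread)
    ),
    class = "log_gabor_params"
  )
}

#' @export
print.log_gabor_params <- function(x, ...) {
  cat("Log-Gabor bank parameters:", x$n_scales, "scales x",
      x$n_orientations, "orientations\n")
  cat("  wavelengths (px):",
      paste(signif(lg_wavelengths(x), 4), collapse = ", "), "\n")
  cat("  sigma_on_f:", x$sigma_on_f,
      " angular spread:", x$angular_spread, "\n")
  invisible(x)
}

#' Center wavelengths and frequencies of a bank
#'
#' @param params A [log_gabor_params()] object.
#' @return `lg_wavelengths()` gives the geometric sequence of center
#'   wavelengths in pixels; `lg_center_frequencies()` their reciprocals
#'   (normalized frequency, cycles per pixel).
#' @export
lg_wavelengths <- function(params) {
  params$min_wavelength * params$scale_mult^(seq_len(params$n_scales) - 1)
}

#' @rdname lg_wavelengths
#' @export
lg_center_frequencies <- function(params) 1 / lg_wavelengths(params)

#' Orientation centers of a bank, equally spaced in `[0, pi)`
#' @param params A [log_gabor_params()] object.
#' @export
lg_orientations <- function(params) {
  (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
}

#' Normalized frequency grid for a 2-D DFT
#'
#' Builds the polar frequency coordinates of the standard (unshifted) discrete
#' Fourier grid: `radius[i, j]` is `sqrt(u^2 + v^2)` and `angle[i, j]` is
#' `atan2(v, u)`, where `u` is the normalized frequency along columns (x) and
#' `v` along rows (y). Per-axis frequencies follow the usual DFT ordering
#' `0, 1/n, ..., -1/n`; for even `n` the Nyquist frequency sits on the
#' negative side (`-1/2`), so responses are reproducible across runs.
#'
#' @param height,width Grid dimensions in pixels (each >= 2).
#' @return A list with `radius`, `angle` (height x width matrices), `height`,
#'   `width`. The zero-frequency (DC) bin is at `[1, 1]`.
#' @examples
#' g <- make_frequency_grid(4, 4)
#' g$radius[1, 1]      # 0 at DC
#' max(g$radius)       # sqrt(0.5) at the corner bin
#' @export
make_frequency_grid <- function(height, width) {
  stopifnot(
    "height must be an integer >= 2" = is_count(height) && height >= 2,
    "width must be an integer >= 2" = is_count(width) && width >= 2
  )
  v <- dft_freqs(height) # rows -> y
  u <- dft_freqs(width)  # cols -> x
  U <- matrix(u, nrow = height, ncol = width, byrow = TRUE)
  V <- matrix(v, nrow = height, ncol = width)
  structure(
    list(radius = sqrt(U^2 + V^2), angle = atan2(V, U),
         height = as.integer(height), width = as.integer(width)),
    class = "frequency_grid"
  )
}

dft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Radial component of a Log-Gabor transfer function
#'
#' `exp(-log(r / f0)^2 / (2 * sigma_r^2))` over the grid, with the DC bin
#' forced to exactly 0 (the log has a singularity at r = 0, and a Log-Gabor
#' filter has no DC response by construction).
#'
#' @param grid A [make_frequency_grid()] result.
#' @param f0 Center frequency, normalized cycles/pixel, in (0, 0.5).
#' @param sigma_r Radial Gaussian sigma on the log-frequency axis (> 0).
#' @return A height x width matrix of values in `[0, 1]`, peaking at 1 on
#'   the circle where the radius equals `f0`.
#' @export
radial_component <- function(grid, f0, sigma_r) {
  stopifnot(
    "f0 must be in (0, 0.5)" =
      is.numeric(f0) && length(f0) == 1 && f0 > 0 && f0 < 0.5,
    "sigma_r must be > 0" =
      is.numeric(sigma_r) && length(sigma_r) == 1 && sigma_r > 0
  )
  r <- grid$radius
  out <- matrix(0, nrow(r), ncol(r))
  nz <- r > 0
  out[nz] <- exp(-(log(r[nz] / f0))^2 / (2 * sigma_r^2))
  out
}

#' Angular component of a Log-Gabor transfer function
#'
#' Gaussian in the wrapped angular distance between the grid angle and the
#' filter orientation `theta0`. The distance is computed through
#' `atan2(sin(d), cos(d))` so it lies in `[0, pi]` and the component is
#' periodic in the orientation.
#'
#' @param grid A [make_frequency_grid()] result.
#' @param theta0 Filter orientation in radians.
#' @param sigma_theta Angular Gaussian sigma in radians (> 0).
#' @return A height x width matrix of values in `[0, 1]`, peaking at 1 where
#'   the grid angle equals `theta0`.
#' @export
angular_component <- function(grid, theta0, sigma_theta) {
  stopifnot(
    "sigma_theta must be > 0" =
      is.numeric(sigma_theta) && length(sigma_theta) == 1 && sigma_theta > 0
  )
  d <- grid$angle - theta0
  dtheta <- abs(atan2(sin(d), cos(d)))
  exp(-dtheta^2 / (2 * sigma_theta^2))
}

#' Build a 2-D Log-Gabor filter bank in the frequency domain
#'
#' Constructs the `n_scales * n_orientations` transfer functions on a
#' height x width DFT grid. Scale `s` has center frequency
#' `1 / (min_wavelength * scale_mult^(s-1))`; orientation `o` is centered at
#' `(o-1) * pi / n_orientations`. Each transfer function is the pointwise
#' product of the radial and angular components, so values are in `[0, 1]`
#' and the DC bin is exactly 0 for every filter. Orientations cover only the
#' half-plane `[0, pi)`: because real images have conjugate-symmetric
#' spectra, single-half-plane filters recover the analytic (complex) response
#' whose modulus is the local texture energy.
#'
#' @param params A [log_gabor_params()] object.
#' @param height,width Grid size in pixels.
#' @return An object of class `log_gabor_bank`: list with `transfers` (list
#'   of matrices, scale-major order: filter `(s, o)` is element
#'   `(o - 1) * n_scales + s`), `params`, `height`, `width`, and a `meta`
#'   tibble (scale, orientation, wavelength, f0, theta0).
#' @examples
#' bank <- build_bank(log_gabor_params(), 64, 64)
#' length(bank$transfers) # 80
#' @export
build_bank <- function(params, height, width) {
  stopifnot(inherits(params, "log_gabor_params"))
  grid <- make_frequency_grid(height, width)
  if (min(height, width) < params$min_wavelength) {
    stop("grid smaller than min_wavelength: filters unresolvable",
         call. = FALSE)
  }
  f0s <- lg_center_frequencies(params)
  if (any(f0s <= 0) || any(f0s >= 0.5)) {
    stop("center frequencies fall outside (0, 0.5); adjust min_wavelength",
         call. = FALSE)
  }
  thetas <- lg_orientations(params)
  sigma_r <- abs(log(params$sigma_on_f))
  sigma_theta <- (pi / params$n_orientations) / params$angular_spread
  radials <- lapply(f0s, function(f0) radial_component(grid, f0, sigma_r))
  angulars <- lapply(thetas, function(t0) angular_component(grid, t0, sigma_theta))
  meta <- tidyr::expand_grid(
    orientation = seq_along(thetas),
    scale = seq_along(f0s)
  )
  transfers <- purrr::map2(meta$scale, meta$orientation,
                           function(s, o) radials[[s]] * angulars[[o]])
  meta <- tibble::tibble(
    filter = seq_along(transfers),
    scale = meta$scale,
    orientation = meta$orientation,
    wavelength = lg_wavelengths(params)[meta$scale],
    f0 = f0s[meta$scale],
    theta0 = thetas[meta$orientation]
  )
  structure(
    list(transfers = transfers, params = params, meta = meta,
         height = as.integer(height), width = as.integer(width)),
    class = "log_gabor_bank"
  )
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat("Log-Gabor filter bank:", length(x$transfers), "filters on a",
      x$height, "x", x$width, "grid\n")
  print(x$params)
  invisible(x)
}

#' Filter an image with every filter of a bank
#'
#' Frequency-domain filtering: each response is the inverse DFT of the image
#' spectrum multiplied by the (single-half-plane) transfer function, so it is
#' complex; its modulus is the local oriented band energy. Filtering is
#' circular (periodic boundary) and linear in the input.
#'
#' @param image A height x width numeric matrix matching the bank's grid.
#' @param bank A [build_bank()] result.
#' @param magnitude_only If `TRUE` (default) return moduli, else complex
#'   responses.
#' @return An object of class `response_stack`: list with `responses` (list
#'   of matrices, same order and spatial shape as the bank), `bank` metadata.
#' @export
apply_bank <- function(image, bank, magnitude_only = TRUE) {
  stopifnot(inherits(bank, "log_gabor_bank"), is.matrix(image))
  if (nrow(image) != bank$height || ncol(image) != bank$width) {
    stop("image shape does not match bank grid (",
         bank$height, " x ", bank$width, ")", call. = FALSE)
  }
  spectrum <- stats::fft(image)
  npix <- length(image)
  responses <- lapply(bank$transfers, function(tf) {
    r <- stats::fft(spectrum * tf, inverse = TRUE) / npix
    if (magnitude_only) Mod(r) else r
  })
  structure(
    list(responses = responses, meta = bank$meta, params = bank$params,
         height = bank$height, width = bank$width,
         magnitude = magnitude_only),
    class = "response_stack"
  )
}

#' Pool a stack of filter responses
#'
#' @param stack An [apply_bank()] result.
#' @param mode `"none"` keeps all `n_scales * n_orientations` maps;
#'   `"mean_over_scales"` averages magnitude maps over scales, leaving one
#'   map per orientation; `"global_energy_vector"` reduces each map to its
#'   mean magnitude, giving one fixed-length feature vector.
#' @return For the map modes, a list of matrices; for
#'   `"global_energy_vector"`, a numeric vector of length equal to the number
#'   of filters, in bank order.
#' @export
pool_responses <- function(stack,
                           mode = c("none", "mean_over_scales",
                                    "global_energy_vector")) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(stack, "response_stack"))
  mags <- if (isTRUE(stack$magnitude)) stack$responses
          else lapply(stack$responses, Mod)
  switch(mode,
    none = mags,
    mean_over_scales = {
      ns <- stack$params$n_scales
      lapply(seq_len(stack$params$n_orientations), function(o) {
        idx <- (o - 1) * ns + seq_len(ns)
        Reduce(`+`, mags[idx]) / ns
      })
    },
    global_energy_vector = vapply(mags, mean, numeric(1))
  )
}

#' Log-Gabor energy feature vector of an image
#'
#' Convenience wrapper: grayscale conversion if needed, [apply_bank()], then
#' [pool_responses()] with `"global_energy_vector"`. This is the fixed-length
#' handcrafted descriptor used by the classifier benchmark.
#'
#' @param image Numeric matrix (grayscale) or height x width x 3 array (RGB,
#'   converted with Rec. 601 luminance weights).
#' @param bank A [build_bank()] result.
#' @return Numeric vector, one mean magnitude per filter.
#' @export
log_gabor_energy <- function(image, bank) {
  pool_responses(apply_bank(to_luminance(image), bank), "global_energy_vector")
}

#' Convert an image to a single luminance channel
#'
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); grayscale matrices pass
#' through unchanged.
#' @param image Matrix or 3-channel array.
#' @return Numeric matrix.
#' @export
to_luminance <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3 && dim(image)[3] >= 3) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  if (length(dim(image)) == 3 && dim(image)[3] == 1) return(image[, , 1])
  stop("image must be a matrix or an array with 1 or 3 channels",
       call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 &&
    x == as.integer(x)
}
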