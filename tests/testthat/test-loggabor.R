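test_that("frequency grid has the documented DFT layout", {
  g <- make_frequency_grid(4, 4)
  expect_identical(g$radius[1, 1], 0)
  expect_equal(max(g$radius), sqrt(0.5^2 + 0.5^2))
  expect_equal(sum(g$radius == 0), 1)
  # even dimension: Nyquist on the negative side, never +0.5
  expect_true(any(gaborleaf:::dft_freqs(4) == -0.5))
  expect_false(any(gaborleaf:::dft_freqs(4) == 0.5))
  g5 <- make_frequency_grid(5, 5)
  expect_equal(sum(g5$radius == 0), 1)
  expect_equal(dim(g5$angle), dim(g5$radius))
  expect_true(all(g5$angle > -pi & g5$angle <= pi))
  expect_error(make_frequency_grid(0, 4), "height")
})

test_that("radial component follows the log-Gaussian form", {
  g <- make_frequency_grid(32, 32)
  f0 <- 1 / 6
  sigma_r <- abs(log(0.65))
  tf <- radial_component(g, f0, sigma_r)
  expect_identical(tf[1, 1], 0) # DC suppressed by construction
  # peak of 1 exactly where r == f0 (synthetic grid containing r = f0)
  gm <- g; gm$radius[2, 2] <- f0
  expect_equal(radial_component(gm, f0, sigma_r)[2, 2], 1)
  # one log-sigma below center: exp(-1/2)
  gm$radius[3, 3] <- 0.65 * f0
  expect_equal(radial_component(gm, f0, abs(log(0.65)))[3, 3], exp(-0.5))
  expect_error(radial_component(g, 0.6, 1), "f0")
  expect_error(radial_component(g, -0.1, 1), "f0")
})

test_that("angular component uses wrapped angular distance", {
  g <- make_frequency_grid(16, 16)
  st <- 0.2
  gm <- g
  gm$angle[2, 2] <- 0.7
  expect_equal(angular_component(gm, 0.7, st)[2, 2], 1)
  gm$angle[3, 3] <- 0.7 + st
  expect_equal(angular_component(gm, 0.7, st)[3, 3], exp(-0.5))
  # wrap-around: angles just above -pi and just below pi are near theta0 = pi
  eps <- 1e-3
  gm$angle[4, 4] <- pi - eps
  gm$angle[5, 5] <- -pi + eps
  a <- angular_component(gm, pi, st)
  expect_equal(a[4, 4], a[5, 5], tolerance = 1e-6)
  # oracle: distance through atan2(sin, cos)
  d <- abs(atan2(sin(gm$angle - 0.3), cos(gm$angle - 0.3)))
  expect_equal(angular_component(gm, 0.3, st), exp(-d^2 / (2 * st^2)))
})

test_that("build_bank produces the full scale-orientation grid", {
  bank <- build_bank(log_gabor_params(), 64, 64)
  expect_length(bank$transfers, 80)
  expect_true(all(vapply(bank$transfers, function(t) t[1, 1] == 0, TRUE)))
  expect_true(all(vapply(bank$transfers, max, 1) <= 1 + 1e-12))
  expect_true(all(vapply(bank$transfers, min, 1) >= 0))
  # wavelengths: geometric sequence, strictly increasing
  expect_equal(lg_wavelengths(log_gabor_params()), 3 * 2^(0:7))
  expect_true(all(diff(bank$meta$f0[1:8]) < 0)) # frequencies decrease with s
})

test_that("each transfer equals the radial x angular pointwise product", {
  p <- log_gabor_params(n_scales = 1, n_orientations = 1)
  bank <- build_bank(p, 24, 24)
  g <- make_frequency_grid(24, 24)
  oracle <- radial_component(g, 1 / 3, abs(log(0.65))) *
    angular_component(g, 0, pi / 1.5)
  expect_equal(bank$transfers[[1]], oracle)
})

test_that("every filter peaks within one grid bin of its center", {
  bank <- build_bank(log_gabor_params(), 64, 64)
  fr <- gaborleaf:::dft_freqs(64)
  step <- 1 / 64
  for (f in seq_along(bank$transfers)) {
    i <- arrayInd(which.max(bank$transfers[[f]]), c(64, 64))
    du <- abs(fr[i[2]] - bank$meta$f0[f] * cos(bank$meta$theta0[f]))
    dv <- abs(fr[i[1]] - bank$meta$f0[f] * sin(bank$meta$theta0[f]))
    expect_lte(max(du, dv), step + 1e-12)
  }
})

test_that("apply_bank suppresses DC, is linear and shift-covariant", {
  p <- tiny_params()
  bank <- build_bank(p, 16, 16)
  expect_error(apply_bank(matrix(0, 8, 8), bank), "shape")
  flat <- apply_bank(matrix(0.7, 16, 16), bank)
  expect_lt(max(unlist(flat$responses)), 1e-8 * 0.7)
  img <- matrix(runif(256), 16, 16)
  r1 <- apply_bank(img, bank)
  r2 <- apply_bank(2 * img, bank)
  expect_equal(lapply(r2$responses, function(m) m / 2), r1$responses,
               tolerance = 1e-12)
  # circular shift covariance (periodic filtering is exact)
  sh <- img[c(4:16, 1:3), c(7:16, 1:6)]
  rs <- apply_bank(sh, bank)
  shifted <- lapply(r1$responses, function(m) m[c(4:16, 1:3), c(7:16, 1:6)])
  expect_equal(rs$responses, shifted, tolerance = 1e-10)
})

test_that("gratings are claimed by their matched filter", {
  bank <- build_bank(log_gabor_params(), 64, 64)
  meta <- bank$meta
  # every filter whose center wavelength fits two full cycles in the grid
  for (f in which(meta$wavelength <= 32)) {
    img <- make_grating(64, meta$wavelength[f], meta$theta0[f])
    expect_identical(which.max(log_gabor_energy(img, bank)),
                     as.integer(f))
  }
})

test_that("low-frequency scales are matched on a grid that resolves them", {
  bank <- build_bank(log_gabor_params(), 256, 256)
  meta <- bank$meta
  idx <- which(meta$wavelength %in% c(48, 96) &
                 meta$orientation %in% c(1, 4, 8))
  for (f in idx) {
    img <- make_grating(256, meta$wavelength[f], meta$theta0[f])
    expect_identical(which.max(log_gabor_energy(img, bank)),
                     as.integer(f))
  }
})

test_that("frequency filtering matches direct spatial circular convolution", {
  bank <- build_bank(tiny_params(), 16, 16)
  set.seed(11)
  img <- matrix(runif(256), 16, 16)
  st <- apply_bank(img, bank, magnitude_only = FALSE)
  for (k in seq_along(bank$transfers)) {
    kern <- stats::fft(bank$transfers[[k]], inverse = TRUE) / 256
    direct <- matrix(0 + 0i, 16, 16)
    for (a in 0:15) {
      for (b in 0:15) {
        direct[a + 1, b + 1] <-
          sum(img * kern[((a - (0:15)) %% 16) + 1, ((b - (0:15)) %% 16) + 1])
      }
    }
    rel <- max(Mod(direct - st$responses[[k]])) /
      max(Mod(st$responses[[k]]))
    expect_lt(rel, 1e-6)
  }
})

test_that("pool_responses modes agree with direct recomputation", {
  p <- tiny_params()
  bank <- build_bank(p, 16, 16)
  set.seed(3)
  stack <- apply_bank(matrix(runif(256), 16, 16), bank)
  expect_length(pool_responses(stack, "none"), 6)
  mos <- pool_responses(stack, "mean_over_scales")
  expect_length(mos, 3)
  # orientation o mean recomputed independently
  for (o in 1:3) {
    idx <- (o - 1) * 2 + 1:2
    expect_equal(mos[[o]], (stack$responses[[idx[1]]] +
                              stack$responses[[idx[2]]]) / 2)
  }
  gev <- pool_responses(stack, "global_energy_vector")
  expect_equal(gev, vapply(stack$responses, mean, numeric(1)))
  # zero input -> zero vector
  z <- apply_bank(matrix(0, 16, 16), bank)
  expect_equal(pool_responses(z, "global_energy_vector"), rep(0, 6))
  expect_error(pool_responses(stack, "bogus"))
})

test_that("banks round-trip through the array container + JSON sidecar", {
  bank <- build_bank(tiny_params(), 12, 12)
  path <- withr::local_tempfile(fileext = ".bank")
  write_bank(bank, path)
  back <- read_bank(path)
  expect_equal(back$transfers, bank$transfers)
  expect_equal(unclass(back$params), unclass(bank$params))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(log_gabor_params(min_wavelength = 1), "Nyquist")
  expect_error(log_gabor_params(sigma_on_f = 1.2), "sigma_on_f")
  expect_error(log_gabor_params(scale_mult = 1), "scale_mult")
  expect_error(log_gabor_params(n_scales = 0), "n_scales")
  # Nyquist violation through the scale ladder: f0 >= 0.5
  expect_error(build_bank(log_gabor_params(min_wavelength = 2), 32, 32),
               "frequencies")
})
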