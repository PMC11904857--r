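# Intensity-profile morphometry.

test_that("profile extraction: flat image, row identity, diagonal geometry", {
  m <- matrix(3, 20, 40)
  img <- multichannel_image(list(m), pixel_size = 0.1)
  pr <- extract_profile(img)
  expect_true(all(pr$intensity[, 1L] == 3))

  # axis-aligned line reproduces the pixel row exactly
  m2 <- matrix(runif(20 * 40), 20, 40)
  img2 <- multichannel_image(list(m2), pixel_size = 0.1)
  pr2 <- extract_profile(img2, line = c(1, 7, 40, 7))
  expect_equal(pr2$intensity[, 1L], m2[7, ])

  # diagonal line across vertical ridges stretches the period by 1/cos(theta)
  g <- striation_geometry(period = 2, actin_shift = 0, image_size = c(120, 160),
                          pixel_size = 0.1)
  imgd <- simulate_striation_image(g)
  prd <- extract_profile(imgd, line = c(1, 1, 120, 120))   # 45 degrees
  mx <- detect_extrema(prd, 1L, "max")
  expect_equal(median(diff(as.numeric(mx))), 2 * sqrt(2), tolerance = 0.02)

  expect_error(extract_profile(img, line = c(0, 1, 100, 1)),
               class = "cmq_invalid_argument")
})

test_that("extremum detection is sub-pixel accurate and prominence-gated", {
  px <- 0.05
  pr <- profile_from_function(function(x) exp(-(x - 5)^2 / (2 * 0.3^2)),
                              pixel_size = px)
  pos <- detect_extrema(pr, 1L, "max")
  expect_length(pos, 1L)
  expect_lt(abs(as.numeric(pos) - 5), 0.25 * px)

  # pure cosine of period p: maxima spaced p
  p <- 1.7
  prc <- profile_from_function(function(x) cos(2 * pi * x / p), pixel_size = px)
  mx <- detect_extrema(prc, 1L, "max")
  expect_equal(unname(diff(as.numeric(mx))), rep(p, length(mx) - 1L),
               tolerance = 0.01)

  # monotone ramp: no extrema
  prr <- profile_from_function(function(x) x, pixel_size = px)
  expect_length(detect_extrema(prr, 1L, "max"), 0L)
})

test_that("actin shift recovers generator ground truth and flags ties", {
  for (shift in c(0, 0.20, -0.3)) {
    g <- striation_geometry(actin_shift = shift, image_size = c(32, 200),
                            pixel_size = 0.1)
    pr <- extract_profile(simulate_striation_image(g))
    got <- actin_shift(pr)
    expect_lt(abs(as.numeric(got) - abs(shift)), 0.02 + 0.25 * g$pixel_size)
  }

  # sub-pixel recovery with Poisson noise at SNR >= 10
  g <- striation_geometry(actin_shift = 0.2, image_size = c(64, 200),
                          pixel_size = 0.1)
  pr <- extract_profile(simulate_striation_image(g, photons = 200, seed = 1))
  expect_lt(abs(as.numeric(actin_shift(pr)) - 0.2), 0.02)

  # shift of exactly period/2: nearest minimum is ambiguous -> flagged
  per <- 2
  prt <- profile_from_function(
    function(x) cos(2 * pi * x / per),
    function(x) 1 - cos(2 * pi * (x - per / 2) / per),  # minima at per/2 offset
    length_um = 20, pixel_size = 0.05)
  expect_error(actin_shift(prt), class = "cmq_degenerate_input")
})

test_that("FWHM machinery: Gaussian identity, rectangle, linearity, offsets", {
  px <- 0.05
  ridges <- function(sig) function(x) {
    d <- x - 2 * round(x / 2)
    exp(-d^2 / (2 * sig^2))
  }
  pr <- profile_from_function(ridges(0.15), pixel_size = px)
  w <- zdisk_width(pr, 1L)
  expect_lt(abs(as.numeric(w) - 2 * sqrt(2 * log(2)) * 0.15), px)

  # doubling sigma doubles the FWHM
  w2 <- zdisk_width(profile_from_function(ridges(0.30), pixel_size = px), 1L)
  expect_equal(as.numeric(w2) / as.numeric(w), 2, tolerance = 0.02)

  # additive offset invariance (trough-referenced half level)
  pro <- profile_from_function(function(x) 10 + ridges(0.15)(x), pixel_size = px)
  expect_equal(as.numeric(zdisk_width(pro, 1L)), as.numeric(w), tolerance = 1e-6)

  # rectangular ridge of width 0.6 um
  rectf <- function(x) {
    d <- abs(x - 2 * round(x / 2))
    ifelse(d <= 0.3, 1, 0)
  }
  wr <- zdisk_width(profile_from_function(rectf, pixel_size = px), 1L)
  expect_lt(abs(as.numeric(wr) - 0.6), 2 * px)

  # two merged Gaussians form one wider band than a single Gaussian
  merged <- function(x) {
    d <- x - 4 * round(x / 4)
    exp(-(d - 0.2)^2 / (2 * 0.15^2)) + exp(-(d + 0.2)^2 / (2 * 0.15^2))
  }
  wm <- band_length(profile_from_function(function(x) 0 * x, merged,
                                          pixel_size = px), 2L)
  expect_gt(as.numeric(wm), as.numeric(w))
})

test_that("band length recovers the generator's band geometry", {
  g <- striation_geometry(band_length = 0.8, image_size = c(32, 200),
                          pixel_size = 0.1)
  pr <- extract_profile(simulate_striation_image(g))
  expect_lt(abs(as.numeric(band_length(pr, 2L)) - 0.8), g$pixel_size)
})

test_that("normalized intensity: identity, doubling, gains, gain invariance", {
  base <- matrix(runif(400, 0.2, 1), 20, 20)
  img_same <- multichannel_image(list(base, base), pixel_size = 0.1)
  expect_equal(normalized_intensity(img_same, 1L, 2L), 1.0)

  img_2x <- multichannel_image(list(2 * base, base), pixel_size = 0.1)
  expect_equal(normalized_intensity(img_2x, 1L, 2L), 2.0)

  # synthetic channel gains (3, 1.5) -> ratio 2 despite Poisson noise
  g <- striation_geometry(channel_gains = c(3, 1.5))
  gref <- striation_geometry(channel_gains = c(1.5, 1.5))
  img <- simulate_striation_image(g, photons = 500, seed = 2)
  # use the same pattern in both channels to isolate the gain ratio
  img$channels[[2L]] <- simulate_striation_image(gref, photons = 500,
                                                 seed = 3)$channels[[1L]]
  expect_equal(normalized_intensity(img, 1L, 2L), 2.0, tolerance = 0.05)

  # global gain applied to both channels leaves the ratio unchanged
  img_g <- multichannel_image(lapply(img$channels, `*`, 7), pixel_size = 0.1)
  expect_equal(normalized_intensity(img_g, 1L, 2L),
               normalized_intensity(img, 1L, 2L), tolerance = 1e-12)

  img_zero <- multichannel_image(list(base, matrix(1, 20, 20)), pixel_size = 0.1)
  expect_error(normalized_intensity(img_zero, 1L, 2L),
               class = "cmq_degenerate_input")
})

test_that("length outputs scale with the pixel-size metadata", {
  g1 <- striation_geometry(pixel_size = 0.1, image_size = c(32, 200))
  img <- simulate_striation_image(g1)
  res1 <- analyze_image(img)
  # same pixels declared twice as large -> all lengths double
  img2 <- multichannel_image(img$channels, pixel_size = 0.2,
                             channel_labels = img$channel_labels)
  res2 <- analyze_image(img2)
  expect_equal(res2$actin_shift, 2 * res1$actin_shift, tolerance = 1e-9)
  expect_equal(res2$zdisk_width, 2 * res1$zdisk_width, tolerance = 1e-9)
  expect_equal(res2$band_length, 2 * res1$band_length, tolerance = 1e-9)
})
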