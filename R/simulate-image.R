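# Synthetic two-channel striated (sarcomeric) images with known geometry.

#' Striation geometry for the synthetic image generator
#'
#' Describes a field of parallel sarcomeric striations: Z-disk ridges of
#' Gaussian cross-section repeating at `period` in channel 1
#' (phalloidin/alpha-actinin-like) and complementary bands in channel 2
#' (cardiac-actin-like) whose minima sit at the channel-1 maxima
#' translated by `actin_shift`.
#'
#' @param period sarcomere length, um.
#' @param zdisk_sigma Gaussian sigma of the Z-disk ridge, um; must satisfy
#'   `0 < zdisk_sigma < period/2`.
#' @param actin_shift translation of the channel-2 minima relative to the
#'   channel-1 maxima, um; `|actin_shift| < period/2`.
#' @param band_length bright-band length (FWHM) of channel 2, um.
#' @param pixel_size physical pixel size, um/px.
#' @param image_size c(rows, cols) in px.
#' @param channel_gains per-channel multiplicative gains.
#' @return an object of class `striation_geometry`.
#' @export
striation_geometry <- function(period = 1.9, zdisk_sigma = 0.15,
                               actin_shift = 0.2, band_length = 0.8,
                               pixel_size = 0.1, image_size = c(64, 192),
                               channel_gains = c(1, 1)) {
  assert_num(pixel_size, "pixel_size", positive = TRUE)
  if (!(zdisk_sigma > 0 && zdisk_sigma < period / 2))
    cmq_stop("need 0 < zdisk_sigma < period/2", "cmq_invalid_argument")
  if (!(abs(actin_shift) < period / 2))
    cmq_stop("need |actin_shift| < period/2", "cmq_invalid_argument")
  if (!(band_length > 0 && band_length < period))
    cmq_stop("need 0 < band_length < period", "cmq_invalid_argument")
  structure(list(period = period, zdisk_sigma = zdisk_sigma,
                 actin_shift = actin_shift, band_length = band_length,
                 pixel_size = pixel_size, image_size = as.integer(image_size),
                 channel_gains = channel_gains),
            class = "striation_geometry")
}

# distance from x to the nearest point of the lattice {offset + k*period}
wrapped_dist <- function(x, period, offset = 0) {
  d <- x - offset
  d - period * round(d / period)
}

#' Simulate a two-channel striated image
#'
#' Channel 1 carries periodic Gaussian ridges (Z-disks); channel 2 carries
#' complementary bright bands whose intensity minima coincide with the
#' channel-1 ridge positions translated by the geometry's `actin_shift`.
#' Optional Poisson photon noise is applied per pixel.
#'
#' @param geom a [striation_geometry()].
#' @param photons expected photon count per unit intensity; `Inf` (default)
#'   gives a noiseless image. At intensity `I` the signal-to-noise ratio is
#'   `sqrt(photons * I)`.
#' @param seed integer seed for the noise.
#' @return a `multichannel_image`: list of channel matrices, pixel size and
#'   channel labels, with the generating geometry attached as ground truth.
#' @export
simulate_striation_image <- function(geom = striation_geometry(),
                                     photons = Inf, seed = NULL) {
  stopifnot(inherits(geom, "striation_geometry"))
  if (geom$pixel_size > geom$period / 4)
    cmq_stop("pixel_size > period/4: striations would be undersampled",
             "cmq_undersampling")
  nr <- geom$image_size[1L]; nc <- geom$image_size[2L]
  x <- (seq_len(nc) - 0.5) * geom$pixel_size
  offset <- geom$period / 2                       # first ridge away from the edge
  bg <- 0.05

  d1 <- wrapped_dist(x, geom$period, offset)
  ridge <- exp(-d1^2 / (2 * geom$zdisk_sigma^2))
  ch1_row <- geom$channel_gains[1L] * (bg + ridge)

  # channel 2: bright Gaussian bands centered midway between the shifted
  # ridge lattice, so the intensity minima sit exactly at the channel-1
  # maxima translated by actin_shift, and the band FWHM is band_length
  band_sigma <- geom$band_length / (2 * sqrt(2 * log(2)))
  d2 <- wrapped_dist(x, geom$period, offset + geom$actin_shift + geom$period / 2)
  band <- exp(-d2^2 / (2 * band_sigma^2))
  ch2_row <- geom$channel_gains[2L] * (bg + band)

  ch1 <- matrix(ch1_row, nrow = nr, ncol = nc, byrow = TRUE)
  ch2 <- matrix(ch2_row, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.finite(photons)) {
    if (is.null(seed)) cmq_stop("`seed` is required for Poisson noise",
                                "cmq_invalid_argument")
    set.seed(seed)
    ch1 <- matrix(stats::rpois(length(ch1), photons * ch1) / photons, nr, nc)
    ch2 <- matrix(stats::rpois(length(ch2), photons * ch2) / photons, nr, nc)
  }
  multichannel_image(list(ch1, ch2), pixel_size = geom$pixel_size,
                     channel_labels = c("phalloidin", "actin"),
                     ground_truth = geom)
}

#' Construct a multi-channel image container
#'
#' @param channels list of numeric matrices, all the same dimension.
#' @param pixel_size physical pixel size, um/px.
#' @param channel_labels character labels, one per channel.
#' @param ground_truth optional generating [striation_geometry()].
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size,
                               channel_labels = NULL, ground_truth = NULL) {
  if (!length(channels)) cmq_stop("no channels", "cmq_invalid_argument")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1L))) ||
      length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    cmq_stop("all channels must be matrices of identical dimension",
             "cmq_invalid_argument")
  assert_num(pixel_size, "pixel_size", positive = TRUE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 channel_labels = channel_labels %||%
                   paste0("ch", seq_along(channels)),
                 ground_truth = ground_truth),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<multichannel_image> %d channel(s) [%s], %d x %d px at %g um/px\n",
              length(x$channels), paste(x$channel_labels, collapse = ", "),
              d[1L], d[2L], x$pixel_size))
  invisible(x)
}
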