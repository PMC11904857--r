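# Intensity-profile morphometry of two-channel striated images:
# actin shift, Z-disk width (FWHM), band lengths, normalized intensity.

bilinear <- function(mat, x, y) {
  # x = column coordinate, y = row coordinate (1-based, px)
  nr <- nrow(mat); nc <- ncol(mat)
  x0 <- pmin(pmax(floor(x), 1L), nc - 1L); y0 <- pmin(pmax(floor(y), 1L), nr - 1L)
  fx <- x - x0; fy <- y - y0
  mat[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    mat[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    mat[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    mat[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Sample an intensity profile along a line
#'
#' Bilinear sampling of every channel along the straight line from
#' `(x0, y0)` to `(x1, y1)` (pixel coordinates, x = column, y = row) at
#' one-pixel spacing. Positions are reported in um.
#'
#' @param image a `multichannel_image`.
#' @param line numeric `c(x0, y0, x1, y1)` in px; default: the horizontal
#'   mid-row across the full width.
#' @return an `intensity_profile`: `positions` (um), an
#'   `intensity` matrix (samples x channels), pixel size, line endpoints
#'   and channel labels.
#' @export
extract_profile <- function(image, line = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  nr <- nrow(image$channels[[1L]]); nc <- ncol(image$channels[[1L]])
  if (is.null(line)) line <- c(1, (nr + 1) / 2, nc, (nr + 1) / 2)
  if (length(line) != 4L || any(!is.finite(line)))
    cmq_stop("`line` must be c(x0, y0, x1, y1)", "cmq_invalid_argument")
  if (any(line[c(1L, 3L)] < 1) || any(line[c(1L, 3L)] > nc) ||
      any(line[c(2L, 4L)] < 1) || any(line[c(2L, 4L)] > nr))
    cmq_stop("line endpoints outside the image", "cmq_invalid_argument")
  len <- sqrt((line[3L] - line[1L])^2 + (line[4L] - line[2L])^2)
  n <- floor(len) + 1L
  f <- if (n == 1L) 0 else (seq_len(n) - 1L) / (n - 1L)
  xs <- line[1L] + f * (line[3L] - line[1L])
  ys <- line[2L] + f * (line[4L] - line[2L])
  inten <- vapply(image$channels, bilinear, numeric(n), x = xs, y = ys)
  spacing <- if (n == 1L) image$pixel_size else len / (n - 1L) * image$pixel_size
  structure(list(positions = (seq_len(n) - 1L) * spacing,
                 intensity = inten, pixel_size = image$pixel_size,
                 spacing = spacing, line = line,
                 channel_labels = image$channel_labels),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples over %.1f um, channels: %s\n",
              length(x$positions), max(x$positions),
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

profile_channel <- function(profile, channel) {
  if (is.character(channel))
    channel <- match(channel, profile$channel_labels)
  if (is.na(channel) || channel < 1L || channel > ncol(profile$intensity))
    cmq_stop("unknown channel", "cmq_invalid_argument")
  profile$intensity[, channel]
}

# topographic prominence of local maxima of s at indices pk
peak_prominence <- function(s, pk) {
  vapply(pk, function(i) {
    left <- s[seq_len(i)]
    hi_l <- which(left > s[i])
    base_l <- if (length(hi_l)) min(left[max(hi_l):i]) else min(left)
    right <- s[i:length(s)]
    hi_r <- which(right > s[i])
    base_r <- if (length(hi_r)) min(right[1L:min(hi_r)]) else min(right)
    s[i] - max(base_l, base_r)
  }, numeric(1L))
}

#' Detect sub-pixel extremum positions along a profile
#'
#' Smooths with a 3-point moving average, finds interior local maxima (or
#' minima) exceeding a prominence threshold, and refines each position by
#' 3-point parabolic interpolation.
#'
#' @param profile an `intensity_profile`.
#' @param channel channel index or label.
#' @param kind `"max"` or `"min"`.
#' @param prominence minimum topographic prominence as a fraction of the
#'   channel's dynamic range (default 10%).
#' @return numeric positions in um (possibly empty); `attr(, "values")`
#'   carries the raw intensities at the detected extrema.
#' @export
detect_extrema <- function(profile, channel = 1L, kind = c("max", "min"),
                           prominence = 0.10) {
  stopifnot(inherits(profile, "intensity_profile"))
  kind <- match.arg(kind)
  y <- profile_channel(profile, channel)
  ys <- moving_average(y, 3L)
  s <- if (kind == "min") -ys else ys
  n <- length(s)
  if (n < 3L) return(numeric(0L))
  cand <- which(s[2:(n - 1L)] > s[1:(n - 2L)] & s[2:(n - 1L)] >= s[3:n]) + 1L
  if (!length(cand)) return(numeric(0L))
  rng <- diff(range(s))
  if (rng > 0) cand <- cand[peak_prominence(s, cand) >= prominence * rng]
  if (!length(cand)) return(numeric(0L))
  dx <- profile$spacing
  pos <- vapply(cand, function(i) {
    den <- s[i - 1L] - 2 * s[i] + s[i + 1L]
    delta <- if (den == 0) 0 else 0.5 * (s[i - 1L] - s[i + 1L]) / den
    profile$positions[i] + min(max(delta, -0.5), 0.5) * dx
  }, numeric(1L))
  structure(pos, values = y[cand], index = cand)
}

#' Measure the actin shift along a striation profile
#'
#' For each detected maximum of the Z-disk channel (phalloidin-like), the
#' distance to the nearest minimum of the actin channel is taken; the
#' mean of the absolute distances across periods is returned. Maxima
#' whose two nearest minima are equidistant within a quarter pixel
#' (shift of half a period) are ambiguous: they are flagged and excluded.
#'
#' @param profile an `intensity_profile`.
#' @param max_channel channel carrying the ridge maxima (default 1).
#' @param min_channel channel carrying the complementary minima (default 2).
#' @return mean absolute shift, um, with attributes `n_periods_used` and
#'   `ambiguous` (count of flagged ties).
#' @export
actin_shift <- function(profile, max_channel = 1L, min_channel = 2L) {
  maxima <- detect_extrema(profile, max_channel, "max")
  if (length(maxima) < 3L)
    cmq_stop("need at least 3 ridge maxima for an actin shift estimate",
             "cmq_insufficient_data")
  minima <- detect_extrema(profile, min_channel, "min")
  if (!length(minima))
    cmq_stop("no minima detected in the actin channel", "cmq_insufficient_data")
  tol <- 0.25 * profile$spacing
  d <- numeric(0L); ambiguous <- 0L
  for (m in as.numeric(maxima)) {
    dist <- sort(abs(minima - m))
    if (length(dist) > 1L && dist[2L] - dist[1L] < tol) {
      ambiguous <- ambiguous + 1L            # half-period tie: undefined
    } else d <- c(d, dist[1L])
  }
  if (!length(d))
    cmq_stop("all maxima had ambiguous nearest minima", "cmq_degenerate_input")
  structure(mean(d), n_periods_used = length(d), ambiguous = ambiguous)
}

# FWHM of one ridge: half level referenced to the local trough, crossings
# searched outward from the peak on the raw profile (noise-robust and
# unbiased by smoothing).
ridge_fwhm <- function(pos, y, i_peak, trough_level) {
  half <- trough_level + (y[i_peak] - trough_level) / 2
  n <- length(y)
  il <- i_peak
  while (il > 1L && y[il] > half) il <- il - 1L
  if (y[il] > half) return(NA_real_)
  xl <- pos[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (pos[il + 1L] - pos[il])
  ir <- i_peak
  while (ir < n && y[ir] > half) ir <- ir + 1L
  if (y[ir] > half) return(NA_real_)
  xr <- pos[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) *
    (pos[ir] - pos[ir - 1L])
  xr - xl
}

fwhm_by_channel <- function(profile, channel, min_ridges = 3L) {
  pos <- profile$positions
  y <- profile_channel(profile, channel)
  maxima <- detect_extrema(profile, channel, "max")
  if (length(maxima) < min_ridges)
    cmq_stop(sprintf("need at least %d ridges for a width estimate", min_ridges),
             "cmq_insufficient_data")
  minima <- detect_extrema(profile, channel, "min")
  idx <- attr(maxima, "index")
  period_est <- stats::median(diff(sort(as.numeric(maxima))))
  widths <- numeric(0L); flagged <- 0L
  for (j in seq_along(idx)) {
    m <- as.numeric(maxima)[j]
    # local trough level: raw minima adjacent to this ridge, else global min
    left <- minima[minima < m]; right <- minima[minima > m]
    vals <- attr(minima, "values")
    tl <- c(if (length(left)) vals[which(minima < m)][which.max(left)],
            if (length(right)) vals[which(minima > m)][which.min(right)])
    trough <- if (length(tl)) mean(tl) else min(y)
    w <- ridge_fwhm(pos, y, idx[j], trough)
    if (is.na(w)) next
    if (w > period_est) { flagged <- flagged + 1L; next }  # overlapping ridges
    widths <- c(widths, w)
  }
  if (!length(widths))
    cmq_stop("no measurable ridges", "cmq_degenerate_input")
  structure(mean(widths), n_periods_used = length(widths), flagged = flagged)
}

#' Z-disk width from a striation profile
#'
#' Per-ridge full width at half maximum above the local trough level
#' (offset-invariant), crossings located by linear interpolation; the
#' mean across ridges is returned. Ridges wider than the striation period
#' are flagged as overlapping and excluded.
#'
#' @param profile an `intensity_profile`.
#' @param channel Z-disk channel index or label (default 1).
#' @return mean FWHM, um, with attributes `n_periods_used` and `flagged`.
#' @export
zdisk_width <- function(profile, channel = 1L) fwhm_by_channel(profile, channel)

#' Stained-band length from a profile
#'
#' The same trough-referenced FWHM machinery as [zdisk_width()], applied
#' to a band-staining channel (e.g. troponin I or tropomyosin).
#'
#' @param profile an `intensity_profile`.
#' @param channel band channel index or label (default 2).
#' @return mean band FWHM, um, with attribute `n_periods_used`.
#' @export
band_length <- function(profile, channel = 2L) fwhm_by_channel(profile, channel)

#' Background-corrected intensity ratio of two channels
#'
#' `(mean(target) - bg_t) / (mean(reference) - bg_r)` within an optional
#' mask, with per-channel background taken as the 5th intensity
#' percentile. Invariant to a global gain applied to both channels.
#'
#' @param image a `multichannel_image`.
#' @param target_channel,reference_channel channel indices or labels.
#' @param mask optional logical matrix selecting pixels.
#' @param bg_quantile background quantile (default 0.05).
#' @return unitless intensity ratio.
#' @export
normalized_intensity <- function(image, target_channel = 1L,
                                 reference_channel = 2L, mask = NULL,
                                 bg_quantile = 0.05) {
  stopifnot(inherits(image, "multichannel_image"))
  pick <- function(ch) {
    if (is.character(ch)) ch <- match(ch, image$channel_labels)
    if (is.na(ch) || ch < 1L || ch > length(image$channels))
      cmq_stop("unknown channel", "cmq_invalid_argument")
    image$channels[[ch]]
  }
  tg <- pick(target_channel); rf <- pick(reference_channel)
  if (is.null(mask)) mask <- !logical(length(tg))
  bg_t <- stats::quantile(tg, bg_quantile, names = FALSE)
  bg_r <- stats::quantile(rf, bg_quantile, names = FALSE)
  denom <- mean(rf[mask]) - bg_r
  if (!is.finite(denom) || denom <= 0)
    cmq_stop("reference channel has no signal above background",
             "cmq_degenerate_input")
  (mean(tg[mask]) - bg_t) / denom
}

#' Analyze a striation image end to end
#'
#' Extracts the default (or supplied) profile and reports the full
#' morphometry row: actin shift, Z-disk width, band length and the
#' channel-1-to-channel-2 normalized intensity.
#'
#' @param image a `multichannel_image`.
#' @param line optional profile line, see [extract_profile()].
#' @return a one-row data.frame (`morphometry_result` columns).
#' @export
analyze_image <- function(image, line = NULL) {
  pr <- extract_profile(image, line)
  shift <- actin_shift(pr)
  zw <- zdisk_width(pr, 1L)
  bl <- band_length(pr, 2L)
  data.frame(actin_shift = as.numeric(shift),
             zdisk_width = as.numeric(zw),
             band_length = as.numeric(bl),
             normalized_intensity = normalized_intensity(image, 1L, 2L),
             n_periods_used = attr(shift, "n_periods_used"))
}

#' Analyze an image cohort
#'
#' @param cohort a `cohort` with `modality = "image"`.
#' @return a data.frame, one [analyze_image()] row per cell.
#' @export
analyze_image_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"), cohort$modality == "image")
  rows <- lapply(seq_along(cohort$cells), function(j) {
    cbind(data.frame(cell = j, group = cohort$group[j]),
          analyze_image(cohort$cells[[j]]))
  })
  do.call(rbind, rows)
}
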