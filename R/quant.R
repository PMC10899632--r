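#' Detect marker band peaks in a lane profile
#'
#' Finds local intensity maxima whose topographic prominence exceeds
#' `min_prominence` times the profile maximum, then refines each peak to
#' sub-pixel precision by 3-point parabolic interpolation.
#'
#' @param profile A `lane_profile` (tibble with `pixel`, `intensity`).
#' @param min_prominence Prominence threshold as a fraction of the profile
#'   maximum.
#' @param n_expected Optional expected number of peaks; an error naming both
#'   counts is raised on mismatch.
#' @return Numeric vector of peak pixel positions, sorted increasing; empty
#'   for a flat profile.
#' @export
detect_marker_peaks <- function(profile, min_prominence = 0.1,
                                n_expected = NULL) {
  y <- profile$intensity
  n <- length(y)
  if (n == 0) abort("empty profile")
  ymax <- max(y)
  peaks <- numeric(0)
  if (ymax > 0) {
    is_peak <- which(diff(sign(diff(y))) < 0) + 1L
    prom <- vapply(is_peak, function(i) peak_prominence(y, i), numeric(1))
    keep <- is_peak[prom >= min_prominence * ymax]
    peaks <- vapply(keep, function(i) {
      if (i <= 1L || i >= n) return(as.numeric(i - 1L))
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      shift <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
      (i - 1L) + shift
    }, numeric(1))
    peaks <- sort(peaks)
  }
  if (!is.null(n_expected) && length(peaks) != n_expected) {
    abort(sprintf("expected %d marker peaks but detected %d",
                  n_expected, length(peaks)))
  }
  peaks
}

## topographic prominence of the local maximum at index i; each side's key
## saddle is the minimum between the peak and the nearest point at least as
## high (or the side minimum when no higher ground exists on that side)
peak_prominence <- function(y, i) {
  n <- length(y)
  side_min <- function(idx) {
    if (length(idx) == 0) return(min(y))
    vals <- y[idx]                      # ordered moving away from the peak
    higher <- which(vals >= y[i])
    if (length(higher) == 0) min(vals) else min(vals[seq_len(higher[1])])
  }
  left <- side_min(rev(seq_len(i - 1L)))
  right <- side_min(if (i >= n) integer(0) else seq(i + 1L, n))
  y[i] - max(left, right)
}

#' Fit the marker-based size calibration
#'
#' Ordinary least squares of marker pixel position on marker length (`linear`
#' mode) or on log length (`log` mode), the regression used to convert lane
#' pixel coordinates into RNA lengths. The fitted line is inverted
#' analytically for the pixel-to-length lookup used by [bin_lane()].
#'
#' @param peak_pixels Detected marker peak positions (pixels), one per
#'   marker, in the same order as `marker_lengths`.
#' @param marker_lengths Known marker lengths (nt), strictly increasing.
#' @param mode `"linear"` or `"log"`.
#' @return An object of class `size_calibration`: the underlying `lm` plus
#'   `mode`, `intercept`, `slope`, `r_squared` and per-marker `residuals`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
fit_size_calibration <- function(peak_pixels, marker_lengths,
                                 mode = c("linear", "log")) {
  mode <- match.arg(mode)
  if (length(peak_pixels) != length(marker_lengths)) {
    abort(sprintf("%d peaks but %d marker lengths",
                  length(peak_pixels), length(marker_lengths)))
  }
  if (length(marker_lengths) < 2) abort("need at least 2 markers")
  if (any(diff(marker_lengths) <= 0)) {
    abort("marker_lengths must be strictly increasing")
  }
  d <- diff(peak_pixels)
  if (!(all(d > 0) || all(d < 0))) {
    abort("peak/length pairing is not monotonic")
  }
  x <- if (mode == "log") log(marker_lengths) else marker_lengths
  fit <- lm(peak_pixels ~ x, data = data.frame(peak_pixels, x))
  ssr <- sum(resid(fit)^2)
  sst <- sum((peak_pixels - mean(peak_pixels))^2)
  r2 <- if (length(peak_pixels) == 2L || sst == 0) 1 else 1 - ssr / sst
  structure(
    list(
      model = fit, mode = mode,
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      r_squared = r2,
      residuals = unname(resid(fit)),
      marker_lengths = marker_lengths, peak_pixels = peak_pixels
    ),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("<size_calibration> %s: pixel = %.4g %+.4g * %s, R^2 = %.5f\n",
              x$mode, x$intercept, x$slope,
              if (x$mode == "log") "log(length)" else "length", x$r_squared))
  invisible(x)
}

#' Map lengths to pixels (and back) through a fitted calibration
#'
#' @param calibration A [fit_size_calibration()] result.
#' @param lengths,pixels Values to convert.
#' @return Numeric vector.
#' @export
calibration_pixel <- function(calibration, lengths) {
  x <- if (calibration$mode == "log") log(lengths) else lengths
  calibration$intercept + calibration$slope * x
}

#' @rdname calibration_pixel
#' @export
calibration_length <- function(calibration, pixels) {
  x <- (pixels - calibration$intercept) / calibration$slope
  if (calibration$mode == "log") exp(x) else x
}

#' Subtract lane background
#'
#' `"min"` subtracts the lane minimum. `"rolling_min"` estimates a slowly
#' varying baseline by a running-minimum (erosion) pass followed by a
#' running-maximum (dilation) pass over the same centered window — a
#' morphological opening, which hugs sloped baselines without the half-window
#' lag of a bare running minimum and never rises into band peaks. Output
#' intensities are clamped at zero.
#'
#' @param profile A `lane_profile`.
#' @param method `"rolling_min"` (default) or `"min"` or `"none"`.
#' @param width Window width in pixels for `rolling_min`; must exceed the
#'   widest band (default 301 px, ~15 nt at the default mobility).
#' @return A `lane_profile` with non-negative intensities.
#' @export
subtract_background <- function(profile, method = c("rolling_min", "min", "none"),
                                width = 301L) {
  method <- match.arg(method)
  y <- profile$intensity
  if (method == "none") return(profile)
  base <- if (method == "min") {
    rep(min(y), length(y))
  } else {
    if (width < 1) abort("width must be >= 1")
    rolling_extreme(rolling_extreme(y, width, min), width, max)
  }
  out <- profile
  out$intensity <- pmax(0, y - base)
  out
}

rolling_extreme <- function(y, width, f) {
  h <- (as.integer(width) - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    f(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Integrate a lane profile into seven-bin length fractions
#'
#' Maps each bin's length boundaries into pixel coordinates through the
#' calibration (boundaries at half-integer lengths, so bin 1 covers the
#' single stalled length), integrates the profile intensity over each pixel
#' interval (half-open toward increasing length so the bins partition the
#' lane), and normalizes by the total signal inside the binned region.
#'
#' @param profile A (background-subtracted) `lane_profile`.
#' @param calibration A [fit_size_calibration()] result, monotonic over the
#'   scheme's length support.
#' @param scheme A [bin_scheme()].
#' @return One-row tibble with columns `bin1`..`bin7` summing to 1.
#' @export
bin_lane <- function(profile, calibration, scheme = default_bin_scheme()) {
  validate_bin_scheme(scheme)
  stall <- scheme$upper[1]
  len_edges <- c(stall - 0.5, stall + 0.5, scheme$upper[2:7] + 0.5)
  px_edges <- calibration_pixel(calibration, len_edges)
  n_px <- nrow(profile)
  if (any(!is.finite(px_edges)) ||
      any(px_edges < 0) || any(px_edges > n_px)) {
    abort("calibration domain does not cover the bin scheme")
  }
  if (any(diff(px_edges) == 0)) abort("calibration is not monotonic over the scheme")
  y <- profile$intensity

  ## integral of the piecewise-constant profile over pixel interval [a, b)
  integrate_px <- function(a, b) {
    if (a > b) return(integrate_px(b, a))
    lo <- floor(a); hi <- ceiling(b)
    idx <- seq(max(0, lo), min(n_px - 1, hi - 1))
    if (length(idx) == 0) return(0)
    w <- pmin(b, idx + 1) - pmax(a, idx)
    sum(y[idx + 1] * pmax(0, w))
  }
  raw <- vapply(1:7, function(b) {
    integrate_px(px_edges[b], px_edges[b + 1])
  }, numeric(1))
  total <- sum(raw)
  if (total <= 0) abort("no signal inside the binned region")
  out <- as.list(raw / total)
  names(out) <- bin_column_names()
  as_tibble(out)
}

#' Waterfall normalization of a gel time course
#'
#' Divides every lane's per-pixel intensities by the *total* signal of the
#' starting-material (SM) lane, the normalization used for waterfall plots of
#' transcript-length distributions over time. Unlike per-lane fractions, the
#' output is not constrained to sum to 1; conservation of signal shows up as
#' normalized lane sums near 1.
#'
#' @param profiles Named list of `lane_profile`s (or a `gel_bundle`, whose
#'   sample lanes are used).
#' @param sm_profile The SM `lane_profile`; taken from the bundle when
#'   `profiles` is a `gel_bundle`.
#' @param calibration Optional [fit_size_calibration()]; when given, a
#'   `length` column is added.
#' @return Long tibble with columns `lane`, `pixel`, (`length`,)
#'   `rel_intensity`.
#' @export
waterfall_normalize <- function(profiles, sm_profile = NULL,
                                calibration = NULL) {
  if (inherits(profiles, "gel_bundle")) {
    bundle <- profiles
    sm_lane <- bundle$manifest$lane[bundle$manifest$role == "sm"]
    if (is.null(sm_profile)) {
      if (length(sm_lane) != 1) abort("bundle has no unique SM lane")
      sm_profile <- bundle$lanes[[sm_lane]]
    }
    keep <- bundle$manifest$lane[bundle$manifest$role %in% c("sm", "sample")]
    profiles <- bundle$lanes[keep]
  }
  if (is.null(sm_profile)) abort("sm_profile is required")
  sm_total <- sum(sm_profile$intensity)
  if (sm_total == 0) abort("SM lane total signal is zero")
  out <- purrr::imap(profiles, function(p, nm) {
    tibble(lane = nm, pixel = p$pixel,
           rel_intensity = p$intensity / sm_total)
  }) |> purrr::list_rbind()
  if (!is.null(calibration)) {
    out$length <- calibration_length(calibration, out$pixel + 0.5)
    out <- out[, c("lane", "pixel", "length", "rel_intensity")]
  }
  out
}

#' Quantify a gel bundle into a seven-bin fraction table
#'
#' The ImageQuant-equivalent pipeline: detect marker peaks in the marker
#' lane, fit the size calibration, background-subtract every sample lane, and
#' integrate each into seven-bin fractions.
#'
#' @param bundle A `gel_bundle` ([synthesize_gel()] / [read_gel_bundle()]).
#' @param marker_lengths Known marker lengths (nt).
#' @param scheme A [bin_scheme()].
#' @param mode Calibration regression mode, `"linear"` or `"log"`.
#' @param background Background subtraction method (see
#'   [subtract_background()]).
#' @param min_prominence Peak detection threshold.
#' @param condition,tfs,replicate Metadata stamped onto the output rows.
#' @return List of class `gel_quantification`: `bin_table` (one row per
#'   sample lane: `condition`, `tfs`, `replicate`, `time_s`, `bin1`..`bin7`)
#'   and `calibration` (a [fit_size_calibration()] result).
#' @export
quantify_gel <- function(bundle, marker_lengths = default_markers(),
                         scheme = default_bin_scheme(),
                         mode = c("linear", "log"),
                         background = c("rolling_min", "min", "none"),
                         min_prominence = 0.1,
                         condition = NA_character_, tfs = NA,
                         replicate = NA_integer_) {
  stopifnot(inherits(bundle, "gel_bundle"))
  mode <- match.arg(mode)
  background <- match.arg(background)
  mrow <- bundle$manifest$lane[bundle$manifest$role == "marker"]
  if (length(mrow) != 1) abort("bundle must contain exactly one marker lane")
  srows <- bundle$manifest[bundle$manifest$role == "sample", ]
  if (nrow(srows) == 0) abort("bundle contains no sample lanes")

  peaks <- detect_marker_peaks(bundle$lanes[[mrow]],
                               min_prominence = min_prominence,
                               n_expected = length(marker_lengths))
  calibration <- fit_size_calibration(peaks, marker_lengths, mode = mode)

  rows <- purrr::map2(srows$lane, srows$time_s, function(lane, t) {
    prof <- subtract_background(bundle$lanes[[lane]], method = background)
    f <- bin_lane(prof, calibration, scheme)
    dplyr::bind_cols(
      tibble(condition = condition, tfs = tfs, replicate = replicate,
             time_s = t),
      f
    )
  }) |> purrr::list_rbind()

  structure(list(bin_table = rows, calibration = calibration),
            class = "gel_quantification")
}

#' Write a size-calibration report as JSON
#'
#' Records the regression mode, coefficients, R-squared and per-marker
#' residuals of a fitted calibration.
#'
#' @param calibration A [fit_size_calibration()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calibration, path) {
  stopifnot(inherits(calibration, "size_calibration"))
  jsonlite::write_json(
    list(
      mode = calibration$mode,
      intercept = calibration$intercept,
      slope = calibration$slope,
      r_squared = calibration$r_squared,
      marker_lengths = calibration$marker_lengths,
      peak_pixels = calibration$peak_pixels,
      residuals = calibration$residuals
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.gel_quantification <- function(x, ...) {
  cat(sprintf("<gel_quantification> %d lane(s), calibration R^2 = %.5f\n",
              nrow(x$bin_table), x$calibration$r_squared))
  invisible(x)
}
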