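#' Electrophoretic mobility model for synthetic lane profiles
#'
#' Maps transcript lengths to pixel positions along a 1-D densitometry trace.
#' `linear` mode maps pixel = intercept + slope * length; `log` mode maps
#' pixel = intercept + slope * log(length), the classical behavior of
#' denaturing PAGE. The linear default matches the linear size regression the
#' quantification stage fits; log mode exists precisely so that the
#' model-mismatch (curved residuals under a linear fit) can be exercised
#' rather than hidden.
#'
#' When `intercept`/`slope` are omitted they are chosen so `length_range`
#' spans `pixel_range`. The defaults give 20 px per nt over the 58-231 nt
#' assay window on a 4096-px lane: single-nucleotide bands are fully
#' resolved (adjacent lengths sit 10 band-sigmas apart at the default 2-px
#' point-spread), so inter-band valleys reach baseline and bin-boundary
#' leakage is negligible.
#'
#' @param mode `"linear"` or `"log"`.
#' @param lane_length Lane length in pixels.
#' @param pixel_range,length_range Used to derive `intercept` and `slope`
#'   when they are not given explicitly.
#' @param intercept,slope Explicit mapping coefficients (pixels, and pixels
#'   per nt or per log-nt).
#' @return An object of class `mobility_model`.
#' @examples
#' mob <- mobility_model()
#' map_length_to_pixel(mob, c(58, 231))
#' @export
mobility_model <- function(mode = c("linear", "log"),
                           lane_length = 4096L,
                           pixel_range = c(40, 3500),
                           length_range = c(58, 231),
                           intercept = NULL,
                           slope = NULL) {
  mode <- match.arg(mode)
  xf <- if (mode == "log") log else identity
  if (is.null(slope)) {
    slope <- diff(pixel_range) / diff(xf(length_range))
  }
  if (is.null(intercept)) {
    intercept <- pixel_range[1] - slope * xf(length_range[1])
  }
  m <- structure(
    list(mode = mode, intercept = as.numeric(intercept),
         slope = as.numeric(slope), lane_length = as.integer(lane_length)),
    class = "mobility_model"
  )
  px <- map_length_to_pixel(m, length_range)
  if (m$slope == 0) abort("mobility must be strictly monotonic")
  if (any(px < 0 | px >= m$lane_length)) {
    abort("mapped positions fall outside [0, lane_length)")
  }
  m
}

#' @rdname mobility_model
#' @param mobility A `mobility_model`.
#' @param lengths Transcript lengths (nt).
#' @export
map_length_to_pixel <- function(mobility, lengths) {
  stopifnot(inherits(mobility, "mobility_model"))
  x <- if (mobility$mode == "log") log(lengths) else lengths
  mobility$intercept + mobility$slope * x
}

new_lane_profile <- function(pixel, intensity, lane = NA_character_,
                             gain = NA_real_) {
  out <- tibble(pixel = as.integer(pixel), intensity = as.numeric(intensity))
  structure(out, class = c("lane_profile", class(out)),
            lane = lane, gain = gain)
}

## Gaussian band: exact area over unit pixel bins [p, p+1); sigma = 0 puts
## the whole band into the bin containing the center.
band_profile <- function(n_pixels, center, area, sigma) {
  y <- numeric(n_pixels)
  if (sigma == 0) {
    i <- floor(center) + 1L
    if (i >= 1L && i <= n_pixels) y[i] <- area
    return(y)
  }
  edges <- 0:n_pixels
  mass <- diff(pnorm(edges, mean = center, sd = sigma))
  y + area * mass
}

#' Synthesize a 1-D lane densitometry profile from a length distribution
#'
#' Each transcript length contributes a Gaussian band centered at its mapped
#' pixel with area `gain * fraction`; band areas are computed exactly per
#' unit pixel bin, so the noiseless profile total equals `gain` times the
#' distribution mass inside the lane. Optional additive Gaussian noise is
#' truncated at zero.
#'
#' @param dist Tibble with columns `length` and `fraction` (a single
#'   timepoint; a `prob` column is accepted as a synonym).
#' @param mobility A [mobility_model()].
#' @param psf_sigma Band point-spread (pixels, >= 0).
#' @param gain Total counts per unit distribution mass.
#' @param noise_sd Additive Gaussian noise SD (counts); 0 disables noise.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @param lane Lane label stored as an attribute.
#' @return A `lane_profile` tibble with columns `pixel`, `intensity`.
#' @export
lengths_to_profile <- function(dist, mobility = mobility_model(),
                               psf_sigma = 2, gain = 1e4, noise_sd = 0,
                               seed = NULL, lane = NA_character_) {
  dist <- as_tibble(dist)
  if (!"fraction" %in% names(dist) && "prob" %in% names(dist)) {
    dist$fraction <- dist$prob
  }
  stopifnot(all(c("length", "fraction") %in% names(dist)))
  if ("time_s" %in% names(dist) && length(unique(dist$time_s)) > 1L) {
    abort("dist spans several timepoints; synthesize one lane per timepoint")
  }
  if (psf_sigma < 0) abort("psf_sigma must be >= 0")
  if (gain <= 0) abort("gain must be > 0")
  keep <- dist$fraction > 0
  centers <- map_length_to_pixel(mobility, dist$length[keep])
  if (length(centers) > 1 && any(diff(sign(diff(centers))) != 0)) {
    abort("mobility is not monotonic over the distribution support")
  }
  n_px <- mobility$lane_length
  y <- numeric(n_px)
  fr <- dist$fraction[keep]
  for (i in seq_along(centers)) {
    y <- y + band_profile(n_px, centers[i], gain * fr[i], psf_sigma)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("seed is required when noise_sd > 0")
    set.seed(as.integer(seed))
    y <- pmax(0, y + rnorm(n_px, sd = noise_sd))
  }
  new_lane_profile(0:(n_px - 1L), y, lane = lane, gain = gain)
}

#' Default single-stranded DNA size markers (nt)
#' @export
default_markers <- function() c(60, 90, 120, 150, 180, 210)

#' Synthesize a marker lane with one equal-area band per size standard
#'
#' @param marker_lengths Marker lengths (nt), strictly increasing, within the
#'   mobility domain.
#' @inheritParams lengths_to_profile
#' @return A `lane_profile`; flat zero profile for an empty marker list.
#' @export
marker_lane <- function(marker_lengths = default_markers(),
                        mobility = mobility_model(), psf_sigma = 2,
                        gain = 1e4, noise_sd = 0, seed = NULL) {
  if (length(marker_lengths) == 0) {
    return(new_lane_profile(0:(mobility$lane_length - 1L),
                            numeric(mobility$lane_length),
                            lane = "marker", gain = gain))
  }
  dist <- tibble(length = as.numeric(marker_lengths),
                 fraction = rep(1 / length(marker_lengths),
                                length(marker_lengths)))
  lengths_to_profile(dist, mobility, psf_sigma = psf_sigma, gain = gain,
                     noise_sd = noise_sd, seed = seed, lane = "marker")
}

#' Synthesize a gel bundle (marker + SM + timepoint lanes) from distributions
#'
#' Builds the full set of lanes the quantification stage expects for one
#' reaction: a marker lane, a starting-material (SM) lane holding the stalled
#' +58 species, and one lane per observation time.
#'
#' @param dists Tibble of per-length distributions with columns `time_s`,
#'   `length`, `fraction` (one reaction, i.e. one condition x replicate).
#' @param template A [tec_template()] (defines the SM lane species).
#' @inheritParams lengths_to_profile
#' @param marker_lengths Marker lengths for the marker lane.
#' @param seed Base seed for lane noise (lane index is added per lane).
#' @return An object of class `gel_bundle`: list with `lanes` (named list of
#'   `lane_profile`s) and `manifest` (tibble: `lane`, `role`, `time_s`).
#' @export
synthesize_gel <- function(dists, template = default_template(),
                           mobility = mobility_model(),
                           marker_lengths = default_markers(),
                           psf_sigma = 2, gain = 1e4, noise_sd = 0,
                           seed = NULL) {
  dists <- as_tibble(dists)
  stopifnot(all(c("time_s", "length", "fraction") %in% names(dists)))
  times <- sort(unique(dists$time_s))
  lanes <- list()
  manifest <- tibble(lane = character(), role = character(),
                     time_s = numeric())

  lanes[["marker"]] <- marker_lane(
    marker_lengths, mobility, psf_sigma, gain,
    noise_sd = noise_sd, seed = if (is.null(seed)) NULL else seed + 1L
  )
  manifest <- dplyr::add_row(manifest, lane = "marker", role = "marker",
                             time_s = NA_real_)

  sm <- tibble(length = template$stall_pos, fraction = 1)
  lanes[["SM"]] <- lengths_to_profile(
    sm, mobility, psf_sigma, gain, noise_sd,
    seed = if (is.null(seed)) NULL else seed + 2L, lane = "SM"
  )
  manifest <- dplyr::add_row(manifest, lane = "SM", role = "sm", time_s = 0)

  for (i in seq_along(times)) {
    lab <- sprintf("t%gs", times[i])
    d <- dists[dists$time_s == times[i], c("length", "fraction")]
    lanes[[lab]] <- lengths_to_profile(
      d, mobility, psf_sigma, gain, noise_sd,
      seed = if (is.null(seed)) NULL else seed + 2L + i, lane = lab
    )
    manifest <- dplyr::add_row(manifest, lane = lab, role = "sample",
                               time_s = times[i])
  }
  structure(list(lanes = lanes, manifest = manifest), class = "gel_bundle")
}

#' @export
print.gel_bundle <- function(x, ...) {
  cat(sprintf("<gel_bundle> %d lanes (%s)\n", length(x$lanes),
              paste(x$manifest$lane, collapse = ", ")))
  invisible(x)
}

#' Read and write gel bundles as plain-text lane CSVs plus a JSON manifest
#'
#' @param bundle A [synthesize_gel()] result.
#' @param dir Directory for the bundle (created if needed).
#' @return `read_gel_bundle()` returns a `gel_bundle`; the writer returns
#'   `dir` invisibly.
#' @export
write_gel_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gel_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (lane in names(bundle$lanes)) {
    readr::write_csv(as_tibble(bundle$lanes[[lane]]),
                     file.path(dir, paste0("lane_", gsub("[^A-Za-z0-9]", "_", lane), ".csv")))
  }
  manifest <- list(
    lanes = bundle$manifest,
    files = as.list(setNames(
      paste0("lane_", gsub("[^A-Za-z0-9]", "_", names(bundle$lanes)), ".csv"),
      names(bundle$lanes)
    ))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_gel_bundle
#' @export
read_gel_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lanes <- lapply(names(manifest$files), function(lane) {
    df <- readr::read_csv(file.path(dir, manifest$files[[lane]]),
                          show_col_types = FALSE)
    new_lane_profile(df$pixel, df$intensity, lane = lane)
  })
  names(lanes) <- names(manifest$files)
  structure(list(lanes = lanes, manifest = as_tibble(manifest$lanes)),
            class = "gel_bundle")
}
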