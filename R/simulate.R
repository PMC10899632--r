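#' Kinetic parameters for the stalled-TEC restart simulation
#'
#' The simulator models each ternary elongation complex (TEC) as a
#' continuous-time pure birth chain over transcript lengths: release from the
#' +58 stall at rate `k_release` (per second), then single-nucleotide addition
#' at `k_step` nt/s, slowed to `k_step / beta` for the step onto a
#' barrier-encounter position with strength `beta`. The template end is
#' absorbing (full-length transcript). Transcription factor S (TFS) is modeled
#' phenomenologically as two multipliers: `tfs_release_mult` scales the stall
#' release rate up, and `tfs_barrier_mult` divides barrier factors (floored at
#' 1), reflecting its observed stimulation of +58 release and partial relief
#' of the first-barrier pause.
#'
#' Default rates define the package's reference study conditions: `k_step`
#' 2.5 nt/s gives a realistic spread of transcript lengths across a
#' 15-240 s time course on the 173-nt run to the template end, and
#' `k_release = log(2) / 30` puts the wild-type stall half-life at 30 s —
#' slow enough that the stalled fraction is still measurable at the 240-s
#' anchor of the two-point half-life fit, fast enough that most stalled
#' complexes restart within the time course.
#'
#' @param k_step Barrier-free single-nucleotide addition rate (nt/s).
#' @param k_release Escape rate from the +58 stalled state (1/s).
#' @param tfs Logical; is TFS present?
#' @param tfs_release_mult Multiplier (>= 0) on `k_release` when TFS present.
#' @param tfs_barrier_mult Divisor (>= 1) applied to barrier factors when TFS
#'   present; the divided factor is floored at 1 (TFS cannot make a barrier
#'   step faster than a barrier-free step).
#' @param n_molecules Number of TECs per simulated reaction.
#' @param obs_times Observation times (s), strictly increasing; the default is
#'   the 15/30/60/120/240 s aliquot schedule. `extended_obs_times()` appends
#'   the 480 and 960 s aliquots of the extended protocol.
#' @param seed Integer seed; mandatory for [simulate_ensemble()].
#' @return An object of class `sim_params` (named list).
#' @examples
#' sim_params(k_step = 0.5, k_release = 10, n_molecules = 1000, seed = 1)
#' @export
sim_params <- function(k_step = 2.5,
                       k_release = log(2) / 30,
                       tfs = FALSE,
                       tfs_release_mult = 1.85,
                       tfs_barrier_mult = 2,
                       n_molecules = 5000,
                       obs_times = default_obs_times(),
                       seed = NULL) {
  p <- structure(
    list(
      k_step = as.numeric(k_step),
      k_release = as.numeric(k_release),
      tfs = isTRUE(tfs),
      tfs_release_mult = as.numeric(tfs_release_mult),
      tfs_barrier_mult = as.numeric(tfs_barrier_mult),
      n_molecules = as.integer(n_molecules),
      obs_times = as.numeric(obs_times),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

#' @rdname sim_params
#' @export
default_obs_times <- function() c(15, 30, 60, 120, 240)

#' @rdname sim_params
#' @export
extended_obs_times <- function() c(15, 30, 60, 120, 240, 480, 960)

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (!is.finite(p$k_step) || p$k_step <= 0) abort("k_step must be > 0")
  if (!is.finite(p$k_release) || p$k_release <= 0) abort("k_release must be > 0")
  if (p$tfs_release_mult < 0) abort("tfs_release_mult must be >= 0")
  if (p$tfs_barrier_mult < 1) abort("tfs_barrier_mult must be >= 1")
  if (p$n_molecules < 1L) abort("n_molecules must be >= 1")
  if (length(p$obs_times) < 1L || any(p$obs_times < 0) ||
      any(diff(p$obs_times) <= 0)) {
    abort("obs_times must be non-negative and strictly increasing")
  }
  invisible(p)
}

#' Instantaneous forward rate at a transcript position
#'
#' @param L Transcript length(s) (nt), `stall_pos <= L < full_length`.
#' @param params A [sim_params()].
#' @param landscape A [make_landscape()] result.
#' @param template A [tec_template()].
#' @return Rate(s) in 1/s for the transition from length `L` to `L + 1`:
#'   the (TFS-adjusted) stall release rate at the stall, otherwise
#'   `k_step / beta(L + 1)` where `beta` is the (TFS-adjusted) barrier factor
#'   if `L + 1` is a barrier-encounter position and 1 otherwise.
#' @export
position_rate <- function(L, params, landscape, template = default_template()) {
  validate_sim_params(params)
  validate_template(template)
  if (any(L < template$stall_pos | L >= template$full_length)) {
    abort(sprintf("L must be in [%g, %g)", template$stall_pos,
                  template$full_length))
  }
  beta <- rep(1, length(L))
  if (length(landscape$barrier_positions) > 0) {
    hit <- match(L + 1, landscape$barrier_positions)
    ok <- !is.na(hit)
    b <- landscape$barrier_factors[hit[ok]]
    if (params$tfs) b <- pmax(1, b / params$tfs_barrier_mult)
    beta[ok] <- b
  }
  rate <- params$k_step / beta
  k_rel <- params$k_release * (if (params$tfs) params$tfs_release_mult else 1)
  rate[L == template$stall_pos] <- k_rel
  rate
}

## per-state forward rates for lengths stall..(full-1)
state_rates <- function(params, landscape, template) {
  L <- seq(template$stall_pos, template$full_length - 1)
  position_rate(L, params, landscape, template)
}

#' Simulate an ensemble of TECs restarting through a chromatin landscape
#'
#' Samples `n_molecules` independent TEC trajectories of the birth chain
#' described in [sim_params()]: exponential dwell at each length with the
#' position-dependent rate, absorption at the template end. Arrival times are
#' sampled exactly (no time discretization); the transcript length at each
#' observation time is the number of completed transitions. Results are
#' bit-exactly reproducible for a given seed.
#'
#' @param params A [sim_params()] with a non-`NULL` seed.
#' @inheritParams position_rate
#' @param chunk_size Molecules simulated per block (memory control only; does
#'   not affect the sampled values for a given seed).
#' @return A tibble of class `length_distribution` with columns `time_s`,
#'   `length` (full support `stall..full_length`), `count`, `fraction`; one
#'   block of 174 rows per observation time under the default template.
#'   Fractions in each block sum to 1.
#' @examples
#' p <- sim_params(k_step = 0.5, k_release = 10, n_molecules = 500, seed = 42)
#' free <- make_landscape(default_template(), "HTkA-free")
#' simulate_ensemble(p, free)
#' @export
simulate_ensemble <- function(params, landscape,
                              template = default_template(),
                              chunk_size = 20000L) {
  validate_sim_params(params)
  if (is.null(params$seed)) abort("simulate_ensemble requires params$seed")
  rates <- state_rates(params, landscape, template)
  n_steps <- length(rates)
  times <- params$obs_times
  lengths <- seq(template$stall_pos, template$full_length)

  set.seed(params$seed)
  counts <- matrix(0L, nrow = length(lengths), ncol = length(times))
  remaining <- params$n_molecules
  while (remaining > 0L) {
    m <- min(remaining, as.integer(chunk_size))
    acc <- numeric(m)
    nsteps_at <- matrix(0L, nrow = m, ncol = length(times))
    for (j in seq_len(n_steps)) {
      acc <- acc + rexp(m, rate = rates[j])
      for (k in seq_along(times)) {
        nsteps_at[, k] <- nsteps_at[, k] + (acc <= times[k])
      }
    }
    for (k in seq_along(times)) {
      counts[, k] <- counts[, k] +
        tabulate(nsteps_at[, k] + 1L, nbins = length(lengths))
    }
    remaining <- remaining - m
  }

  out <- tidyr::expand_grid(time_s = times, length = lengths)
  out$count <- as.integer(counts[cbind(
    match(out$length, lengths),
    match(out$time_s, times)
  )])
  out$fraction <- out$count / params$n_molecules
  structure(out, class = c("length_distribution", class(out)),
            n_total = params$n_molecules)
}

#' Exact transient length distribution of the elongation birth chain
#'
#' Deterministic oracle for [simulate_ensemble()]: integrates the forward
#' (master) equations of the birth chain over transcript lengths
#' `stall..full_length` with `deSolve::lsoda` at tight tolerances. The state
#' at the stall empties exponentially at the (TFS-adjusted) release rate; the
#' template end is absorbing.
#'
#' @inheritParams simulate_ensemble
#' @param t Observation time(s) in seconds, `>= 0`.
#' @return A tibble with columns `time_s`, `length`, `prob`; probabilities at
#'   each time sum to 1 within 1e-8.
#' @examples
#' p <- sim_params(k_step = 0.5, k_release = 10)
#' free <- make_landscape(default_template(), "HTkA-free")
#' d <- transient_distribution(p, free, t = 60)
#' sum(d$prob)
#' @export
transient_distribution <- function(params, landscape,
                                   template = default_template(),
                                   t = params$obs_times) {
  validate_sim_params(params)
  rates <- state_rates(params, landscape, template)
  if (any(!is.finite(rates))) abort("non-finite transition rates")
  n_steps <- length(rates)
  lengths <- seq(template$stall_pos, template$full_length)
  t <- as.numeric(t)
  if (any(t < 0)) abort("t must be >= 0")

  p0 <- c(1, numeric(n_steps))
  deriv <- function(time, p, parms) {
    flow <- parms * p[seq_len(n_steps)]
    list(c(0, flow) - c(flow, 0))
  }
  tt <- sort(unique(c(0, t)))
  if (length(tt) == 1L) {
    sol <- matrix(c(0, p0), nrow = 1)
  } else {
    sol <- deSolve::lsoda(p0, tt, deriv, parms = rates,
                          rtol = 1e-10, atol = 1e-12)
  }
  probs <- sol[match(t, tt), -1, drop = FALSE]
  probs[probs < 0] <- 0

  out <- tidyr::expand_grid(time_s = t, length = lengths)
  out$prob <- as.numeric(t(probs))
  out
}

#' Mean transcript length of a distribution
#'
#' @param dist Output of [simulate_ensemble()] or [transient_distribution()].
#' @return Tibble with `time_s` (plus any grouping columns present) and
#'   `mean_length` in nt.
#' @export
distribution_mean_length <- function(dist) {
  dist <- as_tibble(dist)
  w <- if ("fraction" %in% names(dist)) "fraction" else "prob"
  keys <- intersect(c("condition", "tfs", "replicate", "time_s"), names(dist))
  dist |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_length = sum(.data$length * .data[[w]]) / sum(.data[[w]]),
      .groups = "drop"
    )
}
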