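#' Tidy a size calibration fit
#'
#' @param x A [fit_size_calibration()] result.
#' @param ... Unused.
#' @return One row per regression term: `term`, `estimate`, `std.error`.
#' @method tidy size_calibration
#' @export
tidy.size_calibration <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("(Intercept)",
             if (x$mode == "log") "log(length)" else "length"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname tidy.size_calibration
#' @method glance size_calibration
#' @export
glance.size_calibration <- function(x, ...) {
  tibble(
    mode = x$mode,
    r.squared = x$r_squared,
    sigma = summary(x$model)$sigma,
    n_markers = length(x$marker_lengths),
    max_abs_residual = max(abs(x$residuals))
  )
}

#' Tidy kinetic results
#'
#' @param x A [compute_kinetics()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-replicate rate table; `glance()`: a one-row
#'   overview (numbers of conditions/replicates, histone-free reference rate,
#'   reference half-life).
#' @method tidy tec_kinetics
#' @export
tidy.tec_kinetics <- function(x, ...) x$per_replicate

#' @rdname tidy.tec_kinetics
#' @method glance tec_kinetics
#' @export
glance.tec_kinetics <- function(x, ...) {
  ref <- x$half_lives[
    x$half_lives$condition == x$reference$condition &
      x$half_lives$tfs == x$reference$tfs, ]
  free <- x$summary[x$summary$condition == x$free_condition &
                      !x$summary$tfs, ]
  tibble(
    n_conditions = nrow(x$summary),
    n_replicates = nrow(x$per_replicate),
    free_rate = if (nrow(free) == 1) free$rate else NA_real_,
    reference_condition = x$reference$condition,
    reference_t_half = if (nrow(ref) == 1) ref$t_half else NA_real_
  )
}
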