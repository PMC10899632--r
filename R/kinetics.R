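#' Bin-midpoint mean transcript length
#'
#' The ensemble mean RNA length of a lane, computed as the fraction-weighted
#' sum of the bins' theoretical RNA lengths (midpoints):
#' `sum_b f_b * m_b`.
#'
#' @param x Either a numeric vector of seven bin fractions, or a data frame
#'   with columns `bin1`..`bin7` (one value per row is returned).
#' @param scheme A [bin_scheme()] supplying the midpoints.
#' @param tol Tolerance on the fractions-sum-to-1 check.
#' @return Numeric vector of mean lengths (nt).
#' @examples
#' mean_transcript_length(c(1, 0, 0, 0, 0, 0, 0))  # all stalled: 58
#' @export
mean_transcript_length <- function(x, scheme = default_bin_scheme(),
                                   tol = 1e-6) {
  validate_bin_scheme(scheme)
  m <- if (is.numeric(x)) {
    if (length(x) != 7L) abort("need exactly 7 bin fractions")
    matrix(x, nrow = 1)
  } else {
    bin_fraction_matrix(x, tol = tol)
  }
  if (is.numeric(x) && abs(sum(x) - 1) > tol) {
    abort("bin fractions must sum to 1")
  }
  as.numeric(m %*% scheme$midpoint)
}

#' Average elongation rate of one reaction (nt/s)
#'
#' The published rate statistic: for each observation time `t`, the increase
#' of the mean transcript length over the stall position divided by `t`; the
#' reported rate is the unweighted mean of these per-timepoint rates. Note
#' this statistic underestimates the instantaneous stepping rate once
#' transcripts saturate at the template end; it is implemented as defined,
#' not corrected.
#'
#' @param bin_table Rows of one reaction (one condition x replicate): columns
#'   `time_s` and `bin1`..`bin7`, all times > 0.
#' @param scheme A [bin_scheme()].
#' @param stall_pos Stall position (nt) subtracted from each mean length.
#' @return Single numeric rate (nt/s).
#' @export
average_elongation_rate <- function(bin_table,
                                    scheme = default_bin_scheme(),
                                    stall_pos = scheme$upper[1]) {
  bin_table <- as_tibble(bin_table)
  if (!"time_s" %in% names(bin_table)) abort("bin_table needs a time_s column")
  if (nrow(bin_table) < 1) abort("need at least one timepoint")
  if (any(bin_table$time_s <= 0)) {
    abort("the rate statistic is undefined at time_s <= 0; drop t = 0 rows")
  }
  lbar <- mean_transcript_length(bin_table, scheme)
  mean((lbar - stall_pos) / bin_table$time_s)
}

#' Per-replicate elongation rates for a whole study
#'
#' Applies [average_elongation_rate()] to every condition x tfs x replicate
#' group of a bin table.
#'
#' @param bin_table A `BinTable` (see [generate_study()]).
#' @inheritParams average_elongation_rate
#' @return Tibble with `condition`, `tfs`, `replicate`, `rate`.
#' @export
elongation_rates <- function(bin_table, scheme = default_bin_scheme(),
                             stall_pos = scheme$upper[1]) {
  bin_table |>
    as_tibble() |>
    dplyr::group_by(.data$condition, .data$tfs, .data$replicate) |>
    dplyr::group_modify(~ tibble(
      rate = average_elongation_rate(.x, scheme, stall_pos)
    )) |>
    dplyr::ungroup()
}

#' Rate relative to the histone-free template
#'
#' @param r_condition Rate(s) on the condition of interest (nt/s).
#' @param r_free Rate on the histone-free template (nt/s), > 0.
#' @return Dimensionless ratio(s).
#' @export
relative_rate <- function(r_condition, r_free) {
  if (!is.finite(r_free) || r_free <= 0) abort("r_free must be > 0")
  r_condition / r_free
}

#' Two-point exponential pause kinetics at the stall
#'
#' Fits the single-exponential decay of the bin-1 (stalled, +58) fraction
#' through two timepoints: `C2 = C1 * exp(-k * (t2 - t1))`, giving
#' `k = log(C1 / C2) / (t2 - t1)` and half-life `t_half = log(2) / k`. When
#' `C2 >= C1` there is no decay: `k <= 0` and the half-life is flagged
#' undefined (`NA`), never reported negative.
#'
#' @param C1,C2 Bin-1 fractions at `t1` and `t2`, both > 0. Vectorized.
#' @param t1,t2 Timepoints (s), `t2 > t1`; defaults 15 and 240 s.
#' @return Tibble of class `pause_kinetics` with columns `C1`, `C2`, `t1`,
#'   `t2`, `k`, `t_half`, `defined`.
#' @examples
#' pause_half_life(0.5, 0.25, t1 = 15, t2 = 240)  # halves over 225 s
#' @export
pause_half_life <- function(C1, C2, t1 = 15, t2 = 240) {
  if (any(!is.finite(C1)) || any(!is.finite(C2)) ||
      any(C1 <= 0) || any(C2 <= 0)) {
    abort("C1 and C2 must be finite and > 0")
  }
  if (any(t2 <= t1)) abort("t2 must exceed t1")
  k <- log(C1 / C2) / (t2 - t1)
  defined <- k > 0
  t_half <- ifelse(defined, log(2) / k, NA_real_)
  out <- tibble(C1 = C1, C2 = C2, t1 = t1, t2 = t2, k = k,
                t_half = t_half, defined = defined)
  structure(out, class = c("pause_kinetics", class(out)))
}

#' Stall-pause kinetics per condition from a bin table
#'
#' Computes the replicate-mean bin-1 fraction at the two anchor timepoints
#' for every condition x TFS state and feeds them to [pause_half_life()].
#' Replicate-mean percentages (rather than per-replicate fits) match the
#' tabulated-half-life convention; per-replicate mode is available.
#'
#' @param bin_table A `BinTable`.
#' @param t1,t2 Anchor timepoints (s); both must be present in the table.
#' @param per_replicate If `TRUE`, one fit per replicate instead of the
#'   replicate-mean fit.
#' @return Tibble with `condition`, `tfs` (and `replicate` if per-replicate)
#'   plus the [pause_half_life()] columns.
#' @export
half_life_table <- function(bin_table, t1 = 15, t2 = 240,
                            per_replicate = FALSE) {
  bt <- as_tibble(bin_table)
  if (!all(c(t1, t2) %in% bt$time_s)) {
    abort(sprintf("timepoints %g and %g s must both be present", t1, t2))
  }
  keys <- c("condition", "tfs", if (per_replicate) "replicate")
  anchors <- bt |>
    dplyr::filter(.data$time_s %in% c(t1, t2)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "time_s")))) |>
    dplyr::summarise(bin1 = mean(.data$bin1), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time_s", values_from = "bin1",
                       names_prefix = "t")
  C1 <- anchors[[paste0("t", t1)]]
  C2 <- anchors[[paste0("t", t2)]]
  ## a condition can release completely (or never be seen stalled) within the
  ## time course: its half-life is not estimable from these two anchors and
  ## is flagged undefined rather than erroring out of the whole table
  ok <- C1 > 0 & C2 > 0
  out <- tibble(k = rep(NA_real_, length(C1)), t_half = NA_real_,
                defined = FALSE, C1 = C1, C2 = C2)
  if (any(ok)) {
    hk <- pause_half_life(C1[ok], C2[ok], t1 = t1, t2 = t2)
    out$k[ok] <- hk$k
    out$t_half[ok] <- hk$t_half
    out$defined[ok] <- hk$defined
  }
  dplyr::bind_cols(anchors[, keys], out)
}

#' Half-lives relative to a reference condition
#'
#' Divides every condition's stall half-life by the reference condition's
#' (wild-type chromatin without TFS by default); the reference row is exactly
#' 1. Undefined half-lives propagate as `NA` and are excluded from relative
#' comparison rather than reported as negative values.
#'
#' @param half_lives Output of [half_life_table()].
#' @param reference_condition,reference_tfs The reference row.
#' @return `half_lives` with an extra `rel_t_half` column.
#' @export
relative_half_life <- function(half_lives, reference_condition = "WT",
                               reference_tfs = FALSE) {
  hl <- as_tibble(half_lives)
  ref <- hl$condition == reference_condition & hl$tfs == reference_tfs
  if (!any(ref)) abort("reference condition is missing from the table")
  ref_t <- hl$t_half[ref]
  if (length(ref_t) != 1 || !is.finite(ref_t)) {
    abort("reference half-life is undefined")
  }
  hl$rel_t_half <- hl$t_half / ref_t
  hl
}

#' Fraction of transcripts that reached full length
#'
#' @param bin_table A `BinTable` (or any data frame with a `bin7` column).
#' @return Numeric vector: the bin-7 fraction (transcripts at the template
#'   end) per row.
#' @export
full_length_fraction <- function(bin_table) {
  if (!"bin7" %in% names(bin_table)) abort("bin_table needs a bin7 column")
  bin_table$bin7
}

#' Replicate mean and standard error
#'
#' @param results Tibble of per-replicate values.
#' @param value Name of the value column to summarize.
#' @param by Grouping columns.
#' @return Tibble with `mean`, `se` (sd / sqrt(n); `NA` with fewer than two
#'   replicates) and `n` per group.
#' @export
summarize_replicates <- function(results, value = "rate",
                                 by = c("condition", "tfs")) {
  results <- as_tibble(results)
  if (nrow(results) == 0) abort("no replicate results to summarize")
  if (!value %in% names(results)) {
    abort(sprintf("column '%s' not found", value))
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      se = ifelse(dplyr::n() >= 2,
                  sd(.data[[value]]) / sqrt(dplyr::n()), NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Full kinetic analysis of a seven-bin fraction table
#'
#' One call from a `BinTable` to the complete result set: per-replicate mean
#' lengths and rates, rates relative to the histone-free template (matched
#' for TFS state when possible), replicate summaries with standard errors,
#' per-timepoint full-length fractions, and the reference-normalized stall
#' half-life table.
#'
#' @param bin_table A `BinTable` (see [generate_study()] or
#'   [quantify_gel()]).
#' @param scheme The [bin_scheme()] the table was built with.
#' @param free_condition Label of the histone-free condition used as the
#'   rate reference.
#' @param reference_condition,reference_tfs Reference row for relative
#'   half-lives.
#' @param t1,t2 Anchor timepoints for the pause fit.
#' @return Object of class `tec_kinetics`: list with `per_replicate`,
#'   `summary`, `mean_lengths`, `full_length`, `half_lives`. [tidy()] returns
#'   the per-replicate table, [glance()] a one-row overview.
#' @export
compute_kinetics <- function(bin_table, scheme = default_bin_scheme(),
                             free_condition = "HTkA-free",
                             reference_condition = "WT",
                             reference_tfs = FALSE,
                             t1 = 15, t2 = 240) {
  bt <- as_tibble(bin_table)
  need <- c("condition", "tfs", "replicate", "time_s", bin_column_names())
  missing <- setdiff(need, names(bt))
  if (length(missing) > 0) {
    abort(sprintf("bin table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bin_fraction_matrix(bt)

  mean_lengths <- bt |>
    dplyr::mutate(mean_length = mean_transcript_length(bt, scheme)) |>
    dplyr::select("condition", "tfs", "replicate", "time_s", "mean_length") |>
    dplyr::mutate(delta = .data$mean_length - scheme$upper[1])

  rates <- elongation_rates(bt, scheme)
  if (!free_condition %in% rates$condition) {
    abort(sprintf("histone-free condition '%s' absent: cannot form relative rates",
                  free_condition))
  }
  free_by_tfs <- rates |>
    dplyr::filter(.data$condition == free_condition) |>
    dplyr::group_by(.data$tfs) |>
    dplyr::summarise(r_free = mean(.data$rate), .groups = "drop")
  if (any(free_by_tfs$r_free <= 0)) {
    abort("histone-free reference rate must be > 0")
  }
  rates <- rates |>
    dplyr::left_join(free_by_tfs, by = "tfs") |>
    dplyr::mutate(
      r_free = ifelse(is.na(.data$r_free),
                      mean(free_by_tfs$r_free), .data$r_free),
      rel_rate = .data$rate / .data$r_free
    ) |>
    dplyr::select(-"r_free")

  summary <- dplyr::left_join(
    summarize_replicates(rates, "rate") |>
      dplyr::rename(rate = "mean", rate_se = "se"),
    summarize_replicates(rates, "rel_rate") |>
      dplyr::rename(rel_rate = "mean", rel_rate_se = "se") |>
      dplyr::select(-"n"),
    by = c("condition", "tfs")
  )

  fl <- bt |>
    dplyr::mutate(full_length = full_length_fraction(bt)) |>
    summarize_replicates("full_length", by = c("condition", "tfs", "time_s")) |>
    dplyr::rename(full_length = "mean", full_length_se = "se")

  half_lives <- relative_half_life(
    half_life_table(bt, t1 = t1, t2 = t2),
    reference_condition = reference_condition,
    reference_tfs = reference_tfs
  )

  structure(
    list(per_replicate = rates, summary = summary,
         mean_lengths = mean_lengths, full_length = fl,
         half_lives = half_lives,
         free_condition = free_condition,
         reference = list(condition = reference_condition,
                          tfs = reference_tfs)),
    class = "tec_kinetics"
  )
}

#' @export
print.tec_kinetics <- function(x, ...) {
  cat(sprintf("<tec_kinetics> %d condition(s)\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
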