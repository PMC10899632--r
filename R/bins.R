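#' Seven-bin transcript-length scheme
#'
#' Gel lanes are quantified by parsing transcript lengths into seven bins.
#' Bin 1 is the single length at the stall (+58, the unextended TECs); bins
#' 2-7 partition the remaining lengths up to the template end. Each bin
#' carries a "theoretical RNA length" midpoint `m_b` used for the mean-length
#' calculation: the stall position for bin 1, the arithmetic middle of the
#' interval for every multi-length bin.
#'
#' The default interior edges split (58, 231] into six near-equal intervals
#' (58,87], (87,116], (116,145], (145,174], (174,202], (202,231]. Numeric
#' edges are not independently determined for this assay, so the default is
#' a convention, fully configurable via `interior_edges`.
#'
#' @param template A [tec_template()]; supplies the stall position (bin 1) and
#'   template end (contained in bin 7).
#' @param interior_edges Five strictly increasing lengths strictly between the
#'   stall and the template end; bin b (b = 2..7) covers
#'   `(edge[b-2], edge[b-1]]` with `edge[0] = stall` and `edge[6] = end`.
#' @return A tibble of class `bin_scheme` with columns `bin`, `lower`,
#'   `upper`, `midpoint` (`lower` is exclusive and `upper` inclusive for bins
#'   2-7; bin 1 is the point \{stall\}).
#' @examples
#' default_bin_scheme()
#' @export
bin_scheme <- function(template = default_template(),
                       interior_edges = c(87, 116, 145, 174, 202)) {
  validate_template(template)
  stall <- template$stall_pos
  end <- template$full_length
  interior_edges <- as.numeric(interior_edges)
  if (length(interior_edges) != 5L) {
    abort("exactly five interior edges are required for a seven-bin scheme")
  }
  edges <- c(stall, interior_edges, end)
  if (any(diff(edges) <= 0)) {
    abort("bin edges must be strictly increasing between the stall and the template end")
  }
  scheme <- tibble(
    bin = 1:7,
    lower = c(stall, edges[1:6]),
    upper = c(stall, edges[2:7])
  )
  scheme$midpoint <- ifelse(scheme$bin == 1L, stall,
                            (scheme$lower + scheme$upper) / 2)
  structure(scheme, class = c("bin_scheme", class(scheme)))
}

#' @rdname bin_scheme
#' @export
default_bin_scheme <- function(template = default_template()) {
  bin_scheme(template)
}

validate_bin_scheme <- function(scheme) {
  if (!inherits(scheme, "bin_scheme") || nrow(scheme) != 7L) {
    abort("scheme must be a seven-row bin_scheme")
  }
  invisible(scheme)
}

#' Assign transcript lengths to bins
#'
#' @param lengths Numeric transcript lengths (nt).
#' @param scheme A [bin_scheme()].
#' @return Integer bin indices in 1..7; lengths outside the scheme give `NA`.
#' @export
bin_assign <- function(lengths, scheme = default_bin_scheme()) {
  validate_bin_scheme(scheme)
  stall <- scheme$upper[1]
  edges <- c(stall, scheme$upper[2:7])
  idx <- findInterval(lengths, edges, left.open = TRUE) + 1L
  idx[lengths == stall] <- 1L
  idx[lengths < stall | lengths > scheme$upper[7]] <- NA_integer_
  idx
}

bin_column_names <- function() paste0("bin", 1:7)

#' Bin a transcript-length distribution into seven fractions
#'
#' Collapses a per-length distribution (for one or more timepoints) into the
#' seven-bin fraction schema used throughout the pipeline.
#'
#' @param dist A tibble with columns `length` and `fraction` (and optionally
#'   `time_s` plus grouping columns such as `condition`, `tfs`, `replicate`),
#'   e.g. the output of [simulate_ensemble()] or [transient_distribution()].
#'   A `prob` column is accepted as a synonym for `fraction`.
#' @param scheme A [bin_scheme()].
#' @return A tibble with the grouping columns of `dist` and columns
#'   `bin1`..`bin7`; each row's fractions sum to the total fraction mass of
#'   its group (1 for a proper distribution).
#' @export
bin_distribution <- function(dist, scheme = default_bin_scheme()) {
  validate_bin_scheme(scheme)
  dist <- as_tibble(dist)
  if (!"fraction" %in% names(dist) && "prob" %in% names(dist)) {
    dist$fraction <- dist$prob
  }
  if (!all(c("length", "fraction") %in% names(dist))) {
    abort("dist must have columns 'length' and 'fraction' (or 'prob')")
  }
  keys <- intersect(c("condition", "tfs", "replicate", "time_s"), names(dist))
  dist$..bin <- bin_assign(dist$length, scheme)
  if (anyNA(dist$..bin)) abort("distribution contains lengths outside the bin scheme")
  out <- dist |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "..bin")))) |>
    dplyr::summarise(f = sum(.data$fraction), .groups = "drop") |>
    dplyr::mutate(..bin = factor(.data$..bin, levels = 1:7)) |>
    tidyr::pivot_wider(
      names_from = "..bin", values_from = "f",
      names_prefix = "bin", names_expand = TRUE, values_fill = 0
    )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}

## extract the 7-column fraction matrix from a bin table, with validation
bin_fraction_matrix <- function(bin_table, tol = 1e-6) {
  cols <- bin_column_names()
  missing <- setdiff(cols, names(bin_table))
  if (length(missing) > 0) {
    abort(sprintf("bin table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(bin_table[, cols])
  if (any(m < -tol)) abort("bin fractions must be non-negative")
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    abort(sprintf("bin fractions must sum to 1 (worst row off by %.3g)",
                  max(abs(rowSums(m) - 1))))
  }
  m
}
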