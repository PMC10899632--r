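#' Default study design: ten chromatin conditions, -/+ TFS
#'
#' One row per condition x TFS state. Reactions without TFS have four
#' replicates and reactions with TFS three, matching the replicate structure
#' of the assay the generator emulates.
#'
#' @param variants Character vector of registry variant names.
#' @param n_minus,n_plus Replicates without / with TFS.
#' @return Tibble with columns `variant`, `tfs`, `n_replicates`.
#' @export
default_conditions <- function(variants = htka_variants()$variant,
                               n_minus = 4L, n_plus = 3L) {
  dplyr::bind_rows(
    tibble(variant = variants, tfs = FALSE, n_replicates = as.integer(n_minus)),
    tibble(variant = variants, tfs = TRUE, n_replicates = as.integer(n_plus))
  )
}

#' Generate a complete simulated elongation study
#'
#' Runs the stochastic simulator for every condition x replicate of a study
#' design and bins the resulting transcript-length distributions into the
#' seven-bin fraction table (`BinTable`) schema. Per-condition kinetics are
#' derived from the registry: the stall release rate is
#' `params$k_release / rel_t_half(variant)` (so conditions inherit the
#' reference-normalized stall half-lives shipped in [htka_variants()]), and
#' TFS reactions use the registry's per-variant release multiplier and
#' barrier divisor. Per-replicate seeds are drawn once from `master_seed`,
#' so the full study is byte-identical on rerun.
#'
#' @param conditions Study design tibble, see [default_conditions()].
#' @param params Baseline [sim_params()] (its `k_release` is the wild-type
#'   stall release rate; `tfs` and `seed` fields are overridden per
#'   replicate).
#' @param template A [tec_template()].
#' @param scheme A [bin_scheme()].
#' @param master_seed Integer master seed.
#' @param extended Logical; use the extended 480/960 s protocol.
#' @param keep_distributions Logical; if `TRUE`, the per-length distributions
#'   are attached as `attr(out, "distributions")` (needed to synthesize gels).
#' @return A `BinTable` tibble: one row per condition x tfs x replicate x
#'   timepoint with columns `condition`, `tfs`, `replicate`, `time_s`,
#'   `bin1`..`bin7`. The replicate seed table is attached as
#'   `attr(out, "seeds")`.
#' @examples
#' bt <- generate_study(default_conditions()[1:2, ],
#'                      params = sim_params(n_molecules = 200),
#'                      master_seed = 7)
#' @export
generate_study <- function(conditions = default_conditions(),
                           params = sim_params(),
                           template = default_template(),
                           scheme = default_bin_scheme(template),
                           master_seed = 1L,
                           extended = FALSE,
                           keep_distributions = FALSE) {
  conditions <- as_tibble(conditions)
  stopifnot(all(c("variant", "tfs", "n_replicates") %in% names(conditions)))
  if (anyDuplicated(conditions[, c("variant", "tfs")]) > 0) {
    abort("duplicate condition labels in study design")
  }
  reg <- htka_variants()
  unknown <- setdiff(conditions$variant, reg$variant)
  if (length(unknown) > 0) {
    abort(sprintf("variant(s) not in registry: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (extended) params$obs_times <- extended_obs_times()

  reps <- conditions |>
    dplyr::rowwise() |>
    dplyr::reframe(variant = .data$variant, tfs = .data$tfs,
                   replicate = seq_len(.data$n_replicates))
  set.seed(as.integer(master_seed))
  reps$seed <- sample.int(.Machine$integer.max - 1L, nrow(reps))

  run_one <- function(variant, tfs, replicate, seed) {
    row <- reg[reg$variant == variant, ]
    p <- params
    p$k_release <- params$k_release / row$rel_t_half
    p$tfs <- tfs
    p$tfs_release_mult <- row$tfs_release_mult
    p$tfs_barrier_mult <- row$tfs_barrier_mult
    p$seed <- seed
    land <- make_landscape(template, variant)
    dist <- simulate_ensemble(p, land, template)
    dist$condition <- variant
    dist$tfs <- tfs
    dist$replicate <- replicate
    dist
  }
  dists <- purrr::pmap(reps, run_one) |> purrr::list_rbind()

  bin_table <- bin_distribution(dists, scheme)
  bin_table <- dplyr::arrange(
    bin_table,
    match(.data$condition, reg$variant), .data$tfs, .data$replicate,
    .data$time_s
  )
  attr(bin_table, "seeds") <- reps
  if (keep_distributions) {
    attr(bin_table, "distributions") <- dists
  }
  bin_table
}
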