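bin_table_schema <- function() {
  c("condition", "tfs", "replicate", "time_s", bin_column_names())
}

#' Read and write seven-bin fraction tables (BinTable CSV)
#'
#' The on-disk schema is a UTF-8 comma-separated file with a mandatory header
#' `condition,tfs,replicate,time_s,bin1,...,bin7`; fractions are written with
#' six decimal places and each row's fractions must sum to 1 within 1e-6.
#'
#' @param bin_table A `BinTable` tibble.
#' @param path CSV path.
#' @return `read_bin_table()` returns a validated tibble; the writer returns
#'   `path` invisibly.
#' @export
write_bin_table <- function(bin_table, path) {
  bt <- as_tibble(bin_table)[, bin_table_schema()]
  bin_fraction_matrix(bt)
  for (col in bin_column_names()) {
    bt[[col]] <- sprintf("%.6f", bt[[col]])
  }
  readr::write_csv(bt, path)
  invisible(path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  bt <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          condition = readr::col_character(),
                          tfs = readr::col_logical(),
                          replicate = readr::col_integer(),
                          time_s = readr::col_double(),
                          .default = readr::col_double()
                        ))
  missing <- setdiff(bin_table_schema(), names(bt))
  if (length(missing) > 0) {
    abort(sprintf("bin table CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bin_fraction_matrix(bt)
  bt
}

#' Study configuration: defaults, validation, JSON/YAML round trip
#'
#' A study config bundles everything [run_study()] needs: the template
#' geometry, the condition list, simulator parameters, the bin scheme's
#' interior edges, gel-synthesis parameters, and the mandatory master seed.
#'
#' @param template A [tec_template()].
#' @param conditions A [default_conditions()]-shaped tibble.
#' @param params A [sim_params()].
#' @param interior_edges Bin-scheme interior edges.
#' @param seed Master seed (mandatory).
#' @param gel Optional list of gel parameters (`psf_sigma`, `gain`,
#'   `noise_sd`) enabling gel-bundle synthesis in [run_study()]; `NULL`
#'   disables gels.
#' @return A list of class `study_config`.
#' @export
study_config <- function(template = default_template(),
                         conditions = default_conditions(),
                         params = sim_params(),
                         interior_edges = c(87, 116, 145, 174, 202),
                         seed = NULL,
                         gel = NULL) {
  if (is.null(seed)) abort("a master seed is mandatory for simulate commands")
  cfg <- structure(
    list(template = template, conditions = as_tibble(conditions),
         params = params, interior_edges = as.numeric(interior_edges),
         seed = as.integer(seed), gel = gel),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  validate_template(cfg$template)
  validate_sim_params(cfg$params)
  if (anyDuplicated(cfg$conditions[, c("variant", "tfs")]) > 0) {
    abort("conditions: duplicate condition labels")
  }
  if (is.null(cfg$seed)) abort("seed: mandatory")
  invisible(cfg)
}

#' @rdname study_config
#' @param path JSON (`.json`) or YAML (`.yaml`/`.yml`) file.
#' @export
write_study_config <- function(cfg, path) {
  validate_study_config(cfg)
  raw <- list(
    template = unclass(cfg$template),
    conditions = as.data.frame(cfg$conditions),
    params = unclass(cfg$params),
    interior_edges = cfg$interior_edges,
    seed = cfg$seed,
    gel = cfg$gel
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  params <- raw$params
  params$obs_times <- as.numeric(unlist(params$obs_times))
  study_config(
    template = do.call(tec_template, raw$template),
    conditions = as_tibble(as.data.frame(raw$conditions)),
    params = do.call(sim_params, params),
    interior_edges = as.numeric(unlist(raw$interior_edges)),
    seed = raw$seed,
    gel = raw$gel
  )
}

#' Run a full simulated study from a configuration
#'
#' The `simulate` entry point of the pipeline: generates the bin table for
#' every condition/replicate (and gel bundles when the config requests them),
#' optionally writing the bin table CSV, gel bundles, and a manifest sidecar
#' (config hash + package version) to an output directory. Outputs are pure
#' functions of (config, seed): reruns are byte-identical.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional output directory.
#' @return The `BinTable` tibble (invisibly carries `seeds` and, when gels
#'   were synthesized, a `gel_bundles` attribute: a named list keyed
#'   `condition|tfs|replicate`).
#' @export
run_study <- function(cfg, out_dir = NULL) {
  validate_study_config(cfg)
  scheme <- bin_scheme(cfg$template, cfg$interior_edges)
  bt <- generate_study(
    conditions = cfg$conditions, params = cfg$params,
    template = cfg$template, scheme = scheme, master_seed = cfg$seed,
    keep_distributions = !is.null(cfg$gel)
  )
  bundles <- NULL
  if (!is.null(cfg$gel)) {
    dists <- attr(bt, "distributions")
    keys <- dplyr::distinct(dists[, c("condition", "tfs", "replicate")])
    bundles <- purrr::pmap(
      c(as.list(keys), list(..i = seq_len(nrow(keys)))),
      function(condition, tfs, replicate, ..i) {
        d <- dists[dists$condition == condition & dists$tfs == tfs &
                     dists$replicate == replicate, ]
        synthesize_gel(
          d, template = cfg$template,
          psf_sigma = cfg$gel$psf_sigma %||% 2,
          gain = cfg$gel$gain %||% 1e4,
          noise_sd = cfg$gel$noise_sd %||% 0,
          seed = cfg$seed + 17L * ..i
        )
      }
    )
    names(bundles) <- sprintf("%s|%s|%d", keys$condition,
                              ifelse(keys$tfs, "TFS", "noTFS"),
                              keys$replicate)
    attr(bt, "gel_bundles") <- bundles
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_bin_table(bt, file.path(out_dir, "bin_table.csv"))
    if (!is.null(bundles)) {
      for (nm in names(bundles)) {
        write_gel_bundle(bundles[[nm]],
                         file.path(out_dir, "gels",
                                   gsub("[^A-Za-z0-9]+", "_", nm)))
      }
    }
    write_manifest(out_dir, cfg)
  }
  bt
}

#' Write a manifest sidecar recording the config hash
#'
#' @param dir Output directory.
#' @param cfg The [study_config()] that produced the outputs.
#' @return Path to `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, cfg) {
  manifest <- list(
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    package = "teckit",
    version = as.character(utils::packageVersion("teckit"))
  )
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write kinetic results to CSV and JSON
#'
#' @param kin A [compute_kinetics()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_kinetics_results <- function(kin, dir) {
  stopifnot(inherits(kin, "tec_kinetics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(kin$per_replicate, file.path(dir, "rates_per_replicate.csv"))
  readr::write_csv(kin$summary, file.path(dir, "rates_summary.csv"))
  readr::write_csv(kin$half_lives, file.path(dir, "half_lives.csv"))
  readr::write_csv(kin$full_length, file.path(dir, "full_length.csv"))
  jsonlite::write_json(
    list(summary = kin$summary, half_lives = kin$half_lives),
    file.path(dir, "kinetics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}
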