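#' DNA template geometry for stalled-TEC elongation assays
#'
#' A `tec_template` records the geometry of the linear transcription template:
#' the position of the nucleotide-deprivation stall, the template end, and the
#' layout of the tandem histone positioning sequence (HPS) that histone dimers
#' occupy downstream of the stall. All coordinates are 1-based transcript
#' positions in nucleotides from the transcription start site (the "+58/+231"
#' convention of in vitro walk-out assays).
#'
#' The first barrier encounter happens when the leading edge of the RNA
#' polymerase reaches the first bound histone dimer, i.e. at transcript
#' position `hps_start - leading_edge_offset`. The assay this package models
#' places that encounter at +70; subsequent encounters recur every
#' `dimer_footprint` nucleotides because each archaeal histone dimer protects
#' ~30 bp of DNA.
#'
#' @param stall_pos Transcript position (nt) of the nucleotide-deprivation
#'   stall. Default 58.
#' @param full_length Transcript position (nt) of the template end (the
#'   absorbing full-length state). Default 231.
#' @param hps_start Template coordinate (nt) of the first bound histone dimer.
#' @param dimer_footprint DNA footprint of one histone dimer (nt). Default 30.
#' @param n_dimers Number of tandem histone dimers bound downstream.
#' @param rnap_footprint DNA footprint of the RNA polymerase (nt). Default 20.
#' @param leading_edge_offset Distance (nt) from the RNA 3'-end position to the
#'   leading edge of the polymerase. With the defaults,
#'   `hps_start - leading_edge_offset = 70`, anchoring the first barrier
#'   encounter at the observed ~+70 pause.
#'
#' @return An object of class `tec_template` (a named list).
#' @seealso [barrier_encounter_positions()], [make_landscape()]
#' @examples
#' tpl <- default_template()
#' barrier_encounter_positions(tpl)
#' @export
tec_template <- function(stall_pos = 58,
                         full_length = 231,
                         hps_start = 82,
                         dimer_footprint = 30,
                         n_dimers = 5,
                         rnap_footprint = 20,
                         leading_edge_offset = 12) {
  tpl <- structure(
    list(
      stall_pos = as.numeric(stall_pos),
      full_length = as.numeric(full_length),
      hps_start = as.numeric(hps_start),
      dimer_footprint = as.numeric(dimer_footprint),
      n_dimers = as.integer(n_dimers),
      rnap_footprint = as.numeric(rnap_footprint),
      leading_edge_offset = as.numeric(leading_edge_offset)
    ),
    class = "tec_template"
  )
  validate_template(tpl)
  tpl
}

#' @rdname tec_template
#' @export
default_template <- function() tec_template()

validate_template <- function(tpl) {
  stopifnot(inherits(tpl, "tec_template"))
  with(tpl, {
    if (!all(is.finite(c(stall_pos, full_length, hps_start, dimer_footprint,
                         rnap_footprint, leading_edge_offset)))) {
      abort("template coordinates must be finite")
    }
    if (dimer_footprint <= 0) abort("dimer_footprint must be > 0")
    if (n_dimers < 0) abort("n_dimers must be >= 0")
    if (full_length <= stall_pos) abort("full_length must exceed stall_pos")
    if (stall_pos >= hps_start - leading_edge_offset + dimer_footprint) {
      abort("stall_pos must lie upstream of the first histone dimer")
    }
    if (hps_start > full_length + leading_edge_offset) {
      abort("hps_start lies beyond the template")
    }
  })
  invisible(tpl)
}

#' @export
print.tec_template <- function(x, ...) {
  cat("<tec_template>\n")
  cat(sprintf("  stall at +%g, template end +%g\n", x$stall_pos, x$full_length))
  cat(sprintf("  %d histone dimer(s), footprint %g nt, HPS start %g\n",
              x$n_dimers, x$dimer_footprint, x$hps_start))
  cat(sprintf("  first barrier encounter at +%g\n",
              x$hps_start - x$leading_edge_offset))
  invisible(x)
}

#' Transcript positions at which the TEC encounters histone-dimer barriers
#'
#' The leading edge of the polymerase meets the first bound dimer when the RNA
#' 3'-end reaches `hps_start - leading_edge_offset`; each subsequent dimer is
#' met one dimer footprint (~30 nt) later. Encounters beyond the template end
#' are dropped.
#'
#' @param template A [tec_template()].
#' @return Numeric vector of strictly increasing transcript positions (nt);
#'   empty when `n_dimers = 0`.
#' @examples
#' barrier_encounter_positions(default_template())
#' @export
barrier_encounter_positions <- function(template = default_template()) {
  validate_template(template)
  if (template$n_dimers == 0L) return(numeric(0))
  first <- template$hps_start - template$leading_edge_offset
  pos <- first + template$dimer_footprint * (seq_len(template$n_dimers) - 1)
  pos[pos <= template$full_length]
}

#' Registry of HTkA histone variants with illustrative barrier strengths
#'
#' Ships qualitative defaults for the ten chromatin conditions the package
#' simulates by default: histone-free DNA, wild-type HTkA, and eight HTkA
#' point variants. Barrier strength factors (`beta`, dimensionless multipliers
#' on the dwell time at a barrier encounter) are *illustrative*: they are
#' ordered to reproduce the qualitative ranking of elongation impediment
#' (free < T55L ~ R20S ~ E3A < WT < G52K < E34A < G17D < E19K < E19K/G52K),
#' calibrated once against the exact transient oracle so that the simulated
#' relative-rate ordering under the default kinetics respects that ranking,
#' but they are not fitted to measured rates. Stall-release half-lives relative to
#' wild-type (`rel_t_half`, and `rel_t_half_tfs` with transcription factor S
#' present) are taken from the published reference-normalized half-life table
#' for these conditions and seed the per-condition release rates of the study
#' generator.
#'
#' @return A tibble with one row per variant: `variant`, `beta` (first-barrier
#'   strength), `beta_later` (strength at the 2nd..nth encounters),
#'   `first_only` (whether strong pausing is restricted to the first barrier),
#'   `rel_t_half`, `rel_t_half_tfs`, `tfs_release_mult` (fold increase of the
#'   +58 release rate when TFS is present, derived as
#'   `rel_t_half / rel_t_half_tfs`), and `tfs_barrier_mult` (divisor applied
#'   to barrier factors when TFS is present; 1 for the E19K/G52K double
#'   variant, whose dominant +70 pause TFS cannot relieve).
#' @examples
#' htka_variants()
#' @export
htka_variants <- function() {
  reg <- tibble(
    variant = c("HTkA-free", "T55L", "R20S", "E3A", "WT",
                "G52K", "E34A", "G17D", "E19K", "E19K/G52K"),
    beta = c(1, 3, 3, 3, 11, 47, 110, 190, 250, 1800),
    first_only = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE, TRUE, TRUE),
    rel_t_half = c(0.28, 0.28, 0.30, 0.27, 1.00,
                   0.77, 0.56, 0.65, 0.84, 0.44),
    rel_t_half_tfs = c(0.19, 0.17, 0.18, 0.19, 0.54,
                       0.38, 0.29, 0.40, 0.59, 0.41),
    tfs_barrier_mult = c(1, 2, 2, 2, 2, 2, 2, 2, 2, 1)
  )
  reg$beta_later <- 1 + (reg$beta - 1) / 8
  reg$tfs_release_mult <- reg$rel_t_half / reg$rel_t_half_tfs
  reg[, c("variant", "beta", "beta_later", "first_only", "rel_t_half",
          "rel_t_half_tfs", "tfs_release_mult", "tfs_barrier_mult")]
}

#' Build a chromatin landscape for a named histone variant
#'
#' A `tec_landscape` pairs the barrier-encounter positions derived from the
#' template geometry with per-barrier strength factors `beta >= 1`: the dwell
#' time at a barrier encounter is multiplied by its factor (`beta = 1` means
#' no barrier). When `first_only` is set, only the first encounter keeps its
#' factor — the regime in which only the first histone dimer met by the TEC
#' imposes a substantial pause.
#'
#' @param template A [tec_template()].
#' @param variant_name Condition label. Known registry names (see
#'   [htka_variants()]) supply default factors; any other label requires
#'   explicit `barrier_factors`.
#' @param barrier_factors Numeric: either a single factor recycled across all
#'   encounters, or one factor per encounter position. All factors must be
#'   >= 1 (`beta = 1` is the no-barrier identity).
#' @param first_only Logical; force factors at the 2nd..nth encounters to 1.
#'   Defaults to the registry value for known variants, `FALSE` otherwise.
#' @return An object of class `tec_landscape`.
#' @examples
#' make_landscape(default_template(), "E19K/G52K")
#' make_landscape(default_template(), "custom", barrier_factors = 10)
#' @export
make_landscape <- function(template = default_template(),
                           variant_name = "HTkA-free",
                           barrier_factors = NULL,
                           first_only = NULL) {
  validate_template(template)
  positions <- barrier_encounter_positions(template)
  reg <- htka_variants()
  hit <- match(variant_name, reg$variant)

  if (is.null(barrier_factors)) {
    if (is.na(hit)) {
      abort(sprintf(
        "variant '%s' is not in the registry; supply barrier_factors",
        variant_name
      ))
    }
    barrier_factors <- c(reg$beta[hit],
                         rep(reg$beta_later[hit], max(0, length(positions) - 1)))
    barrier_factors <- barrier_factors[seq_along(positions)]
  } else {
    if (any(!is.finite(barrier_factors)) || any(barrier_factors <= 0)) {
      abort("barrier_factors must be finite and > 0")
    }
    if (any(barrier_factors < 1)) {
      abort("barrier_factors must be >= 1 (1 means no barrier)")
    }
    if (length(barrier_factors) == 1L) {
      barrier_factors <- rep(barrier_factors, length(positions))
    } else if (length(barrier_factors) != length(positions)) {
      abort(sprintf(
        "got %d barrier_factors for %d barrier positions",
        length(barrier_factors), length(positions)
      ))
    }
  }
  if (is.null(first_only)) {
    first_only <- if (!is.na(hit)) reg$first_only[hit] else FALSE
  }
  if (isTRUE(first_only) && length(barrier_factors) > 1L) {
    barrier_factors[-1L] <- 1
  }

  structure(
    list(
      variant_name = variant_name,
      barrier_positions = positions,
      barrier_factors = as.numeric(barrier_factors),
      first_only = isTRUE(first_only)
    ),
    class = "tec_landscape"
  )
}

#' @export
print.tec_landscape <- function(x, ...) {
  cat(sprintf("<tec_landscape> %s\n", x$variant_name))
  if (length(x$barrier_positions) == 0L) {
    cat("  no barriers\n")
  } else {
    cat(sprintf("  barriers at +%s\n",
                paste(x$barrier_positions, collapse = ", +")))
    cat(sprintf("  factors %s%s\n",
                paste(signif(x$barrier_factors, 3), collapse = ", "),
                if (x$first_only) " (first barrier only)" else ""))
  }
  invisible(x)
}

#' Serialize templates and landscapes to and from JSON
#'
#' @param x A [tec_template()] or `tec_landscape`.
#' @param path File path.
#' @return `read_template_json()` returns a `tec_template`;
#'   `read_landscape_json()` a `tec_landscape`. Writers return `path`
#'   invisibly.
#' @export
write_template_json <- function(x, path) {
  validate_template(x)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tec_template, x)
}

#' @rdname write_template_json
#' @export
write_landscape_json <- function(x, path) {
  stopifnot(inherits(x, "tec_landscape"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_landscape_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      variant_name = x$variant_name,
      barrier_positions = as.numeric(x$barrier_positions),
      barrier_factors = as.numeric(x$barrier_factors),
      first_only = isTRUE(x$first_only)
    ),
    class = "tec_landscape"
  )
}
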