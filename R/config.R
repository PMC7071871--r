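#' Quantification configuration (persistence thresholds and constants)
#'
#' Bundles every tunable used by the quantification pipeline. All lengths
#' are micrometres on the ball-radius scale of the filtration (see
#' [compute_persistence()]).
#'
#' Defaults follow measured pigment-cell spacings: dimension-0 persistence
#' thresholds `tp0` of 100 um for iridophores (`Id`, `Il`) and 90 um for
#' melanophores (`M`); a universal dimension-1 persistence threshold `tp1`
#' of 200 um; dimension-1 birth thresholds `tb1` of 100 um for `Xl`, 80 um
#' for `Xd` and 90 um for `M`. Wild-type patterns at the analysis stage are
#' expected to show three complete interstripes and two complete stripes.
#' Formation events are scanned between days `d0 = 32` and `d1 = 62` with a
#' 200 um bound-jump threshold.
#'
#' @param tp0 Named numeric vector of dimension-0 persistence thresholds per
#'   cell type (um). Entries supplied here override the defaults.
#' @param tp1 Universal dimension-1 persistence threshold (um).
#' @param tb1 Named numeric vector of dimension-1 birth-radius thresholds
#'   per cell type (um).
#' @param expected_interstripes,expected_stripes Expected complete band
#'   counts for break flagging.
#' @param trim_fraction Fraction of the domain height trimmed top and bottom
#'   before analysis.
#' @param formation_threshold Minimum day-over-day jump of a pattern bound
#'   (um) that signals a new stripe forming.
#' @param d0,d1 First and last day (inclusive) of the formation search
#'   window.
#'
#' @return A list of class `quant_config`.
#' @export
#'
#' @examples
#' quant_config()
#' quant_config(tb1 = c(Xd = 70))
quant_config <- function(tp0 = NULL, tp1 = 200, tb1 = NULL,
                         expected_interstripes = 3, expected_stripes = 2,
                         trim_fraction = 0.1, formation_threshold = 200,
                         d0 = 32, d1 = 62) {
  tp0_def <- c(M = 90, Id = 100, Il = 100)
  tb1_def <- c(Xl = 100, Xd = 80, M = 90)
  if (!is.null(tp0)) tp0_def[names(tp0)] <- tp0
  if (!is.null(tb1)) tb1_def[names(tb1)] <- tb1
  stopifnot(all(tp0_def > 0), all(tb1_def > 0), tp1 > 0,
            trim_fraction >= 0, trim_fraction < 0.5,
            formation_threshold > 0, d0 < d1)
  structure(list(tp0 = tp0_def, tp1 = tp1, tb1 = tb1_def,
                 expected_interstripes = expected_interstripes,
                 expected_stripes = expected_stripes,
                 trim_fraction = trim_fraction,
                 formation_threshold = formation_threshold,
                 d0 = as.integer(d0), d1 = as.integer(d1)),
            class = "quant_config")
}

#' @export
print.quant_config <- function(x, ...) {
  cat("<quant_config>\n")
  cat("  tp0 (um):", paste(names(x$tp0), x$tp0, sep = "=", collapse = " "), "\n")
  cat("  tp1 (um):", x$tp1, "\n")
  cat("  tb1 (um):", paste(names(x$tb1), x$tb1, sep = "=", collapse = " "), "\n")
  cat(sprintf("  expected interstripes/stripes: %d/%d, trim %.0f%%\n",
              x$expected_interstripes, x$expected_stripes,
              100 * x$trim_fraction))
  cat(sprintf("  formation: >%g um jump in [%d, %d] dpf\n",
              x$formation_threshold, x$d0, x$d1))
  invisible(x)
}

assert_config <- function(config) {
  if (!inherits(config, "quant_config")) {
    rlang::abort("`config` must be a `quant_config` object; see `quant_config()`.")
  }
  invisible(config)
}

threshold_for <- function(table, cell_type, what) {
  v <- unname(table[cell_type])
  if (length(v) != 1 || is.na(v)) {
    rlang::abort(sprintf(
      "no %s threshold configured for cell type '%s'; supply one via `quant_config()`.",
      what, cell_type))
  }
  v
}

#' Stable hash of a configuration
#'
#' Changes iff any threshold or constant changes; recorded in report
#' provenance.
#'
#' @param config A [quant_config()].
#' @return A character scalar hash.
#' @export
config_hash <- function(config) {
  assert_config(config)
  rlang::hash(unclass(config))
}
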