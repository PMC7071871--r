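#' Detect stripe-formation days from a snapshot series
#'
#' Estimates when the dorsal (`X1D`) and ventral (`X1V`) neighbours of the
#' central interstripe first form, from daily snapshots of the band-forming
#' cells (`Xd`). Assuming a single central band initially, a new dorsal band
#' announces itself as a jump in the maximum y coordinate, and a new ventral
#' band as a drop in the minimum y coordinate, larger than
#' `formation_threshold` from one day to the next. Only days in
#' `(d0, d1]` are scanned. Untrimmed patterns should be supplied: trimming
#' would mask growth at the domain edges.
#'
#' @param snapshots A list of [point_pattern()]s with consecutive integer
#'   `day` attributes covering at least `[d0, d1]`; each non-empty.
#' @param config A [quant_config()] providing `formation_threshold`, `d0`,
#'   `d1`.
#'
#' @return A list of class `formation_times` with `day_X1D` and `day_X1V`
#'   (integer day or `NA` if no qualifying jump occurs).
#' @export
formation_times <- function(snapshots, config = quant_config()) {
  assert_config(config)
  if (!is.list(snapshots) || length(snapshots) < 2) {
    rlang::abort("`snapshots` must be a list of at least two point patterns.")
  }
  days <- vapply(snapshots, function(p) {
    assert_pattern(p)
    day <- pattern_day(p)
    if (is.null(day)) rlang::abort("every snapshot needs a `day` attribute.")
    day
  }, integer(1))
  if (is.unsorted(days, strictly = TRUE)) {
    rlang::abort("snapshots must be sorted by strictly increasing day.")
  }
  if (days[1] > config$d0 || days[length(days)] < config$d1) {
    rlang::abort(sprintf("snapshots must cover days [%d, %d].",
                         config$d0, config$d1))
  }
  in_window <- days >= config$d0 & days <= config$d1
  if (any(diff(days[in_window]) != 1L)) {
    rlang::abort("the day series has gaps inside the formation window.")
  }
  wdays <- days[in_window]
  upper <- vapply(snapshots[in_window], function(p) max(p$y), numeric(1))
  lower <- vapply(snapshots[in_window], function(p) min(p$y), numeric(1))
  thr <- config$formation_threshold
  up_jump <- which(diff(upper) > thr)
  down_jump <- which(diff(lower) < -thr)
  structure(list(
    day_X1D = if (length(up_jump)) wdays[up_jump[1] + 1] else NA_integer_,
    day_X1V = if (length(down_jump)) wdays[down_jump[1] + 1] else NA_integer_
  ), class = "formation_times")
}

#' @export
print.formation_times <- function(x, ...) {
  cat(sprintf("<formation_times> X1D: %s dpf, X1V: %s dpf\n",
              ifelse(is.na(x$day_X1D), "none", x$day_X1D),
              ifelse(is.na(x$day_X1V), "none", x$day_X1V)))
  invisible(x)
}
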