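#' Read labelled cell coordinates from a delimited file
#'
#' Reads a CSV/TSV table with columns `cell_type`, `x`, `y` (micrometres)
#' and returns one [point_pattern()] per cell type. Domain extents come from
#' the arguments or, if absent, from a header comment line of the form
#' `# domain: length_x=3000 length_y=2200` (written by [write_pattern()]).
#' x coordinates are canonicalized into `[0, length_x)`; y coordinates
#' outside `[0, length_y]` are parse errors naming the offending rows.
#'
#' @param path File path.
#' @param length_x,length_y Domain extents (um); `NULL` to read them from
#'   the file header.
#' @param delim Field delimiter (`","` or `"\t"`); guessed from the file
#'   extension when `NULL`.
#'
#' @return A named list of [point_pattern()]s, one per cell type present.
#' @export
read_pattern <- function(path, length_x = NULL, length_y = NULL, delim = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  header <- readLines(path, n = 1)
  if (grepl("^#\\s*domain:", header)) {
    lx <- as.numeric(sub(".*length_x=([0-9.eE+-]+).*", "\\1", header))
    ly <- as.numeric(sub(".*length_y=([0-9.eE+-]+).*", "\\1", header))
    if (is.null(length_x)) length_x <- lx
    if (is.null(length_y)) length_y <- ly
  }
  if (is.null(length_x) || is.null(length_y)) {
    rlang::abort("domain extents missing: supply `length_x`/`length_y` or a '# domain:' header.")
  }
  dom <- domain(length_x, length_y)
  tab <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  need <- c("cell_type", "x", "y")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  xy <- suppressWarnings(list(x = as.numeric(tab$x), y = as.numeric(tab$y)))
  bad <- which(is.na(xy$x) | is.na(xy$y))
  if (length(bad) > 0) {
    rlang::abort(sprintf("non-numeric coordinates at row(s): %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad_y <- which(xy$y < 0 | xy$y > dom$length_y)
  if (length(bad_y) > 0) {
    rlang::abort(sprintf("y outside [0, %g] at row(s): %s", dom$length_y,
                         paste(utils::head(bad_y, 5), collapse = ", ")))
  }
  types <- as.character(tab$cell_type)
  out <- lapply(split(seq_len(nrow(tab)), types), function(idx) {
    point_pattern(tibble::tibble(x = xy$x[idx], y = xy$y[idx]), dom,
                  cell_type = types[idx[1]])
  })
  out[sort(names(out))]
}

#' Write point patterns to a delimited file
#'
#' The inverse of [read_pattern()]: writes a `# domain:` header followed by
#' a `cell_type,x,y` table.
#'
#' @param patterns A [point_pattern()], a named list of them (sharing one
#'   domain), or a `pattern_set` from a generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(patterns, path) {
  if (inherits(patterns, "pattern_set")) patterns <- patterns$patterns
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  doms <- lapply(patterns, pattern_domain)
  if (!all(vapply(doms, identical, logical(1), y = doms[[1]]))) {
    rlang::abort("all patterns must share one domain.")
  }
  d <- doms[[1]]
  tab <- dplyr::bind_rows(lapply(patterns, function(p) {
    tibble::tibble(cell_type = pattern_cell_type(p), x = p$x, y = p$y)
  }))
  writeLines(sprintf("# domain: length_x=%g length_y=%g",
                     d$length_x, d$length_y), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Quantify a labelled pattern set
#'
#' Front door of the pipeline: trims the margins per the configuration and
#' dispatches to the stripe, spot or formation analysis, assembling a
#' report with provenance (configuration hash, package version, mode).
#'
#' Modes and required cell types:
#' \describe{
#'   \item{`"stripes"`}{needs `Xd`, `Xl` and `M` patterns; runs
#'     [quantify_stripes()].}
#'   \item{`"spots"`}{needs one pattern (or the `cell_type` argument to pick
#'     one); runs [quantify_spots()].}
#'   \item{`"formation"`}{needs a day-indexed series of `Xd` patterns (a
#'     `pattern_set` from [generate_snapshot_series()] or a list); runs
#'     [formation_times()] on untrimmed patterns.}
#' }
#'
#' @param patterns A named list of [point_pattern()]s (names = cell types),
#'   or a `pattern_set`.
#' @param mode `"stripes"`, `"spots"` or `"formation"`.
#' @param config A [quant_config()].
#' @param cell_type For `mode = "spots"` with several patterns: which cell
#'   type to analyse.
#' @param midline Passed to [quantify_spots()].
#'
#' @return A list of class `pattern_report` with elements `mode`, `results`
#'   (the mode's report) and `provenance`.
#' @export
quantify <- function(patterns, mode = c("stripes", "spots", "formation"),
                     config = quant_config(), cell_type = NULL,
                     midline = FALSE) {
  mode <- match.arg(mode)
  assert_config(config)
  if (inherits(patterns, "pattern_set")) patterns <- patterns$patterns
  if (inherits(patterns, "point_pattern")) {
    patterns <- stats::setNames(list(patterns), pattern_cell_type(patterns))
  }
  found <- paste(names(patterns), collapse = ", ")
  results <- switch(mode,
    stripes = {
      need <- c("Xd", "Xl", "M")
      if (!all(need %in% names(patterns))) {
        rlang::abort(sprintf(
          "mode 'stripes' needs cell types Xd, Xl, M; found: %s", found))
      }
      tr <- lapply(patterns[need], trim_margins, fraction = config$trim_fraction)
      quantify_stripes(tr$Xd, tr$Xl, tr$M, config)
    },
    spots = {
      if (is.null(cell_type)) {
        if (length(patterns) != 1) {
          rlang::abort(sprintf(
            "mode 'spots' needs `cell_type` when several types are present; found: %s",
            found))
        }
        cell_type <- names(patterns)[1]
      }
      if (!cell_type %in% names(patterns)) {
        rlang::abort(sprintf("cell type '%s' not present; found: %s",
                             cell_type, found))
      }
      quantify_spots(trim_margins(patterns[[cell_type]], config$trim_fraction),
                     config, midline = midline)
    },
    formation = {
      formation_times(patterns, config)
    })
  structure(list(mode = mode, results = results,
                 provenance = list(
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("pigmentr")),
                   cell_types = names(patterns))),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("<pattern_report> mode: %s\n", x$mode))
  print(x$results)
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the report with explicit units metadata alongside each numeric
#' block.
#'
#' @param report A `pattern_report`, `band_report`, `spot_report` or
#'   `formation_times` object.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  units <- list(lengths = "micrometre", curviness = "percent",
                spot_size = "cells", days = "dpf")
  payload <- list(report = unclass_deep(report), units = units)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Export cluster labels per cell
#'
#' Writes the cluster assignment of every cell as a CSV (`x`, `y`,
#' `cluster`) for audit.
#'
#' @param clusters A [cluster_pattern()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(clusters, path) {
  assert_cluster_set(clusters)
  readr::write_csv(clusters$assignments, path)
  invisible(path)
}
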