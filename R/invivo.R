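#' Reference in-vivo pigment-cell length scales
#'
#' Published point estimates of cellular length scales on the developing
#' zebrafish flank, used to gauge how much relative noise (coefficient of
#' variation) real cell interactions carry: the centre-to-centre distance of
#' neighbouring dense xanthophores at 40 dpf, and the longest xanthophore
#' filopodia (measured from the cell centre) before and after iridophores
#' arrive on the skin.
#'
#' @return A tibble with columns `measurement`, `mean_um`, `sd_um`.
#' @export
#'
#' @examples
#' dplyr::mutate(invivo_length_scales(), cv = cv_percent(mean_um, sd_um))
invivo_length_scales <- function() {
  tibble::tibble(
    measurement = c("xanthophore neighbour distance (40 dpf)",
                    "xanthophore filopodia length, pre-iridophore",
                    "xanthophore filopodia length, post-iridophore"),
    mean_um = c(27, 58, 25),
    sd_um = c(4.6, 6.7, 5))
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean`: the relative noise level of a length scale. Applied to
#' [invivo_length_scales()] it estimates how large the standard deviation of
#' stochastic cell-interaction length scales is relative to their means
#' (about 17%, 12% and 20% respectively), which brackets the biologically
#' relevant noise regime for simulation studies.
#'
#' @param mean,sd Numeric vectors (any common unit).
#' @return Numeric vector of percentages.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0)) rlang::abort("`mean` must be positive.")
  100 * sd / mean
}
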