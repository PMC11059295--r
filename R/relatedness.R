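#' Summary relatedness statistics for a kinship composition
#'
#' Maps a sibling composition to the mean and standard deviation of the
#' coefficient of relatedness \code{r} among juvenile dyads, and classifies
#' the group as \code{"related"} (almost all natal dyads are kin) or
#' \code{"mix-related"}.
#'
#' The relatedness summary uses the sibling-dyad approximation: dyads take
#' \code{r = 0.5} (full siblings), \code{r = 0.25} (either class of
#' half-sibling) or \code{r = 0} (non-siblings), so
#' \code{mean_r = 0.5 p_full + 0.25 (p_mat + p_pat)} and \code{sd_r} is the
#' standard deviation of \code{r} over the four categories. Relatedness
#' through shared grandparents between non-sibling dyads is not included; the
#' \code{grandparent_r} hook adds a user-supplied expected contribution of
#' such paths to \code{mean_r} and defaults to 0. \code{mean_r} is therefore a
#' lower bound on full-pedigree mean relatedness, and the summary is labelled
#' accordingly in all outputs (\code{approximation = "sibling-dyad"}).
#'
#' A group is classified \code{"related"} when more than \code{kin_threshold}
#' of dyads are kin (share at least a grandparent, i.e.
#' \code{p_kin > kin_threshold}), else \code{"mix-related"}.
#'
#' @param composition A \code{\link{sibling_composition}} data.frame (any
#'   number of rows).
#' @param kin_threshold Kin-fraction cutoff for the \code{"related"}
#'   classification; default 0.95.
#' @param grandparent_r Optional additive contribution of grandparent-mediated
#'   relatedness to \code{mean_r}; default 0.
#' @return A data.frame with columns \code{mean_r}, \code{sd_r},
#'   \code{classification}, \code{approximation}, one row per composition row.
#' @examples
#' comp <- sibling_composition(kin_params(2, 2, 2, 0.9, 0.2, 4, 0.9, 0.9))
#' summarize_relatedness(comp)
#' @export
summarize_relatedness <- function(composition, kin_threshold = 0.95,
                                  grandparent_r = 0) {
  need <- c("p_full", "p_mat", "p_pat", "p_non", "p_kin")
  if (!all(need %in% names(composition)))
    stop("`composition` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  total <- composition$p_full + composition$p_mat + composition$p_pat +
    composition$p_non
  if (any(abs(total - 1) > 1e-8))
    stop("composition rows must sum to 1", call. = FALSE)
  half <- composition$p_mat + composition$p_pat
  mean_r <- 0.5 * composition$p_full + 0.25 * half + grandparent_r
  ex2 <- 0.25 * composition$p_full + 0.0625 * half
  sd_r <- sqrt(pmax(ex2 - (0.5 * composition$p_full + 0.25 * half)^2, 0))
  data.frame(
    mean_r = mean_r,
    sd_r = sd_r,
    classification = ifelse(composition$p_kin > kin_threshold,
                            "related", "mix-related"),
    approximation = "sibling-dyad",
    stringsAsFactors = FALSE
  )
}
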