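#' Write a single-group composition record as JSON
#'
#' Emits one JSON object containing the parameters, all composition fields,
#' the relatedness summary and the five per-scenario probability profiles.
#' Numbers are written at full double precision.
#'
#' @param params A \code{\link{kin_params}} object.
#' @param path Output file path.
#' @return The record (a list), invisibly.
#' @export
write_composition_json <- function(params, path) {
  comp <- sibling_composition(params)
  rel <- summarize_relatedness(comp)
  rec <- c(as.list(as.data.frame(params)),
           as.list(comp[1, c("p_full", "p_mat", "p_pat", "p_non", "p_kin",
                             "feasible")]),
           as.list(rel[1, ]),
           list(scenarios = scenario_profiles(params)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rec)
}

#' Write / read a FIO sweep table as CSV
#'
#' The draw table is written with one row per draw (feasibility flag
#' included) at full round-trip double precision, so a written table re-read
#' with \code{read_fio_csv} reproduces correlation tables exactly. Column
#' names use the ASCII parameter symbols (\code{N_m, N_f, n, alpha, beta,
#' kappa, tau_m, tau_f, eps}).
#'
#' @param results A \code{\link{run_fio}} result.
#' @param path CSV file path.
#' @return \code{results}, invisibly.
#' @export
write_fio_csv <- function(results, path) {
  stopifnot(inherits(results, "fio_result"))
  data.table::fwrite(results$draws, path)
  invisible(results)
}

#' @rdname write_fio_csv
#' @param set,seed Optional metadata recorded in the reconstructed config
#'   (the CSV itself carries only the draws).
#' @return \code{read_fio_csv} returns a \code{"fio_result"} whose draw table
#'   is the file contents and whose exclusion fraction is recomputed from the
#'   feasibility column.
#' @export
read_fio_csv <- function(path, set = "main", seed = NULL) {
  draws <- as.data.frame(data.table::fread(path))
  if (!"feasible" %in% names(draws))
    stop("not a FIO sweep table: no `feasible` column in ", path, call. = FALSE)
  structure(list(draws = draws,
                 exclusion_fraction = if (nrow(draws)) mean(!draws$feasible)
                                      else NA_real_,
                 config = fio_config(set, n_iterations = nrow(draws),
                                     seed = seed)),
            class = "fio_result")
}

#' Write a correlation table as CSV
#'
#' @param tab A \code{\link{correlation_table}} data.frame.
#' @param path CSV file path.
#' @return \code{tab}, invisibly.
#' @export
write_correlation_csv <- function(tab, path) {
  data.table::fwrite(tab, path)
  invisible(tab)
}

#' Write threshold summaries as JSON
#'
#' @param summaries A \code{\link{threshold_summaries}} list.
#' @param path JSON file path.
#' @return \code{summaries}, invisibly.
#' @export
write_summaries_json <- function(summaries, path) {
  jsonlite::write_json(summaries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(summaries)
}
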