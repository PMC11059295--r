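#' Configuration for a "fitting to idealised outcomes" (FIO) sweep
#'
#' The FIO analysis probes the deterministic model by evaluating it over many
#' independently drawn random parameter sets and correlating parameters with
#' outcomes. Two draw sets are defined. The \code{"main"} set draws every
#' parameter uniformly over its declared range with pair-bond stability fixed
#' at \code{eps = 0.5} (no pair bond), which makes every draw feasible. The
#' \code{"pairbond"} set varies \code{eps} uniformly on \code{[0.5, 1)} and
#' restricts \code{N_f} to \code{{5..10}} and \code{beta} to \code{[0.5, 1]}
#' to keep infeasible combinations rare; the few remaining infeasible draws
#' are flagged and excluded from statistics.
#'
#' @param set \code{"main"} or \code{"pairbond"}.
#' @param n_iterations Number of random draws (default 1e5).
#' @param seed Integer seed; required for reproducible sweeps.
#' @return A list of class \code{"fio_config"} with elements \code{set},
#'   \code{n_iterations}, \code{seed} and \code{ranges} (per-parameter
#'   numeric ranges; integers sampled uniformly on their integer range, reals
#'   uniformly on their interval).
#' @examples
#' fio_config("main", n_iterations = 1000, seed = 42)
#' @export
fio_config <- function(set = c("main", "pairbond"), n_iterations = 100000L,
                       seed = NULL) {
  set <- match.arg(set)
  if (!is.numeric(n_iterations) || length(n_iterations) != 1L ||
      is.na(n_iterations) || n_iterations < 0 ||
      n_iterations != round(n_iterations))
    stop("n_iterations must be a single non-negative integer", call. = FALSE)
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || is.na(seed)))
    stop("seed must be a single integer", call. = FALSE)
  ranges <- list(
    N_m = c(2L, 10L), N_f = c(2L, 10L), n = c(1L, 6L), kappa = c(1L, 6L),
    alpha = c(0, 1), beta = c(0, 1), tau_m = c(0, 1), tau_f = c(0, 1),
    eps = c(0.5, 0.5)
  )
  if (set == "pairbond") {
    ranges$N_f <- c(5L, 10L)
    ranges$beta <- c(0.5, 1)
    ranges$eps <- c(0.5, 1)
  }
  structure(list(set = set, n_iterations = as.integer(n_iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ranges = ranges),
            class = "fio_config")
}

#' Draw random parameter sets for a FIO sweep
#'
#' Integer parameters (\code{N_m, N_f, n, kappa}) are uniform on their integer
#' ranges; real parameters (\code{alpha, beta, tau_m, tau_f, eps}) are uniform
#' on their intervals, with the open endpoints of \code{alpha} (upper) and
#' \code{beta} (lower) respected because \code{runif} never returns its
#' bounds. All draws are independent and reproducible from the seed.
#'
#' @param config A \code{\link{fio_config}}.
#' @return A data.frame of \code{n_iterations} rows with the nine parameter
#'   columns.
#' @export
sample_parameters <- function(config) {
  stopifnot(inherits(config, "fio_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_iterations
  r <- config$ranges
  draw_int <- function(rg) if (n == 0L) integer(0) else
    sample(seq.int(rg[1], rg[2]), n, replace = TRUE)
  draw_real <- function(rg) if (rg[1] == rg[2]) rep(rg[1], n) else
    stats::runif(n, rg[1], rg[2])
  data.frame(
    N_m = draw_int(r$N_m), N_f = draw_int(r$N_f), n = draw_int(r$n),
    alpha = draw_real(r$alpha), beta = draw_real(r$beta),
    kappa = draw_int(r$kappa), tau_m = draw_real(r$tau_m),
    tau_f = draw_real(r$tau_f), eps = draw_real(r$eps)
  )
}

#' Run a FIO parameter sweep
#'
#' Draws \code{n_iterations} random parameter sets, evaluates the kinship
#' composition and relatedness summary for each, flags infeasible draws
#' (excluded from all downstream statistics but retained in the table), and
#' records the adult sex ratio \code{N_m / (N_m + N_f)}.
#'
#' @param config A \code{\link{fio_config}}.
#' @return A list of class \code{"fio_result"}: \code{draws} (one row per
#'   draw: parameters, \code{sex_ratio}, composition, \code{mean_r},
#'   \code{sd_r}, \code{classification}, \code{feasible}),
#'   \code{exclusion_fraction}, and the \code{config}.
#' @examples
#' res <- run_fio(fio_config("main", n_iterations = 500, seed = 1))
#' head(res$draws)
#' @export
run_fio <- function(config) {
  stopifnot(inherits(config, "fio_config"))
  pt <- sample_parameters(config)
  if (nrow(pt) == 0L) {
    draws <- cbind(pt, sex_ratio = numeric(0), p_full = numeric(0),
                   p_mat = numeric(0), p_pat = numeric(0),
                   p_non = numeric(0), p_kin = numeric(0),
                   mean_r = numeric(0), sd_r = numeric(0),
                   classification = character(0), feasible = logical(0))
    return(structure(list(draws = draws, exclusion_fraction = NA_real_,
                          config = config), class = "fio_result"))
  }
  comp <- sibling_composition(pt)
  rel <- summarize_relatedness(comp)
  draws <- cbind(pt,
                 sex_ratio = pt$N_m / (pt$N_m + pt$N_f),
                 comp[c("p_full", "p_mat", "p_pat", "p_non", "p_kin")],
                 rel[c("mean_r", "sd_r", "classification")],
                 feasible = comp$feasible)
  structure(list(draws = draws,
                 exclusion_fraction = mean(!comp$feasible),
                 config = config),
            class = "fio_result")
}

#' @export
print.fio_result <- function(x, ...) {
  cat(sprintf("FIO sweep (%s set): %d draws, %.2f%% infeasible (excluded)\n",
              x$config$set, nrow(x$draws), 100 * x$exclusion_fraction))
  invisible(x)
}

fio_outcomes <- function() {
  c(mean_r = "mean_r", sd_r = "sd_r", p_full = "p_full", p_pat = "p_pat",
    p_mat = "p_mat", p_sibs = "p_sibs")
}

feasible_draws <- function(results) {
  stopifnot(inherits(results, "fio_result"))
  d <- results$draws[results$draws$feasible, , drop = FALSE]
  d$p_sibs <- 1 - d$p_non
  d
}

#' Rank-correlation sensitivity table of a FIO sweep
#'
#' Spearman rank correlation of each model parameter against each outcome
#' (mean and SD of dyad relatedness under the sibling-dyad approximation, and
#' the proportions of full, paternal-half, maternal-half and all siblings)
#' over the feasible draws. Rank correlation is used because the
#' parameter-outcome relationships are monotonic but rarely linear. Ties take
#' midranks. A parameter held constant in the sweep (e.g. \code{eps} in the
#' main set) has no defined correlation and is reported as \code{NA}.
#'
#' @param results A \code{\link{run_fio}} result.
#' @return A data.frame with one row per parameter (column \code{parameter})
#'   and one column per outcome: \code{mean_r}, \code{sd_r}, \code{p_full},
#'   \code{p_pat}, \code{p_mat}, \code{p_sibs}.
#' @export
correlation_table <- function(results) {
  d <- feasible_draws(results)
  if (nrow(d) < 3L)
    stop("correlation_table() needs at least 3 feasible draws", call. = FALSE)
  out <- sapply(fio_outcomes(), function(oc) {
    sapply(param_names(), function(pn) {
      x <- d[[pn]]
      if (length(unique(x)) < 2L || length(unique(d[[oc]])) < 2L)
        return(NA_real_)
      stats::cor(x, d[[oc]], method = "spearman")
    })
  })
  data.frame(parameter = param_names(), out, row.names = NULL)
}

#' Threshold and binned summaries of a FIO sweep
#'
#' Conditional and binned summaries over the feasible draws:
#' \itemize{
#'   \item \code{p_full_gt20_monotocy}, \code{p_full_gt20_polytocy}: fraction
#'     of draws with more than 20\% full-sibling dyads, conditional on litter
#'     size 1 vs litter size 2 or more.
#'   \item \code{frac_pat_gt_mat}: fraction of draws where paternal
#'     half-siblings outnumber maternal half-siblings.
#'   \item \code{exclusion_fraction}: fraction of all draws flagged
#'     infeasible.
#'   \item \code{bins}: mean composition within regions of parameter space —
#'     high male skew (\code{alpha > 0.75, tau_m > 0.75}), high female skew
#'     (\code{beta < 0.25, tau_f > 0.75}), both, and male-/female-biased
#'     adult sex ratio (\code{N_m/(N_m+N_f) > 0.7} or \code{< 0.3}).
#' }
#' An empty bin yields \code{NA} means and is listed in
#' \code{empty_bins}.
#'
#' @param results A \code{\link{run_fio}} result.
#' @return A list with the elements described above.
#' @export
threshold_summaries <- function(results) {
  d <- feasible_draws(results)
  if (nrow(d) == 0L)
    stop("threshold_summaries() needs at least one feasible draw", call. = FALSE)
  cond_frac <- function(cond, event) {
    if (!any(cond)) NA_real_ else mean(event[cond])
  }
  bin_defs <- list(
    high_male_skew = d$alpha > 0.75 & d$tau_m > 0.75,
    high_female_skew = d$beta < 0.25 & d$tau_f > 0.75,
    high_both_skew = d$alpha > 0.75 & d$tau_m > 0.75 &
      d$beta < 0.25 & d$tau_f > 0.75,
    male_biased_sex_ratio = d$sex_ratio > 0.7,
    female_biased_sex_ratio = d$sex_ratio < 0.3
  )
  bins <- lapply(bin_defs, function(sel) {
    if (!any(sel))
      return(data.frame(n = 0L, p_full = NA_real_, p_mat = NA_real_,
                        p_pat = NA_real_, p_non = NA_real_))
    data.frame(n = sum(sel),
               p_full = mean(d$p_full[sel]), p_mat = mean(d$p_mat[sel]),
               p_pat = mean(d$p_pat[sel]), p_non = mean(d$p_non[sel]))
  })
  list(
    p_full_gt20_monotocy = cond_frac(d$kappa == 1, d$p_full > 0.20),
    p_full_gt20_polytocy = cond_frac(d$kappa >= 2, d$p_full > 0.20),
    frac_pat_gt_mat = mean(d$p_pat > d$p_mat),
    exclusion_fraction = results$exclusion_fraction,
    bins = bins,
    empty_bins = names(bin_defs)[!vapply(bin_defs, any, logical(1))]
  )
}

#' Parameter histograms of draws exceeding an outcome threshold
#'
#' For the feasible draws whose \code{outcome} exceeds \code{threshold},
#' counts draws per parameter-value bin: one bin per value for the integer
#' parameters, 10 equal-width bins over the sampled range for the real
#' parameters. Monotonic parameter-outcome relationships show up as monotone
#' count profiles.
#'
#' @param results A \code{\link{run_fio}} result.
#' @param outcome One of \code{"mean_r"}, \code{"sd_r"}, \code{"p_full"},
#'   \code{"p_pat"}, \code{"p_mat"}, \code{"p_sibs"}.
#' @param threshold Numeric cutoff; draws with \code{outcome > threshold} are
#'   counted.
#' @return A named list (one element per parameter) of data.frames with
#'   columns \code{bin} (label), \code{midpoint} and \code{count}. Bins with
#'   no qualifying draws have count 0.
#' @export
outcome_histograms <- function(results, outcome, threshold) {
  outcome <- match.arg(outcome, unname(fio_outcomes()))
  d <- feasible_draws(results)
  sel <- d[[outcome]] > threshold
  ranges <- results$config$ranges
  ints <- c("N_m", "N_f", "n", "kappa")
  out <- lapply(param_names(), function(pn) {
    rg <- ranges[[pn]]
    if (pn %in% ints) {
      vals <- seq.int(rg[1], rg[2])
      counts <- vapply(vals, function(v) sum(sel & d[[pn]] == v), integer(1))
      data.frame(bin = as.character(vals), midpoint = as.numeric(vals),
                 count = counts, stringsAsFactors = FALSE)
    } else {
      edges <- seq(rg[1], rg[2], length.out = 11L)
      if (rg[1] == rg[2]) {
        data.frame(bin = sprintf("%g", rg[1]), midpoint = rg[1],
                   count = sum(sel), stringsAsFactors = FALSE)
      } else {
        idx <- findInterval(d[[pn]], edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        counts <- vapply(1:10, function(b) sum(sel & idx == b), integer(1))
        data.frame(bin = sprintf("[%.2f,%.2f%s", edges[1:10], edges[2:11],
                                 c(rep(")", 9), "]")),
                   midpoint = (edges[1:10] + edges[2:11]) / 2,
                   count = counts, stringsAsFactors = FALSE)
      }
    }
  })
  names(out) <- param_names()
  out
}
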