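#' Social and life-history parameters for one group
#'
#' Bundles the nine parameters of the kinship-composition model and validates
#' them against the ranges the model was designed for. Integer parameters are
#' counts; real parameters are probabilities or skew/stability coefficients.
#'
#' @param N_m Number of adult males (integer, >= 2).
#' @param N_f Number of adult females (integer, >= 2).
#' @param n Number of juvenile cohorts simultaneously present (integer, >= 1).
#' @param alpha Male reproductive skew in \code{[0, 1]}: the fraction of the
#'   non-dominant males' expected paternity captured by the dominant male.
#'   \code{alpha = 1} (full monopoly) is admitted as a limit case.
#' @param beta Probability that a subordinate female reproduces, in
#'   \code{(0, 1]}. Low \code{beta} means high female reproductive skew.
#' @param kappa Litter size (integer, >= 1). \code{kappa = 1} is monotocy.
#' @param tau_m Probability that the dominant male retains dominance between
#'   successive cohorts, in \code{[0, 1]}.
#' @param tau_f As \code{tau_m}, for the dominant female.
#' @param eps Pair-bond stability in \code{[0.5, 1]}: an odds multiplier making
#'   offspring of the same mother more likely to share a father.
#'   \code{eps = 0.5} is independence (random mating); \code{eps = 1} is strict
#'   fidelity, admitted as a limit case.
#' @param relaxed If \code{TRUE}, the upper bounds on the count parameters
#'   (\code{N_m, N_f <= 10}; \code{n, kappa <= 6}) are not enforced; structural
#'   bounds (lower bounds, probability ranges) always are.
#'
#' @return An object of class \code{"kin_params"}: a named list of the nine
#'   validated parameters.
#' @examples
#' kin_params(N_m = 10, N_f = 10, n = 4, alpha = 0, beta = 1,
#'            kappa = 1, tau_m = 1, tau_f = 1, eps = 1)
#' @export
kin_params <- function(N_m, N_f, n, alpha, beta, kappa, tau_m, tau_f,
                       eps = 0.5, relaxed = FALSE) {
  p <- list(N_m = N_m, N_f = N_f, n = n, alpha = alpha, beta = beta,
            kappa = kappa, tau_m = tau_m, tau_f = tau_f, eps = eps)
  validate_kin_params(p, relaxed = relaxed)
  structure(p, class = "kin_params", relaxed = relaxed)
}

#' @export
print.kin_params <- function(x, ...) {
  cat("Kinship-composition model parameters\n")
  cat(sprintf("  males N_m = %d, females N_f = %d, cohorts n = %d, litter kappa = %d\n",
              x$N_m, x$N_f, x$n, x$kappa))
  cat(sprintf("  male skew alpha = %.3f, subordinate female breeding beta = %.3f\n",
              x$alpha, x$beta))
  cat(sprintf("  tenure tau_m = %.3f, tau_f = %.3f, pair-bond eps = %.3f\n",
              x$tau_m, x$tau_f, x$eps))
  invisible(x)
}

#' @export
as.data.frame.kin_params <- function(x, ...) {
  data.frame(N_m = x$N_m, N_f = x$N_f, n = x$n, alpha = x$alpha,
             beta = x$beta, kappa = x$kappa, tau_m = x$tau_m,
             tau_f = x$tau_f, eps = x$eps)
}

param_names <- function() {
  c("N_m", "N_f", "n", "alpha", "beta", "kappa", "tau_m", "tau_f", "eps")
}

# Declared ranges: count parameters 2..10 (N_m, N_f) and 1..6 (n, kappa);
# alpha in [0,1], beta in (0,1], tau in [0,1], eps in [0.5,1], with
# alpha = 1 and eps = 1 admitted as explicit limit cases.
param_ranges_text <- function() {
  paste("  N_m, N_f : integers in {2, ..., 10}",
        "  n, kappa : integers in {1, ..., 6}",
        "  alpha    : real in [0, 1]   (1 = full male monopoly, limit case)",
        "  beta     : real in (0, 1]",
        "  tau_m, tau_f : reals in [0, 1]",
        "  eps      : real in [0.5, 1] (1 = strict fidelity, limit case)",
        sep = "\n")
}

validate_kin_params <- function(p, relaxed = FALSE) {
  fail <- function(sym, msg) {
    stop(sprintf("invalid parameter %s: %s\nAccepted ranges:\n%s",
                 sym, msg, param_ranges_text()), call. = FALSE)
  }
  chk_int <- function(v, sym) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v))
      fail(sym, "must be a single integer")
  }
  chk_real <- function(v, sym, lo, hi, lo_open = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      fail(sym, "must be a single number")
    if (v > hi || v < lo || (lo_open && v == lo))
      fail(sym, sprintf("value %g outside %s%g, %g]", v,
                        if (lo_open) "(" else "[", lo, hi))
  }
  chk_int(p$N_m, "N_m"); chk_int(p$N_f, "N_f")
  chk_int(p$n, "n"); chk_int(p$kappa, "kappa")
  if (p$N_m < 2) fail("N_m", "at least 2 adult males are required")
  if (p$N_f < 2) fail("N_f", "at least 2 adult females are required")
  if (p$n < 1) fail("n", "at least 1 juvenile cohort is required")
  if (p$kappa < 1) fail("kappa", "litter size must be at least 1")
  if (!relaxed) {
    if (p$N_m > 10) fail("N_m", "above the declared upper bound 10")
    if (p$N_f > 10) fail("N_f", "above the declared upper bound 10")
    if (p$n > 6) fail("n", "above the declared upper bound 6")
    if (p$kappa > 6) fail("kappa", "above the declared upper bound 6")
  }
  chk_real(p$alpha, "alpha", 0, 1)
  chk_real(p$beta, "beta", 0, 1, lo_open = TRUE)
  chk_real(p$tau_m, "tau_m", 0, 1)
  chk_real(p$tau_f, "tau_f", 0, 1)
  chk_real(p$eps, "eps", 0.5, 1)
  invisible(TRUE)
}

# Accept either a kin_params object or a data.frame with the nine columns;
# returns a plain data.frame of parameter draws (no per-row validation for
# data.frames: the sweep engine generates in-range draws by construction).
as_param_table <- function(params) {
  if (inherits(params, "kin_params")) return(as.data.frame(params))
  if (is.data.frame(params)) {
    missing <- setdiff(param_names(), names(params))
    if (length(missing))
      stop("parameter table is missing columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    return(as.data.frame(params))
  }
  stop("`params` must be a kin_params object or a data.frame of parameter draws",
       call. = FALSE)
}
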