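#' Proportion of a cohort sired by the dominant male
#'
#' The dominant male takes a share \code{d = 1/N_m + alpha * (N_m - 1)/N_m} of
#' the paternity in a cohort: at \code{alpha = 0} all males sire equally, at
#' \code{alpha = 1} the dominant sires every offspring. \code{alpha^2} equals
#' Bradbury's bounded skew index for this distribution.
#'
#' All closed-form functions in this file are vectorised over their arguments.
#'
#' @param N_m Number of adult males (>= 2).
#' @param alpha Male reproductive skew in \code{[0, 1]}.
#' @return The dominant's paternity share \code{d} in \code{[1/N_m, 1]}.
#' @examples
#' dominant_male_share(4, 0.5) # 0.625
#' @export
dominant_male_share <- function(N_m, alpha) {
  if (any(N_m < 2)) stop("N_m must be at least 2", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  1 / N_m + alpha * (N_m - 1) / N_m
}

#' Probability of sharing a father under a stable dominance regime
#'
#' For two juveniles conceived under the same dominant male (same cohort, or
#' different cohorts with no intervening male dominance turnover), the
#' probability of sharing a father is \code{p0 = d^2 + (1 - d)^2 / (N_m - 1)}:
#' either both were sired by the dominant, or both by the same one of the
#' \code{N_m - 1} subordinates, who share the residual paternity equally.
#'
#' @inheritParams dominant_male_share
#' @return Probability \code{p0} in \code{[1/N_m, 1]}; equals \code{1/N_m}
#'   exactly when \code{alpha = 0}.
#' @examples
#' p_father_same_regime(10, 0)  # 0.1
#' @export
p_father_same_regime <- function(N_m, alpha) {
  d <- dominant_male_share(N_m, alpha)
  d^2 + (1 - d)^2 / (N_m - 1)
}

# Binomially weighted sum over the number of breeding females i = 1..N_f.
# The dominant female always breeds; each of the N_f - 1 subordinates breeds
# with probability beta, so i - 1 ~ Binomial(N_f - 1, beta). `ratio_fun(i)`
# gives the dyad probability conditional on i breeders.
breeders_weighted_sum <- function(N_f, beta, ratio_fun) {
  out <- 0
  for (i in seq_len(max(N_f))) {
    w <- ifelse(i <= N_f, stats::dbinom(i - 1, N_f - 1, beta), 0)
    out <- out + w * ratio_fun(i)
  }
  out
}

#' Probability that two same-cohort juveniles share a mother
#'
#' Within a cohort, two juveniles share a mother only if they are littermates.
#' Conditional on \code{i} breeding females, each producing a litter of
#' \code{kappa}, a juvenile has \code{kappa - 1} littermates among the
#' \code{i * kappa - 1} other juveniles, giving \code{(kappa - 1)/(i*kappa - 1)};
#' the result averages this over the binomial distribution of \code{i}.
#'
#' Under monotocy (\code{kappa = 1}) every litter is a single offspring, so no
#' within-cohort dyad can share a mother and the probability is exactly 0 (the
#' \code{i = 1} term, formally 0/0, is resolved to 0: a sole breeder produces
#' one offspring and no within-cohort dyad at all).
#'
#' @param N_f Number of adult females (>= 2).
#' @param beta Subordinate female breeding probability in \code{(0, 1]}.
#' @param kappa Litter size (>= 1).
#' @return Probability in \code{[0, 1]}.
#' @examples
#' p_mother_within_cohort(3, 0.5, 2) # 7/15 = 0.4667
#' @export
p_mother_within_cohort <- function(N_f, beta, kappa) {
  if (any(N_f < 2)) stop("N_f must be at least 2", call. = FALSE)
  if (any(beta <= 0 | beta > 1)) stop("beta must lie in (0, 1]", call. = FALSE)
  if (any(kappa < 1)) stop("kappa must be at least 1", call. = FALSE)
  breeders_weighted_sum(N_f, beta, function(i) {
    ifelse(kappa == 1, 0, (kappa - 1) / (i * kappa - 1))
  })
}

#' Probability that juveniles of different cohorts share a mother (stable regime)
#'
#' Between cohorts with no female dominance turnover, the same set of females
#' breeds in both cohorts, so conditional on \code{i} breeders the probability
#' of sharing a mother is \code{1/i} regardless of litter size. The result
#' averages \code{1/i} over the binomial distribution of \code{i}.
#'
#' @inheritParams p_mother_within_cohort
#' @return Probability in \code{(0, 1]}; equals \code{1/N_f} when
#'   \code{beta = 1} and approaches 1 as \code{beta} approaches 0.
#' @examples
#' p_mother_between_cohorts(3, 0.5) # 0.5833
#' @export
p_mother_between_cohorts <- function(N_f, beta) {
  if (any(N_f < 2)) stop("N_f must be at least 2", call. = FALSE)
  if (any(beta <= 0 | beta > 1)) stop("beta must lie in (0, 1]", call. = FALSE)
  breeders_weighted_sum(N_f, beta, function(i) 1 / i)
}

#' Conditional probability of sharing a father given a shared mother
#'
#' Pair-bond stability \code{eps} tilts the odds of sharing a father for
#' maternal siblings: the baseline odds \code{O(F) = p/(1 - p)} are multiplied
#' by \code{O(eps) = eps/(1 - eps)} and converted back to a probability. At
#' \code{eps = 0.5} the multiplier is 1 (independence); at \code{eps = 1} all
#' offspring of one mother share a father. Degenerate baselines
#' \code{p_father} of 0 or 1 map to themselves for every \code{eps}.
#'
#' @param p_father Baseline probability of sharing a father, in \code{[0, 1]}.
#' @param eps Pair-bond stability in \code{[0.5, 1]}.
#' @return \code{P(Father | Mother)} in \code{[0, 1]}, non-decreasing in
#'   \code{eps}.
#' @examples
#' p_father_given_mother(0.1, 0.9) # 0.5
#' @export
p_father_given_mother <- function(p_father, eps) {
  if (any(p_father < 0 | p_father > 1))
    stop("p_father must lie in [0, 1]", call. = FALSE)
  if (any(eps < 0.5 | eps > 1))
    stop("eps must lie in [0.5, 1]", call. = FALSE)
  odds <- (p_father / (1 - p_father)) * (eps / (1 - eps))
  out <- odds / (1 + odds)
  # limit cases: eps = 1 forces certainty whenever sharing is possible at all;
  # a degenerate baseline is unchanged by the odds tilt
  out <- ifelse(eps == 1 & p_father > 0, 1, out)
  ifelse(p_father %in% c(0, 1), p_father, out)
}

#' Relative frequencies of the five dyad scenarios
#'
#' A dyad of juveniles drawn from \code{n} equal-sized cohorts falls in one of
#' five scenarios: (1) same cohort; different cohorts with (2) no dominance
#' change, (3) a female dominance change only, (4) a male dominance change
#' only, (5) both. Counting ordered cohort pairs, same-cohort dyads have mass
#' \code{n/n^2} and lag-\code{i} pairs mass \code{2(n - i)/n^2}; retention
#' across a lag of \code{i} cohorts has probability \code{tau^i}, and the four
#' between-cohort scenarios split the lag mass by the products of retention
#' and turnover probabilities for each sex.
#'
#' @param n Number of juvenile cohorts (>= 1).
#' @param tau_m,tau_f Dominance retention probabilities per cohort step, in
#'   \code{[0, 1]}.
#' @return For scalar input, a named numeric vector of the five scenario
#'   weights (summing to 1); for vector input, a matrix with one row per input
#'   and columns \code{s1..s5}.
#' @examples
#' scenario_weights(4, 1, 1) # c(0.25, 0.75, 0, 0, 0)
#' @export
scenario_weights <- function(n, tau_m, tau_f) {
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  len <- max(length(n), length(tau_m), length(tau_f))
  n <- rep_len(n, len); tau_m <- rep_len(tau_m, len); tau_f <- rep_len(tau_f, len)
  w <- matrix(0, len, 5, dimnames = list(NULL, paste0("s", 1:5)))
  w[, 1] <- 1 / n
  for (i in seq_len(max(n) - 1)) {
    lag_mass <- ifelse(n - 1 >= i, 2 * (n - i) / n^2, 0)
    rm_ <- tau_m^i; rf_ <- tau_f^i
    w[, 2] <- w[, 2] + lag_mass * rm_ * rf_
    w[, 3] <- w[, 3] + lag_mass * rm_ * (1 - rf_)
    w[, 4] <- w[, 4] + lag_mass * (1 - rm_) * rf_
    w[, 5] <- w[, 5] + lag_mass * (1 - rm_) * (1 - rf_)
  }
  if (len == 1L) w[1, ] else w
}

# Vectorised scenario ingredients for a table of parameter draws: returns a
# list of three len x 5 matrices (PF, PM, PFM) plus the weight matrix W.
scenario_matrices <- function(pt) {
  p0 <- p_father_same_regime(pt$N_m, pt$alpha)
  e1 <- p_mother_within_cohort(pt$N_f, pt$beta, pt$kappa)
  e2 <- p_mother_between_cohorts(pt$N_f, pt$beta)
  pfm <- p_father_given_mother(p0, pt$eps)
  PF  <- cbind(p0, p0, p0, 1 / pt$N_m, 1 / pt$N_m)
  PM  <- cbind(e1, e2, 1 / pt$N_f, e2, 1 / pt$N_f)
  # a male dominance change (scenarios 4-5) disrupts any pair bond, so the
  # conditional collapses to the baseline there
  PFM <- cbind(pfm, pfm, pfm, 1 / pt$N_m, 1 / pt$N_m)
  W <- scenario_weights(pt$n, pt$tau_m, pt$tau_f)
  if (!is.matrix(W)) W <- matrix(W, 1)
  colnames(PF) <- colnames(PM) <- colnames(PFM) <- colnames(W) <- paste0("s", 1:5)
  list(PF = PF, PM = PM, PFM = PFM, W = W)
}

#' Per-scenario probability profiles
#'
#' Expands one parameter set into the five dyad scenarios, giving for each its
#' probability of sharing a father, of sharing a mother, the pair-bond
#' conditional \code{P(Father | Mother)}, and the scenario weight.
#'
#' @param params A \code{\link{kin_params}} object.
#' @return A five-row data.frame with columns \code{scenario},
#'   \code{p_father}, \code{p_mother}, \code{p_father_given_mother},
#'   \code{weight}.
#' @examples
#' scenario_profiles(kin_params(10, 10, 4, 0, 1, 1, 1, 0.5, eps = 1))
#' @export
scenario_profiles <- function(params) {
  pt <- as_param_table(params)
  if (nrow(pt) != 1L)
    stop("scenario_profiles() expects a single parameter set", call. = FALSE)
  m <- scenario_matrices(pt)
  data.frame(scenario = 1:5,
             p_father = as.numeric(m$PF),
             p_mother = as.numeric(m$PM),
             p_father_given_mother = as.numeric(m$PFM),
             weight = as.numeric(m$W))
}

#' Feasibility of a parameter combination
#'
#' A strong pair bond applied to a group where sharing a mother is common but
#' sharing a father is rare can imply the impossible joint probability
#' \code{P(Father | Mother) * P(Mother) > P(Father)}. A parameter set is
#' feasible iff this holds in none of the scenarios where the pair bond is
#' active (scenarios 1-3); scenarios 4-5 satisfy it automatically.
#'
#' @param params A \code{\link{kin_params}} object or a data.frame of
#'   parameter draws (one row per draw).
#' @return Logical (vector for a data.frame input).
#' @export
is_feasible <- function(params) {
  pt <- as_param_table(params)
  m <- scenario_matrices(pt)
  joint <- m$PFM * m$PM
  rowSums(joint > m$PF + 1e-12) == 0
}

#' Kinship composition of the juveniles of a group
#'
#' The central quantity of the model: the probabilities that a random dyad of
#' juveniles born into the group are full siblings, maternal half-siblings,
#' paternal half-siblings, or non-siblings, plus the probability
#' \code{p_kin = 1 - p_non^2} that they share at least one parent or
#' grandparent.
#'
#' Per scenario, full siblings arise with probability
#' \code{P(Father | Mother) * P(Mother)}, maternal half-siblings with
#' \code{(1 - P(Father | Mother)) * P(Mother)}, and paternal half-siblings
#' with \code{P(Father | not Mother) * (1 - P(Mother))}, where the last
#' conditional follows from total probability:
#' \code{P(F | !M) = (P(F) - P(F|M) P(M)) / (1 - P(M))}. The group-level
#' composition is the scenario-weight average; the four categories sum to 1.
#'
#' @param params A \code{\link{kin_params}} object or a data.frame of
#'   parameter draws (columns \code{N_m, N_f, n, alpha, beta, kappa, tau_m,
#'   tau_f, eps}); all rows are evaluated at once.
#' @param strict If \code{TRUE}, an infeasible parameter combination (see
#'   \code{\link{is_feasible}}) is an error; otherwise it is returned with
#'   \code{feasible = FALSE} so sweeps can exclude it.
#' @return A data.frame of class \code{"sibling_composition"} with columns
#'   \code{p_full}, \code{p_mat}, \code{p_pat}, \code{p_non}, \code{p_kin},
#'   \code{feasible}, one row per parameter set.
#' @examples
#' sibling_composition(kin_params(10, 10, 4, 0, 1, 1, 1, 0.5, eps = 1))
#' @export
sibling_composition <- function(params, strict = FALSE) {
  pt <- as_param_table(params)
  m <- scenario_matrices(pt)
  joint <- m$PFM * m$PM
  feasible <- rowSums(joint > m$PF + 1e-12) == 0
  if (strict && any(!feasible))
    stop("infeasible parameter combination: P(Father|Mother)*P(Mother) exceeds ",
         "P(Father) in a pair-bonded scenario", call. = FALSE)
  p_full <- rowSums(m$W * joint)
  p_mat  <- rowSums(m$W * (1 - m$PFM) * m$PM)
  pf_not_m <- ifelse(m$PM < 1, (m$PF - joint) / (1 - m$PM), 0)
  p_pat  <- rowSums(m$W * pf_not_m * (1 - m$PM))
  p_non  <- 1 - p_full - p_mat - p_pat
  out <- data.frame(p_full = p_full, p_mat = p_mat, p_pat = p_pat,
                    p_non = p_non, p_kin = 1 - p_non^2, feasible = feasible)
  class(out) <- c("sibling_composition", class(out))
  out
}
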