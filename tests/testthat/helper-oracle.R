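# Brute-force generative oracle for the kinship-composition model.
#
# Simulates one juvenile dyad per replicate, mechanistically: a cohort pair
# drawn uniformly over ordered pairs, male/female dominance chains with
# per-step turnover probability 1 - tau, a breeding-female set per dominance
# regime (dominant always breeds, subordinates with probability beta, the set
# persisting while the regime lasts), litters of size kappa, and fathers
# assigned from the dominant's share d with the residual split equally.
# Pair-bond stability eps > 0.5 is applied as dyad-level resampling with the
# odds-tilt conditional; the scenario-level P(Mother) it needs is estimated
# empirically from the simulated dyads themselves, so the closed-form
# mother-sharing equations never enter the oracle.
oracle_composition <- function(params, reps = 1e5, seed = 1) {
  set.seed(seed)
  Nm <- params$N_m; Nf <- params$N_f; n <- params$n
  alpha <- params$alpha; beta <- params$beta; kap <- params$kappa
  tm <- params$tau_m; tf <- params$tau_f; eps <- params$eps
  R <- as.integer(reps)
  d <- 1 / Nm + alpha * (Nm - 1) / Nm

  # dominance turnover chains (gap j-1 separates cohorts j-1 and j)
  Tm <- Tf <- matrix(FALSE, R, max(n - 1, 1))
  if (n > 1) {
    Tm <- matrix(stats::runif(R * (n - 1)) < 1 - tm, R, n - 1)
    Tf <- matrix(stats::runif(R * (n - 1)) < 1 - tf, R, n - 1)
  }

  # dominant male per cohort
  Dm <- matrix(0L, R, n)
  Dm[, 1] <- sample.int(Nm, R, TRUE)
  if (n > 1) for (j in 2:n)
    Dm[, j] <- ifelse(Tm[, j - 1], sample.int(Nm, R, TRUE), Dm[, j - 1])

  # breeding-female set per cohort (R x n x Nf); redrawn on female turnover
  new_regime <- function() {
    dom <- sample.int(Nf, R, TRUE)
    set <- matrix(stats::runif(R * Nf) < beta, R, Nf)
    set[cbind(seq_len(R), dom)] <- TRUE
    set
  }
  B <- array(FALSE, c(R, n, Nf))
  B[, 1, ] <- new_regime()
  if (n > 1) for (j in 2:n) {
    fresh <- new_regime()
    keep <- matrix(!Tf[, j - 1], R, Nf)  # recycle the keep flag per female
    prev <- B[, j - 1, ]
    B[, j, ] <- ifelse(keep, prev, fresh)
  }

  # the dyad: an ordered cohort pair, uniform over n^2
  c1 <- sample.int(n, R, TRUE)
  c2 <- sample.int(n, R, TRUE)
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  same <- c1 == c2

  cum_count <- function(Tmat) {
    cm <- matrix(0L, R, n)
    if (n > 1) for (j in 2:n) cm[, j] <- cm[, j - 1] + Tmat[, j - 1]
    cm
  }
  cmm <- cum_count(Tm); cmf <- cum_count(Tf)
  idx <- seq_len(R)
  any_tm <- (cmm[cbind(idx, hi)] - cmm[cbind(idx, lo)]) > 0
  any_tf <- (cmf[cbind(idx, hi)] - cmf[cbind(idx, lo)]) > 0

  # fathers: dominant with probability d, else uniform among the others
  father_of <- function(coh) {
    dom <- Dm[cbind(idx, coh)]
    alt <- sample.int(Nm - 1, R, TRUE)
    alt <- alt + (alt >= dom)
    ifelse(stats::runif(R) < d, dom, alt)
  }
  f1 <- father_of(c1)
  f2 <- father_of(c2)
  F0 <- f1 == f2

  # mothers: same cohort -> two distinct juveniles among the i*kappa born,
  # sharing a mother iff littermates; different cohorts -> each juvenile's
  # mother uniform among that cohort's breeders
  breeders_at <- function(coh) {
    out <- matrix(FALSE, R, Nf)
    for (f in seq_len(Nf)) out[, f] <- B[cbind(idx, coh, f)]
    out
  }
  B1 <- breeders_at(c1); B2 <- breeders_at(c2)
  i1 <- rowSums(B1)
  tot <- i1 * kap
  j1 <- pmin(floor(stats::runif(R) * tot) + 1, tot)
  j2 <- pmin(floor(stats::runif(R) * (tot - 1)) + 1, pmax(tot - 1, 1))
  j2 <- j2 + (j2 >= j1)
  M_same <- tot >= 2 & ceiling(j1 / kap) == ceiling(j2 / kap)
  pick_mother <- function(Bm) {
    U <- matrix(stats::runif(R * Nf), R, Nf)
    max.col(U - 1e9 * !Bm)
  }
  M_diff <- pick_mother(B1) == pick_mother(B2)
  M <- ifelse(same, M_same, M_diff)

  # pair-bond resampling (odds-tilt conditional) where no male turnover
  Fs <- F0
  if (eps > 0.5 && d < 1) {
    p0 <- d^2 + (Nm - 1) * ((1 - d) / (Nm - 1))^2  # enumeration over fathers
    odds <- (p0 / (1 - p0)) * if (eps == 1) Inf else eps / (1 - eps)
    pi_ <- if (is.infinite(odds)) 1 else odds / (1 + odds)
    q_copy <- (pi_ - p0) / (1 - p0)
    scen <- ifelse(same, 1L, ifelse(!any_tm & !any_tf, 2L,
                   ifelse(!any_tm & any_tf, 3L, 0L)))  # 0 = male turnover
    pm_hat <- vapply(1:3, function(s) {
      sel <- scen == s
      if (!any(sel)) NA_real_ else mean(M[sel])
    }, numeric(1))
    q_split <- 1 - (p0 - pi_ * pm_hat) / ((1 - pm_hat) * p0)
    q_split[!is.finite(q_split)] <- 0
    active <- scen > 0L
    u <- stats::runif(R)
    Fs <- ifelse(active & M, F0 | (u < q_copy),
                 ifelse(active & !M, F0 & !(u < q_split[pmax(scen, 1L)]), F0))
  }

  p_full <- mean(M & Fs); p_mat <- mean(M & !Fs); p_pat <- mean(!M & Fs)
  se <- function(p) sqrt(p * (1 - p) / R)
  list(p_full = p_full, p_mat = p_mat, p_pat = p_pat,
       p_non = 1 - p_full - p_mat - p_pat,
       se = c(p_full = se(p_full), p_mat = se(p_mat), p_pat = se(p_pat)))
}

# random in-range parameter draws for property tests
random_param_table <- function(n, seed, set = "main") {
  kincomp::sample_parameters(kincomp::fio_config(set, n_iterations = n,
                                                 seed = seed))
}
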