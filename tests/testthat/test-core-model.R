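test_that("dominant male share interpolates between equal shares and monopoly", {
  expect_equal(dominant_male_share(2, 0), 0.5)
  expect_equal(dominant_male_share(5, 1), 1)
  expect_equal(dominant_male_share(4, 0.5), 0.625) # 1/4 + 0.5 * 3/4
  alphas <- seq(0, 1, by = 0.05)
  d <- dominant_male_share(7, alphas)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 1 / 7 & d <= 1))
  expect_error(dominant_male_share(1, 0.5), "N_m")
})

test_that("same-regime father-sharing probability matches enumeration", {
  expect_equal(p_father_same_regime(10, 0), 0.1) # 0.01 + 0.81/9
  expect_equal(p_father_same_regime(3, 1), 1)
  expect_equal(p_father_same_regime(2, 0), 0.5) # 0.25 + 0.25/1
  # alpha = 0: all males equal, so sharing probability is exactly 1/N_m
  for (nm in 2:10) expect_equal(p_father_same_regime(nm, 0), 1 / nm,
                                tolerance = 1e-12)
  # enumeration oracle: sum over fathers of P(father)^2
  for (a in c(0.2, 0.7)) {
    d <- dominant_male_share(6, a)
    pvec <- c(d, rep((1 - d) / 5, 5))
    expect_equal(p_father_same_regime(6, a), sum(pvec^2), tolerance = 1e-12)
  }
})

test_that("within-cohort mother sharing averages littermate odds over breeders", {
  expect_equal(p_mother_within_cohort(3, 0.5, 2), 7 / 15, tolerance = 1e-12)
  expect_equal(p_mother_within_cohort(2, 1, 2), 1 / 3, tolerance = 1e-12)
  # monotocy: litters of one, no within-cohort maternal siblings at all
  expect_equal(p_mother_within_cohort(5, 1, 1), 0)
  expect_equal(p_mother_within_cohort(4, 0.3, 1), 0)
  expect_error(p_mother_within_cohort(3, 0, 2), "beta")
  # direct finite-sum oracle at small size
  nf <- 4; b <- 0.35; k <- 3
  manual <- sum(sapply(1:4, function(i)
    choose(3, i - 1) * b^(i - 1) * (1 - b)^(4 - i) * (k - 1) / (i * k - 1)))
  expect_equal(p_mother_within_cohort(nf, b, k), manual, tolerance = 1e-12)
})

test_that("between-cohort mother sharing is litter-size free", {
  expect_equal(p_mother_between_cohorts(10, 1), 0.1, tolerance = 1e-12)
  expect_equal(p_mother_between_cohorts(3, 0.5),
               0.25 * 1 + 0.5 * (1 / 2) + 0.25 * (1 / 3), tolerance = 1e-12)
  # only the dominant breeds as beta -> 0+
  expect_equal(p_mother_between_cohorts(4, 1e-12), 1, tolerance = 1e-9)
  expect_error(p_mother_between_cohorts(3, 0), "beta")
})

test_that("pair-bond conditional tilts the odds and respects limit cases", {
  expect_equal(p_father_given_mother(0.3, 0.5), 0.3)
  expect_equal(p_father_given_mother(0.1, 0.9), 0.5) # odds (1/9)*9 = 1
  expect_equal(p_father_given_mother(0.4, 1), 1)
  expect_equal(p_father_given_mother(0, 0.9), 0)
  expect_equal(p_father_given_mother(1, 0.7), 1)
  expect_equal(p_father_given_mother(0, 1), 0)
  eps_grid <- seq(0.5, 0.99, by = 0.01)
  out <- p_father_given_mother(0.2, eps_grid)
  expect_true(all(diff(out) > 0))
  expect_error(p_father_given_mother(0.3, 0.4), "eps")
})

test_that("scenario weights count dyads across cohorts and sum to one", {
  expect_equal(unname(scenario_weights(1, 0.3, 0.8)), c(1, 0, 0, 0, 0))
  expect_equal(unname(scenario_weights(4, 1, 1)), c(0.25, 0.75, 0, 0, 0))
  expect_equal(unname(scenario_weights(2, 0.5, 0.5)),
               c(0.5, 0.125, 0.125, 0.125, 0.125))
  set.seed(11)
  W <- scenario_weights(sample(1:6, 200, TRUE), runif(200), runif(200))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_true(all(W >= 0))
})

test_that("scenario profiles assemble the five dyad scenarios", {
  p <- kin_params(10, 10, 4, 0, 1, 1, 1, 0.5, eps = 1)
  prof <- scenario_profiles(p)
  expect_equal(prof$p_father[2], 0.1)
  expect_equal(prof$p_mother[2], 0.1, tolerance = 1e-12)
  expect_equal(prof$p_father_given_mother[2], 1)
  # male dominance change nullifies the pair bond (scenarios 4-5)
  expect_equal(prof$p_father_given_mother[4:5], prof$p_father[4:5])
  expect_equal(sum(prof$weight), 1, tolerance = 1e-12)

  # eps = 0.5: conditional equals baseline everywhere
  p2 <- kin_params(6, 4, 3, 0.3, 0.7, 2, 0.5, 0.5, eps = 0.5)
  prof2 <- scenario_profiles(p2)
  expect_equal(prof2$p_father_given_mother, prof2$p_father, tolerance = 1e-12)

  # full male monopoly: father shared with certainty in stable-regime scenarios
  prof3 <- scenario_profiles(kin_params(2, 5, 2, 1, 0.5, 2, 0.5, 0.5))
  expect_equal(prof3$p_father[1:3], rep(1, 3))
})

test_that("feasibility flags impossible pair-bond joint probabilities", {
  set.seed(21)
  draws <- random_param_table(300, seed = 21, set = "main")
  expect_true(all(is_feasible(draws))) # eps = 0.5 is always feasible
  # few females breeding (high P(Mother)) + many males (low P(Father)) + a
  # strong pair bond implies P(F|M) P(M) > P(F): infeasible
  bad <- kin_params(10, 10, 3, 0, 0.05, 2, 0.5, 0.5, eps = 0.99)
  expect_false(is_feasible(bad))
  expect_error(sibling_composition(bad, strict = TRUE), "infeasible")
  comp <- sibling_composition(bad)
  expect_false(comp$feasible)
  # full monopoly: P(Father) = 1 can never be exceeded
  expect_true(is_feasible(kin_params(2, 10, 3, 1, 0.05, 2, 0.5, 0.5, eps = 0.99)))
})

test_that("composition matches the closed-form pair-bond illustration", {
  base <- list(N_m = 10, N_f = 10, n = 4, alpha = 0, beta = 1, kappa = 1,
               tau_m = 1, tau_f = 0.5)
  random_mating <- do.call(kin_params, c(base, eps = 0.5))
  monogamy <- do.call(kin_params, c(base, eps = 1))
  expect_equal(sibling_composition(random_mating)$p_full, 0.0075,
               tolerance = 1e-12)
  expect_equal(sibling_composition(monogamy)$p_full, 0.075,
               tolerance = 1e-12)
  # with tau_m = 1 and beta = 1 the result is independent of tau_f
  alt <- do.call(kin_params, c(base[-8], tau_f = 0.1, eps = 1))
  expect_equal(sibling_composition(alt)$p_full, 0.075, tolerance = 1e-12)
})

test_that("a permanently monopolizing male makes every dyad paternal kin", {
  p <- kin_params(2, 4, 3, 1, 0.6, 2, 1, 0.4)
  comp <- sibling_composition(p)
  expect_equal(comp$p_full + comp$p_pat, 1, tolerance = 1e-12)
  expect_equal(comp$p_non, 0, tolerance = 1e-12)
  expect_equal(comp$p_kin, 1, tolerance = 1e-12)
})

test_that("parameter validation names the offending symbol and honours limits", {
  expect_error(kin_params(1, 5, 2, 0.5, 0.5, 2, 0.5, 0.5), "N_m")
  expect_error(kin_params(5, 5, 2, 0.5, 0.5, 2, 0.5, 0.5, eps = 0.3), "eps")
  expect_error(kin_params(5, 5, 2, 1.2, 0.5, 2, 0.5, 0.5), "alpha")
  expect_error(kin_params(12, 5, 2, 0.5, 0.5, 2, 0.5, 0.5), "N_m")
  expect_silent(kin_params(12, 5, 2, 0.5, 0.5, 2, 0.5, 0.5, relaxed = TRUE))
  expect_silent(kin_params(5, 5, 2, 1, 0.5, 2, 0.5, 0.5, eps = 1))
})
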