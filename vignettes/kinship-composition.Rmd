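---
title: "The kinship composition of mammal groups: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kinship composition of mammal groups: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincomp)
```

## The question

Mammal social groups differ enormously in how related groupmates are, and in
*what kinds* of relatives they contain. A group where most juveniles are
paternal half-siblings (one male monopolizing paternity) presents different
opportunities for kin-directed behaviour than a group with the same mean
relatedness made of full-sibling clusters (stable pair bonds) or maternal
half-sibling lines (a dominant female monopolizing reproduction). `kincomp`
implements a deterministic model of the **kinship composition** of the
juveniles born into one social group: the probabilities that a randomly
chosen dyad of juveniles are full siblings ($P_{full}$), maternal
half-siblings ($P_{mat}$), paternal half-siblings ($P_{pat}$) or non-siblings
($P_{non}$), plus the probability $P_{kin} = 1 - P_{non}^2$ that they share
at least one parent or grandparent.

## Parameters

Nine parameters describe the group (see `?kin_params`):

| symbol | meaning | default range |
|---|---|---|
| $N_m$, $N_f$ | adult males, adult females | integers 2–10 |
| $n$ | juvenile cohorts present simultaneously | integers 1–6 |
| $\alpha$ | male reproductive skew | $[0, 1)$, with 1 as limit case |
| $\beta$ | probability a subordinate female breeds | $(0, 1]$ |
| $\kappa$ | litter size | integers 1–6 |
| $\tau_m$, $\tau_f$ | per-cohort-step dominance retention | $[0, 1]$ |
| $\varepsilon$ | pair-bond stability | $[0.5, 1)$, with 1 as limit case |

Cohorts are discrete: seasonal or synchronized breeding. The upper bounds on
the count parameters delimit the region the sensitivity analysis explores;
`kin_params(..., relaxed = TRUE)` lifts them for larger groups. $\alpha = 1$
and $\varepsilon = 1$ are admitted although the sweep ranges are half-open,
because the monopoly and strict-fidelity limits are instructive (the
pair-bond illustration below uses $\varepsilon = 1$).

## Sharing a father

One male is dominant and sires a share
$d = 1/N_m + \alpha (N_m - 1)/N_m$
of a cohort; the other $N_m - 1$ males split the rest equally
(`dominant_male_share()`). Two juveniles conceived under the same dominant
share a father with probability
$p_0 = d^2 + (1 - d)^2 / (N_m - 1)$
(`p_father_same_regime()`): both sired by the dominant, or both by the same
subordinate. Between cohorts the dominant retains his position with
probability $\tau_m$ per step; after any turnover the new dominant is uniform
among all males, which makes the probability of sharing a father across the
turnover exactly $1/N_m$ regardless of $\alpha$.

## Sharing a mother

The dominant female always breeds; each of the $N_f - 1$ subordinates breeds
with probability $\beta$, so the number of breeders is
$i \sim 1 + \mathrm{Binomial}(N_f - 1, \beta)$. Every breeder produces a
litter of $\kappa$. Within a cohort two juveniles share a mother only if they
are littermates: conditional on $i$ breeders a juvenile has $\kappa - 1$
littermates among $i\kappa - 1$ other juveniles, and
`p_mother_within_cohort()` averages $(\kappa - 1)/(i\kappa - 1)$ over the
binomial weight of each $i$. Between cohorts with no female dominance
turnover the same females breed again, so the littermate ratio becomes simply
$1/i$ (`p_mother_between_cohorts()`), independent of litter size; after a
turnover the mother of a juvenile is uniform among the $N_f$ females, giving
$1/N_f$.

### The monotocy corner case

At $\kappa = 1$ and $i = 1$ the within-cohort ratio is formally $0/0$. The
package resolves it to **0**: under monotocy every litter is a single
offspring, so no within-cohort dyad can share a mother — indeed, a sole
monotocous breeder produces no within-cohort dyad at all. The alternative
continuity reading ($\lim_{\kappa \to 1}$ of the $i = 1$ term, i.e. 1) makes
within-cohort maternal sibship jump to near-certainty precisely where it is
physically impossible, and visibly distorts the monotocy-conditional
summaries of the sensitivity sweep. With the 0 convention,
$P(\text{Mother within cohort}) \equiv 0$ whenever $\kappa = 1$.

## Pair-bond stability

Sharing a mother raises the odds of sharing a father when females re-mate
with the same male across seasons (not necessarily monogamously). The model
multiplies the baseline odds $O(F) = p_0/(1 - p_0)$ by
$O(\varepsilon) = \varepsilon/(1 - \varepsilon)$:

$$P(F \mid M) = \frac{O(F)\,O(\varepsilon)}{1 + O(F)\,O(\varepsilon)}.$$

$\varepsilon = 0.5$ leaves the odds untouched (independence);
$\varepsilon = 1$ forces all maternal siblings to be full siblings. Boundary
baselines $p_0 \in \{0, 1\}$ map to themselves for every $\varepsilon$. The
marginal $P(F)$ is held fixed, so $P(F \mid \neg M)$ follows from total
probability: $P(F \mid \neg M) = (P(F) - P(F \mid M) P(M)) / (1 - P(M))$.
A male dominance turnover is assumed disruptive enough to dissolve any pair
bond, so scenarios involving one use $P(F \mid M) = P(F)$.

### Feasibility

A strong pair bond in a group where sharing a mother is common but sharing a
father is rare can demand the impossible,
$P(F \mid M) P(M) > P(F)$. `is_feasible()` checks this in each of the three
scenarios where the bond is active; `sibling_composition(strict = TRUE)`
raises on violation, while the sweep engine flags and excludes such draws
(the flag is kept in the output table and the exclusion fraction is always
reported).

## Five dyad scenarios and their weights

A dyad drawn from $n$ cohorts falls into one of five scenarios: same cohort;
different cohorts with no dominance change, a female change only, a male
change only, or both. Weighting by dyad counts over ordered cohort pairs
(equal cohort sizes), the same-cohort mass is $n/n^2 = 1/n$ and the
lag-$i$ mass is $2(n - i)/n^2$; retention across lag $i$ has probability
$\tau^i$, so e.g. the no-change scenario weighs
$\sum_{i=1}^{n-1} \frac{2(n-i)}{n^2} \tau_m^i \tau_f^i$. The five weights sum
to 1 by construction (`scenario_weights()`). The $1/n$ within-cohort weight
treats cohorts as large relative to 1 (dyad counting at equal cohort sizes);
it is the unique normalization consistent with the model's own illustrative
closed-form values, and at very small realized cohort sizes it is an
idealization. `sibling_composition()` assembles, per scenario,
$P_{full} = P(F|M)P(M)$, $P_{mat} = (1 - P(F|M))P(M)$,
$P_{pat} = P(F|\neg M)(1 - P(M))$, averages them over the scenario weights,
and sets $P_{non}$ as the remainder (the four categories sum to 1 to
$10^{-12}$, asserted).

```{r fig1d}
base <- data.frame(N_m = 10, N_f = 10, n = 4, alpha = 0, beta = 1,
                   kappa = 1, tau_m = 1, tau_f = 1)
sibling_composition(transform(base, eps = 0.5))$p_full  # 0.0075
sibling_composition(transform(base, eps = 1))$p_full    # 0.075
```

A monotocous ten-male, ten-female group with no skew produces ten times more
full siblings under strict pair bonds than under random mating — with mean
relatedness essentially unchanged, since each full-sib dyad created costs two
half-sib dyads.

## Relatedness summary

`summarize_relatedness()` maps a composition to the mean and SD of the dyad
coefficient of relatedness under the **sibling-dyad approximation**: $r$ is
0.5 for full siblings, 0.25 for either half-sibling class, 0 for
non-siblings. This is a lower bound on full-pedigree relatedness because
grandparent-mediated paths between non-sibling dyads are ignored; the
`grandparent_r` argument is an additive hook for such a contribution and
defaults to 0. Every output row carries `approximation = "sibling-dyad"` to
keep the label attached to the number. Groups are classified `"related"`
when more than 95% of dyads are kin ($P_{kin} > 0.95$), else
`"mix-related"`; kin share at least a grandparent and so are related by at
least $r = 0.0625$.

## The FIO sensitivity sweep

The model is deterministic but opaque: nine interacting parameters. The
"fitting to idealised outcomes" (FIO) engine (`run_fio()`) evaluates the
composition over $10^5$ independently drawn parameter sets and correlates
parameters with outcomes by Spearman's rank correlation
(`correlation_table()`), because the relationships are monotonic but rarely
linear. Draws are independent uniforms — integers uniform on their integer
ranges, reals uniform on their intervals — the minimal-assumption reading of
"randomly set within ranges", and the one under which the test suite verifies
the expected sensitivities. Two sets are defined:

* **main**: all parameters over their full ranges, $\varepsilon$ fixed at
  0.5, so every draw is feasible;
* **pairbond**: $\varepsilon$ uniform on $[0.5, 1)$, with $N_f$ restricted to
  5–10 and $\beta$ to $[0.5, 1]$ to keep infeasible combinations rare (the
  remaining ~2% are flagged and excluded listwise from all statistics).

`threshold_summaries()` reports the conditional fractions and parameter-space
bins the analysis turns on (cutoffs 20% full siblings, $\alpha > 0.75$,
$\beta < 0.25$, $\tau > 0.75$, sex ratio $N_m/(N_m{+}N_f)$ above 0.7 / below
0.3); `outcome_histograms()` exports per-parameter histograms of the draws
exceeding an outcome threshold (10 equal bins for reals, one per value for
integers), which is how non-linear but monotone responses are inspected.

With a seed, sweeps are bit-reproducible; the CSV writer
(`write_fio_csv()`) stores doubles at full round-trip precision so
correlation tables computed from a re-read file are identical.

## What the tests do and do not show

The suite verifies, at fixed seeds: the closed-form worked examples
(within-cohort mother-sharing $7/15 \approx 0.47$ for $N_f = 3$,
$\beta = 0.5$, $\kappa = 2$; the pair-bond illustration 0.75% vs 7.5% above)
to $10^{-12}$; composition normalization over $10^4$ random draws; the
$\varepsilon = 0.5$ independence identity exactly; and the sweep
sensitivities at $10^5$ draws (e.g. $\alpha$ vs % siblings $\approx 0.50$,
$\alpha$ vs % paternal sibs $\approx 0.59$, $\beta$ vs % maternal sibs
$\approx -0.46$, monotocy/polytocy conditionals $\approx 3.9\%$ vs
$21.2\%$, pairbond exclusions $\approx 2\%$).

The closed form is additionally cross-checked against an **independent
generative simulator** (a test helper): it assigns dominance chains,
breeding-female sets, litters and fathers mechanistically for $10^5$
simulated dyads and must agree with the closed form within 3 Monte-Carlo
standard errors on small groups ($N_m, N_f \le 4$, $n \le 3$,
$\kappa \le 2$). The pair-bond coupling in the simulator resamples fathers
using the odds-tilt conditional with the scenario-level $P(M)$ estimated
empirically from its own draws, so the closed-form mother-sharing equations
never enter the oracle. Problem sizes ($10^4$–$10^5$ draws; $10^5$ oracle
replicates) were chosen to make Monte-Carlo error small against the effect
sizes being checked.

Passing tests show the implementation computes *this idealized model*
correctly; they do not show the model describes any particular species. The
model ignores dispersal, extra-group paternity, overlapping adult
generations, juveniles-per-adult ratios, multiple-paternity litters beyond
the $\varepsilon$ coupling, and kin beyond siblings and shared grandparents;
cohorts are discrete and equal-sized in expectation.

## Numerical choices

* All probability arithmetic is in double precision; composition rows are
  defined with $P_{non}$ as the remainder, so sums are exact to rounding.
* Feasibility comparisons use a $10^{-12}$ slack so the exact boundary
  (e.g. the $\varepsilon = 1$ illustration, where $P(F|M)P(M) = P(F)$) is
  feasible.
* `runif()` never returns its endpoints, which realizes the half-open
  $\alpha$ and $\beta$ ranges without further handling.
* A parameter held constant in a sweep has no defined rank correlation and
  is reported `NA`, never 0.
* Ties in Spearman correlations take midranks (`stats::cor`).
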