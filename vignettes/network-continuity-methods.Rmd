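---
title: "Referral-network structure and patient outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Referral-network structure and patient outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenets)
```

## The problem

Mental-health care for people with severe mental illness is delivered by
*networks* of services — primary care, community mental-health teams,
crisis/outreach teams, rehabilitation teams, social services, psychiatric
wards, sheltered housing, nursing homes — and a long-standing question in
health-services research is which network *structure* best supports
patient-level outcomes. Two outcomes are of particular interest: experienced
**continuity of care** (measured with the 31-item ACSS-MH, total 31–155) and
objective **social integration** (the SIX index, 0–6, summing employment
0–2, accommodation 0–2, family contact 0–1 and friendship 0–1).

`carenets` implements that analysis as a reusable pipeline: tie-survey
ingestion, network construction, a network-metric suite, patient scoring,
and random-intercept regressions linking network exposures to outcomes. The
original survey data behind this class of study are typically not
deposited, so the package ships a synthetic-study generator that reproduces
the *statistical structure* of such a study — 19 networks of 11–115
services, ordinal tie reports, 8 recruitment services × 10 patients per
network — and every stage is validated against planted truth.

## Network construction

Each participating service rates the frequency of contact (never /
sometimes / often, coded 0/1/2) with every other member of its network,
separately for referrals sent, referrals received, patient-related
information exchange, and organizational activity. The clinical-contact
network dichotomizes the ordinal ratings: under the main rule a tie is
present when rated *sometimes or often*; the sensitivity variant counts
*often* only. Organizational ties are excluded.

Three conventions are not fixed by the survey design, and we made them
explicit, documented choices:

* **Dyad merge.** The three clinical relation kinds are merged by logical
  OR after thresholding: any clinical contact is a tie. Per-kind networks
  are available through the `relations` argument of `build_network()`.
* **Direction.** A referral *received* reported by j about i is reversed to
  the directed edge i → j, mirroring a referral sent. Information exchange
  is directed reporter → alter; because the survey is one-mode (each
  service rates its own contacts) we do not symmetrize it by default
  (`symmetrize_info = FALSE`).
* **Scope.** The main analysis keeps participating services only. The
  full-matrix sensitivity variant keeps non-responders as nodes, with their
  incident edges taken from participants' reports — the only information
  available about them, and exactly what that sensitivity analysis is meant
  to probe.

These rules give two invariants the tests exercise on every simulated
study: the often-only edge set is a subset of the main edge set, and the
participants-only node set is a subset of the full-matrix node set with an
identical participant block.

## Network-level exposures

All metrics are computed directly on the binary adjacency matrix and kept
as fractions internally; percent scaling is a rendering concern.

* **Density**: ties present / `n(n-1)`.
* **Freeman degree centralization**: `sum(d_max - d_i) / (n-1)^2`, on
  in-degree by default (being nominated is the centrality signal in a
  referral network); 0 for any in-regular network, 1 for an inward star.
  Out- and total-degree variants are exposed but non-default.
* **Clustering**: the local density of ties among each service's
  neighbours, on the undirected projection (the verbal definition of
  "density of connections around a service" does not use direction);
  services with fewer than two neighbours contribute 0, and the network
  value is the mean over all services. 1 on a complete network, 0 on a
  star.
* **Reciprocity**: share of directed ties whose reverse exists.
* **Composition** and the **index of dissimilarity**: half the L1 distance
  between a network's service-type mix and a reference mix. The reference
  is the *unweighted mean composition across networks* (each network counts
  once); a pooled-services reference can be passed explicitly.
* **Coleman homophily index** per service type (primary care,
  crisis/outreach, social services merged with rehabilitation, psychiatric
  wards by default): with `w` the share of the type's out-ties landing on
  same-type alters and `e = (n_g - 1)/(n - 1)` its random-mixing
  expectation, the index is `(w - e)/(1 - e)` above `e` and `(w - e)/e`
  below. +1 means all referrals stay within type, −1 none do, 0 random
  mixing. A type with no out-ties gives a *missing* value, not zero, and a
  type comprising the whole network is undefined (`e = 1`).

Two numerical points worth knowing. First, because the two branches of the
Coleman normalization scale deviations differently, the Monte-Carlo mean of
the index under uniformly random ties is exactly zero only when `e = 1/2`
(conditional on the out-tie count, present ties are exchangeable over
possible targets, so `E[w] = e`); away from `e = 1/2` there is a small
finite-size bias toward the more compressed side. The null-calibration test
therefore uses a 21-node network with an 11-member group. Second, the mean
*normalized in-degree* (mean in-degree / (n−1)) is reported as its own
descriptive row for compatibility with published tables even though it
coincides with density on a binary directed network; descriptive tables in
the literature print it on an unstated scale, and we make the definition
explicit rather than chase that scale.

## Patient outcomes

ACSS-MH totals are the plain sum of the 31 items (1–5 each). The
instrument's item→subscale map is licensed and not public in our sources,
so the shipped map (`default_subscale_map()`, also as
`inst/extdata/acss_subscales.yaml`) is a clearly marked stand-in partition
— items 1–12 / 13–22 / 23–31 plus a "relational base" subset — and nothing
in the package's validation depends on its exact membership beyond
partition consistency. No item is reverse-scored by default; the map is
fully configurable. SIX components follow the 2/2/1/1 caps with total 0–6.
HoNOS (0–48) is validated and used as a case-mix control. Patients with
any missing outcome item or covariate are excluded listwise, with
exclusion counts reported.

## Outcome models

The clustered design (patients within 19 networks) is handled with
network-level random intercepts throughout — the intra-class correlation
rows these studies report imply exactly that structure.

**Continuity (linear mixed model).** `fit_continuity()` fits, by REML,

```
z(outcome) ~ z(metric) + age + sex + HoNOS + recruitment type + (1 | network)
```

The outcome is z-scored over the analysis set; the network covariate is
z-scored over the *distinct network values* (each network counts once,
matching how the descriptive tables summarize exposures), so the reported
coefficient is a standardized beta. Patient controls stay on their natural
scales. Fixed-effect p-values are Wald t tests with Satterthwaite
denominator degrees of freedom (the `lmerTest` default): with only 19
clusters the normal approximation is anti-conservative for network-level
covariates, and the package's own type-I calibration (see below) presumes
a calibrated test. ICC is `s2_network / (s2_network + s2_residual)`; its
p-value is a likelihood-ratio test of the variance component against the
50:50 mixture of a point mass and a 1-df chi-square (the boundary-corrected
reference). AIC comes from the ML refit so that fixed-effect comparisons
are meaningful.

**Model 2 (stepwise).** `fit_continuity_stepwise()` screens each candidate
metric bivariately, keeps those with p < 0.05, then selects forward with
entry p < 0.05 and removal at p ≥ 0.05, ties broken by smaller screening
p then alphabetically; controls are always retained. "Stepwise" is
underdetermined in the literature this mirrors; these fixed thresholds are
our definition. With no significant candidate a controls-only model is
returned with a warning.

**Social integration (ordinal mixed model).** The SIX total is an ordered
0–6 score, and published analyses of it report a *single* odds ratio per
covariate — which a general multinomial model would not produce. We
therefore fit a random-intercept proportional-odds model,
`P(Y <= k) = logit^{-1}(zeta_k - x'beta - u)`, `u ~ N(0, s2)`:
the parallel-lines structure is what yields one odds ratio per covariate,
`exp(beta)`, for higher social integration. A plain per-category
multinomial fit (no random effects) remains available behind
`multinomial = TRUE` for comparison. No installed package fits this mixed
ordinal model, so `polr_mixed()` implements it directly: maximum
likelihood with 15-node Gauss–Hermite quadrature over the random
intercept, analytic gradients, ordered thresholds via a log-difference
parameterization, starting values from `MASS::polr`, and standard errors
from the numerically differentiated Hessian at the optimum. The sigma = 0
special case collapses exactly to proportional odds and matches
`MASS::polr` to 4+ decimals in the tests; that nested fit also provides
the ICC likelihood-ratio test. The latent-scale ICC uses the logistic
residual variance `pi^2/3`.

## The synthetic generator

`sim_config()` fixes the study conditions; `generate_study()` draws a full
survey. The tie model is a typed inhomogeneous random digraph: each
observable ordered pair carries a tie with probability
`baseline × within_type_mult^[same type] × hub_boost^[alter is hub]`
(capped at 1), rated often with probability `p_often`. This gives direct,
independent dials for density (baseline), homophily (within-type
multiplier; < 1 plants the mild heterophily such networks show) and
centralization (hub boost), each verified monotone in the tests. Ties are
emitted in survey form — sender reports (referral sent / information
exchange), receiver reports (referral received, the only channel for ties
from non-responders), plus organizational records that the builder must
ignore — so the generator exercises the same parsing and reversal paths as
real data.

Defaults emulate the published descriptive statistics of a 19-network
national study and were fixed once, up front: sizes lognormal within
11–115 (mean ≈ 52), the published nine-type mix, participation 0.52, tie
baseline 0.53 with within-type multiplier 0.5 and hub boost 1.8 (density
≈ 0.49, mildly negative Coleman indices, centralization ≈ 0.2–0.3),
continuity intercept 115.6 with residual SD 13.9 and network-intercept SD
2.5 (network variance share ≈ 3%), SIX latent thresholds tuned once so the
null mean is 3.1 with a network-intercept SD of 0.6 (latent ICC ≈ 10%).

Patient outcomes follow the models the analysis assumes. The continuity
latent is `intercept + sigma_tot * sum(beta_k z_k) + covariate terms +
network intercept + Gaussian residual`, with `sigma_tot =
sqrt(ri_sd^2 + resid_sd^2)`, so planted `effects` are standardized betas on
the same scale the models report; the latent total is spread over the 31
items with bounded rounding (items differ by at most one and sum exactly
to the rounded total). The SIX total is drawn directly from the
ordered-threshold logistic latent — planted `effects` are latent log-odds,
i.e. log odds ratios — and then allocated at random to the four components
within their caps. Drawing the total (rather than four separate component
latents) keeps the generator exactly congruent with the proportional-odds
analysis model, which is what makes planted odds ratios and latent ICCs
recoverable benchmarks rather than approximations.

What the generator does *not* emulate: real item-level response styles
(items are near-constant within patient; only totals carry signal), tie
non-response beyond the participation flag, topology beyond the
density/homophily/centralization dials (no community structure or
degree-sequence matching), and patient dropout. Passing tests therefore
demonstrate that the pipeline recovers what it assumes, on data satisfying
its assumptions — not that those assumptions hold in any particular real
network.

## Calibration results the tests compute

With effects planted at the study's own design size (19 networks × 80
patients), the test suite verifies: a standardized continuity effect of
0.15 is recovered with absolute bias below 0.05 over 100 replicates (the
small expected attenuation — a factor `sd_net/sd_realized` from covariate
variance inflation, about 2–3% — is well inside that band); a planted
latent odds ratio of 2.0 is recovered within ±0.2 over 100 replicates; the
bivariate continuity test holds its 5% level within [0.02, 0.09] over 200
null replicates; and the Coleman index averages within ±0.02 of zero over
2000 uniform random networks at `e = 1/2`. Smaller configurations (4–8
networks, 2 clusters × 4–10 patients) are used for structural and
round-trip tests; these sizes are the package's own choice of test design,
balancing Monte-Carlo error against suite runtime.

## Known limitations

* The ACSS subscale map is a stand-in; subscale-level conclusions require
  the licensed instrument's map.
* Wald-type inference with 19 clusters remains approximate even with
  Satterthwaite df; the package deliberately stops short of small-sample
  corrections such as Kenward–Roger.
* The proportional-odds assumption for SIX is adopted, not tested; the
  multinomial flag exists precisely to probe it.
* Stepwise selection inherits all the usual caveats of post-selection
  inference; the screened bivariate fits are returned alongside the final
  model so users can see the full path.
* Metrics on very small networks (n < 3) are undefined and reported as
  errors or missing values rather than extrapolated.
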