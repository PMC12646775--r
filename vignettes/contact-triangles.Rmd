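---
title: "Modelling first- and second-order contact network structure from egocentric surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first- and second-order contact network structure from egocentric surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egotriad)
```

## The scientific problem

Egocentric contact diaries measure *first-order* network structure well:
each participant reports the people (or groups of people) they met
face-to-face the previous day, and the sum of the reported group sizes is
their daily degree. *Second-order* structure — whether a person's contacts
also contact each other, i.e. local clustering or transitivity — shapes
epidemic speed and final size but is much harder to measure without
enumerating the whole network.

`egotriad` implements an intermediate design. For each participant, two
reported contact events are selected at random (the *primary contacts*);
the participant is then asked, for every other reported event (the
*secondary contact*), whether the primary and secondary interacted during
the previous week, answering on a four-level certainty scale ("yes",
"probably yes", "probably no", "no"). Each (participant, primary,
secondary) triple is a *potential contact triangle*, and the affirmative
share of these triangles is a relative measure of local clustering.

## Two hierarchical models

### Daily contact counts

The number of contacts $y_{iv}$ reported by participant $i$ at visit $v$
is modelled as an overdispersed Poisson count:

$$y_{iv} \sim \mathrm{Poisson}(\lambda_{iv}), \qquad
\log \lambda_{iv} = x_{iv}'\beta + \gamma_v + u_{\ell(i)} + u_{h(i)} +
u_i + e_{iv},$$

with independent normal random effects at the location
($\sigma_\mathrm{loc}$), household ($\sigma_\mathrm{hh}$), participant
($\sigma_\mathrm{part}$) and observation ($\sigma_\mathrm{obs}$) levels.
The observation-level deviate makes this a lognormal-Poisson model: its
variance absorbs the overdispersion that motivates quasi-Poisson fitting,
while remaining a fully generative likelihood whose pointwise values feed
WAIC. Covariates are participant age group (2–15, then 10-year bands to
76+; reference 36–45), sex (reference male), occupation class (employed /
student / other; reference employed), log household size, and
$\log_{10}$ population density. The outcome is either all reported
contacts or the extra-household subset (all settings except the home;
transport and shopping are extra-household).

### Triangle connectedness and the any-of-m likelihood

Because contacts can be reported as groups, one potential triangle whose
events have group sizes $g_1$ and $g_2$ stands for $m = g_1 g_2$
*underlying* person-level triangles (two groups of 10 imply 100). A
participant asked about such a pair can only report whether *any* member
of one group interacted with *any* member of the other. The model
therefore treats each underlying triangle as connected independently with
probability $p$, giving the observation likelihood

$$P(\text{reported connected}) = 1 - (1 - p)^m, \qquad
P(\text{reported not connected}) = (1 - p)^m,$$

with $\operatorname{logit} p = x'\beta + \gamma_v + u_\mathrm{loc} +
u_\mathrm{hh} + u_\mathrm{part}$. This "any-of-m" construction — the same
aggregation that appears in group-testing likelihoods — is the core of
the package. It is evaluated through `log1p`/`expm1` so that it stays
finite and accurate for $m$ up to $10^4$ and $p$ within $10^{-12}$ of
either boundary ($p$ is clamped to $[10^{-12}, 1-10^{-12}]$; both
behaviours are unit-tested). At $m = 1$ it reduces exactly to the
Bernoulli-logistic likelihood, which the test suite exploits by checking
the whole fitting path against an independent hierarchical logistic fit
(`lme4::glmer`) on data with all group sizes 1.

Three nested specifications are fitted (`triangle_spec_terms()`):

* **participant_only** — participant and household covariates plus visit;
* **individual_contact** — adds the attributes of the two contact events.
  Categorical attributes (setting, frequency, duration, touch) enter
  symmetrically as the count (0–2) of the pair's events at each
  non-reference level, so the coefficient is an effect per contact and
  does not depend on which event happened to be the primary. Group
  structure is captured by a pair-level any-group indicator and
  $\log m$ — the attributes named for this purpose in the study design;
  the scale of the $m$ covariate is not prescribed there, and the
  continuous log form is this package's choice;
* **shared_contact** — adds indicators for shared attributes of the pair:
  same setting, same frequency category, same duration category, both
  involving touch. The exact shared-attribute list used in the original
  analyses is not published in full; this set covers the attributes the
  main text discusses and is fixed by the design builder.

Observations in the top 0.5% of $m$ are trimmed before fitting
(`trim_by_underlying_count()`): a handful of enormous group pairs would
otherwise dominate the likelihood. The threshold is the empirical type-7
quantile of $m$; ties at the threshold are retained, which makes trimming
deterministic and idempotent. The threshold is computed on the pooled
table by default (whether the original analysis pooled or stratified by
visit is not stated; `per_visit = TRUE` gives the alternative).

### Certainty dichotomisation

The main analysis counts "yes" and "probably yes" as affirmative
(`cutoff = "probably-yes"`). The stricter `"yes-only"` and more lenient
`"probably-no"` cutoffs reproduce the sensitivity analyses;
`dichotomize_certainty()` is monotone in cutoff leniency by construction.

## Priors, sampling and diagnostics

The study protocol specifies the MCMC budget (four chains of 2000
iterations, half warm-up) but not priors. The package uses weakly
informative defaults: Normal(0, 5) on the intercept, Normal(0, 2.5) on
all other fixed effects, and half-Normal(0, 1) on every random-effect SD.
These are wide relative to the plausible effect sizes (rate and odds
ratios between roughly 1/20 and 20) and sit well above the realised SDs,
so they regularise without informing.

Sampling is done by an in-package compiled sampler (`src/sampler.cpp`)
rather than an external probabilistic-programming engine, which keeps the
any-of-m likelihood, its gradient and the fitting loop in one place:

* the fixed-effect block is updated by Hamiltonian (leapfrog) proposals
  with a diagonal mass matrix estimated from the warm-up draws and a step
  size adapted towards 80% acceptance (a short component-wise random-walk
  stretch opens the warm-up to seed the adaptation);
* random effects are updated one unit at a time with adaptive random
  walks — each unit touches only its own observations, so a full sweep is
  linear in the data;
* each random-effect SD gets three moves per iteration: a centred
  Metropolis update given the effects, a non-centred *interweaving* move
  that rescales the whole effect vector (keeping $u/\sigma$ fixed), and a
  recentering move that shifts the intercept against the effect vector
  without changing the likelihood. The interweaving and recentering pair
  substitutes for the non-centred parameterisation a Stan implementation
  would use: it keeps the scales mobile when $\sigma$ is near zero and
  frees the intercept from the random-effect means.

All randomness flows from one integer seed; chains use derived sub-seeds,
so any fit is draw-for-draw reproducible. Convergence is summarised by
rank-normalised split R-hat and bulk/tail effective sample sizes (the
modern forms of the Gelman–Rubin statistic the protocol cites, chosen so
reported numbers are exactly reproducible), with the reporting threshold
of 200 on both ESS flavours. `waic()` computes
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{WAIC})$ from the pointwise
log-likelihood draws with log-sum-exp stabilisation, and
`compare_models()` ranks specifications with ties broken by name.

Point estimates throughout are posterior means; intervals are central 95%
credible intervals; `relative_rates()` and `odds_ratios()` exponentiate
the coefficient draws before summarising.

## The synthetic-data generator

Real survey data cannot be redistributed with the package, so
`simulate_survey()` generates surveys whose statistical structure matches
what the models assume, with every generating parameter recorded as
recoverable ground truth. Defaults emulate the originating study's
design: 40 communities along a population-density transect (a four-order-
of-magnitude geometric gradient, 100–20,000 people/km², with small
household-level jitter), 20 households per community, all members aged
2+ enrolled, and visits 2–5 analysed with visit 2 as reference. Ages span
2–90 with occupation conditional on age; contact totals follow the count
model above; totals are split into events by a zero-truncated negative
binomial (mean 2.7, dispersion 0.35 — heavy-tailed, so that a large
share of contacts sit in big groups without copying any empirical
distribution); event attributes are drawn conditional on occupation
class; and triangle responses follow the any-of-m model, with 10% of
latent reports softened to the neighbouring "probably" category so the
certainty-cutoff sensitivity machinery has something to act on.

Default generating coefficients are set to values of the magnitude
reported for contact surveys in dense Asian settings — about a dozen
daily contacts at the reference covariates, contact rates declining to a
0.60 relative rate in the oldest group, a U-shaped age pattern in
clustering with a baseline per-underlying-triangle probability of 0.15,
odds falling 0.57-fold per 10-fold density increase, strongly reduced
odds for group contacts and a large same-setting effect. These are
realistic operating points for recovery tests, not reproductions: the
real-data coefficient estimates cannot be recomputed without the deposited
data.

What the generator deliberately does **not** emulate: spatial structure
beyond the monotone transect, ageing and panel attrition across visits,
joint setting-by-intimacy dependence beyond occupation conditioning, and
reporting biases such as recall decay with group size. Passing recovery
tests therefore demonstrate that the estimators are correct for the
declared data-generating process, not that real surveys satisfy it.

## Numerical and design choices

* Population density enters as $\log_{10}(\text{density}) - 3$, i.e.
  centred at 1000 people/km². A fixed centring constant (rather than the
  sample mean) makes coefficients comparable across subsets and
  replications; effects are reported per 10-fold increase either way.
* Household size enters as $\log(\text{size})$; the banded alternative
  used in descriptive figures is available in the reporting layer.
* A participant-visit's repeat-flagged events re-list people already
  counted: they contribute zero to contact totals and are excluded from
  triangle enumeration (the dyad already exists through the original
  event).
* The pair of the two primaries can be elicited from either side; the
  enumerator collapses duplicate elicitations of an unordered pair onto
  the lower event id, counting the pair connected if any elicitation was
  affirmative. With $E$ events and two primaries this yields exactly
  $2(E-2)+1$ potential triangles.
* Complete-case analysis: rows with unknown age group, sex or occupation
  (and, for contact-level specifications, unknown event attributes) are
  dropped at design construction, with a reported count.
* Quantiles use R's default type-7 order statistic everywhere, for
  bit-reproducibility.
* Degenerate diagnostics inputs are reported by convention: all-constant
  chains give R-hat 1 and ESS equal to the chain count, both flagged.

## Problem sizes used in the tests

The test suite exercises full fits at reduced, fixed scales chosen so the
whole suite runs in minutes on one CPU: the parameter-recovery benchmark
uses about 800 participants over two visits (~1600 participant-visit
counts and ~16,000 potential triangles) with 2 chains of 1000–1200
iterations, 20 independent replicates per model; WAIC comparisons use 10
replicates of ~2000 triangles with all three specifications; the
reduction oracle compares roughly 5000 all-singleton triangles against
`lme4::glmer`. Production analyses should use the protocol preset
(`mcmc_config()`: 4 × 2000, 1000 warm-up) and check
`check_convergence()`.

## Known limitations

* The sampler is tailored to these two models; it does not generalise to
  arbitrary likelihoods, and very small random-effect SDs mix more slowly
  than gradient-based samplers on the non-centred scale would.
* WAIC is the only comparison criterion implemented (as in the study
  protocol); no cross-validation.
* The 4-level certainty response is always dichotomised; an ordinal model
  is out of scope.
* Group contacts carry no member-level information, so contact-age
  analyses exclude multi-age group events, and the group-size and setting
  effects on clustering cannot be fully disentangled — a limitation of
  the design itself, not of the implementation.
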