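---
title: "Methods: raising estimators, hurdle CPUE models and the synthetic fishery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raising estimators, hurdle CPUE models and the synthetic fishery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palinurid)
```

This vignette is the package's own account of its statistical content:
the models and their assumptions, the tunable parameters and defaults,
what the synthetic generator does and does not emulate, the numerical
choices, and the design decisions taken where the design was genuinely
open.

## The raising estimator

Monthly landings are estimated from beach surveys as
$L = E \times C$ with effort $E = D \times B \times F$, where $D$ is
days in the month, $B$ the boat activity coefficient, $F$ the fleet
size and $C$ the mean sampled CPUE (kg boat-day⁻¹).

Per survey, $B = A / T$: the total boat count $T$ (at sea, from drag
marks, plus inactive boats on the beach) multiplied by the proportion of
*sampled* returning boats that were lobster fishing gives the estimated
active boats $A$, which is kept fractional. Assumptions worth making
explicit:

* **Main-site rule.** The monthly $B$ averages Main-site surveys only;
  the Lodge fleet (typically under 10 boats) is too small and erratic to
  represent fleet-wide activity. A property test poisons Lodge surveys
  and checks the monthly BAC is unchanged.
* **Representativeness.** Applying an at-sea sample's activity ratio to
  at-sea *and inactive* boats assumes beached boats would have split
  between activities the same way. When a fleet has genuinely idle boats
  this overestimates activity; see the generator notes below.
* **True zeros.** Boats that fished and landed nothing count toward the
  CPUE denominator. Zeros here are real outcomes of fishing, not missing
  data.
* **Unrounded chains.** The identities $E = DBF$, $L = EC$, $V = LP$
  hold to machine precision internally. `monthly_report()` rounds for
  display ($B$, $C$ to 2 dp; $F$, $E$, $L$, $V$ to integers), which is
  why a published-style row need not satisfy the identities exactly —
  e.g. a July row computed from rounded $B = 0.80$, $F = 82$, $D = 31$
  gives $E = 2033.6$, not the printed 1,926, and a season column can sum
  to 11,988 while the independently rounded total prints 11,990.
* **Imputation is explicit.** An unsurveyed month is only ever filled by
  `impute_month(estimates, target, donors)` — the mean of named donor
  months — never automatically.
* **Sample adequacy.** The survey protocol's "90% accuracy" rule is not
  spelled out in detail anywhere we can reproduce; `sample_adequacy()`
  adopts the finite-population-corrected relative standard error
  convention, $1 - \frac{s/\sqrt{n}}{\bar x}\sqrt{\frac{N-n}{N-1}}$,
  with a configurable threshold (default 0.90). This is a documented
  convention choice, not a citation.

`percent_change()` implements both conventions seen in season summaries:
`"increase"` ($100(v - \bar r)/\bar r$; equality gives 0%) and `"ratio"`
($100 v/\bar r$; equality gives 100%), because headline fishery
statistics mix the two.

## Hurdle (zero-altered) CPUE models

Per-boat lobster counts $y$ are modelled in two parts:

* a **hurdle part**: $\Pr(y > 0) = \pi = \mathrm{logit}^{-1}(x'\beta_z)$;
* a **count part**: $y \mid y > 0$ follows a zero-truncated Poisson
  (ZAP) or NB2 negative binomial (ZANB), mean $\mu = \exp(x'\beta_c)$,
  NB2 variance $\mu + \mu^2/\theta$.

Covariates are NTZ status (binary), pots per boat (untransformed,
numeric) and their interaction; the intercept is mandatory and
marginality is enforced. This structure treats zeros as informative
outcomes ("true" zeros) rather than contamination, which is why hurdle
models are preferred to zero-inflated mixtures here.

The joint log-likelihood factorises into the two parts, so
`fit_hurdle()` maximises them separately (the estimates are identical to
a joint maximisation; a test checks the combined maximum against
`hurdle_loglik()` directly). Numerical choices:

* everything is evaluated in log space; $\log \Pr(y = 0)$ of the NB is
  $-\theta \log(1 + \mu/\theta)$ and $\log(1 - e^{x})$ uses the stable
  two-branch form;
* $\theta$ is estimated as $\log\theta$ for positivity, with three
  starts ($\log\theta = 0, 6, 12$) and a clamp at $\log\theta = 30$,
  beyond which the NB is numerically Poisson. On equidispersed data the
  ZANB likelihood supremum ($\theta \to \infty$) is approached rather
  than attained, so nesting comparisons carry a $10^{-3}$ slack;
* the count part is warm-started from an (untruncated) Poisson
  regression; BFGS with `reltol = 1e-12`; standard errors from the
  observed information; convergence and possible separation in the zero
  part are reported honestly on the fit object.

**Family selection** (`select_family()`): the ZANB is kept only if its
AIC is lower *and* the 1-df dispersion LRT is significant at 0.05;
otherwise the ZAP wins (parsimony breaks ties). The dispersion test sits
on the boundary of the parameter space; the default follows common
practice with a plain $\chi^2_1$, and a 50:50 $\chi^2_0{:}\chi^2_1$
mixture is exposed via `boundary = TRUE` as the statistically correct
variant.

**Simplification** (`stepwise_simplify()`): in each part independently,
the interaction is considered before main effects; the candidate with
the largest LRT p-value above $\alpha = 0.05$ is dropped and the process
repeats. If the interaction is significant in both parts the full model
is the minimum adequate model. The drop path is recorded on the result.

**Prediction and validation.** `predict_cpue()` returns the
unconditional hurdle mean $\pi\mu/(1 - f(0;\mu,\theta))$ (used for CPUE
standardised to a reference pot number, default comparisons at 19.6
pots). `residuals_vs_fitted()` returns Pearson residuals under the full
fitted hurdle variance, $\mathrm{Var}(Y) = \pi\,\mathbb E[Y^2 \mid Y>0]
- (\pi\,\mathbb E[Y \mid Y>0])^2$, for residual-vs-fitted validation.

Counts are modelled in lobsters boat-day⁻¹ only; kg CPUE is never
modelled (not integer-valued). Years are pooled with no year term by
default — the data give no basis for one, and a year covariate can be
emulated by filtering records before fitting.

## The synthetic fishery

`default_config()` states the world the estimators assume, with the
fishery's published summary statistics as fixed points:

| parameter | default | basis |
|---|---|---|
| fleet | 62 Main + 7 Lodge + 5 upstream = 74 | fleet mean 74.1; Lodge < 10; +5 upstream |
| fishers/boat | 3.6 (sd 0.7), clamped 1–8 | survey mean |
| pots/boat | NB matched to mean 22.0, sd 13.5, truncated ≥ 1 | survey mean/sd; overdispersed positive integers |
| months | Feb–Sep 2015; NTZ open Jul–Sep | season design |
| `bac_true` | 0.74, 0.47, 0.67, 0.19, 0.09, 0.80, 0.80, 0.50 | published monthly BACs |
| price | 15,000 MGA kg⁻¹, 20,000 from 1 July | negotiated step at opening |
| hurdle coefs (zero) | −1.2, 0.2, 0.065, 0.02 | calibration (below) |
| hurdle coefs (count) | −0.2, 0.5, 0.025, 0.012 | calibration (below) |
| dispersion θ | 1.5 | strong overdispersion, typical of catch counts |
| species mix | P. longipes-leaning when closed, P. homarus-dominated when open | composition pattern |
| TL distributions | e.g. P. homarus N(205, 32²) mm, truncated (80, 450) | puts ~44% of the catch under the 200 mm MLS |
| CL from TL | male P. homarus slope 1/3.1 | TL ≈ 3.1 × CL, giving ~186 mm TL at CL 60 |
| weight | W = 8×10⁻⁸ · TL^2.9 kg | allometric; mean ≈ 0.45 kg so kg-CPUE and count-CPUE scales cohere |
| surveys | 15 days/month, both sites counted, 85% of returning boats sampled | protocol: sample > 50% |

The hurdle coefficients are a calibration, not reproductions of any
fitted values (those are unpublishable without the raw data): they were
chosen once so that closed-season CPUE sits near 0.6–0.9 kg boat-day⁻¹
and opens at roughly twice that, with a strong pot effect and a positive
NTZ × pots interaction in both parts. They are exposed in
`GroundTruth`, and the recovery tests check the fitter against whatever
the config says, not against these particular numbers.

**Activity structure.** The generator draws lobster fishing per boat-day
as Bernoulli(`bac_true`). For the activity-ratio BAC estimator to be
*consistent* for `bac_true`, the sampled returning boats must be
representative of the whole fleet — which holds when non-lobstering
boats go to sea on other activities rather than staying beached. The
default world therefore sets `p_inactive = 0` (every non-lobster boat is
at sea on "other" work, as in a fleet whose pirogues also serve other
fisheries). Setting `p_inactive > 0` creates genuinely idle boats and
reproduces the estimator's upward bias; this is deliberately available
but not the default, because the stated world is the one in which the
published estimator is well-founded.

**What the generator does not emulate:** within-month trends in activity
or CPUE (parameters are stationary inside a month), weather-driven
day-to-day correlation, boat-level heterogeneity (no random effects),
spatial structure or effort reallocation, and measurement error in
lengths and weights. A green recovery test therefore establishes that
the estimators are correct *under the stated model*, not that the model
captures every feature of real monitoring data.

**Reproducibility.** All randomness flows from the config seed; each
month derives its own sub-stream, so month $k$ is bit-identical no
matter which other months are generated. `census = TRUE` surveys every
day, attributes the whole fleet to one site and samples every returning
boat — the regime in which the raising estimator must (and does) match
ground-truth landings exactly, because $E$ collapses to the realised
number of lobster boat-days and $C$ to total weight over that count.

## Composition statistics

* **Grouping:** dominant species (*P. homarus*, *P. longipes*) are kept
  separate; remaining spiny and slipper lobsters pool into
  `other_spiny` / `other_slipper`. Per-month proportions sum to 1.
* **MLS:** strictly below 200 mm TL; boundary individuals are legal.
  (Published figures for this quantity are internally inconsistent —
  42.8% in one place, 48.2% in another — so no specific value is
  asserted anywhere in the package.)
* **KS test:** $D$ is the maximum ECDF gap over pooled unique points
  (robust to ties in 0.5 mm-resolution length data); the p-value uses
  the asymptotic Kolmogorov series at effective size $n_1 n_2/(n_1 +
  n_2)$, matching the common reference implementation for untied data.
* **Histograms/KDE:** 10 mm bins, left-closed, anchored at 0 mm;
  Gaussian kernels with caption bandwidths when reproducing published
  figures (8.565 mm for the all-species histogram) or Silverman's rule
  otherwise.
* **NTZ split:** closed vs open periods are resolved from the calendar
  date of each record (February–June vs July–September in 2015), not
  from any per-record flag.
* **Earnings:** each lobster-fishing record contributes weight divided
  by crew size; the median of those per-fisher catches times the beach
  price gives daily earnings (0.18 kg × 15,000 MGA = 2,700 MGA).

## Known limitations

* No variance or confidence intervals on raised landings: the estimator
  is a point-estimate chain, as published.
* The BAC estimator's bias under genuinely idle boats is demonstrated,
  not corrected; a design-based correction would need a sampling frame
  for beached boats.
* Stepwise LRT simplification inherits the usual multiple-testing
  caveats of minimum-adequate-model selection; the path is recorded so
  the full model is always recoverable.
* The asymptotic KS p-value is anticonservative for very small samples;
  the statistic itself is exact.
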