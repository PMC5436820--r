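# palinurid

Catch, effort and hurdle-model CPUE analysis for a small-scale, pot-based
spiny lobster fishery managed with a periodic no-take zone (NTZ).

## The problem

In the Sainte Luce lobster fishery (southeast Madagascar), landings and
effort are monitored by participatory beach surveys: dawn counts of boats
at sea (drag marks in the sand) and inactive boats, per-boat catch/effort
records from an opportunistic sample of more than half the returning
boats, and individual measurements (species, total length TL, carapace
length CL, sex, berried status) of sampled catches. The community closes
a 13 km² area to lobster fishing for most of the year and opens it for a
few months; the analytical questions are how much is landed each month,
whether catch per unit effort (CPUE) changes when the NTZ opens, and what
the catch composition says about compliance with the minimum landing size
(MLS, 200 mm TL) and the ban on landing berried females.

`palinurid` implements that full analysis chain as tested, reusable
functions, plus a seeded synthetic fishery generator with known ground
truth so every estimator can be validated against the world it assumes.

## The statistics

**Raising estimator.** Monthly landings are raised from the sample as

    L = E × C        (landings, kg)
    E = D × B × F    (effort, boat-days)
    B = A ÷ T        (boat activity coefficient)

where *D* is days in the month, *F* the fleet size (mean of total-boat
counts on days when both landing sites were surveyed, plus five upstream
boats), *C* the mean sampled CPUE (zero catches included — they are true
zeros), *A* the estimated number of boats lobster fishing (the sampled
activity ratio applied to the full count) and *T* the total boats
counted. Value is `V = L × P` with *P* the beach price (MGA kg⁻¹). All
chains are computed unrounded; rounding is display-only.

**Hurdle CPUE models.** Lobster counts per boat-day are zero-inflated
with "true" zeros, so they are modelled with zero-altered (hurdle)
models: a logistic model for P(count > 0) and a zero-truncated Poisson
(ZAP) or NB2 negative binomial (ZANB) for the positive counts, each on
NTZ status × pots. Both parts are fitted by direct maximum likelihood
(the likelihood factorises). ZAP vs ZANB is decided by AIC plus a
likelihood-ratio test on the dispersion; the minimum adequate model (MAM)
is found by stepwise likelihood-ratio simplification respecting
marginality. Predictions use the unconditional hurdle mean
π·μ/(1 − f(0; μ, θ)).

**Composition and compliance.** Species/berried proportions by month,
10 mm size-frequency histograms with Gaussian kernel density estimates,
two-sample Kolmogorov–Smirnov comparison of size distributions between
NTZ-closed and NTZ-open periods, TL–CL ordinary least squares per
species × sex, proportion of the catch under the MLS, and median daily
earnings per fisher.

## Worked example

```r
library(palinurid)
cfg <- default_config(seed = 1)       # 74 boats, 3.6 fishers, 22.0 pots
sim <- simulate_season(cfg)           # full 2015-style season
est <- estimate_season(sim$surveys, sim$boat_records,
                       default_price_schedule())
monthly_report(est)
```

```
    month  D  n    B  F    E    C    L     P        V imputed
1 2015-02 28 15 0.74 74 1527 0.66 1014 15000 15216486   FALSE
2 2015-03 31 15 0.48 74 1099 0.61  674 15000 10104801   FALSE
3 2015-04 30 15 0.67 74 1483 0.61  904 15000 13558626   FALSE
4 2015-05 31 15 0.19 74  427 0.60  255 15000  3822162   FALSE
5 2015-06 30 15 0.09 74  193 0.62  119 15000  1787611   FALSE
6 2015-07 31 15 0.79 74 1815 1.39 2527 20000 50539805   FALSE
7 2015-08 31 15 0.80 74 1832 1.45 2652 20000 53031214   FALSE
8 2015-09 30 15 0.47 74 1042 1.33 1383 20000 27650735   FALSE
```

One row per month: the monthly BAC *B* tracks the configured activity
probabilities (0.74, 0.47, …), the fleet *F* is recovered at 74 boats,
CPUE *C* roughly doubles when the NTZ opens in July, and landings *L*
and value *V* follow. The season summary
(`season_summary(est)`) gives 9,527 kg against a simulated ground truth
of 9,497 kg — sampling error of the raising estimator, which becomes
exactly zero under full enumeration (`simulate_season(cfg, census =
TRUE)`).

Fitting the hurdle model to the same season:

```r
rec <- subset(sim$boat_records, site == "Main" & activity == "lobster_fishing")
ntz <- as.numeric(ntz_status(default_ntz_calendar(), rec$date) == "open")
sel <- select_family(rec$n_lobsters, hurdle_design(ntz, rec$n_pots))
mam <- stepwise_simplify(sel$fit)
mam
```

```
zero-altered negative binomial (ZANB), n = 3352
logLik -6074.208, AIC 12166.417, params 9, converged: TRUE
zero part (logit P(count>0)):
         intercept    ntz   pots ntz_pots
estimate   -1.1551 0.0742 0.0633   0.0253
se          0.1087 0.1634 0.0048   0.0078
count part (log conditional mean):
         intercept    ntz   pots ntz_pots
estimate   -0.1125 0.5508 0.0242   0.0085
se          0.0836 0.1027 0.0024   0.0031
dispersion theta = 1.5106
```

The ZANB is chosen over the ZAP, the NTZ × pots interaction is retained
in both parts, and the estimates sit within sampling error of the
generator's coefficients (zero part −1.2, 0.2, 0.065, 0.02; count part
−0.2, 0.5, 0.025, 0.012; θ = 1.5). Standardised CPUE at the reference
19.6 pots (`predict_cpue(mam, c(0, 1), 19.6)`) is 1.18 lobsters
boat-day⁻¹ with the NTZ closed and 2.40 with it open.

## Command line

```sh
Rscript inst/exec/palinurid simulate --seed 7 --out-dir data/
Rscript inst/exec/palinurid estimate --surveys data/daily_surveys.csv \
    --records data/boat_records.csv --out monthly.csv
Rscript inst/exec/palinurid model   --records data/boat_records.csv --out-dir out/
Rscript inst/exec/palinurid compose --lobsters data/lobsters.csv --out-dir out/
Rscript inst/exec/palinurid report  --estimates monthly.csv --out headline.csv
```

Every output carries a `#` provenance header (version, seed, config
hash); all randomness flows from `--seed`.

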