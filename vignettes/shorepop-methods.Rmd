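---
title: "Methods: within-site demography of intertidal mussel populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-site demography of intertidal mussel populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shorepop)
```

`shorepop` analyses quadrat surveys of rocky-shore mussel populations at the
within-site scale: individual growth inferred from length frequencies,
mortality from age structure, cover-standardized density and biomass, the
crowding of monolayer aggregations, recruitment, tidal immersion, and
potential reproductive output. This vignette documents the models, the
frozen numerical choices, and the scope of the validation the package's own
simulator supports.

## Seasonal von Bertalanffy growth

Shell length at time $t$ follows the seasonally oscillating von Bertalanffy
growth function (soVBGF)

$$L_t = L_\infty\left(1 - e^{-K(t - t_0) + S_t - S_{t_0}}\right),
\qquad S_t = \frac{CK}{2\pi}\,\sin\!\big(2\pi(t - t_s)\big),$$

with asymptotic length $L_\infty$ (mm), growth constant $K$ (yr$^{-1}$),
anchor time $t_0 \in [0,1)$ (the fraction of the year when length is zero —
in length-frequency work effectively the recruitment period), oscillation
amplitude $C \in [0,1]$ and season start $t_s \in [0,1)$. For $C \le 1$ the
curve is monotone, so ageing by numerical inversion
(`age_from_length()`, bisection to $10^{-6}$ mm) is well defined; $C > 1$
would imply seasonal shrinkage and is rejected at construction. Growth
performance is summarized by $\varphi' = \log_{10} K + 2\log_{10} L_\infty$,
which is comparable across populations because $K$ and $L_\infty$ trade off
along lines of constant $\varphi'$.

The recruit threshold — the length separating month-old settlers from the
established population — is the curve evaluated one month past $t_0$
with the seasonal terms off (`recruit_threshold()`). The seasonal phase at
settlement of a pooled sample is not identifiable, so making the threshold
depend on it would manufacture precision; a `seasonal = TRUE` switch exposes
the alternative. The conventional field value 1.07 mm is the default
threshold constant wherever one is needed directly.

## ELEFAN: restructuring, scoring, genetic algorithm

Growth parameters are estimated from binned length frequencies
(`build_lfq()`: uniform bins, half-open $[lo, lo+w)$ so edge lengths go to
the upper bin; default width 2 mm). The histogram is first *restructured*
(`restructure_lfq()`) so cohort modes score positively and troughs
negatively. The exact restructuring variant matters for reproducibility and
is frozen as:

1. centered moving average (MA) over `ma` bins, the window shrinking at the
   histogram edges — a flat column therefore restructures to exactly zero;
2. score $= n_i/\mathrm{MA}_i - 1$ (with $0/0 = 0$);
3. positive scores capped at 5;
4. isolated peaks (both neighbours empty) halved;
5. the score of every empty bin divided by the length of its contiguous run
   of empty bins;
6. all scores multiplied by the reliability weight
   $\min(1, \mathrm{MA}_i / (0.02\sum_i n_i))$;
7. positive scores normalized so each column's maximum is $+1$ (negatives
   are already bounded below by $-1$).

Steps 5 and 6 are the low-count de-emphasis: without them the sparse tail of
the length distribution dominates the fit — empty tail bins carry $-1$
penalties that crush any curve passing near the largest individuals, while
one- and two-count tail bins generate spurious peaks that reward curves
threading them. Both effects push the fitted $L_\infty$ far upward. The
default `ma = 9` follows the convention that the MA window should span the
youngest cohort; with mussel recruit cohorts roughly 9 mm wide this
corresponds to 1 mm bins, which the validation suite uses.

A candidate parameter vector is scored (`score_growth_curve()`) by ESP/ASP:
cohort trajectories, one per birth year up to `max_age` (default 11 yr, the
observed longevity of the motivating population) before the first sample,
cross each sampling date at one predicted length. ASP is the sum over dates
of every positive run's maximum. ESP credits each positive run at most once
per date with the best score among the bins actually crossed — so curves
aligned with mode centres outscore curves clipping mode shoulders — and adds
the (negative) score of every distinct trough bin crossed. The score is at
most 1.

`elefan_ga()` maximizes the score with a real-coded genetic algorithm:
tournament selection (size 3), blend crossover (rate 0.8), Gaussian
mutation (sd 5 % of each range, per-gene probability 0.3), elitism (the
best vector always survives, so the best score is monotone), five random
immigrants per generation, 300 generations with early stop after 60
stagnant generations, population 50. The immigrant and budget settings were
chosen because shorter, immigrant-free runs converged prematurely on
realistic 12-month surveys: the score surface is multimodal in $(t_0, t_s)$
and a purely exploitative population stalls far below the attainable score.
All settings are exposed through `control`.

Uncertainty comes from a bootstrap that resamples individuals within each
sampling date (multinomial resampling of the count columns) and refits;
resampling dates instead would destroy the temporal design the cohort
trajectories rely on.

### The asymptotic-length search range

ELEFAN score surfaces are ridge-shaped in $(L_\infty, K)$: larger asymptotic
lengths with compensating smaller growth constants trace nearly the same
curve through the observed length range, so an unconstrained search drifts
toward arbitrarily large $L_\infty$. This is the classic $\varphi'$ ridge,
and the standard remedy is to restrict the $L_\infty$ range around the
largest observed individuals before the final fit. By default
(`search_space = NULL`) the package anchors the range at $0.8$–$1.5 \times
L_{max}$ (largest occupied bin's upper edge): below $0.8\,L_{max}$ the
largest individuals could not exist, while beyond $\sim 1.5\,L_{max}$ even
the oldest observed cohort would sit far below the asymptote on a scale
length-frequency data cannot resolve. `rsa_grid()` provides the exploratory
response-surface scan over a wide $(L_\infty, K)$ window for choosing a
range by inspection instead.

## Mortality

Ages from inverted lengths are grouped into one-year classes, class $t$
covering $[t-1, t)$ years, so "age class 1" is the first year of life.
`fit_mortality()` fits the negative exponential survivorship model
$N_t = N_1 e^{-Zt}$ as a catch curve: ordinary least squares of
$\ln N_t$ on $t$ over positive classes. Age class 1 is excluded by default —
its size reflects the latest recruitment pulse, not cumulative mortality.
Zero-count classes cannot enter the log regression and are omitted. $Z$ is
invariant to rescaling all counts, so raw counts and cover-standardized
densities give identical estimates. A log-linear fit (rather than nonlinear
least squares on counts) is the frozen choice, matching the catch-curve
tradition; all-equal counts return $Z = 0$ with $r^2 = 0$.

## Population metrics

All per-quadrat metrics standardize by the *covered* area
$\mathrm{CC} \times \mathrm{QA}$ (covered fraction times quadrat area,
default 0.0625 m$^2$), describing the aggregate rather than the whole
shore: biomass $\sum \mathrm{TWW} / (\mathrm{CC\,QA})$ in kg m$^{-2}$,
density and monthly recruit density in ind m$^{-2}$. Total wet weight
missing from a record is predicted from shell length through the power-law
allometry $\mathrm{TWW} = a\,\mathrm{SL}^b$, fitted by nonlinear least
squares in natural space (`fit_allometry()`, via `minpack.lm`), with the
imputation count reported per quadrat.

The crowding index is the summed basal area of all adults,
$\mathrm{SL}^2/4.32$ each (from the biometric footprint
$(\mathrm{SL}/1.8)(\mathrm{SL}/2.4)$), divided by the observed covered area
in mm$^2$. One means footprints exactly tile the patch; above one,
individuals overlap. The index is quoted in this orientation (overlap
$\Rightarrow$ index $> 1$); the reciprocal is available behind
`inverse = TRUE` for comparison with formulations stated the other way
round. Recruits are excluded throughout (strict `<` threshold comparison),
and the even-sample median uses the midpoint convention.

## Tidal immersion

`empirical_immersion()` is the fraction of hourly tide-gauge records with
water at or above a height (ties count as immersed; the grand fraction over
all records, which equals the mean of daily percentages for complete days).
It is non-increasing in height by construction. A cubic polynomial is
fitted to the empirical curve on a 0.1 m grid over the mussel zone
(default 3.0–5.5 m above lowest astronomical tide) and evaluated per
quadrat, clamped to $[0, 100]$ with out-of-range heights flagged (below the
range 100 %, above it 0 %).

## Reproductive output

Potential reproductive output per m$^2$ of covered area multiplies the
summed flesh dry weight of mature individuals (strictly above 12 mm) by the
fecundity fraction (0.28 of dry mass) and the female fraction (0.5 under
the 1:1 sex-ratio assumption — eggs are a female product, so the halving is
applied; setting `female_fraction = 1` recovers the unhalved reading), then
converts mass to eggs with the equivalence $10^6$ eggs $= 52.5$ mg. Missing
dry weights are predicted from a dry-mass allometry fitted with the same
machinery as the wet-weight one. Spawning phenology contrasts use the
likelihood-ratio $G$-test per date and the sex ratio a $1:1$ chi-square,
both as closed forms with $\chi^2_1$ reference.

The condition index is $\mathrm{CI} = \mathrm{FDW}/\mathrm{SL}^3$ with SL
in mm; only relative comparisons are meaningful, so the unit is a labelling
convention.

## The individual-based generator

`simulate_population()` produces datasets in the field schema with known
truth, per quadrat and date: monthly cohorts drawn from a 12-month
recruitment schedule (Poisson counts, uniform birth times within the
month) over an 11-year burn-in; survival $e^{-Z\,\mathrm{age}}$ with
$\ln Z$ linear in intertidal height; lengths from the soVBGF anchored at
each individual's birth time, with individual lognormal $L_\infty$
(CV 5 % — variability acts on $L_\infty$ only so the mean curve stays
invertible for ageing); masses from the allometry with 5 % lognormal
noise; flesh wet/dry weights as fixed fractions of total; Bernoulli(½)
sex; spawning stage from a seasonal logistic with shore-specific phase.
The observed patch area is *set* to the summed adult basal area divided by
the configured crowding target, so the realised crowding index is exact by
construction — that makes crowding a round-trip identity, not a statistical
recovery. Default conditions mirror the motivating survey: two shores with
distinct growth truths, three quadrat heights, twelve monthly samples,
0.0625 m$^2$ quadrats, a two-constituent (12.42 h + 12.00 h) tide about a
4 m mean level, and a bimodal recruitment schedule with spring and
early-autumn pulses. Every quadrat draws from its own seeded substream, so
adding quadrats, dates or shores never perturbs existing draws.

Two design points deserve emphasis:

* **Growth-recovery validation uses a single recruitment pulse.** The
  soVBGF is a single-anchor model: one cohort per year, born near $t_0$.
  Under the bimodal field default, two cohorts enter per year and an
  annual-cohort estimator aliases $K$ to the inter-pulse spacing (fitted
  $K$ near half its true value) — a structural limitation of every
  single-$t_0$ ELEFAN, not an implementation defect. Parameter-recovery
  tests therefore generate from the model's own assumptions (one seasonal
  pulse at the anchor), while field-schema datasets keep the realistic
  bimodal default.
* **What passing tests do and do not show.** The generator has no
  measurement error on lengths, no spatial settlement structure, no wave
  dislodgement, no movement, and recruitment independent of density.
  Recovery on its output demonstrates estimator correctness under the
  stated model, not robustness to the many ways real surveys depart
  from it.

## Validation problem sizes

The test suite exercises: growth recovery on 12 monthly samples of ~500
individuals (median of 3 seeds; the estimator is required to return
$L_\infty$ within 10 % and $K$ within 25 %); mortality recovery on 200
replicates of 2000 exponential ages at $Z \in \{0.43, 0.9, 1.43\}$ (median
relative error within 15 %, exact on noise-free counts); allometry recovery
on 100 replicates of $n = 720$ with 5 % multiplicative noise ($b$ within
2 %, $a$ within 15 %, exact without noise); a 5-year hourly two-constituent
tide (fitted immersion at the mean level 50 ± 1 %); and byte-identical
pipeline reruns. These sizes were chosen to match the motivating survey's
design (sample sizes, biometric $n$, tide-record span) while keeping the
default check fast.

## Known limitations

* ELEFAN identifies $(L_\infty, K)$ only up to the $\varphi'$ ridge when
  longevity truncates lengths well below the asymptote; the $L_{max}$
  anchor is a prior, and fits should be read together with the bootstrap
  spread and the sclerochronology check (`validate_against_ages()`).
* The catch curve assumes stationary recruitment and mortality; the
  exclusion of class 1 removes only the most acute violation.
* The crowding index describes monolayer patches; multi-layer aggregations
  violate its premise.
* The immersion model ignores waves, surge and setup; it is a tidal-datum
  calculation.
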