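---
title: "Decentralized ranking trials: models, design choices, and what the synthetic experiments show"
author: "pltricot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decentralized ranking trials: models, design choices, and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pltricot)
```

## The problem

Centralized breeding evaluates many genotypes under few, well-controlled
station environments and extrapolates to farmers' fields — typically through
genomic prediction (GBLUP). Decentralized (citizen-science) testing inverts
this: each farm grows a tiny randomized subset — in the tricot design, three
test genotypes plus one check — and the farmer simply ranks the four entries.
Thousands of small, heterogeneous rankings replace hundreds of measured
plots. `pltricot` implements both arms: the ranking pipeline (Plackett–Luce
trees over agroclimatic covariates, with a genomic prior) and the
centralized GBLUP benchmark, plus a synthetic-data generator that emulates
the joint structure so the entire pipeline is testable end to end.

## The Plackett–Luce model

Each genotype $i$ has a worth $\alpha_i > 0$. The probability that $i$ beats
all other entries of a set is $\alpha_i / \sum_j \alpha_j$ — its normalized
worth — and a full best-to-worst ranking has probability equal to the
product of successive such choices among the remaining entries (Luce's
choice axiom: the relative preference of two entries does not depend on
which others are present). Worths are gauge-fixed to sum to one after
fitting. The reliability of genotype $i$ against a check $j$ is
$\alpha_i / (\alpha_i + \alpha_j)$.

`fit_pl()` maximizes the likelihood with the MM (minorize–maximize)
algorithm, which is monotone and requires no step-size tuning. The MLE
exists only when the pairwise win/loss graph is strongly connected;
`check_connectivity()` reports the strongly-connected components, and
`fit_pl()` refuses disconnected data by design rather than returning
boundary estimates.

### The genomic prior

`fit_pl_genomic()` maximizes
$\ell(\lambda) - \tfrac12 \lambda^\top (\sigma^2 K + \epsilon I)^{-1} \lambda$
over log-worths $\lambda$ (mean-zero gauge), i.e. a MAP fit under a
multivariate normal prior whose covariance is proportional to the VanRaden
additive relationship matrix $K$. Genetically similar genotypes are shrunk
towards each other, and every genotype in $K$ receives a worth even if it
was never ranked — the marker data carry the information across. The prior
scale defaults to 1 on the log-worth scale (prior standard deviation of
about one log-worth unit per unit of kinship — the same order as the
genetic spread the generator assumes); $\epsilon = 10^{-8}$ keeps the
covariance invertible. How exactly a SNP relationship matrix should enter a
ranking model is genuinely open; the normal-prior-on-log-worths reading is
one defensible choice and is isolated behind this single function, so a
pseudo-ranking or hierarchical alternative could be swapped in without
touching the tree machinery.

## Plackett–Luce trees

`pl_tree()` grows a binary tree on numeric covariates. At each node, every
candidate threshold (midpoints between consecutive distinct covariate
values — deterministic, no data-dependent binning) is scored by the
log-likelihood gain of refitting the model separately in the two children;
rows with covariate $\le$ threshold go left. A split is kept when

* both children hold at least `min_size` (default 20%) of **all** records,
  and
* the Bonferroni-adjusted likelihood-ratio p-value is below `alpha`
  (default 0.01): twice the gain is referred to a $\chi^2$ with
  `n_items - 1` degrees of freedom (one additional gauge-fixed worth vector
  per split), multiplied by the number of thresholds and covariates
  searched.

The classical tree literature gates splits with parameter-instability
(structural-change) tests; we use the likelihood-ratio construction instead
because it is exactly computable from the fits the tree already produces,
and the Bonferroni factor over the threshold search controls the optimism of
maximizing the gain. The seeded null simulations in the test suite confirm
the gate is conservative at $\alpha = 0.01$ (homogeneous data yield a single
leaf). This is a declared substitute, not a claim about equivalence with
M-fluctuation tests.

Two numerical details matter for speed. The threshold scan warm-starts each
child fit from the neighbouring threshold's solution with a loose tolerance
(the solution path is continuous in the threshold), then refits the few
leading candidates exactly and returns the best exact gain — so the reported
threshold is the exact argmax while the scan stays close to linear in the
record count. And likelihood-ratio gains are always measured against the node's ML
fit, even when leaves are reported as genomic MAP fits.

When a kinship matrix is supplied, each leaf is refit by the genomic MAP —
which also covers leaves whose comparison graph is disconnected (an item
that never wins inside one environmental stratum is common under strong
genotype-by-environment interaction). Without a kinship matrix such leaves
raise an identifiability error; that is intentional.

`predict()` routes new covariate rows to leaves ($\le$ left, ties at the
threshold go left) and returns normalized leaf worths; items a leaf never
ranked are imputed at the leaf's smallest observed worth before
renormalization, a conservative "no evidence it is good here" convention.

## Covariate selection

`forward_select()` is greedy forward selection with seasons as
cross-validation blocks: each candidate extension is scored by its
leave-one-season-out mean holdout deviance, Akaike weights are computed
across the incumbent and all extensions with penalty = (mean number of
leaves) × (`n_items` − 1), and the best extension is accepted only on a
strict weight improvement. Blocks are combined by the unweighted mean —
√n weighting is reserved for the accuracy metric, where it is part of the
procedure's definition. The AIC-style complexity term is our choice (the
deviance/Akaike-weight recipe leaves it open); it makes the criterion
sensitive to tree size, which the null simulations show is what keeps noise
covariates out. Ties in weight break by covariate name order, making the
trail reproducible bit for bit.

## Agroclimatic covariates

"Night temperature" statistics are computed over daily minimum temperature
and "day temperature" over daily maximum — the convention of the
agroclimatic index packages this module mirrors. Phase windows are half-open
(`[planting, flowering)` vegetative, `[flowering, maturity)` reproductive,
`[maturity, harvest)` grain filling, `[planting, harvest)` full cycle): a
day equal to the flowering date belongs to the reproductive phase only. The
fixed index set (min/max/mean NT and DT, diurnal range, growing degree days
with a 0 °C wheat base, rainfall totals, rainy days, dry/wet runs, 1- and
5-day maxima; 14 indices × 4 phases = 56 covariates) is reproducible but
deliberately not a reconstruction of any particular published covariate
list, which is unavailable; counting parity is not a goal. Sowing windows
are the midpoints of `k` equiprobable quantile intervals of the observed
planting dates, with linear interpolation between order statistics.

## The centralized benchmark

Station plot data are reduced to genotype BLUPs by a deliberately simple
mixed model — environment (location × season) fixed, genotype and
replicate-within-environment random, fit with `lme4` — rather than an
alpha-lattice/spatial model: the incomplete-block layout the generator
produces carries only a small block effect, and the exact published station
models are not reproducible from public information. GBLUP then uses the
VanRaden method-1 relationship matrix and restricted maximum likelihood,
profiled to a one-dimensional optimization of the variance ratio after an
eigendecomposition of $K$. Heritability on the trial-mean basis is
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{gl}/l + \sigma^2_e/(lr))$, with
the additive (genomic) variance substituted for the numerator in $h^2$.
Overall-appreciation scores are pooled across raters and genders before the
BLUP stage; the benchmark can optionally train on rank-transformed
phenotypes.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* the analysis assumes, at the
emulated study's scale by default: 400 station genotypes (41 of which go
on-farm plus one recommended check), 2 stations × 2 seasons × 2 replicates =
3,200 station plots (800 per station field), 1,165 farm fields × 4 ranked
plots = 4,660 farm plots over 3 seasons, and 15 × 3 = 45 seasonal
extrapolation scenarios. Its latent model gives each genotype a base
log-worth (an additive genetic value built from simulated SNP effects) plus
a shift that activates strictly above a night-temperature threshold
(11.5 °C on the vegetative-phase minimum night temperature by default) — a
single hard worth reversal. Farmer rankings are drawn by exact Luce
sampling from the field's worths; grain yield is linked linearly to
centered log-worth (scale-stable in worth ratios) with Gaussian plot noise
truncated at zero; station appreciation scores are a discretized noisy
monotone transform of the station-regime genetic value on an integer 1–5
scale. Stations sit in the warm (above-threshold) regime — that is the
mechanism by which a centralized benchmark mis-ranks cold farms. The check
is chosen at the upper quartile of station genetic value outside the
on-farm subset: strong enough to be a credible commercial recommendation,
not the unbeatable extreme of the panel.

Real data differ in ways the generator deliberately ignores: G×E is
continuous and multi-dimensional rather than a single threshold switch;
farmer appreciation weighs traits beyond yield; rankings can contain ties
and errors; weather is spatially correlated and non-stationary; stations
and farms differ in management. Passing the recovery tests therefore shows
the *machinery* is correct and the inference is consistent under its own
assumptions — it does not certify accuracy on any real dataset.

The published accuracies, reliabilities and heritabilities of the study
this package emulates were computed on a real multi-season Ethiopian wheat
dataset; at desk scale without that data they are not reproducible numbers,
and the package makes no attempt to match them. What is checked instead:
the printed design counts, the self-contained √n-weighted worked example
(0.270/0.276/0.203 on 179/651/335 combine to 0.251), exact small-case
oracles, seeded parameter recovery, and the headline *direction* — trees
beat the benchmark under strong G×E and the gap vanishes without it.

## Numerical and testing choices

* Generator effect sizes are free parameters, documented in
  `default_config()`: base genetic spread 1.0 and switch shift 1.2 on the
  log-worth scale, yield link 0.8 t/ha per log-worth unit around a 3 t/ha
  intercept, 0.4 t/ha plot noise, 35% cold fields. They were chosen once as
  a plausible strong-interaction regime, not fitted to any dataset.
* MM convergence is measured on the maximum absolute change of log-worths
  (default 1e-9 for final fits); ties in measured yield are broken
  lexicographically by item id and flagged; ties in predicted worths break
  the same way before Kendall τ.
* Per-season τ is the mean of per-field τ values (not pooled pairs),
  respecting the grouped structure; seasons combine with √n weights.
* The recovery simulations run at reduced but statistically adequate sizes
  chosen as the package's own test design: threshold recovery at 1,000
  rankings (20 replicates), forward selection at 450 rankings with five
  noise covariates (20 + 20 replicates), variance-ratio recovery at 200
  genotypes, and the two-arm direction experiment at 400 fields and 40
  station genotypes per seed. The acceptance script runs the two-arm
  comparison once at the full 1,165-field scale.

## Limitations

Ties are unsupported in the likelihood (Davidson-type extensions are out of
scope), splits are binary on numeric covariates only, no pruning or honest
leaf estimation is attempted, the station model ignores spatial layout, and
the scenario extrapolation takes its target points and phase durations as
given (no geographic hull or phenology model). The genomic prior's scale is
a user parameter, not estimated.
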