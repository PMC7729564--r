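---
title: "Methods: gating, mortality kinetics, clustering and enrichment in quiescence screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, mortality kinetics, clustering and enrichment in quiescence screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quiescreen)
```

## The experimental system

When fission yeast (*Schizosaccharomyces pombe*) is starved of nitrogen in
the absence of a mating partner, cells divide twice without growth and arrest
in a reversible, differentiated G0 state — cellular quiescence. A
plate-format flow-cytometry screen of a gene-deletion library follows each
mutant from the proliferative stage (day 0) through nitrogen starvation
(days 1, 7, 14, 21, 28), measuring two things per well: the fraction of dead
cells (an amine-reactive viability dye marks dead cells) and the DNA-content
distribution of the live cells, which separates quiescent 1C mononuclear G0
cells from 2C mononuclear G2 cells and 2C binuclear G1/M particles.

`quiescreen` implements the downstream analysis of such a screen as testable
stages: per-well gating, per-strain mortality-curve fitting with model
selection and half-life extrapolation, multi-phenotype hierarchical
clustering, and per-cluster protein-complex enrichment. A synthetic-cytometry
module generates event tables with planted ground truth so that every stage
can be validated end to end without instrument data.

## Gating

Each well is an event table with six channels (`FSC_A`, `FSC_H`, `SSC_A`,
`VIAB`, `DNA_A`, `DNA_W`). The cascade is:

1. **Doublet exclusion.** Two cells passing the laser together double the
   forward-scatter pulse area but not its height, so the `FSC_H / FSC_A`
   ratio of a doublet sits near half that of a singlet. Events inside the
   `singlet_ratio_band` (default 0.7–1.4 around the singlet ratio of 1) are
   singlets. Events with `FSC_A == 0` cannot be classified and are assigned
   to the doublet class while being counted in an anomaly tally.
2. **Viability.** Dead cells carry roughly tenfold dye intensity. Events
   above the viability threshold are dead; mortality is
   `100 * dead / (dead + live)` among singlets. The denominator is the
   singlet population because doublets are excluded before any downstream
   statistic; unclassifiable particles never enter the mortality fraction.
3. **DNA content.** A quadrant rule on `(DNA_A, DNA_W)` classifies live
   singlets: G0 is DNA-A low / DNA-W low, G2 is DNA-A high / DNA-W low,
   G1/M (binuclear) is DNA-A high / DNA-W high. Live cells in the remaining
   quadrant (for example S-phase or >2C particles) are reported as an
   unclassified remainder rather than forced into a class. One uniform
   quadrant rule is applied at every time point, including vegetative day-0
   samples.

Wells with fewer than `min_singlets = 1000` singlets fail QC; their
fractions are still reported but flagged, and the mortality fitter treats
them as missing time points, never as zeros.

**Automatic thresholds.** With `viability_threshold = "auto"` (likewise the
two DNA splits), the cutoff is placed by an exact Otsu split of the log
intensities: the two-class split minimizing within-class variance over the
sorted sample. An acquisition-software workflow would draw these gates by
hand; the automatic split makes the pipeline reproducible, and every
resolved threshold is recorded in the well summary for audit. Otsu's
criterion always produces *some* split, so a bimodality guard is required:
if the between-class mean separation is below `min_separation = 4` pooled
within-class standard deviations (on the log scale), the distribution is
treated as unimodal, the configured fixed fallback threshold is used, and
the well is flagged. Without the guard, a well with no dead cells would have
its live population split in half. The fallbacks default to the geometric
midpoints of the default channel geometry (viability 3, both DNA splits
sqrt(2)).

## Mortality kinetics

Seven nonlinear models are fitted to each strain's `(day, mortality %)`
trajectory:

| model | form | parameters |
|---|---|---|
| exp2p | `a * exp(b t)` | 2 |
| exp3p | `a + b * exp(c t)` | 3 |
| logistic3p | `a / (1 + exp(-b (t - c)))` | 3 |
| logistic5p | `d + (a - d) / (1 + exp(-b (t - c)))^e` | 5 |
| gompertz3p | `a * exp(-exp(-b (t - c)))` | 3 |
| mech_growth | `a * (1 - b * exp(-c t))` | 3 |
| probit4p | `d + (a - d) * pnorm(b (t - c))` | 4 |

These are the standard curve-library parameterizations. Two choices needed
to be made where conventions differ. First, the probit model uses a *linear*
time argument: day 0 is an observed time point, and a log-time argument is
undefined there. Second, `mech_growth` is restricted to its canonical
saturating regime, `b` in [0, 1] and `c >= 0`. Unrestricted, `a (1 - b
e^{-ct})` is an exact reparameterization of `a + b e^{ct}` (exp3p), and no
data could ever distinguish the two families; the restriction makes
`mech_growth` mean what its name says — a bounded, concave approach to an
asymptote.

**Fitting.** Each model is fitted by Levenberg–Marquardt nonlinear least
squares from 8 deterministic starting points derived from the data range
(baseline, rate and midpoint heuristics). Box bounds keep asymptote
parameters in [0, 105] % and rate parameters in [-5, 5] per day. The bounds
are enforced by fit-then-project: the unconstrained optimum is accepted when
it lies inside the box, and only otherwise is a bounded polish run — the
clamped-step bounded iteration alone can stall on an active bound far from
the optimum. The five-parameter logistic gets one extra stage: its error
surface has broad flat basins in the asymmetry exponent `e`, so each start
first fits the other four parameters with `e` pinned to a grid value
(0.1–16) before all five are released. A model is only attempted when the
trajectory has at least one more usable observation than the model has
parameters; with the screen's six time points every model is eligible when
no well fails QC.

**Selection.** Among converged fits, goodness of fit (R²) is standardized
across the candidate models into a z-score, recorded per fit. The selected
model must additionally be able to predict a day of 99% mortality within the
extrapolation horizon (default 1000 days); among the fits that can, the
highest z-score wins. Because several families nest (exp3p contains exp2p;
logistic5p contains logistic3p), noise-free data from a sub-family produce
exact ties; fits within `1e-6` of the best R² are therefore tied and broken
by parsimony (fewest parameters), then by a fixed order that prefers more
constrained families. If no model reaches 99% within the horizon, the
best-R² fit is reported with all threshold times censored at the horizon.

**Threshold times.** T1/4, T1/2 and T99 are the smallest `t` in
`[0, horizon]` where the fitted curve reaches 25, 50 and 99%, located by
coarse bracketing plus bisection to 1e-6 day; for a rising two-parameter
exponential the closed form `log(level / a) / b` is used and the numeric
path is cross-checked against it in the tests. Censored times carry the
horizon and a flag; in the phenotype matrix they enter at the horizon value
(flagged) so that long-lived strains remain clusterable, with exclusion of
censored strains available as a sensitivity toggle.

**Confidence intervals.** 95% intervals for threshold times come from a
residual-resampling bootstrap: residuals are resampled with replacement onto
the fitted curve, the model is refitted (single start at the original
estimate), and the percentile interval is taken over converged, uncensored
replicates. Intervals are flagged unreliable when fewer than half the
refits converge.

## Phenotype clustering

Five features summarize each strain: extrapolated T1/2 and T1/4 (days), G2%
at day 0, and G0% after 1 and 7 days of starvation. Records missing any
feature are excluded with a logged reason. Features are z-scored (sample SD,
n−1 denominator; zero-variance columns are left at 0 and flagged) —
standardization is the default and can be toggled off. Clustering is Ward's
minimum-variance agglomeration on Euclidean distances of the z-scored
features; merges are verified in the tests against an exhaustive
O(n³) reference that minimizes the increase in within-cluster sum of
squares directly.

**Choosing the number of clusters.** The Cubic Clustering Criterion
compares the observed R² of the k-cluster partition with its expectation
under a uniform-hypercube null whose edge lengths derive from the principal
component standard deviations `s_j` of the centered data. A q-cluster
partition idealizes as q cells of edge `c = (v*/q)^(1/p*)` with `v*` the
product of the first `p*` edge lengths; only dimensions with `s_j >= c` are
divided, so the partitionable dimensionality `p*` is found per q by
iterating down from the full dimension until `s_[p*] >= c`. Then

```
CCC = ln[(1 - E(R²)) / (1 - R²)] * sqrt(n p* / 2) / (0.001 + E(R²))^1.2
```

and the chosen k maximizes CCC over the candidate range (default 2–15).
Making `p*` depend on q matters: with a fixed `p*`, the null expectation
flattens while hierarchical partitions keep explaining variance by chopping
noise dimensions, and the criterion drifts upward with k instead of peaking
at the planted structure. CCC values above about 2 indicate real structure;
a maximum below 2 across the whole range is the no-structure convention. A
partition with R² exactly 1 is reported as `+Inf` and chosen.

Mutant-versus-control comparisons use Welch's independent-samples two-sided
t-test on the compared measurements.

## Enrichment

Protein-complex and GO-slim categories are flat gene lists over a fixed
background — the universe of analyzed strains, not the full library; genes
dropped before clustering are not part of the universe the cluster draw is
taken from. For category genes `K` of background `N`, cluster size `n` and
in-cluster category count `k`:

* fold enrichment `(k/n) / (K/N)`,
* the hypergeometric point probability `P(X = k)`,
* the upper tail `P(X >= k)`, the classical one-sided p-value,
* Benjamini–Hochberg adjusted point probabilities across all reported pairs.

Both probabilities are reported because screen literature mixes the two
conventions; the point probability is flagged as the statistic that
published per-complex values of this screen design correspond to. Pairs
with `k = 0` are omitted. Probabilities are computed by `dhyper`/`phyper`
(log-space internally) and are verified in the tests against exhaustive
subset enumeration and the combinatorial quotient for every consistent
count with `N <= 30`.

## The synthetic-cytometry module

The simulator is the package's stand-in for instrument output and defines
the study conditions under which the pipeline is validated:

* **Per well:** about 20,000 events, drawn from a mixture of five
  populations — live singlets in G0, G2 and G1/M, dead singlets, and
  doublets — with log-normal intensities per channel (cytometry intensities
  are strictly positive and right-skewed). `FSC_H` is derived from the
  event's own `FSC_A` times log-normal noise, so the H/A ratio carries the
  doublet discrimination by construction: doublets double FSC-A and DNA-A
  but keep FSC-H near singlet level.
* **Channel geometry (defaults):** DNA in "C" units — G0 at DNA-A 1,
  G2 at 2 (both DNA-W 1), binuclear G1/M at DNA-A 2 with DNA-W 2; dead
  cells at 10x viability-dye intensity; doublet contamination 5% of events;
  channel CVs 8–30% depending on channel. Dead cells are given arbitrary
  DNA values on purpose: they are gated out before DNA analysis, and no
  downstream result may depend on that choice.
* **Per strain:** a generating kinetic model drives the dead fraction over
  the six sampling days with Gaussian measurement noise (default SD 2
  percentage points, clamped to [0, 100]); live-cell phase profiles for
  day 0 / day 1 / later days set the G0/G2/G1M split. The default
  configuration spans seven archetypes: control-like slow mortality, two
  graded fast-mortality classes with normal G0 entry, two G0-entry defects
  of different severity, a high-G2 vegetative profile, and a miscellaneous
  mild class.
* **Reproducibility:** one global seed; every well draws from a substream
  seeded by a hash of `strain:day` folded with the global seed, so any well
  can be regenerated alone. The simulator saves and restores the caller's
  RNG state.

For clustering-scale validation, `simulate_phenotypes()` plants archetypes
directly in five-dimensional feature space: centres with a guaranteed
minimum pairwise separation (in within-cluster SD units), unit within-SD
scatter, rotated through a fixed orthogonal basis so the planted structure
is spread over all features — axis-aligned centres would otherwise be
distorted by per-feature z-scoring.

What the simulator does *not* emulate: spectral spillover and compensation,
acquisition-time drift, debris and clumps beyond doublets, inter-replicate
batch effects, and correlations between mortality and cell-cycle phenotypes
beyond what the archetypes encode. Passing recovery tests on these synthetic
screens demonstrates that the pipeline's statistics are correct and
well-calibrated under the planted mixture model — not that gating thresholds
transfer to any particular instrument's raw data, which is why every
threshold is configurable and recorded.

## Validation scales and numerical conventions

The test suite exercises: half-life recovery on 50 simulated
exponential-mortality strains at noise SD 2 (median relative T1/2 error
under 10%); generating-model identification on noise-free data from each of
the seven models; gating recovery of planted doublet/dead/G0/G2/G1M
fractions within 2 percentage points at 20,000 events averaged over 20
seeds; recovery of 7 planted archetypes (separation 6 SD, 20 strains each)
by Ward+CCC with at least 90% permutation-adjusted label agreement in at
least 80% of 25 replicates; and oracle equivalence of the hypergeometric
and Ward implementations. These problem sizes mirror the screen's structure
at a scale chosen to keep the full suite fast enough to run on every change.

Conventions for degenerate inputs: empty event tables and empty population
lists are rejected; a unimodal dye distribution falls back to the fixed
threshold (flagged); constant phenotype features z-score to 0 (flagged);
ties in merge distances are broken deterministically; identical
configuration and seed reproduce every output byte for byte.

## Limitations

* The five-feature summary discards the full mortality trajectory shape;
  two strains with different kinetics but similar T1/4, T1/2 can cluster
  together.
* CCC assumes roughly spherical clusters after standardization; elongated
  or nested phenotype classes may be over- or under-split.
* The point-probability enrichment statistic is not a tail test; both are
  reported, and the BH column refers to the point statistic.
* FCS files are not read directly; event tables must be exported to
  delimited text with the six canonical channels (a channel-name map is
  supported).
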