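---
title: "Methods: crossover landscapes and interference by Kullback-Leibler divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover landscapes and interference by Kullback-Leibler divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of **meiodiv**: what is
estimated, under which assumptions, which knobs matter, and where the design
was genuinely open and a choice had to be made.

## Data model

The package analyses **testcross gametes**. A progeny genotyped at two-state
SNP markers (`A`/`B`, the two parental alleles) reveals one gamete of the F1
parent; a change of state between adjacent markers is a crossover. Three
consequences shape everything downstream:

* **Minimal counting.** Two-state data cannot see an even number of
  exchanges inside one marker interval, so `call_crossovers()` returns the
  *minimal* crossover count consistent with the calls, and a called event is
  localized only to its interval. We place its point position at the
  interval **midpoint** — the unbiased choice given interval-level
  localization — and that convention propagates to binning and genetic
  interpolation.
* **Meiocyte doubling.** A meiocyte produces four gametes carrying each
  crossover twice among them; sampling one gamete per progeny halves the
  expectation, so per-meiocyte means are `2 × total / n`.
* **Complete rows only.** A missing call hides the parental state over a
  stretch of markers; `crossover_population()` therefore drops individuals
  with any missing call (logged) rather than imputing.

Markers are ordered by physical position; multipoint map-order estimation is
deliberately out of scope. Segregation-distorted markers (chi-squared
`(a−b)²/(a+b)`, 1 df, 5%) are flagged but kept by default — removal is a
policy decision exposed as `drop_distorted`.

## Genetic maps

Per-interval recombination fractions `r = recombinants / n` become
centimorgans via the Kosambi function `d = 25 ln((1+2r)/(1−2r))`, which
assumes moderate interference and satisfies `d ≥ 100r` (equality at 0).
An interval with `r ≥ 0.5` cannot be mapped: it is flagged, reported as
`NA` and excluded from totals with a warning — never silently truncated.

Between-population comparisons use the Pearson 2×2 chi-squared **without
continuity correction** on recombinant counts, per interval at 5%. At
chromosome and genome scales the decision rule is conservative: two
populations differ iff at least one interval is significant at the
Bonferroni threshold `0.05 / (number of intervals at that scale)`. Whether
the scale-level decision should instead be a single pooled statistic was an
open point; the one-interval-at-Bonferroni rule is the default because it
uses exactly the declared correction and divisor, and it is logged as such.
Zero-margin tables are reported as not testable.

## Landscape divergence

Each chromosome is segmented into `n_bins = 10` bins of identical physical
size; crossover positions are taken relative to chromosome length, so
pooling chromosomes is concatenation. Binning is half-open (`[k/10,
(k+1)/10)`, the last bin closed at 1): a crossover exactly on an internal
edge goes right. The divergence of the binned landscape `P` from flatness
`Q = 1/10` is the plug-in `KL(P,Q) = Σ P_i ln(P_i/Q_i)` in **nats**, with
`0 ln 0 := 0`. An occupied-`P`/empty-`Q` bin is an explicit
infinite-divergence error, never capped; a 0.5-per-bin pseudocount is
available (`pseudocount = TRUE`) but off by default because the estimator is
the plain plug-in.

Inference:

* **Flatness p-value** — every crossover's relative position is redrawn
  uniformly (the flat null is scale-free across chromosomes), KL to flat is
  recomputed for each of `n_randomizations` (default 10,000) draws, and
  `p = #(null ≥ observed) / n_randomizations`. A p-value of 0 prints as
  `< 1/n_randomizations`.
* **Pairwise landscape divergence** — `KL(P_A, Q_B)` with both histograms
  from data; a bootstrap over individuals (both populations resampled,
  replicates paired by index) yields the 2.5%/97.5% quantile interval.
  Whether the original procedure resampled one or both populations per
  replicate is not determinable; both-resampled is implemented. Replicates
  hitting an empty-`Q` bin are redrawn and counted. KL is asymmetric; both
  directions can be requested.
* **Ordering test** — populations are ranked by KL-to-flat; for each pair
  the raw p is `k/B`, the fraction of index-paired bootstrap replicates
  whose ordering reverses the observed one (the pairing across independent
  streams is itself a documented choice — nothing in the procedure requires
  dependence). Bonferroni multiplies by the number of pairs actually
  compared; compact letters (insert-and-absorb) summarise the adjusted
  decisions, `a` for the highest KL.

## Interference divergence

Interference is probed through distances between successive crossovers
within a gamete, measured in **genetic** units and normalized by chromosome
genetic length (a relative-physical variant would be a trivial switch of
the position column; the genetic reading is the default because map
distance is the natural scale for interference). Genetic positions come
from linear interpolation of cumulative cM at the event midpoint. Units
with fewer than two crossovers contribute nothing; distances never span
chromosomes.

The "no interference" null shuffles crossovers across individuals within
each chromosome — a permutation of the pooled position multiset with every
gamete's crossover count held fixed. This exactly preserves the
recombination landscape and the count distribution while destroying
within-gamete correlations. `Q` pools the binned distances of all
`n_shuffles` (default 10,000) shuffles; the p-value is the fraction of
shuffles whose own distance histogram `P_S` has `KL(P_S, Q) ≥ KL(P, Q)`.

**Detection filtering (an implementation-forced design change).** Applied
to *called* crossovers, the raw permutation null is anti-conservative:
called events can never share an interval midpoint within one gamete (even
exchange counts are invisible to two-state genotyping), but a shuffled
gamete can receive duplicate midpoints, inflating the null's shortest
distance bin. In calibration runs at ν = 1 (300 gametes, 10 chromosomes,
1.5 Mbp marker spacing) the raw null rejected in three quarters of
replicates. The default (`detection_filter = TRUE`) therefore re-applies
the genotyping parity rule to shuffled gametes — positions with even
within-gamete multiplicity cancel pairwise — so the null describes
interference-free meiosis *as seen through the same detection process as
the data*. With the filter the test is calibrated (see the test suite's
calibration block) and power against ν = 8 is unaffected. The raw
behaviour remains available for sensitivity analysis.

The interference ordering test mirrors the landscape one, except the null
`Q` depends on the sample, so each bootstrap replicate recomputes `Q` on
its resample with a reduced shuffle count (`shuffles_per_replicate`,
default 100); recomputing the full-depth null inside every replicate is
configurable but computationally disproportionate. Resampled copies of one
individual are relabelled as distinct gametes so their crossover sets stay
separate units.

## The simulator

`simulate_population()` emulates the statistical structure the analyses
target, with defaults chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `genetic_length` | 1 Morgan | 2 crossovers per bivalent per chromosome — the 1–4 per-meiosis range of a crop chromosome |
| `physical_length` | 30 Mbp | a mid-size *Brassica*-like chromosome |
| marker spacing | 1.5 Mbp | one SNP per 1.5 Mbp, a ~170-marker genome over 10 chromosomes |
| `nu` | 1 | gamma shape; 1 = Poisson (no interference), larger = stronger interference |
| `thinning` | 1/2 | two of four chromatids carry each bivalent crossover |
| `marey` | `"flat"` | `"distal"` preset: anchors (0,0), (0.25,0.45), (0.5,0.5), (0.75,0.55), (1,1) — half the genetic length in each outer physical quarter |

Crossovers on the bivalent follow a stationary gamma renewal process with
inter-event distances `Gamma(shape = ν, rate = 2ν)` (mean 1/2 Morgan).
Stationarity is achieved by starting the chain 5 Morgans before the origin
and keeping events in `[0, L]`; the residual bias is negligible for
`ν ≤ 20` and this avoids the length-biased first-interval formula. There is
no obligate-crossover enforcement — the Poisson-limit checks require its
absence, and none of the analyses condition on ≥ 1 crossover. The Marey
warp maps genetic to physical positions by piecewise-linear interpolation
of user-supplied anchors, so arbitrary landscape shapes need no parametric
family.

The generator deliberately omits genotyping error, segregation distortion,
sex differences and homeologous exchange. Passing tests therefore
demonstrate correctness of the estimators and calibration of the tests
under clean two-state data — not robustness to miscalls or distorted
transmission, which real datasets must screen for upstream (the Mendelian
check and logging exist for that reason).

## Numerical and reproducibility choices

* All coordinates are bp, 0-based half-open internally (BED convention);
  event files sort by chromosome then start.
* Every randomized routine takes a `seed` and restores the caller's RNG
  state; the pipeline derives one named substream per stage from a single
  master seed, so changing one stage's resampling depth never perturbs
  another stage's draws. Identical config + seed reproduces every output
  byte for byte.
* Degenerate inputs fail loudly and specifically: empty populations,
  zero-crossover units (KL undefined), zero-margin tables (not testable),
  constant regressors (degenerate design), `r ≥ 0.5` intervals, markers
  outside chromosome bounds.
* Test and acceptance experiments run at the study scale — populations of
  200–300 gametes over 10 chromosomes, 1,000 randomizations/bootstraps/
  shuffles, 20–200 replicates per experiment — sizes chosen to give the
  binomial success criteria adequate resolution.

## Known limitations

* Crossover positions are interval midpoints; with sparse markers the
  binned landscape inherits interval-scale granularity.
* The minimal-count contract undercounts double crossovers within an
  interval, so genetic lengths are slight underestimates at wide spacing
  (Kosambi compensates only partially).
* KL-based ordering compares divergence magnitudes, not shapes: two
  populations can differ from flatness equally yet differently.
* The interference statistic summarises the pooled distance distribution;
  it does not estimate a gamma shape parameter or separate interfering and
  non-interfering crossover classes.
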