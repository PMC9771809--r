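---
title: "Modelling RNA in-line hydrolysis from sequence and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNA in-line hydrolysis from sequence and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rnadeg)
```

## The problem

Unmodified RNA cleaves itself: the 2'-OH of each ribose can attack the
adjacent phosphodiester bond (in-line hydrolysis), at a rate accelerated by
Mg^2+^, high pH and temperature. For an mRNA therapeutic this intrinsic
chemistry bounds shelf stability, and the rate at each linkage depends
strongly on local sequence and secondary-structure context — unpaired
nucleotides, and particular loop geometries, degrade fastest. This package
implements the modelling, scoring and dataset-curation machinery used to
study that process at single-nucleotide resolution with high-throughput
probing data: per-construct records carrying a SHAPE reactivity channel and
up to four accelerated-degradation channels (10 mM Mg^2+^ at pH 10 or at
50 °C, and the corresponding Mg^2+^-free 7-day conditions), each with
per-position uncertainty estimates.

## Structure features

Measured constructs come with a dot-bracket secondary structure and, from
it, a per-position loop-type string over the bpRNA alphabet: `S` stem,
`H` hairpin loop, `B` bulge, `I` internal loop, `M` multiloop, `X`
exterior-loop run between helices, `E` exterior run touching a sequence
end. `parse_dotbracket()` builds the pair table, `annotate_loop_types()`
derives the classes directly from it (no external annotation tool is
invoked; pseudoknot layers and base multiplets are out of scope), and
`graph_distance_matrix()` computes hop distances over the
backbone-plus-pair-edge graph, the proximity embedding commonly fed to
structure-aware models. `unpaired_probability()` condenses an upstream
base-pair probability matrix to a per-position unpaired probability.
Folding itself is deliberately upstream: any thermodynamic engine's output
can be supplied.

## The windowed linear model

`degscore()` fits, per measurement channel, a linear model of the
measurement at position $i$ in terms of one-hot indicators of the
nucleotide identity ($n \in \{A,C,G,U\}$) and loop type
($s \in \{H,E,I,M,B,S\}$) at every offset $k \in [-w, w]$:

$$Y_i = \sum_{k=-w}^{w} \sum_{n} \beta_{k,n} I_{i+k,n}
      + \sum_{k=-w}^{w} \sum_{s} \beta_{k,s} I_{i+k,s} + \beta_0 .$$

With the default half-width $w = 12$ the model has
$(2w+1)\times 10 + 1 = 251$ parameters. The exterior class `X` is encoded
as `E` by default, reflecting the biophysical similarity of the two
exterior categories; offsets falling outside the sequence contribute
all-zero blocks, which keeps the design linear and is the conventional
boundary treatment for windowed featurizations. Only the scored 5' prefix
of each construct (68 of 107 nt in the standard design; the 3' remainder
is barcode/primer) enters the fit, but predictions are always produced for
the full sequence so that downstream aggregation can capture interactions
with unscored regions.

Estimation is least squares with an L2 penalty `lambda` on the slopes; the
intercept is never penalized. The default `lambda = 0.1` is a deliberately
mild, scale-free shrinkage — with thousands of scored positions per fit the
estimate is data-dominated, and the penalty mainly stabilizes the
structurally collinear design discussed next. `method = "xgb"` trains a
gradient-boosted tree regressor (via xgboost, single-threaded and seeded,
hence reproducible) on the identical feature columns, for contexts where
the linear form underfits.

### Identifiability of the window design

The one-hot window design is exactly rank-deficient, for structural
reasons: within every offset $k$ the four sequence indicators and the six
loop indicators each sum to the same in-bounds flag (2w+1 dependencies);
at offset 0 that flag is the intercept column (one more); and in the
scored-prefix regime, where scored positions end at least $w$ nucleotides
before the 3' end, every non-negative offset is always in-bounds, tying a
further $w$ block-sums to the intercept. At `lambda = 0` the fit therefore
returns the minimum-norm least-squares solution (with a warning naming the
rank). Coefficient vectors are only identified up to these null
directions; predictions are identified, always. The synthetic generator
plants its coefficients in the corresponding canonical form — projected
onto the orthocomplement of the known null directions — which is what makes
exact parameter recovery a meaningful test rather than an impossibility.

## Whole-molecule stability

The overall degradation rate of an mRNA is the sum of its per-linkage
rates, $k_\mathrm{deg}^\mathrm{mRNA} = \sum_i k_\mathrm{deg}^i$, and its
half-life under first-order decay is
$t_{1/2} = \ln 2 / k_\mathrm{deg}^\mathrm{mRNA}$, reported in the
reciprocal unit of the input rates (`total_rate()`, `half_life()`).
Per-nucleotide predictions are used directly as linkage proxies, matching
how per-nucleotide model outputs are summed in practice.
`sum_region_predictions()` sums full-sequence predictions over a stated
window (typically the RT-PCR-captured 5'UTR + CDS region), optionally
length-normalized for comparing constructs of different lengths.

## Scoring

`mcrmse()` implements the multi-channel competition metric: per channel,
the RMSE pooled over every scored nucleotide of every construct in the
dataset, then the arithmetic mean across channels. `sn_ratio()` is the
mean over channels of the mean over positions of $\mu/\sigma$.
`within_error_fraction()` reports the fraction of positions where the
absolute prediction error is *strictly* below the reported uncertainty;
for Gaussian errors an error-free predictor attains
$\mathrm{erf}(1/\sqrt{2}) \approx 68.3\%$, the natural ceiling against
which model agreement is judged. `motif_aggregate()` pools values by
structural context, with two derived bins chosen for their biochemical
salience: triloops (hairpin loops of exactly 3 nt, the most reactive
motif) and the symmetric/asymmetric split of internal loops (equal vs
unequal side lengths); both definitions are configurable rule sets.
`rank_correlation()` returns Spearman's rho with a two-sided p-value (the
asymptotic t approximation by default; the exact distribution is available
for small tie-free samples).

## Curation

`apply_sn_filter()` flags rather than drops: a record passes when every
value across the degradation channels lies strictly inside
(0.5, 20) and the SHAPE-channel signal-to-noise ratio strictly exceeds
1.0. The min/max screen defaults to the degradation channels only (the
SHAPE channel is screened via its SN ratio), and only channels actually
present on a record are consulted, accommodating reduced-channel datasets.

`cluster_sequences()` guards blind-test integrity against near-duplicate
designs: pairwise normalized Levenshtein distances (edit distance over the
longer length — robust to mixed 107/130-nt datasets; Hamming available for
equal lengths), Ward agglomeration, and a cut at cophenetic height 0.5.
Applying Ward's criterion to a precomputed non-Euclidean distance is a
known abuse — we follow the convention of common clustering libraries
(`hclust` method `ward.D2`) and provide average linkage as a well-defined
alternative. Dendrogram heights are linkage-dependent, so the cut height
is a tunable of the procedure, not a sequence-identity percentage.
`assign_splits()` then enforces the quarantine rule: every member of a
cluster with at most three members goes to the private test set, the
private set is topped up with one random member from each of a random
selection of larger clusters, and the remainder is randomly partitioned
into training and public test sets; everything is seeded and reproducible,
and infeasible targets fail loudly with the achievable bound.

## Ensembling

`average_predictions()` is the plain weighted mean of aligned prediction
sets. `ga_select()` searches subsets of at most 10 of up to ~100 candidate
models and their mixing weights by a genetic algorithm minimizing MCRMSE
on the optimization split. The GA hyperparameters (population 64, 200
generations, mutation rate 0.05, tournament selection, 2 elites) are
package defaults, all configurable; chromosomes carry a membership mask
plus continuous weights renormalized over the active members, with a
uniform-weight mode available. The initial population is seeded with the
best single candidate and elites are carried unchanged, so the returned
ensemble provably never scores worse than the best single model on the
optimization split; scoring the spec on a held-out split (via
`ensemble_predictions()`) is kept separate precisely so that ensemble-level
overfitting is observable. Ties are broken toward fewer members, then
lexically.

## The synthetic benchmark

`make_dataset()` generates datasets with the statistical structure the
pipeline assumes, so every stage is testable without downloads:

* 107-nt constructs scored over their first 68 nt (the longer-round
  regime, 130/102, is a parameter change), with a constant `GGAAA` 5'
  prefix and target GC content 0.5;
* structures from a stochastic nested sampler constrained to AU/GC/GU
  pairs and hairpin loops of ≥ 3 nt — structurally valid input features
  without a folding engine, with a hook for externally computed MFE
  structures wherever a dot-bracket is accepted;
* per-channel signal from planted canonical-form linear models
  (intercept 2, slope sd 0.05) plus motif offsets (+0.6 triloop, +0.3
  asymmetric internal loop, +0.1 symmetric — encoding the observed
  ordering) and a shared per-position latent component (sd 0.1) that
  correlates the channels;
* measurement noise with per-position sd
  $\sigma = 0.05 + 0.15\sqrt{\max(y, 0)}$, a counting-noise-like
  heteroscedastic model whose floor keeps every $\sigma$ positive for SN
  computation; reported error arrays are exactly these sds, so the
  generator's data are calibrated by construction;
* optional injection of filter failures (errors inflated until the SN
  ratio falls well below 1) and near-duplicate sequences (two point
  mutations on a copy of an earlier construct) to exercise curation.

What the generator does *not* emulate: thermodynamically realistic
folding, reverse-transcription attenuation artefacts, structure/data
disagreement (misfolded constructs), and the long tail of human design
idiosyncrasy in real crowdsourced libraries. Tests passing on this
benchmark certify the machinery — metrics, fits, curation guarantees —
not predictive accuracy on real chemistry.

## Numerical choices and degenerate inputs

* Positions are 1-based in the R API; serialized CSVs are 0-based and say
  so in a header comment.
* Unbalanced brackets and alphabet violations fail with the offending
  position; validation errors name the record and field.
* `lambda = 0` uses an SVD pseudo-inverse with tolerance
  `max(dim) * eps * d[1]`; rank deficiency warns and returns the
  minimum-norm solution.
* `sn_ratio()` refuses non-positive sigmas unless told to exclude them;
  `within_error_fraction()` is strict, so zero error can never "agree".
* Empty regions, empty masks, constant inputs to rank correlation, and
  infeasible split targets are errors, not silent results.
* Clustering is deterministic given input order; GA and splits are
  deterministic given their seeds.

## Problem sizes used in the test suite

The suite exercises every guarantee at deliberately modest scale: window
half-width 2 (51 parameters) for most fitting tests with ~10–100
constructs of 40–50 nt; the exact-recovery check runs the full published
geometry (w = 12, 251 parameters, 20 × 68 = 1360 scored rows ≥ 5× the
parameter count); Monte-Carlo coverage uses 10^5 draws; the structure
sampler is audited over 1,000 draws. These sizes were chosen as the
smallest at which each property is sharply testable.

## Limitations

The linear model is a baseline by design: it cannot represent
interactions (the boosted variant partially can) and its coefficients are
only identified up to the documented null directions. Loop annotation
covers nested structures; pseudoknot pair layers parse and enter the
structure graph but are not classified into loop types. The curation
module reproduces the procedure, not any historical membership, which
would require the original data and unstated metric details.
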