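---
title: "Predicting bacterial small RNAs with feature ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial small RNAs with feature ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial small non-coding RNAs (sRNAs) are regulators of roughly 45–500 nt
that act by base pairing with their targets. Experimentally cataloguing them
is expensive, so a standard computational formulation treats sRNA discovery
as binary sequence classification: curated sRNAs are positives, and
"pseudo-sRNAs" — fragments cut at the same genomic coordinates from a
residue-shuffled genome — are negatives. The shuffle preserves
mono-nucleotide composition while destroying all higher-order sequence
structure, so whatever separates the classes must live in k-mer and
sequence-order statistics. `srnaens` implements that formulation end to
end: dataset construction, seventeen feature encoders, per-feature
classifiers, and two ensembles that combine them.

```{r, eval = FALSE}
library(srnaens)
```

## Benchmark construction

`build_benchmark()` extracts positives from a genome at 1-based inclusive
coordinates (minus-strand intervals are reverse complemented), removes
exact duplicate sequences, and draws negatives by shuffling the whole
genome `r` times (Fisher–Yates, explicit seed) and re-extracting at the
kept coordinates, giving positive:negative ratios 1:1 through 1:r. Two
conventions are worth stating:

* **Duplicate removal.** The redundancy criterion for curated sRNA sets is
  rarely published; we use exact residue-string identity (first occurrence
  wins) and expose a `key` hook in `deduplicate()` for similarity-based
  schemes.
* **Negative coordinates.** Negatives are extracted at the coordinates of
  the positives *kept after deduplication*, so `|neg| = r × |pos|` holds
  exactly.

Ambiguity codes (`N` and friends) are rejected at every entry point rather
than skipped: all dimension arithmetic below assumes a strict 4-letter
alphabet. `U` is silently mapped to `T` since sRNA databases mix RNA and
DNA alphabets.

## The seventeen features

Every encoder maps a sequence of length $L$ to a fixed-dimension numeric
vector; windows are the $L-k+1$ overlapping k-mers.

| Group | Specs | Dimension | Notes |
|---|---|---|---|
| spectrum | F1–F5, $k=1..5$ | $4^k$ | window counts / window count |
| mismatch | F6–F8, $(k,1)$ for $k=3,4,5$ | $4^k$ | Hamming-ball counts |
| RevcKmer | F9–F13, $k=1..5$ | $4^k/2$ (odd $k$), $(4^k+4^{k/2})/2$ (even) | strand-symmetric |
| pseudo-composition | F14–F17 | $16+\lambda$, $64+\lambda$, $16+6\lambda$, $64+12\lambda$ | sequence-order factors |

Counts are normalized to frequencies by the window count (raw counts are
available via `normalize = FALSE`). K-mer order is lexicographic with
A<C<G<T, and the canonical RevcKmer representative is the lexicographic
minimum of a k-mer and its reverse complement; neither convention is
forced by the mathematics, so both are fixed and documented here for
reproducibility.

The **(k,m)-mismatch profile** credits each window to every k-mer within
Hamming distance $m$ (the exact match is the $j=0$ mismatch term, so
$(k,0)$ is identically the spectrum). Rather than enumerating
neighborhoods per window, `mismatch_profile()` computes all Hamming-ball
sums at once by inclusion–exclusion over position subsets
($\mathrm{ball}_m = \sum_{|T|\le m} \alpha_{|T|} M_T$, where $M_T$
marginalizes the count tensor over positions $T$), which is exact and
vectorizes over the whole dataset; the naive per-window enumeration
survives only as the test oracle.

The **pseudo nucleotide composition** features extend di-/tri-nucleotide
frequencies $f_v$ with correlation factors over standardized
physicochemical property values $P_u(\cdot)$. Parallel-correlation
variants use one factor per lag,
$\theta_j = \frac{1}{M-j}\sum_i \frac{1}{N_p}\sum_u (P_u(O_i)-P_u(O_{i+j}))^2$,
and series-correlation variants one factor per (lag, property) pair,
$\tau_{j,u} = \frac{1}{M-j}\sum_i P_u(O_i)P_u(O_{i+j})$; both are folded
into the vector as $w\,\theta / (1 + w\sum\theta)$ next to the scaled
frequencies, so parallel-variant components sum to exactly 1 (series
components need not, because $\tau$ can be negative). Defaults:
$\lambda = 9, 1, 15, 1$ for PCPseDNC, PCPseTNC, SCPseDNC, SCPseTNC
(selected upstream by cross-validated grid search; `grid_search_lambda()`
re-runs that selection on any dataset), and weight $w = 0.05$, the
conventional default of pseudo-composition software — the literature
rarely states it, and results are insensitive to it at these $\lambda$.

**Property tables.** The published index sets behind the "6 dinucleotide /
12 trinucleotide properties" dimensionality are inherited from
pseudo-composition software rather than printed in papers. The package
ships *synthetic* tables (`inst/extdata/*_properties_synthetic.tsv`,
generic names P1..P6 / T1..T12) whose values are fixed arbitrary draws:
they pin the dimensions and exercise the correlation machinery, and they
are z-scored across the alphabet at load (population moments), after which
only each index's relative profile matters. Users analysing real genomes
should substitute measured indices (twist, tilt, roll, slide, ...) via
`load_property_table()`; a constant column is rejected as degenerate.

The shortest curated sRNAs are ~45 nt, and all seventeen default specs
accept any sequence of length ≥ 45 (the binding constraint is
$\lambda \le L - 2$ for dinucleotide variants).

## Base predictors

`train_base_predictor()` fits one classifier per feature. The default
engine is a 200-tree random forest (probability = fraction of trees voting
positive); an RBF-kernel SVM (Platt-calibrated probabilities — the margin
itself is not a probability) and a one-hidden-layer rectifier network are
drop-in alternatives, and the ensembles interact with all engines only
through `predict_proba()`, so the engine choice changes no interface.
Un-stated hyperparameters stay at library defaults. Every fit seeds the
RNG explicitly; identical data + seed reproduce probabilities exactly.

## WAEM: GA-weighted averaging

The weighted average ensemble predicts
$F(x) = \sum_{i=1}^{N} w_i f_i(x)$ with $\sum w_i = 1$, $w_i \ge 0$.
Weights are found by a genetic algorithm maximizing the AUC of $F$ on the
training data (defaults: 100 chromosomes, 200 generations). Design choices
where the recipe is genuinely open:

* **Chromosome encoding and repair.** Real vectors of length $N$, repaired
  to the simplex by clipping at zero and renormalizing after mutation;
  crossover is an arithmetic (convex) combination, which cannot leave the
  simplex.
* **Adaptive operators.** Crossover and mutation probabilities interpolate
  linearly between configured bounds according to a chromosome's fitness
  relative to the population mean and maximum — fitter chromosomes are
  perturbed less, matching the adaptive-GA idea the method descends from.
* **Corner seeding + elitism.** The initial population contains the $N$
  simplex corners, so the optimum can never fall below the best single
  predictor, and elitism (1 by default) makes the best-so-far fitness
  monotone non-decreasing — both are asserted by tests.
* **Fitness probabilities.** "AUC on the training data" is ill-posed for
  random forests, whose in-sample probabilities are near-degenerate (every
  chromosome would score ≈ 1). We use out-of-bag probabilities as the
  honest training-data estimate; in-sample probabilities are used for
  engines without an OOB notion.

## NNEM: two-stage neural stacking

The seventeen features merge into four group vectors — SP (1364), MP
(1344), RCK (692), PNC (272). Stage 1 fits one rectifier MLP per group
(default hidden width 700, cross entropy + L2 with coefficient 0.3 —
the feature dimension exceeds typical dataset sizes, hence the penalty),
each emitting a single sigmoid output node; stage 2 fits a 10-hidden-node
MLP on the resulting 4-vector (cross entropy, no penalty). The MLP is
implemented in-package (gradient-checked backprop, full-batch Adam,
He initialization, seeded) because the stated architecture — rectifier
hidden layer with an sklearn-style penalty $\frac{\lambda}{2n}\|W\|^2$ —
is not available in the classical R neural net tooling. Group features
are z-scored with statistics fitted on the training folds only.
Stage-2 inputs are stage-1 outputs computed on the same training set (the
literal stacking recipe); this risks optimistic stage-1 inputs, which is
why the cross-validation harness refits both stages inside every fold.
Stage 2 refuses anything but exactly four group inputs.

## Evaluation

`run_cross_validation()` performs repeated stratified 5-fold CV (default
20 runs with re-shuffled folds on a fixed dataset; whether negative sets
should also be regenerated per run is a dataset-construction question we
deliberately keep out of the CV loop). Per-fold class counts deviate from
exact proportionality by at most one instance. All state — encoders are
stateless, but scalers, forests, GA weights and both NNEM stages are not —
is fitted on training folds only, and a guard asserts train/test
disjointness in every fold. Metrics: SN, SP, ACC at threshold 0.5
(probability ≥ 0.5 predicts positive; zero denominators surface as `NA`,
never 0) and AUC as the primary, threshold-free metric, computed as the
Mann–Whitney rank statistic with midrank tie handling — exactly the
all-pairs probability that a positive outscores a negative, ties counting
one half. Fold metrics are averaged within runs, then across runs.
`paired_t_test()` compares per-run AUCs of two methods and reports a
degenerate marker instead of a p-value when the differences have zero
variance. Reference baselines are provided as configurations:
`baseline:carter` (SVM on concatenated 1- and 2-spectrum, i.e. mono + di
composition) and `baseline:barman` (SVM on the 3-spectrum).

## The synthetic benchmark

`gen_planted_dataset()` emulates the statistical structure of the real
task without downloads: positives come from an order-k Markov model
(default k = 3) whose conditional distributions are tilted away from
uniform, negatives are per-sequence shuffles of sequences generated by the
same process — matched mono-nucleotide composition, no higher-order
signal, exactly the contract of shuffle-derived pseudo-sRNAs. Effect size
is parameterized as the KL divergence (nats) of each tilted conditional
from uniform, so "strong" and "null" are reproducible statements; the
default 0.5 nats is a strong, cleanly recoverable bias, and 0 is an exact
null. Lengths are drawn log-uniform on [45, 500] nt to mimic the
right-skew of curated length distributions (the exact empirical
distribution is not recoverable from published histograms; the bounds are
the documented, adjustable condition). An optional lag-copy signal
(position i copies position i−lag with a given probability) plants
autocorrelation that only pseudo-composition features with
$\lambda \ge$ lag can exploit, which is how the λ grid search is
validated.

What passing on this benchmark does *not* show: real sRNAs differ from
genomic background in promoters, terminators and secondary structure, not
only in k-mer statistics, and real negatives are not perfect shuffles.
The synthetic results validate the machinery (encoders, leakage-free CV,
ensemble optimization), not biological transferability.

## Numerical choices and problem sizes

* Mismatch ball sums are exact integers rescaled by the window count; the
  inclusion–exclusion route is algebraically identical to per-window
  enumeration (tested to 1e-12).
* Property standardization uses population moments over the 16/64-letter
  alphabet, under which a two-valued index maps to ±1.
* GA selection uses roulette on min-shifted fitness; an all-equal
  population degenerates to uniform selection with the elite preserved.
* Zero-variance feature columns are centered and left unscaled by
  `fit_scaler()` (they carry no information either way).
* The shipped test-and-acceptance workload uses 200+200 synthetic
  sequences, one run of 5-fold CV, GA population 20 × 30 generations and
  stage-1 hidden width 50 — a deliberately scaled-down mirror of the
  reference configuration (100 × 200 GA, hidden 700) chosen so the whole
  pipeline, not a subsample of it, runs in minutes on one core; the
  ensemble–vs–best-base comparisons are unaffected because all methods see
  the same folds.

## Known limitations

* The shipped property tables are synthetic stand-ins; conclusions about
  *which* physicochemical index matters require measured tables.
* `extract_intervals()` operates on a single genome record; multi-record
  genomes are handled per record, never concatenated.
* SVM probabilities inherit Platt-calibration folklore (small-sample
  calibration noise); the random forest default sidesteps this.
* With strongly imbalanced ratios the 0.5 threshold drives SN down while
  AUC is unaffected; threshold selection is left to the user.
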