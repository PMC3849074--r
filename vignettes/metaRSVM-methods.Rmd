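---
title: "Classifying metagenomes by k-tuple signatures and recursive SVM"
author: "metaRSVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metagenomes by k-tuple signatures and recursive SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaRSVM)
```

## The problem

Comparing microbiome samples from unassembled shotgun sequencing data
usually goes through alignment to reference catalogues, which fails for the
large fraction of microbial sequence with no close reference, or through
unsupervised signature clustering, which only reveals the *dominant*
structure in the data. When the question is a predefined binary contrast —
diseased versus healthy hosts, one environment versus another — the signal
of interest may be far from dominant. metaRSVM addresses that setting with
supervised learning on alignment-free features: k-tuple (k-mer) frequencies
counted directly from the short reads.

## The feature space

For a tuple length $k$, all $4^k$ DNA words are candidate features. Every
read of length $L$ contributes $\max(0, L-k+1)$ overlapping windows and the
window counts are summed per sample. Two standardisation steps follow:

1. **Depth normalisation.** Each sample's count vector is divided by its
   total window count, removing the effect of unequal sequencing depth.
2. **Per-feature z-scoring.** Each feature is centred and scaled to mean 0,
   variance 1 across the samples used for fitting.

Words are counted literally — no reverse-complement collapsing. Because
reads are sequenced from both strands, a discriminative motif surfaces
twice, as itself and as its reverse complement, and the selection results
show exactly that (see the seed-recovery test). Reads containing any
non-A/C/G/T character are discarded whole, generalising the usual rule for
`N` bases to all IUPAC ambiguity codes; lowercase bases are uppercased.

Two numerical choices are deliberate and fixed. The z-score uses the
*population* (divide-by-$n$) standard deviation, so the fitted samples have
variance exactly 1. Features constant across the fitting samples have no
defined z-score; they are dropped from the model and the drop is recorded
in the standardizer so that held-out samples are reduced consistently.

## Recursive SVM

A soft-margin linear SVM is trained on the standardized features; the
linear kernel deliberately keeps model capacity low, since the sample size
(tens) is dwarfed by the feature count (up to $4^8$). With dual
coefficients $\alpha_i \ge 0$ and labels $y_i \in \{-1,+1\}$, the decision
function is

$$g(x) = \mathrm{sgn}(w \cdot x + b), \qquad w = \sum_i \alpha_i y_i x_i .$$

Each feature is then scored by its class-mean difference weighted by its
SVM weight,

$$s_j = w_j\,(m^+_j - m^-_j),$$

where $m^{\pm}_j$ are the means of feature $j$ over the two classes of the
training samples. Selection proceeds down a descending ladder of feature
counts — all features, then 1000, 500, 200, 100, 50, 30, 20, 10, 5 — keeping
the top-scoring features at every step, so the subsets are nested. When
$4^k$ is smaller than a ladder entry the ladder is truncated: with $k=3$ it
becomes 64, 50, 30, 20, 10, 5. Ranking ties are broken by larger $|w_j|$ and
then lower column index, making selection fully deterministic.

Two conventions worth noting: a decision value of exactly zero predicts
class +1, and at every ladder level one model is trained and used both for
scoring and for prediction at that level (no retrain between the two).

The soft-margin penalty defaults to $C = 1$ and is exposed as a parameter.
On the benchmark simulations the results are insensitive to $C$ across
orders of magnitude because the classes are (nearly) separable after
standardisation.

### Implementation note: training in Gram-factor space

The dual problem of a linear SVM depends on the data only through the Gram
matrix $K = XX^\top$. When the feature count exceeds the sample count, the
package trains libsvm on an exact $n$-column factor $B$ with
$BB^\top = K$ (from the eigendecomposition of $K$): the support vectors,
dual coefficients and bias are identical to training on $X$ directly, while
the optimiser never touches the $4^k$-dimensional rows. The primal weights
are then recovered as $w = \sum_i \alpha_i y_i x_i$ from the original rows.
This is an exact reformulation, not an approximation, and it is what makes
leave-one-out over thousands of features practical.

## Leakage-free cross-validation (CV2)

Accuracy is estimated by leave-one-out cross-validation in which the
held-out sample is removed *before* standardisation and before any feature
ranking: in each fold the standardizer and the entire recursive selection
are refit on the remaining samples only, and the held-out sample is
predicted at every ladder level. Selecting features on all samples first
and cross-validating afterwards looks similar but is optimistically biased
— the held-out sample has already influenced which features the model gets
to see. The package ships that biased protocol as `loocvCV1()` purely as a
contrast, and a property test verifies the optimism on label-permuted data.

Standardisation scope is configurable: `"train_only"` (the default) refits
the z-scoring inside each fold, which is the leakage-free choice;
`"global"` standardises once across all samples, which matches the common
simpler practice at the cost of a mild information leak. All results in
the acceptance checks use the default.

Inside a fold, the available (non-constant) feature count can fall below a
ladder level — relevant only for tiny fixtures. The rule is: a level that
asks for more features than the fold has simply uses all available ones.

After cross-validation every fold owns its own feature sets, so the final
deliverable is produced by rerunning the recursive selection on *all*
samples (`finalModel()`), yielding a unique word list and model that can be
serialized to JSON and applied to new samples.

## The best-result rule

Experiments scan $k$ over a grid and all ladder levels. The summary picks,
in this priority order: levels at or below 200 (small feature sets are the
point of the exercise; the cap is inclusive since a level of exactly 200
is a legitimate working model), then highest accuracy, then the smallest
level, then the shortest tuple length.

## Permutation significance

With few samples and an enormous feature space, impressive accuracy can
arise by chance. The permutation test reruns the *entire* CV2 pipeline —
over the whole k grid, with per-fold standardisation and selection — on
datasets whose labels have been randomly reassigned (class sizes
preserved), recording each permuted dataset's best accuracy. The p-value is
the fraction of permutations reaching the observed accuracy, counting ties
as extreme, so the smallest reportable value is $1/n_\text{perm}$; a zero
count is reported as the bound `< 1/nPerm`. Count and frequency matrices
are reused across permutations — labels do not enter counting or depth
normalisation, so this is an exact optimisation. With `"train_only"`
scope the standardizer is refit inside every fold of every permutation,
consistent with the CV2 contract.

## The simulator

The generator emulates the simplest setting in which alignment-free
supervised classification can be studied end to end:

* **Background genomes**: i.i.d. bases, uniform by default, length
  $n = 10{,}000$; 25 genomes per class.
* **Seeds**: short motifs inserted by overwriting $l$ bases at positions
  drawn uniformly (with replacement) from $1..n-l+1$. The per-seed
  insertion count is $\mathrm{round}(\text{density} \cdot n / l)$, rounding
  half away from zero — the count closest to the nominal density, which is
  defined as $l \times \#\text{seed} / n$. Later insertions may overwrite
  earlier ones; the ground-truth table records insertion events, not
  surviving copies.
* **Reads**: error-free 50 bp reads at 10-fold coverage
  ($\mathrm{round}(Cn/\beta)$ reads per genome), start positions uniform
  with replacement, strand fair-coin, minus-strand reads
  reverse-complemented. Because sequencing is error-free, this elementary
  sampler is exactly equivalent to a full read simulator run with its error
  model switched off.

Design 1 inserts seeds into class 2 only; design 2 gives both classes their
own disjoint random seed sets. The standard sweeps cross seed counts
(3/5/10 per class, or the pairs 1/1 through 10/10) with seed lengths 4–7.

What the simulator does *not* emulate: sequencing errors, quality values,
paired ends, fragment-length distributions, taxon abundance structure, GC
bias. Passing the benchmark therefore shows that the pipeline recovers
planted compositional signal under ideal sequencing — it does not by itself
demonstrate robustness to real-data noise, which is why the package keeps
the protocol (CV2, permutation) strict.

All randomness flows from one integer seed per dataset; named child streams
(`childSeed()`) keep the simulator, sweep and permutation streams
independent. Datasets are byte-reproducible from their configuration.

## Problem sizes used in the checks

The packaged checks run the flagship experiment (50 samples, $k=6$) at full
published scale, and the four sweep reproductions over $k \in \{4..7\}$
rather than the full $3..8$ grid. The sweep metric — how many experiments
reach a perfect best result — is insensitive to the omitted tuple lengths:
where $k=3$ can win it does so in experiments that are also perfect at
some $k \in 4..7$, and $k=8$ only surfaces in the weakest corner (short
seeds at the lowest density), where no tuple length reaches 100%. Dropping
them roughly halves the runtime of a sweep. Unit and property tests use
miniature configurations (hundreds
of bases, a handful of samples) because the properties they check —
conservation, nestedness, leakage-freedom, calibration — are
scale-invariant.

## Known limitations

* Binary classification only; no multiclass extension, probability
  calibration or non-linear kernels.
* Dense feature matrices limit $k$ to 10 (and practically to 8 for 50
  samples).
* The score $s_j = w_j(m^+_j - m^-_j)$ is the single supported ranking
  criterion; voting-based final classifiers are deliberately out of scope.
* The p-value floor is $1/n_\text{perm}$; claims below that require more
  permutations.

## A minimal session

```{r example, eval = FALSE}
cfg <- designSimulation(0, 5, seedLength = 6, density = 0.005, rngSeed = 7)
ds  <- generateDataset(cfg)
kte <- toFrequencies(buildCountMatrix(ds$samples, k = 6))
cv  <- loocvCV2(kte)
accuracies(cv)                      # per-level LOOCV accuracy
best <- bestResult(cv)
fm   <- finalModel(kte, best@level) # all-samples refit
featureWords(fm)                    # the selected k-tuple words
```
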