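---
title: "Methods: window-based phosphosite prediction with bagged classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based phosphosite prediction with bagged classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phospred)
```

## The problem and the model

Protein phosphorylation is the most intensively studied posttranslational
modification: kinases attach phosphate groups to serine, threonine or
tyrosine side chains, switching signalling pathways on and off.
Experimentally mapping phosphosites is expensive, so sequence-based
prediction remains a routine first pass. phospred casts the task as binary
classification of candidate residues: every S/T (or Y) in a protein is a
candidate, labelled positive when a Phosphorylation annotation exists at
that position.

Each candidate site is represented by its sequence window — the inclusive
peptide `[p - w, p + w]` around the site, padded with `-` beyond the
sequence ends — and encoded as a fixed-layout feature vector with three
blocks:

1. **KNN scores.** For each of several neighbourhood sizes k, the fraction
   of the k reference windows most similar to the query that are known
   phosphosites. Similarity between two windows is the position-wise sum of
   BLOSUM62 substitution scores, with pads and non-standard letters
   contributing zero. k is expressed as a *fraction* of the reference-set
   size, `k = max(1, round(f * n))`, so a model trained on 5,000 windows
   and one trained on 50,000 use comparable neighbourhoods. Defaults:
   f ∈ {0.0025, 0.005, 0.01, 0.02, 0.04, 0.08}.
2. **Disorder.** The mean intrinsic-disorder score over the window.
   Phosphosites are strongly enriched in disordered regions, which makes
   this a cheap, biologically grounded feature.
3. **Amino-acid frequencies.** The 20-vector of residue frequencies over
   the non-pad window positions.

With the defaults (6 KNN fractions) a feature vector has 6 + 1 + 20 = 27
entries. The layout travels with every trained model so that training and
prediction can never silently disagree about feature order.

## Handling class imbalance: bootstrap aggregating

Real site data are extremely unbalanced (a few percent positives). Rather
than reweighting one monolithic classifier, phospred trains a **bagging
ensemble**: each round draws all positives (up to a cap of 2,000) and an
equal number of negatives, sampled without replacement, and fits a base
learner; the ensemble score is the arithmetic mean of the rounds' decision
values. Rounds differ through per-round derived seeds, so with 20 rounds
(the default) most negatives are seen by some round even though each round
is balanced. Sampling *with* replacement (the classical bootstrap) is
available via `bagging_config(replace = TRUE)`; without-replacement
subsampling was chosen as the default because with `negative_ratio = 1` it
makes every round exactly class-balanced, which is the purpose of the
procedure here.

Two base learners satisfy the binary-classifier contract (train on a
feature matrix, emit deterministic real-valued decision values, serialize):

* a **linear soft-margin SVM** (squared hinge loss, `C = 1`, fitted by
  BFGS on the convex objective — deterministic from a zero start), and
* an **AdaBoost** learner over depth-1 threshold stumps (50 rounds),
  usable *as the bagging base learner* — the composition of a bootstrap
  procedure with a boosting classifier.

Features are standardized per column with statistics stored in each base
model. Aggregation averages raw decision values rather than calibrated
probabilities: the mean commutes with the quantile mapping used for
specificity calibration and avoids extra probability assumptions.

## Continuous stringency via specificity calibration

Users rarely want a hard-coded threshold; they want "show me predictions at
95 % specificity". During training, phospred runs 5-fold cross-validation:
for each fold a bagging ensemble is trained on the other folds and the
held-out fold is scored. The held-out **negative** scores are pooled into
an empirical calibration curve. Specificity at threshold t is the fraction
of calibration negatives scoring below t, linearly interpolated between
order statistics at knots `(s_(i), (i - 0.5)/n)` — the exact inverse of the
type-5 quantile, which `threshold_for_stringency()` uses in the other
direction. This makes stringency a continuous dial: any value in (0, 1)
maps to a threshold and back.

Important subtleties:

* KNN features of training windows are computed **leave-self-out** (the
  window itself is removed from the reference before ranking); without
  this, every training positive finds itself as its own nearest neighbour
  and training scores are trivially inflated, which would corrupt the
  calibration curve.
* The curve is built only from scores produced by ensembles that never saw
  the scored fold, so calibration is honest by construction; the
  acceptance suite checks that the empirical false-positive rate at
  stringency 0.95 on fresh, never-seen negatives lands in [0.02, 0.08].
* Calibration is joint over all residue types of the model (an S/T model
  has one curve, not one per residue).

## Disorder providers

The original tooling in this niche wraps an external disorder predictor;
licenses make bundling one impossible. phospred instead treats disorder as
a pluggable provider: a `"disorder"` track stored in the PTM XML (computed
by any external tool) is used when present, and a built-in heuristic —
a published per-residue disorder-propensity scale averaged over a width-21
sliding window and passed through a logistic with steepness 4 — fills in
otherwise (`disorder_provider = "track_or_builtin"`). The heuristic is a
stand-in: it reproduces the coarse disorder signal (E/P/S/K-rich segments
score high, W/F/I/L-rich segments low) but not the accuracy of a trained
predictor. Providers `"track"` and `"none"` make the absence of a real
track an error, mirroring the run-disorder-prediction-first workflow.

## Dataset construction rules

`build_nonredundant_dataset()` applies three rules, in order: exact
duplicate (peptide, label) pairs collapse to one instance; a peptide seen
with both labels keeps only the positive (an unannotated site is an
unverified absence, a verified positive is evidence); and under the default
`phosphoproteins_only` policy negatives are drawn only from proteins with
at least one phosphosite, since never-assayed proteins contribute
unlabelled rather than negative evidence. Non-redundancy is exact-peptide
deduplication only — sequence-identity clustering would require an external
tool and is out of scope. Training requires at least 30 positives and
warns below 100.

## The synthetic world, and what a green test proves

The generator (`generate_proteome()`) states a fixed world: 200 proteins,
mean length 400 (geometric spread above a floor of 50), background
sequences from average proteome composition, 5 % of S/T positives, a
kinase-like planted motif (R at −3, P at +1) carried by 80 % of positives
and 5 % of negatives, and a disorder track elevated (mean 0.7 vs 0.4,
sd 0.15, width-11 smoothing, clipped to [0, 1]) around positives. The
motif is a plausible proline-directed/basophilic hybrid chosen purely to
create learnable signal; it asserts nothing about real kinases. Splits are
protein-level to prevent near-duplicate windows leaking across train/test.

A green end-to-end test therefore establishes that the pipeline recovers a
planted sequence+disorder signal (held-out AUC ≥ 0.85) and that
calibration is honest under i.i.d. sampling. It does *not* establish
real-proteome accuracy: real data have homology structure, compositional
biases, motif diversity and annotation noise the generator deliberately
omits.

## Numerical and design choices

* **Window half-width** w = 12 (25-mers), stored in the model; the
  field's common choices range from 7 to 15 and the value is configurable.
* **Ties in KNN ranking** are broken by ascending reference insertion
  order (a stable radix sort), making scores fully deterministic and
  permutation-invariant whenever similarities are distinct.
* **`round()`** follows R's round-half-even in `k = max(1, round(f n))`.
* **Model archives** are single RDS files rather than zip containers: RDS
  is the idiomatic R serialization, needs no external binary, and is
  byte-deterministic for identical inputs — which the determinism
  guarantee (identical inputs + seeds ⇒ identical archives) requires. The
  `created` timestamp is part of the training configuration (defaulting to
  the wall clock) so that fully specified configurations reproduce
  byte-identical archives.
* **Reference windows** (needed to recompute KNN features at prediction
  time) are embedded in the archive, with negatives down-sampled above
  20,000 windows to keep models portable.
* **Degenerate inputs**: empty FASTA files yield empty collections; a
  query protein without matching residues yields zero prediction rows; a
  dataset with no positives, a single-class training matrix, or a
  reference emptied by self-exclusion are errors with actionable messages.

## Known limitations

Only sequence windows, disorder and composition are modelled — no solvent
accessibility, secondary structure or kinase-family features. The built-in
disorder heuristic is far weaker than a trained predictor. Exact-peptide
non-redundancy does not remove homologous near-duplicates. Kinase-specific
models are trainable (supply kinase-specific annotation sets) but none are
shipped. File-format support covers FASTA, the package's PTM XML dialect,
UniProt XML (read) and Phospho.ELM-style reports (read); UniProt flat files
and network retrieval are out of scope.
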