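# phospred

Machine-learning prediction of protein phosphorylation sites, for
proteomics researchers who want to train **custom models from their own
phosphorylation datasets** (tissue-, disease- or kinase-specific) and to
tune prediction stringency continuously instead of accepting a fixed
cutoff.

## What it computes

Every serine/threonine (or tyrosine) residue is a candidate site,
represented by its ±w sequence window (default 25-mers) and encoded as a
27-dimensional feature vector:

* **KNN scores** — for k = ⌈f·n⌉ over fractions
  f ∈ {0.0025, …, 0.08} of the n labelled reference windows, the fraction
  of the query's k nearest windows (BLOSUM62 position-sum similarity) that
  are known phosphosites;
* **disorder** — mean intrinsic-disorder score over the window (stored
  track or built-in propensity heuristic);
* **amino-acid frequencies** — the window's 20-residue composition.

Because site data are highly unbalanced, training uses **bootstrap
aggregating**: each of 20 rounds fits a base classifier (linear SVM with
squared hinge loss, or AdaBoost stumps) on a class-balanced subsample, and
the ensemble averages decision values. A 5-fold cross-validated pool of
held-out negative scores forms an empirical **specificity calibration
curve**, so any stringency s ∈ (0, 1) converts to a decision threshold
(type-5 quantile) and every score back to an estimated specificity.

Data plumbing included: FASTA read/write, a PTM-annotation XML dialect
(round-trip lossless, carries score tracks), UniProt XML conversion with
annotation-status filtering, Phospho.ELM-style report parsing, annotation
merging across sources, non-redundant dataset construction, site
statistics, and a synthetic proteome generator with planted motif and
disorder signal for end-to-end validation.

## Worked example

```r
library(phospred)

proteome <- generate_proteome(
  synthetic_config(n_proteins = 60, mean_length = 250, seed = 42))
site_statistics(proteome)
#> Site statistics (Phosphorylation)
#>   proteins:              60
#>   modified proteins:     43
#>   sites on S:            46
#>   sites on T:            40

sp <- split_holdout(proteome, 0.5, seed = 42)
model <- phospred_train(sp$train, config = train_config(
  seed = 42, bagging = bagging_config(n_rounds = 10, seed = 42),
  name = "demo S/T model"))
model
#> <prediction_model 'demo S/T model'> residues {S,T}, 25-mer windows
#>   ensemble: 10 x svm | reference: 708 windows (55 positive)
#>   calibration: 653 held-out negative scores | ...

res <- phospred_classify(model, sp$test, stringency = 0.95)
res
#> <prediction_result> 853 site(s), 44 passing at stringency 0.95
#>    accession position residue     score est_specificity passes
#> 1    SYN0002        5       S -2.326162       0.4771966  FALSE
#> 2    SYN0002       11       T -3.245216       0.1886704  FALSE
#> ...

nrow(filter_predictions(res, min_specificity = 0.99))
#> [1] 28
```

Here 853 held-out S/T sites were scored; 44 passed the 0.95-specificity
threshold and 28 survive tightening to 0.99. Scores are ensemble decision
values (unitless, higher = more phosphosite-like); `est_specificity` is
the calibrated fraction of true negatives expected to score below that
site. On this held-out half the ranking reaches AUC 0.981 and the
empirical false-positive rate at stringency 0.95 is 0.024 — the
calibration doing its job.

A command-line interface covers the same workflow
(`exec/phospred`, or `phospred_cli()` from R):

```sh
phospred synth --seed 7 --out data.xml
phospred disorder data.xml --out data_dis.xml      # if no tracks yet
phospred train --xml data_dis.xml --residues S,T --out model.mdl --seed 7
phospred predict --model model.mdl --fasta query.fasta \
    --stringency 0.95 --out predictions.tsv
phospred stats data.xml --ptm Phosphorylation
phospred convert --from uniprot-xml --to ptm-xml \
    --status experimental,probable uniprot.xml converted.xml
```

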