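# kmethyl

Lysine methylation is a scarce, under-annotated post-translational
modification (PTM): validated methylation sites are outnumbered many-fold by
acetylation, ubiquitination and sumoylation sites, yet the four PTMs compete
for the same lysines and share sequence determinants. `kmethyl` is an R
toolkit for predicting lysine methylation sites from per-residue protein
language model (pLM) embeddings, built for computational proteomics groups
who want to (a) train and evaluate site classifiers under realistic class
imbalance and (b) carry predictions into targeted mass-spectrometry
validation.

The package covers the full pipeline:

* **Curation** — high-confidence labelled datasets from a proteome FASTA, a
  PTM annotation table and per-residue relative solvent accessibility:
  positives are annotated lysines; negatives are buried (RSA < 0.2),
  entirely unannotated lysines in proteins that carry at least one positive.
* **Redundancy reduction** — greedy 70%-identity clustering of 31-residue
  windows with positive-favouring representative selection, then
  label-stratified train/validation/test splits.
* **Models** — an MLP over site embeddings and a transformer over the
  31-token embedded window; the flagship is a **multitask transformer**: a
  shared trunk (token projection, sinusoidal positional encoding, pre-norm
  self-attention blocks, flattening) feeding four PTM-specific
  classification heads, trained on task-homogeneous batches under the loss

  &nbsp;&nbsp;&nbsp;&nbsp;L = γ·L<sub>CE,me</sub> + L<sub>CE,ub</sub> +
  L<sub>CE,ac</sub> + L<sub>CE,su</sub>

  with only the batch's own task active per batch and γ (default 20)
  up-weighting methylation errors. Forward and backward passes are
  implemented in the package and verified against finite differences and an
  independent naive forward pass.
* **Evaluation** — PR/ROC curves, step-wise average precision, precision at
  fixed recall, and prevalence-corrected precision
  PCPr = tp / (tp + w·fp), w = target ratio / test ratio, for translating
  test-set precision (≈1:6.5 imbalance) to deployment conditions (≈1:36),
  plus operating-threshold selection (PCPr ≥ 0.75).
* **Discovery** — proteome scanning, methylome-size extrapolation
  (n·precision/recall), score-matched candidate sampling for wet-lab
  follow-up, and missense-mutation delta-scores.
* **PRM-MS support** — in-silico tryptic digestion (K/R, proline rule),
  monoisotopic precursor and b/y fragment m/z across methyl states 0–3 and
  charges 2–4, and isolation-list CSV export (100 sites → 1,200 precursors).

A synthetic data module (`simulateSiteDataset()` +
`syntheticEmbeddingProvider()`) generates class-conditional embeddings with
a planted, partially task-shared signal so that every stage — including
multitask training and its advantage over single-task training — runs and
is tested without any download.

## Worked example

```r
library(kmethyl)

## simulate a desk-scale four-task study and its embeddings
sim  <- simulateSiteDataset(nPerTask = 500, seed = 7)
prov <- syntheticEmbeddingProvider(sim$proteins, sim$records,
                                   d = 32, sharedEffect = 3, seed = 8)

## split the methylation task; auxiliary tasks are train-only
me    <- partitionHoldout(subset(sim$records, task == "methylation"),
                          testFraction = 0.2, validationFraction = 0.2,
                          seed = 9)
other <- subset(sim$records, task != "methylation")
cols  <- names(other)
train <- embedDataset(rbind(subset(me, partition == "train")[cols], other),
                      prov)
val   <- embedDataset(subset(me, partition == "validation")[cols], prov)
test  <- embedDataset(subset(me, partition == "test")[cols], prov)

## reduced multitask transformer: shared trunk, four heads, gamma = 20
spec <- transformerSpec(32, embedWidth = 16, nBlocks = 1, nHeads = 4,
                        headHidden = setNames(as.list(rep(16L, 4)),
                                              ptmTasks()))
fit <- fitEarlyStopping(initTransformer(spec, seed = 10), train, val,
                        lr = 3e-3, batchSize = 128, gamma = 20,
                        patience = 4, maxEpochs = 25, seed = 11)
fit$model
#> TransformerModel: d=32, embed=16, 1 block(s), 4 heads, context 31
#>   tasks: methylation, ubiquitination, acetylation, sumoylation
#>   parameters: 35,684

## prevalence-corrected evaluation on the held-out methylation test set
scores <- predictSites(fit$model, test, task = "methylation")
rp <- metricReport(scores, test$label,
                   correction = prevalenceCorrection(
                     imbalanceRatio(test$label), 36))
round(c(AUPRC = rp$auprc, AUROC = rp$auroc, rp$prAtRecall,
        imbalance = rp$imbalance), 3)
#>     AUPRC     AUROC  Pr@0.5Re imbalance
#>     0.592     0.865     0.500     6.692
rp$operating
#> $threshold
#> [1] 0.4603568
#> $pcpr
#> [1] 1
#> $recall
#> [1] 0.2307692

## an isolation list for the top-scoring test site
top <- subset(me, partition == "test")[order(-scores), ][1, ]
head(buildIsolationList(top[c("accession", "position")], sim$proteins), 4)
#>   accession sitePosition peptide siteOffset methylState charge        mz
#> 1  SYN00070            3     LGK          3           0      2 159.11280
#> 2  SYN00070            3     LGK          3           0      3 106.41096
#> 3  SYN00070            3     LGK          3           0      4  80.06004
#> 4  SYN00070            3     LGK          3           1      2 166.12063
```

Reading the output: the multitask model, trained on 500 instances per task
of 32-dimensional synthetic embeddings, reaches AUPRC 0.59 / AUROC 0.87 on
a 100-site methylation test set whose imbalance is about 1:6.7. The
operating point is the lowest threshold whose prevalence-corrected
precision (at an assumed 1:36 deployment imbalance) still reaches 0.75 —
here PCPr 1.0 at recall 0.23, i.e. a conservative, high-precision slice of
predictions. The isolation list enumerates the site's tryptic peptide at
every methylation state (0–3 extra CH2, +14.01565 Da each) and charge
(2–4), the table a PRM mass spectrometer needs to monitor the site.

A command-line wrapper over the same functions ships in
`inst/cli/kmethyl.R` with subcommands `curate`, `cluster`, `split`,
`embed-synthetic`, `train`, `evaluate`, `scan`, `sample-candidates`,
`mutate-impact`, `isolate` and `tally`.

See `vignettes/methylation-site-prediction.Rmd` for the full model and
methodology description.

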