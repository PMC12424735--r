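---
title: "Predicting lysine methylation sites with a multitask transformer"
author: "kmethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine methylation sites with a multitask transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmethyl)
```

## The problem

Lysine residues are modified by several competing post-translational
modifications (PTMs): methylation, acetylation, ubiquitination and
sumoylation. Experimentally validated methylation sites are scarce relative
to the other three PTMs, and a large fraction of known methylation sites
also carry another modification — evidence that the PTMs share sequence and
structural determinants. `kmethyl` implements a complete modelling pipeline
that exploits this: it curates high-confidence site datasets for all four
PTMs, trains a transformer classifier over per-residue protein-language-
model (pLM) embeddings with *multitask* learning (one shared trunk, four
task-specific heads), evaluates it under prevalence correction, and produces
the targeted mass-spectrometry artifacts (tryptic peptides, precursor m/z
isolation lists) needed to validate predictions in the laboratory.

## Dataset curation

Inputs are a proteome FASTA, a PTM annotation table (accession, 1-based
position, PTM type) and a per-residue relative solvent accessibility (RSA)
table. For a target PTM:

* **positives** are every lysine annotated with that PTM;
* **negatives** are restricted to proteins that contain at least one
  positive, and are lysines with *no* annotation for any of the four PTMs
  that are predicted buried (RSA strictly below 0.2). Burial makes the
  "never modified" assumption far safer, because exposed unannotated
  lysines may simply be undiscovered substrates;
* all other lysines have unknown status and are discarded. Candidate
  negatives with no RSA value are counted in a skip tally rather than
  silently dropped.

Each retained site is represented by a 31-residue window centred on the
lysine; termini are padded with `-`, which is distinct from `X` (unknown
residue). Two points were genuinely open and resolved as follows: the
"no other PTM" rule is applied over **all four** PTM types including the
target, so e.g. an acetylation-task negative must also lack acetylation
annotations; and the burial filter applies to negatives only — positives
are experimentally observed and need no such guard. Annotations whose
residue is not a lysine raise a named error instead of being skipped,
because they almost always indicate a coordinate-system mismatch. Every
FASTA entry is treated as an independent protein (no isoform collapsing).

## Redundancy reduction and splits

Windows are clustered by *ungapped column-wise identity* at a 70%
threshold using a greedy incremental pass: each record joins the first
cluster whose representative is at least 70% identical, otherwise it founds
a new cluster. No alignment is needed because all windows are pre-aligned
on the central lysine; pad positions match only pad positions. The visit
order is deterministic — positives first, then lexicographic by accession
and position — which both makes runs reproducible and maximises the chance
that positives found clusters, supporting the positive-favouring
representative rule: one representative per cluster is drawn at random,
uniformly from the cluster's positives if it has any, otherwise from all
members.

For the methylation task the representatives are split
label-stratified: 20% of each class to the test partition, then 20% of the
remainder to validation (the published dataset's validation/test counts are
consistent with exactly this arithmetic: 755 = 20% of 3,774 and 604 = 20%
of 3,019). Auxiliary tasks (ubiquitination, acetylation, sumoylation) are
train-only, and each task is clustered separately.

## Embeddings

Models consume per-residue embedding matrices (one L x d matrix per
protein) through a provider abstraction:

* `DirectoryEmbeddingProvider` — a plain-text directory container
  (`index.tsv` plus one matrix file per accession) that users populate with
  any embedder (ProtT5-class models produce d = 1,024); matrices are read
  lazily, one protein at a time;
* `SyntheticEmbeddingProvider` — a generator for desk-scale experiments.

A site's transformer input is the 31 embedding rows centred on the lysine;
rows falling outside the protein are zero vectors with a mask of 0,
generalising the zero-vector padding of the reference protocol from 1,024
dimensions to any d. The MLP baseline input is the site residue's own
embedding row (mean-pooling over the window is available as an option, but
the residue row is the default reading of "embedding vectors of lysine
sites").

### What the synthetic generator emulates

`simulateSiteDataset()` creates a random proteome and labelled windows for
the four tasks sized like the published high-confidence training data
(positive fractions 0.133 / 0.540 / 0.235 / 0.266 — a roughly 1:6.5
methylation imbalance). `syntheticEmbeddingProvider()` then emits, for each
residue, an isotropic Gaussian row keyed deterministically by (seed,
position, residue identity), and adds to each positive site's row a planted
signal `sharedEffect * u + taskEffect * v_t`, where `u` (shared by all
tasks) and the `v_t` (task-private) are orthonormal directions. Defaults
are d = 32, sharedEffect = 3, taskEffect = 1, noiseSd = 1: strong enough
that the methylation class is linearly identifiable from the site row, weak
enough that learning is non-trivial at small sample sizes. Because rows are
keyed by sequence content, mutating a residue changes exactly that row —
which is what makes synthetic mutation delta-scores well-defined.

The generator deliberately does **not** emulate several features of real
data: sites are assigned to exactly one task (no PTM co-occurrence at one
lysine), embeddings carry no long-range sequence context, and the planted
signal is linear in a fixed direction. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that multitask transfer occurs
when a shared signal exists — not that the shipped architecture attains any
particular accuracy on real proteomes.

## Models

**MLP** — a ReLU dense stack with dropout over the pooled site embedding,
sigmoid output.

**Transformer** — per-token dense layer (d to `embedWidth`), sinusoidal
positional encoding added *after* that projection (so the encoding lives in
model width, the natural choice given the projection changes dimension),
pre-norm encoder blocks (multi-head self-attention, GELU feed-forward of
width 4 x `embedWidth`, residual connections, layer normalisation), a
flattening layer concatenating the 31 post-attention token vectors, and a
ReLU classification head per task ending in a sigmoid. Four attention heads
per block. Pad positions are masked out of attention by default and their
token rows zeroed — zero-padded inputs alone still attract attention mass
through biases, and masking makes pad invariance an exactly testable
property (a flag disables it). The shipped full-scale default matches the
best published configuration (2 blocks, embed width 1,600, head widths
1,797 / 1,803 / 338 / 493 mapped to methylation / ubiquitination /
acetylation / sumoylation in that order — the mapping is an assumption, as
the published table does not name the heads — dropout 0.15, learning rate
8e-7, 100 epochs); all tests and examples use reduced specs.

The multitask model shares the trunk (everything through flattening) and
owns one head per task. Forward passes evaluate only the requested task's
head; training uses *task-homogeneous* batches, so a batch updates the
shared trunk and exactly one head. This is asserted bitwise in the tests:
after an optimisation step on a task-t batch, the other three heads'
parameters are unchanged (Adam state is kept per parameter and stepped only
where a gradient exists).

All forward and backward passes are implemented in R and verified two ways:
against an independently hand-coded naive forward pass (1e-6) and against
central finite differences on every parameter tensor (1e-4 relative). A
closed-form parameter-count formula is asserted against each instantiated
model to catch silent architecture drift. The final head layer is
zero-initialised, so an untrained model scores exactly 0.5.

## Training

Binary cross-entropy with probabilities clamped at 1e-12; the multitask
loss is `gamma * L_me + L_ub + L_ac + L_su` with only the batch's own task
contributing per batch, so it reduces to `gamma * L_CE` for methylation
batches and `L_CE` otherwise. Candidate gamma values are {1, 13.5, 20}
(13.5 approximates the methylation-to-other-PTM instance ratio; 20 is the
shipped default). Gradient norms on methylation batches scale exactly
linearly in gamma, which the tests assert.

Optimisation is Adam (canonical moment coefficients) with batch size 64 for
MLPs and 128 for transformers. Each epoch shuffles each task's instances
and emits homogeneous batches whose order is itself shuffled, interleaving
tasks in proportion to dataset size; every instance appears exactly once
per epoch. Early stopping monitors the *methylation* validation loss
(a flag includes all tasks) with patience 10 and at most 100 epochs by
default — patience is not stated in the reference protocol; 10 is standard
practice. Within a run the best state is the lowest validation loss;
across runs (hyperparameter search) the selection metric is validation
AUPRC. Both are recorded because they play different roles.
`randomSearch()` draws independent configurations from user-specified
ranges (log-uniform for learning rates), standing in for a plain
random-sampling tuner.

## Evaluation and prevalence correction

`prRocCurves()` sweeps every distinct score as a threshold with ties
entering or leaving the predicted-positive set together. AUPRC is
step-wise average precision (trapezoidal interpolation in PR space is known
to overestimate); AUROC is the ROC trapezoid, which equals the
tie-corrected Mann-Whitney statistic. Both are pinned to brute-force
threshold enumeration at 1e-12 in the tests.

A test set's imbalance (about 1:6.5 negatives per positive here) is far
milder than the deployment-time imbalance, estimated at roughly 1:36
methylated-to-unmethylated detectable lysines. The prevalence-corrected
precision is

PCPr = tp / (tp + w * fp),   w = targetRatio / testRatio,

i.e. false positives are re-weighted as if negatives were w times more
frequent, leaving recall unchanged. This is the standard correction under
the assumption that class-conditional score distributions do not change
with prevalence; the reference work does not print its formula, and
re-weighting (rather than test-set resampling) was chosen because it is
deterministic and exact. `thresholdForTargetPCPr()` returns the *lowest*
threshold whose PCPr meets a target (0.75 at 1:36 being the conservative
deployment setting), i.e. the recall-maximising operating point under the
precision constraint.

## Discovery tools

`scanProteome()` scores every lysine of a proteome through any provider and
model. `estimateMethylomeSize(n, precision, recall)` extrapolates the total
methylome as `round(n * precision / recall)`; at the published deployment
figures (62,567 predicted sites, precision 0.75, recall 0.30) this gives
156,418 — the formula value is reported exactly, rounding to a headline
"~155,000" is left to the caller. `sampleMatchedCandidates()` draws two
50-site validation sets (other-PTM-bearing vs unmodified, both exposed,
high-scoring and not known methylation sites) with per-score-bin matched
counts (bin width 0.05 over [threshold, 1] — coarse enough to fill bins at
n = 50) and reports the maximum CDF distance between the samples' scores.
`mutationDeltaScores()` re-embeds a mutant sequence and reports the score
drop for every lysine whose window covers the mutated position, flagging
sites whose prediction crosses the threshold; the change floor is an
absolute 0.02 by default (a relative flag exists, since "2%" is ambiguous).

## Targeted-MS support

`digest()` performs in-silico tryptic digestion (cleave C-terminal to K/R
unless followed by proline, zero missed cleavages; the peptides tile the
protein exactly). `sitePeptide()` returns the unique peptide containing a
site; when the site lysine is itself a cleavage point the peptide ends at
it, consistent with the published example peptides, and a missed-cleavage
flag enumerates alternatives for the case where methylation would hinder
trypsin. Precursor masses use the standard monoisotopic residue table,
water 18.0105646 Da, proton 1.0072765 Da and 14.01565 Da per methyl group;
`buildIsolationList()` enumerates one entry per site, methyl state (0-3)
and charge (2-4) — 1,200 rows for a 100-site campaign. Fragment b/y ions
carry the methyl mass exactly when the site residue lies inside the
fragment, and b/y complementarity is asserted for random peptides.
Cysteine is carried unmodified (no fixed carbamidomethyl) since the
reference protocol does not state alkylation; a flag could add it but none
of the shipped outputs assume it. All mass arithmetic is checked to 1e-4 Th
against an independent reference calculator on frozen fixtures.

## Numerical choices and problem sizes

* Score clamping 1e-12 before logarithms; layer-norm epsilon 1e-5.
* Weight initialisation Gaussian 1/sqrt(fan-in); zero biases; zero final
  head layer.
* Tie handling in curves: grouped thresholds (see above).
* Test and example runs use reduced models (embed width 16, one block,
  d = 32) and synthetic datasets of 2,000 instances per task for the
  learnability check and 160 methylation / 600 auxiliary instances per task
  for the ten-seed transfer comparison; these sizes make the full suite and
  the acceptance script complete comfortably on a single CPU while leaving
  the planted-signal conclusions unambiguous.

## Known limitations

* Running actual pLMs is out of scope; embeddings arrive via the provider
  contract. The published accuracy figures require the original
  PhosphoSitePlus-derived datasets, full-scale pLM embeddings and long
  training runs, none of which ship here; the synthetic experiments
  reproduce the *ordering* (multitask above single-task) rather than the
  absolute numbers.
* The greedy clustering preserves the member-representative identity
  contract, not the exact cluster boundaries of any particular external
  clustering tool (no short-word heuristics).
* Spectrum interpretation (mzML parsing, peak detection) is out of scope;
  the MS module ends at isolation lists, transitions and outcome tallies.
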