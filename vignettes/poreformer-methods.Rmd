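---
title: "Detecting pore-forming proteins from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pore-forming proteins from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreformer)
```

## The problem

Pore-forming proteins are sequence-diverse but share a mode of action:
soluble monomers oligomerise and insert into membranes. Homology search
finds only relatives of known families, so a classifier that scores
pore-forming potential from the primary sequence alone — without alignment
to a reference — is useful for prioritising proteins of unknown function.
`poreformer` implements such a classifier together with the dataset
curation, sequence encoding, and evaluation protocol around it.

## Curation model

Three rules assemble a training set:

1. **Length window.** Sequences shorter than 50 or longer than 2000
   residues are eliminated (boundaries inclusive on the kept side). Short
   peptides behave differently from proteins; very long sequences blow up
   the padded input.
2. **De-redundancy of positives.** Greedy incremental clustering at 70%
   identity, longest sequence first with ties broken by id: a sequence
   joins the first representative it matches at or above threshold, else
   founds a cluster. Only representatives are kept. Identity is defined as
   identical columns divided by alignment length (gaps included) under
   optimal global alignment with BLOSUM62, gap open 10, gap extend 1. The
   choice of *global* identity and of representative-only retention are
   design decisions — clustering tools differ here and no single
   convention is canonical; both are fixed and documented so results are
   reproducible.
3. **Purging of suspect negatives.** Every negative is aligned locally
   (Smith–Waterman, same scoring) against every positive; negatives whose
   best hit is significant at E ≤ 0.01 under the Karlin–Altschul
   approximation `E = K·m·n·exp(−λS)` with the standard gapped BLOSUM62
   parameters (λ = 0.267, K = 0.041) are removed. This is an
   approximation to a BLASTP screen that keeps the pipeline self-contained;
   an external search tool can be substituted upstream by filtering the
   negative FASTA before input.

A caveat worth stating: for *unrelated* sequence pairs many co-optimal
global alignments exist (sometimes of different lengths), so the identity
value is alignment-choice-dependent in the regime far below the
threshold. Near and above 70% — the regime that decides clustering — the
optimum is effectively unique and the value is stable.

## Encoding schemes

All encoders produce a fixed `pad_length × channels` matrix; shorter
sequences are zero-padded so a batch is rectangular.

* **One-hot (28 channels).** The alphabet is the 20 canonical residues,
  the extended codes B, J, O, U, X, Z, the translation artifact `*`, and
  one dedicated padding symbol — 28 symbols, each an indicator channel.
  Giving the pad its own channel (rather than an all-zero row) is what
  makes the space 28-dimensional and lets the network distinguish "no
  residue" from any real residue.
* **Atchley (5 channels).** Each residue maps to its five physicochemical
  factor scores (polarity/hydrophobicity; secondary-structure propensity;
  molecular size; codon composition; electrostatic charge), shipped as a
  TSV table in `inst/extdata/` that is the single source of truth.
  Pad rows are all-zero. Non-canonical residues use standard ambiguity
  semantics computed from the table: B = mean(D, N), Z = mean(E, Q),
  J = mean(I, L), X = mean of all 20, U = C, O = K, `*` = zeros.
* **Combined (33 channels).** Columnwise concatenation of the two. The
  indicator part carries exact motif information; the factor part carries
  property information in a space where physicochemically similar
  residues are close.

## Classifier

The network is, in order: convolution (25 filters spanning 100 positions
across all input channels) → ReLU → max-pool (window 5) → convolution
(25 filters × 50 positions) → ReLU → max-pool (5) → dropout (rate 0.25,
training only) → flatten → one fully connected unit → sigmoid. The output
is the probability that the protein is a pore former. Training minimises
the mean squared error between that probability and the 0/1 label, with
mini-batch Adam (learning rate 1e-3, batch 32, 30 epochs by default).

Choices the architecture diagram leaves open are fixed as: max pooling
(the standard reading of a pooling layer), a sigmoid output (forced by
the [0, 1] probability contract combined with MSE loss), a single dense
unit straight after flattening (the smallest fully connected head), and a
second convolution with the same filter count as the first. The decision
threshold for binary calls is 0.5 and configurable.

The implementation is deliberately dependency-free numerical R:
convolution is an im2col gather followed by one BLAS matrix product,
max-pooling tracks argmax offsets for the backward pass, and all
gradients are hand-derived and verified against central finite
differences in the test suite (tolerance 1e-5). Everything that consumes
randomness — weight initialisation (He-scaled normal), epoch shuffling,
dropout masks — draws from a generator seeded by the model
configuration, so a seed fixes the entire training trajectory
bit-for-bit on a given platform. Inference applies no dropout and is
deterministic.

## Evaluation protocol

* **Splits.** Randomised 80:20 train/test, stratified by label so both
  classes appear on each side even at benchmark scale. Stratification is
  a deliberate strengthening of a plain random split: at a few hundred
  sequences an unstratified 20% test draw can lose a class entirely.
  Each class therefore needs at least two records.
* **ROC.** The curve sweeps every distinct score as a threshold, grouping
  ties into one step; AUC is the trapezoidal area. This equals the
  Mann–Whitney pair statistic (positives outscoring negatives, ties half)
  — the suite asserts the equivalence against an exhaustive pair
  enumeration.
* **Per-class curves.** Alpha and beta curves score that family against
  the negatives. A "negative" curve treats the negative class as the
  detection target, which for a binary scorer only makes sense on
  inverted scores (1 − score). The average curve is a macro mean of the
  per-class TPR on a fixed 101-point FPR grid — an average must fix
  *some* interpolation convention, and a uniform grid is the simplest
  reproducible one.
* **Held-out family.** An entire family is excluded from training; the
  protocol refuses to run if any holdout id appears in the training set
  and can additionally require every holdout sequence to be below 70%
  global identity to every training positive. Detection is the fraction
  of the family scoring at or above the threshold.

## The synthetic benchmark

The generator emulates the *structure* of the real task, not its biology:

* **Background negatives** are i.i.d. residues (uniform over the 20
  canonical amino acids by default) with lengths uniform in [100, 400].
* **Positive families** overlay two signal components on background
  chains: up to three short family motifs (8–15 residues, drawn once per
  family from the seed) planted at non-overlapping random positions, and
  a global composition shift toward hydrophobic residues
  (A, C, F, I, L, M, V, W), mixed in with weight 0.35 at full signal.
  Both components scale with `signal_strength`; at 0 the families are
  distributionally identical to background, at 1 every sequence carries
  at least one exact motif copy.
* **The novel family** shares the composition bias but uses a disjoint
  motif set — "same physics, different sequence" — which is exactly what
  a held-out-family generalization test should probe: one-hot filters
  can memorise training motifs, but only the property signal transfers.

Two components exist so the two encoding families are stressed
independently: motifs are visible to indicator channels, the composition
shift to the Atchley channels. The default sizes (100 per family, 200
negatives, 50 holdout, lengths 100–400) keep a full train/evaluate cycle
in minutes on one CPU; the model kernels are scaled to 20/10 accordingly
(`benchmark_model_config()`), since a 100-position kernel would not fit
short sequences sensibly. The benchmark schedule keeps the default 30
epochs with the learning rate doubled to 2e-3, which converges reliably
on the 320-sample training set.

What passing on synthetic data does **not** show: real pore formers are
not i.i.d. chains with planted k-mers — no amphipathic periodicity, no
domain architecture, no phylogenetic correlation — so synthetic
performance says the *pipeline* works (signal in, signal recovered;
no signal in, chance out), not that the trained weights transfer to
UniProt-scale data.

## Numerical and degenerate-input choices

* Padded positions carry the pad indicator (one-hot) or zeros (Atchley);
  they contribute to convolutions like any other position, which is the
  standard zero-padding convention.
* Sequences longer than `pad_length` are an error, never truncated
  silently.
* Max-pool windows that do not fill completely are dropped (floor
  division), matching common deep-learning defaults.
* Greedy clustering ties: candidate order is longest-first then
  lexicographic id; assignment goes to the earliest-founded matching
  representative.
* ROC with tied scores collapses each tie group into a single step, so
  the curve (and AUC) is invariant to within-tie reordering.
* The null-signal test band for AUC (0.4–0.6) corresponds to roughly
  ±1.5 standard deviations of a chance AUC on an 80-sequence test set;
  the suite pins it at a fixed seed.

## Known limitations

* The Karlin–Altschul E-value uses fixed gapped BLOSUM62 parameters; it
  approximates but does not reproduce BLASTP's edge-corrected statistics.
* Identity of unrelated pairs is co-optimum-dependent (see above).
* Training is plain Adam on MSE; no early stopping, no hyperparameter
  search. On hard real datasets the fixed schedule may under- or
  over-train; the history tibble and `autoplot()` exist so users can see
  which.
* The holdout detection rate on the synthetic benchmark is an
  intrinsically noisy quantity (a threshold cutting through the middle
  of the novel family's score distribution); across arbitrary seeds it
  ranges roughly 0.65–0.95.
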