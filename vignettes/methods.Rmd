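---
title: "Predicting T-cell immunogenicity from peptide sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting T-cell immunogenicity from peptide sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
```

## The problem

Most computational epitope pipelines stop at antigen presentation: will a
peptide be processed and displayed on an HLA class-I molecule?  Whether a
*presented* peptide is actually recognized by T cells — its immunogenicity —
is a separate and harder question, and the limiting step when prioritizing
tumor neoantigens for vaccines.  `immunopep` models that second step.  It
takes peptides of 8–12 residues with an eluted-ligand percentile rank
(rank(%), produced upstream by an MHC-binding predictor and supplied as
input — this package never computes binding itself) and scores the
probability that T cells respond.

## The anchor / TCR-contact convention

An HLA-I bound peptide is held in the groove mainly by its N-terminal
residue, position 2 and its C-terminal residue.  Those anchor positions are
assumed buried and invisible to the T-cell receptor, so *every* sequence
feature in this package is computed over the remaining contact positions
`3:(len-1)` — there are always `len - 3` of them.  The convention is fixed,
1-based, and deliberately not configurable: it is load-bearing for the
feature definitions, the anchor-mutation flag and the synthetic generator,
and the tests assert that edits at positions 1, 2 and `len` never change a
sequence feature.

## The features

For a peptide $P$ of length $L$ with residue $A_x$ at position $x$, and
contact positions $\mathcal{C} = \{3, \dots, L-1\}$:

* **C1–C21, physicochemical scale averages.**
  $P_c = \sum_{x \in \mathcal{C}} c(A_x) / (L-3)$ for each of 21
  per-residue characteristic tables $c$ (Kyte–Doolittle hydropathy,
  molecular weight, bulkiness, polarity, recognition factors,
  hydrophobicity, HPLC retention, hetero end/side ratio, flexibility,
  β-sheet, α-helix, β-turn, mutability, codon count, refractivity,
  transmembrane tendency, accessibility, buried area, coil, total and
  parallel β-strand).  The tables are frozen transcriptions of the
  ProtScale/ExPASy renderings of the cited literature scales, shipped as a
  diffable TSV (`inst/extdata/aa_scales.tsv`) with per-scale citations.
  Minor numeric variants of some scales exist across references; the TSV
  documents exactly which variant is bundled, and only the Kyte–Doolittle
  values are relied on numerically elsewhere (the C25 mutation feature).

* **C22, contact-site frequency score.**
  $P_{score} = \sum_{x \in \mathcal{C}} [f^{+}(A_x) - f^{-}(A_x)]$, where
  $f^{+}$ and $f^{-}$ are amino-acid frequencies pooled over the contact
  positions of immunogenic and nonimmunogenic training peptides.  The sum
  is intentionally *not* length-normalized; a `normalize` flag exists for
  sensitivity analyses but defaults off.  Frequencies are pooled across
  positions rather than estimated per position: per-position tables would
  be data-starved at realistic training sizes, and the motivating
  observation (hydrophobic residues enriched at contact sites of
  immunogenic peptides, D/K enriched in nonimmunogenic ones) is a
  per-amino-acid statement.  One pooled model over all supertypes is the
  default; nothing prevents estimating per-supertype models by filtering
  the input first.

* **C23, background peptide entropy.**
  $P_H = -\sum_{x \in \mathcal{C}} f(A_x) \log_2 f(A_x) / (L-3)$ with $f$
  the amino-acid frequency in the human reference proteome.  A frozen
  background table ships with the package (approximate published
  human-proteome frequencies, renormalized); supplying a proteome FASTA
  recomputes it.  Duplicated residues are *not* collapsed before the sum —
  each contact position contributes its own term, as the formula reads.

* **C24, rank(%).**  Passed through from the input.  It is a feature, not
  a computation: recomputing MHC binding is out of scope by design.

* **C25–C27, neoantigen mutation features** (wild-type/mutant pairs
  differing at exactly one position): the Kyte–Doolittle hydrophobicity
  change of the substituted residue (C25); the differential agretopicity
  index, DAI (C26), operationalized as `wt_rank - mut_rank` because
  rank(%) is the binding quantity this package ingests (the same
  subtraction applies unchanged if affinity columns are supplied instead);
  and a 0/1 flag for whether the mutation sits on an anchor position
  (C27).  C25 is defined at residue level rather than as a difference of
  the C1 peptide averages: for interior mutations the two differ only by
  the $1/(L-3)$ factor, and the residue-level form stays informative for
  anchor mutations, which the peptide average cannot see.  C1–C24 of a
  pair are computed on the **mutant** sequence — the candidate neoepitope
  is the species actually presented.

All smoothing is add-one (Laplace) per amino acid, so class and background
frequencies are strictly positive, the entropy is defined for every
residue, and C22 is stable for rare residues.  The pseudocount is a
documented argument (`pseudocount = 1`, `0` disables it).

## Avoiding frequency-estimation leakage (cross-fitted C22)

C22 is the one feature estimated *from the labels*.  If a labeled training
set is scored against class frequencies estimated from that same set, the
shared estimation noise couples each peptide's score to its own label:
even on data with **no** class signal, a random forest can exploit the
coupling and report cross-validated AUCs well above chance (we observed
≈0.58 at 1000 peptides per class; a leave-one-out correction merely flips
the sign of the coupling and the forest exploits that instead).  The
package therefore:

* cross-fits C22 whenever a labeled table is assembled
  (`peptide_features(..., c22 = "cross_fit")`, the default for labeled
  input): records are dealt into interleaved per-class folds and each fold
  is scored with frequencies estimated from the other folds only — a
  deterministic split, no RNG;
* re-estimates the frequency model inside every cross-validation training
  fold when `ep_train()` is given a raw peptide or pair table, scoring
  each held-out fold with a model that never saw it.  This raw-table path
  is the recommended way to train;
* scores genuinely new records at prediction time against the stored
  training model (`c22 = "model"`), which is the correct deployment
  behavior.

With this design the null calibration in the test suite holds: at effect
size 0 the repeated-CV AUC averages 0.5 within ±0.05 over 20 generator
seeds, and the shadow screen confirms no feature.

## Curation of training data

Training sets built from response assays contain negatives that are
uninformative about TCR recognition, and the cascade removes them in a
fixed, reported order — length filter (8–11 during training; prediction
accepts 8–12), deduplication, then two negative-only filters, then an
optional supertype filter:

* **Rank filter.**  A nonimmunogenic record with rank(%) strictly greater
  than 2 is predicted not to be presented at all; its lack of response
  says nothing about T cells.  The boundary is exact: rank = 2.0 is
  retained.  Positives are never removed by this rule.
* **Proteome filter.**  A nonimmunogenic record occurring verbatim as a
  substring of any human reference protein plausibly reflects central
  tolerance.  Exact-substring matching is used because epitopes are
  protein fragments; whole-record equality would almost never fire.
  Again, negatives only.
* **Deduplication** keys on (sequence, normalized HLA allele).  On label
  conflict the immunogenic record wins: a peptide with any validated
  T-cell response is immunogenic.
* **Supertype filter.**  Records whose allele is unmapped or outside the
  allowed supertype set are dropped; peptides presented by supertypes
  absent from training cannot be scored consistently.  The bundled map
  covers 17 class-I alleles across the ten supertypes A1, A2, A3, A24,
  B7, B8, B27, B44, B58, B62.

Every filter annotates its output with a running report (counts per stage
and class, removal reason per record); the cascade is idempotent and the
tests verify both properties.

## Feature screening and the classifier

The relevance screen is a shadow-feature (Boruta-style) loop: each
iteration duplicates every active feature, permutes the duplicates, trains
a random forest on real + shadow columns, and credits a *hit* to each real
feature whose permutation-importance Z score (mean decrease in accuracy
over its standard deviation across trees; Gini importance available)
exceeds the best shadow's.  Hits are tested against Binomial(iterations,
½) with a two-sided binomial test, Bonferroni-corrected over the starting
feature count; significantly-above-chance features are confirmed,
significantly-below rejected and removed from later forests, the rest stay
tentative at the iteration cap (default 30).  With the correction,
confirmation is mathematically impossible before 13 iterations at
α = 0.01 with 24 features — a deliberate guard against sequential-testing
false confirmations.

The classifier is a `randomForest` with 500 trees and `mtry` 15 (antigen,
24 features) or 14 (neoantigen, 27 features); other parameters stay at
package defaults.  Performance is estimated by stratified 5-fold
cross-validation repeated 3 times: within a repeat, out-of-fold scores are
pooled into one AUC, and the three repeat AUCs are averaged (pooling
within repeats uses all scores on a common scale; averaging across repeats
keeps repeats exchangeable).  AUC is computed by the rank-sum
(Mann–Whitney) formulation with ties counted half, and is verified in the
tests against brute-force pairwise counting and against pROC.  The final
bundle is refit on all data and persists with a JSON metadata sidecar
(feature list, thresholds, seed, schema version); loading refuses a
schema-version mismatch.

Prediction reports the fraction of trees voting immunogenic and maps it to
the reporting bands: score > 0.5 *positive-high*, 0.4 ≤ score ≤ 0.5
*positive-low*, score < 0.4 *negative-high*.  The band edges at exactly
0.4 and 0.5 both land in *positive-low*; the boundary semantics are
asserted in the tests.  Records with rank(%) ≥ 2 are scored but flagged —
if the HLA does not present the peptide, the immunogenicity score is not
meaningful.

Class imbalance: no resampling or reweighting is applied by default, since
the method is defined on the features as they come; real epitope corpora
are heavily imbalanced, and users who need balanced operating points
should choose thresholds from the reported ROC rather than expecting the
0.4/0.5 bands to be optimal.

## The synthetic generator

Real training corpora require database downloads and an external binding
predictor, so the package ships a generator that emulates the statistical
structure the method assumes — it is first-class, tested code, and it
defines the study conditions for the calibration experiments:

* **Anchors** follow per-allele motif sets at positions 1, 2 and the
  C-terminus (e.g. A*02:01: position 2 ∈ {L, M}, C-terminus ∈ {I, L, V});
  unmotifed anchor positions draw from the background distribution.
* **Contact residues** are drawn from the background distribution
  exponentially tilted by `exp(±effect)` on the hydrophobic set
  {L, W, P, A, V, M} (enriched in positives) and on {D, K} (enriched in
  negatives).
* **rank(%)** is log-normal (`meanlog 0`, `sdlog 0.8` at effect 0) with a
  class location shift of `∓ effect × 0.75` on the log scale — positives
  bind better.  The log-normal shape and its parameters are the package's
  choice of a realistic, strictly positive, right-skewed rank
  distribution; no published rank distributions exist to copy.
* **Lengths** are 8–11 with 9-mers dominant (probabilities 0.15 / 0.55 /
  0.20 / 0.10), as in curated HLA-I epitope sets.
* At `effect = 0` the two classes are statistically identical in every
  respect — the null case used for calibration.  The named levels are
  none = 0, weak = 0.2, medium = 0.4, strong = 0.8, chosen once so that
  "strong" produces clearly separable classes and "weak" does not.

Mutant pairs are generated with class-neutral wild types; the substitution
carries the signal (substituted residue from the class-tilted
distribution at contact positions, mutant rank shifted by the effect), and
an `anchor_fraction` controls how often the mutation lands on an anchor.

What the generator does **not** emulate: proteasomal cleavage and TAP
transport preferences, position-specific contact-site dependencies,
realistic class imbalance (configurable but defaulting to balanced),
sequence similarity structure between records, or assay noise in the
labels.  Passing tests on generated data therefore demonstrate that the
implementation recovers the structure it assumes — formulas, leakage-free
validation, screening behavior, determinism — not that the trained model
transfers to real epitope data; published headline AUCs on real corpora
are not reproducible without the original data and binding predictor, and
the package makes no claim to reproduce them.

## Problem sizes and numerical choices

The calibration experiments in the test suite use 1000 peptides per class
with 20 generator seeds for the null case (CV forests of 150 trees,
screens of 50 trees capped at 14 iterations — at which confirmation at the
Bonferroni-corrected α = 0.01 is just reachable, so a false confirmation
would be visible) and 600 peptides at strong effect with full defaults for
signal recovery.  These sizes were chosen as the smallest at which the
binomial screen decisions and the ±0.05 AUC band are statistically
comfortable.  Determinism is checked end-to-end: one master seed drives
fold assignment, forest construction and shadow permutations (via
`withr::with_seed`, leaving the user's RNG state untouched), and two runs
of simulate → curate → train → predict produce byte-identical outputs.

Degenerate inputs are rejected rather than guessed at: peptides shorter
than 4 residues (the feature denominator $L-3$ vanishes), nonstandard
residues (B, Z, X, U, O — the scales are undefined for them), single-class
training data, identical or multi-substitution "pairs", and missing rank
columns all raise errors naming the offending record or column.

## Known limitations

* rank(%) must come from the same predictor family for training and
  prediction; mixing predictors shifts C24's scale and silently degrades
  the model.
* The anchor convention is fixed; alleles whose true anchors differ are
  modeled with the default convention regardless.
* The supertype map covers the 17 bundled alleles; others need rows added
  to the map passed into the curation functions.
* Only single-substitution neoantigens are supported — no indels,
  frameshifts, or multi-substitution peptides, and no derivation of
  peptides from variant calls (upstream of this tool).
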