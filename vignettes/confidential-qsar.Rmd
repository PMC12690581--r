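---
title: "Confidential QSAR model exchange: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidential QSAR model exchange: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
ConfQSAR, the assumptions behind them, and the design decisions taken
where more than one reasonable construction existed. The package
simulates and supports a multi-partner exercise in which several
organizations each train a binary activity model on proprietary
compounds, exchange the models in a structure-free form, and combine
them into ensembles.

## The local model

### Pipeline

A local model is fitted by `fitPLSDA()` as a fixed pipeline:

1. **Undersampling.** The majority class is randomly subsampled,
   without replacement, to the minority-class size (`undersample()`).
   Class imbalance is the rule in safety data; balancing by discarding
   majority compounds keeps the decision threshold interpretable. The
   subsample is drawn with the configuration seed and the retained
   records keep their original order.
2. **Descriptors.** Feature-typed circular fingerprints
   (`morganFingerprints()`), radius 2, folded to 2048 bits — see below.
3. **Autoscaling.** Every bit is centered and scaled to unit variance
   (`fitScaler()`); the divisor is the population standard deviation
   (denominator *n*) of the training bits. Features that are constant
   in training are stored with `sd = 0` and their scaled value is
   *defined* as 0 at prediction time: they carry no discriminative
   signal and this convention avoids division by zero while keeping
   prediction total.
4. **Feature selection.** The *K* = 500 bits with the largest one-way
   ANOVA F statistic between the two classes are retained
   (`selectTopK()`). The univariate score is the conventional default
   for selecting features against a labeled target; for a binary
   feature and a binary class it is a monotone transform of the
   class-frequency difference. Ties break toward the lower bit index,
   constant bits never qualify, and if fewer than *K* non-constant
   bits exist, all of them are kept with a warning (small series on a
   narrow chemical series often offer only a few hundred informative
   bits).
5. **PLS1 regression** of the 0/1 class code on the scaled, selected
   bits, fitted by NIPALS. Because the response is a single column,
   the fitted model with *a* latent variables collapses exactly to a
   linear form: one coefficient per selected feature plus an intercept
   (the training class mean, the design being column-centered). This
   collapsed form is the entire portable state of the model and is
   what the confidential export serializes. The NIPALS deflation stops
   early if the residual norm falls below 1e-12 (perfect fit); the
   component count is capped accordingly.

### Hyperparameter search

The number of latent variables and the decision threshold are chosen
by grid search with stratified 5-fold cross-validation, scored by the
mean MCC across folds. MCC is used as the objective because it is the
single balanced summary of a binary confusion matrix. Defaults:
latent variables 2–8; thresholds 0.20–0.80 in steps of 0.05 on the
PLS score scale (the score approximates the class code, so thresholds
near 0.5 are natural and the grid brackets them generously). Both
grids are configurable (`modelConfig()`). Ties are broken toward
fewer latent variables, then the lower threshold — the simpler and
the more sensitive model. Selection and scaling are refit inside
every fold; folds are stratified by class so that each fold carries
both labels, and fold assignment derives from the configuration seed.
Whether the original exercise stratified its folds is not documented;
stratification is this package's choice because it keeps per-fold
metrics defined at small *n*.

Degenerate cases are errors, not silent repairs: single-class input,
folds that lose a class, empty grids. Metric conventions:
sensitivity and specificity return `NA` with a warning when their
denominator is empty; MCC returns 0 with a warning when its
denominator vanishes — the standard convention that keeps validation
loops total without rewarding a degenerate classifier.

## The fingerprint

No installed R package computes circular fingerprints of the required
kind, so the descriptor is implemented in the package and defined
precisely as follows. Molecules are first canonicalized (all parsing,
canonicalization and InChI generation are delegated to Open Babel via
ChemmineOB/ChemmineR); the bit vector is a pure function of the
canonical SMILES.

* **Initial atom invariant** — six pharmacophoric feature bits:
  hydrogen-bond donor (N/O with at least one H), acceptor (N/O with
  non-positive formal charge), positively ionizable (formal positive
  charge, or a non-aromatic amine nitrogen without multiple bonds),
  negatively ionizable (formal negative charge, or an acidic O–H
  whose neighbor bears a double-bonded oxygen), aromatic, halogen.
  This is the "feature-typed" (pharmacophoric) reading of circular
  fingerprints: atoms are abstracted to their interaction roles, so
  similar roles on different scaffolds map to the same environments.
* **Aromaticity perception** is a deliberate, deterministic heuristic:
  a ring system (biconnected component with at least three atoms) is
  aromatic-like when every member carbon carries at least one double
  bond and the remaining members are N, O or S. This classifies the
  common heteroaromatics correctly and never flags saturated rings;
  it does not attempt Hückel counting. Bonds between two aromatic
  atoms inside a ring hash with order 4, which makes the identifiers
  independent of the kekulization.
* **Iteration.** Each atom identifier is rehashed for radius rounds
  1 and 2 together with the sorted (bond order, neighbor identifier)
  pairs of its heavy-atom neighbors. The hash is a polynomial hash
  modulo the Mersenne prime 2^31 − 1, computed exactly in double
  arithmetic, hence identical on every platform.
* **Deduplication and folding.** Among environments covering the same
  atom set, only the smallest identifier is kept (order-independent);
  identifiers fold onto 2048 bits by modulus.

The unit tests verify this definition against an independently coded
oracle (recursive environment enumeration, edge-removal ring
perception) bit for bit. Bit-level compatibility with any external
fingerprint software is *not* a goal — models and archives are only
meaningful within this package's descriptor definition, which the
export format pins by bit index.

## The confidential archive

An export (`exportConfidential()`) is a single gzip-compressed POSIX
tar archive, extension `.qcm`, with exactly three members:

* `parameters.txt` — `key = value` lines: descriptor settings, grids,
  seed, chosen latent variables and threshold, training-series size,
  and an anonymized origin label (single letters by convention).
* `scaler.tsv` — `bit_index  mean  sd`, one row per selected feature,
  sorted by bit index.
* `coefficients.tsv` — `bit_index  coefficient` rows, final line
  `intercept`.

A tar container (rather than ZIP) is used because base R can write
and read it without any external program; the member files themselves
are plain text. Numbers serialize with 12 significant digits, which
round-trips scores well below the 1e-9 equivalence tolerance the
tests enforce. Member timestamps are fixed to a constant epoch so
that exporting the same model twice is byte-identical —
reproducibility a recipient can check by hashing.

The training-series *size* is the only training metadata retained; it
is needed by the chemical-space view. Per-class counts, the series
name and every structural identifier are deliberately absent. The
audit (`auditArchive()`) re-verifies all of this mechanically: member
list, line grammars against a whitelist of keys, index consistency
across files, and a scan that flags InChI/InChIKey patterns, molblock
signatures, and any token that Open Babel parses as a multi-atom
structure. The audit reports findings rather than throwing, so a
broker can audit a batch and report per archive.

The threat model is *disclosure*, matching the exchange setting: the
archive must not contain structures. Defending against adversarial
reconstruction of structures from coefficients (model inversion) is
explicitly out of scope, as is encryption or signing of the archive.

## Ensembles

Member predictions are always computed once per compound and the full
member-call vector is kept for transparency. The logical rules are:
OR — positive if any member calls positive; majority — positive only
on a strict majority, with ties negative (for four members, 2-of-4 is
negative; the generalization to any member count keeps "strictly more
positives than negatives"). A compound for which some member failed
(unparseable record) is excluded from ensemble calls and metrics with
a warning, never imputed: fabricating a member vote would silently
bias the rule.

Trained combiners (RF, SVM, XGBoost; library defaults, fixed seed)
see only the binary member calls. With *m* members there are at most
2^m distinct inputs, so the fitted combiner is collapsed at training
time into its complete truth table over all 2^m patterns. This makes
the combiner exactly serializable as text (auditable like everything
else in the exchange), trivially deterministic at prediction time,
and total on patterns unseen in training. `cutout()` drops one member
by origin label; rule ensembles keep their rule, metamodels are
retrained on the stored training series restricted to the remaining
members.

## Validation-set deduplication

A shared validation set is only fair if no partner's training
compounds are in it. Each partner runs `flagDuplicates()` locally:
criterion 1 compares InChIKeys on their first 25 characters
(deliberately ignoring the final two, which encode protonation state
and standardization version, so salts/ionization variants match);
criterion 2, applied only when criterion 1 misses, computes the
maximum Tanimoto similarity of the circular fingerprints against the
training series and flags at 0.95 or above. The best similarity is
reported for every record, flagged or not, so the broker can study
threshold sensitivity. The exchanged flag file holds record ids,
booleans, the matching reason and the similarity — no structures.
`consolidateFlags()` removes the union of all parties' flags and
reports per-party and overall counts. Tanimoto similarity of two
all-empty fingerprints is defined as 1 (with a warning): two
molecules with no features are indistinguishable to the descriptor
and must not slip through the filter.

## Chemical-space view for locked models

A locked model cannot show its training structures, but its stored
per-feature means and standard deviations support an approximate
coverage view: `generateSyntheticObjects()` draws as many synthetic
descriptor vectors as the training series had compounds, each feature
independently normal with the stored moments (`sd = 0` features stay
constant). `projectChemicalSpace()` scales a predicted series with
the model's statistics, fits a 2-component PCA on those scaled
descriptors, and projects the cloud onto the same plane, reporting
the variance fraction the two components explain. Because the
features are independent draws, the cloud ignores the correlation
structure of real fingerprints and tends to be narrower than the
true training distribution — the view is a coverage sketch, not a
density estimate, and the package labels it approximate. A pooled
all-model view concatenates the per-model scaled blocks of the
predicted series, placing each cloud in its own block with the other
blocks at 0 (the scaled-space mean); this is the simplest consistent
completion for a multi-model panel and is likewise labeled
approximate. Interactive selection of compounds is out of scope;
coordinates are exported as CSV so any front-end can draw them.

## The synthetic-data generator

The generator exists so that every step above is testable without
proprietary data. Molecules are enumerated from a fragment grammar —
curated scaffold cores with substitution slots crossed with a
substituent alphabet — which guarantees chemically valid,
standardizer-stable SMILES (nitro groups are written in their
zwitterionic form, which the neutralization step preserves). Four
aromatic scaffold pools (benzenoid, azines, five-membered
heteroaromatics, fused/biaryl systems) plus an aliphatic pool act as
distinct chemical-space regions; partner series draw from different
pools, which is what makes the multi-partner setting non-trivial.

The activity rule is a structural alert with a context exception:
a nitro group on an aromatic ring is activating — label 1 — unless an
ortho ring atom carries a heavy substituent, in which case it is
sterically deactivated and the molecule is rule-negative. The
exception mirrors a classic structure–activity observation for
aromatic nitro compounds and, more importantly for the simulation,
it makes chemical-space coverage matter: the deactivating ortho
contexts are scaffold-specific, so a model trained on one pool
recognizes its own deactivated decoys but not another pool's. Without
the exception the bare alert transfers essentially perfectly across
scaffolds and every partner model saturates at the label-noise
ceiling, leaving ensembles nothing to improve. Deactivated-nitro
decoys make up 25% of the rule-negative molecules by default (where
the pool provides them). The slot-level activating/deactivated
classification is derived by running the rule detector itself on
representative instantiations, so generator labels and detector
(`hasActivatingNitro()`) agree by construction.

Observed labels are the rule labels XOR seeded binomial flips
(default noise in the multi-partner simulation: 5%, a plausible
assay-reproducibility figure). Ground truth — pre-noise rule labels,
flip positions, planted duplicate ids — is stored in the series
object, enabling exact oracles downstream.

Two constructions keep experiments clean. First, each pool's combo
space is split into two reserved halves ("train"/"cvd") by a
permutation-invariant character signature, so that training and
validation series never share a molecule by accident — symmetric ring
positions can generate the same molecule from differently ordered
substituent tuples, which is why the signature must be
order-independent. Second, `generatePartnerPartition()` plants exact
copies of partner compounds into the validation series at requested
counts and records them, giving the deduplication tests a known
answer.

What the generator does **not** emulate: realistic mutagenicity SAR
beyond the single alert-plus-exception, the size and diversity of
real corporate collections, tautomerism, stereochemistry, or
measurement error structure beyond symmetric label flips. Passing
tests on generated data therefore demonstrate that the machinery is
correct and that the protocol behaves as designed under a known
signal, not that any particular predictive performance would be
attained on real assay data.

## Problem sizes and seeds

The test suite and the acceptance script use desk-scale sizes chosen
to exercise every code path with comfortable statistical margins:
partner series of 200 compounds, a validation series of 400 (about
380 after cleanup), signal-recovery runs at n = 400, the
feature-selection check on a mixed five-pool series of 3,500 (which
offers over a thousand informative bits, so the top-500 selection is
a genuine cut), and 20 independent models for the export/import
equivalence sweep. All randomness — generation, undersampling, fold
assignment, combiner training, synthetic clouds — flows from explicit
integer seeds recorded in the objects, so every reported number is
reproducible from its seed.

## Known limitations

* The fingerprint's aromaticity perception is heuristic; exotic ring
  systems outside the generator's vocabulary may be typed
  differently than a full aromaticity model would.
* The confidential format protects against disclosure, not
  inversion; coefficients on 500 named bits leak *some* information
  about which substructural features mattered.
* The synthetic-cloud coverage view understates training-series
  spread (independence assumption) and its pooled variant is an
  ad-hoc block construction.
* PLS-DA with a scalar class code is the only supported learner, by
  design: its collapsed linear form is what makes the structure-free
  export possible. Regression end points and multiclass labels are
  out of scope.
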