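# ConfQSAR

Collaborative QSAR modeling without sharing chemical structures.

Pharmaceutical and chemical companies hold large in-house series of
compounds annotated with assay outcomes (for example AMES mutagenicity:
positive/negative), but the structures are confidential and cannot be
pooled into one joint training set. ConfQSAR implements a simple
alternative to federated learning for this setting: every partner
trains a **local** binary PLS-DA model on its own series, exports it as
a **confidential archive** that carries only model coefficients and
per-feature scaling statistics — no structures, identifiers or
provenance — and a neutral coordinator combines the exchanged archives
into **ensemble metamodels** that outperform the individual models.
The package is aimed at computational toxicologists and cheminformatics
groups who want to run or study such an exchange end to end, including
the data-hygiene and audit steps that make it trustworthy.

## What is inside

**Local models.** Compounds are standardized (largest organic
fragment, charge neutralization, canonicalization) and described by
feature-typed (pharmacophoric) circular fingerprints, radius 2, folded
to 2048 bits. The protocol is: random undersampling of the majority
class; autoscaling of every bit to zero mean / unit variance;
univariate top-*K* selection (ANOVA-F score, *K* = 500); PLS1
regression on the 0/1 class code. The number of latent variables *a*
and the decision threshold *t* are chosen by grid search maximizing the
mean Matthews correlation coefficient in a stratified 5-fold
cross-validation. The fitted model collapses to a linear form

    score(x) = sum_j  b_j * (x_j - m_j) / s_j  +  b_0,
    call     = positive  iff  score >= t

with one coefficient `b_j`, mean `m_j` and standard deviation `s_j`
per selected bit `j`. Quality is reported as sensitivity TP/(TP+FN),
specificity TN/(TN+FP), and

    MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

**Confidential exchange.** `exportConfidential()` writes a single
compressed `.qcm` archive holding exactly three human-readable text
files — `parameters.txt`, `scaler.tsv`, `coefficients.tsv` — which is
the bare minimum needed to predict. `importConfidential()` yields a
locked model that predicts identically to the original;
`auditArchive()` verifies the member list, the line grammars, the
cross-file index consistency and the absence of anything that parses
as a structure (SMILES, InChI, InChIKey, molblock signatures).

**Ensembles.** Locked models from several partners combine by logical
OR (positive if any member is positive), majority voting (positive
only on a strict majority; ties are negative), or a trained combiner
(random forest, SVM or XGBoost) whose only inputs are the members'
binary calls — for four members there are just 2^4 = 16 possible input
patterns, so the fitted combiner is stored as its complete truth
table. `cutout()` rebuilds an ensemble without one partner's model for
fair validation on that partner's own compounds.

**Validation-set hygiene.** `flagDuplicates()` marks validation
compounds present in a partner's training series, first by
InChIKey match ignoring the protonation-sensitive last two characters,
then by Tanimoto similarity of the fingerprints at a 0.95 threshold;
`consolidateFlags()` is the honest-broker step that removes the union
of all flags. Only record ids and booleans ever leave a company.

**Chemical-space view for locked models.** Structures are gone, but
the stored means/SDs allow `generateSyntheticObjects()` to draw a
normal synthetic cloud of the training-series size, and
`projectChemicalSpace()` overlays it with a predicted series on a
2-component PCA plane to show coverage (applicability domain) —
approximately, and documented as such.

**Synthetic data.** A fragment-grammar generator
(`generateSeries()`, `generatePartnerPartition()`) builds valid,
standardizer-stable molecules from scaffold pools that act as distinct
chemical-space regions, with a substructure-driven activity signal
(an aromatic nitro group activates, unless sterically deactivated by
an ortho substituent), seeded label noise, and planted duplicates —
so the whole workflow is testable without any proprietary data.

## Worked example

```r
library(ConfQSAR)

train <- generateSeries(200, positiveFraction = 0.5, flipNoise = 0.05,
                        scaffoldPool = "benzenoid", seed = 1)
train
#> AnnotatedSeries "synthetic_benzenoid_1": 200 molecules (99 positive, 101 negative)

model <- fitPLSDA(train, modelConfig(seed = 1))
model
#> LocalModel (open lock): 308 features, 3 latent variable(s), threshold 0.6,
#>   trained on 198 compounds [series: synthetic_benzenoid_1]

cv <- crossValidate(train, modelConfig(seed = 1))
round(cv$mean, 2)
#> sensitivity specificity         mcc
#>        0.96        0.96        0.92

exportConfidential(model, "modelA.qcm", originLabel = "A")
locked <- importConfidential("modelA.qcm")
locked
#> ConfidentialModel (closed lock): 308 features, 3 latent variable(s),
#>   threshold 0.6, trained on 198 compounds [origin: A]
auditArchive("modelA.qcm")$pass
#> TRUE

test <- generateSeries(150, 0.5, 0.05, "benzenoid", seed = 42,
                       comboHalf = "cvd")
p <- predictConfidential(locked, test)
cc <- confusionCounts(p$call, seriesLabels(test))
round(c(sensitivity = sensitivity(cc), specificity = specificity(cc),
        mcc = mcc(cc)), 2)
#> sensitivity specificity         mcc
#>        0.93        0.95        0.88
```

The balanced training set shrinks from 200 to 198 compounds (99 per
class), the model keeps the 308 informative bits this series offers,
and the locked model reproduces the open model's predictions exactly —
here with MCC 0.88 on unseen molecules from a reserved half of the
same chemical-space region. `runCollaborativeSimulation()` runs the
full four-partner exercise (generation, deduplication, four local
models, audited exchange, OR/majority/metamodel ensembles, cutout
validation) in one call.

A thin command-line wrapper covering the same workflow is installed as
`inst/scripts/qcm` (subcommands `synth`, `build`, `predict`, `export`,
`audit`, `ensemble-build`, `dedup-flag`, `adspace`, `validate`, ...).

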