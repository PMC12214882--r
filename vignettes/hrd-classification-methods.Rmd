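---
title: "Methods: channel-based HRD classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-based HRD classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hrdsig)
```

## The problem and the model

Homologous-recombination-deficient (HRD) tumors cannot repair double-strand
breaks by homologous recombination and instead accumulate a recognizable
constellation of somatic scars: deletions healed by microhomology-mediated
end joining, widespread loss of heterozygosity (LOH) of intermediate size,
and mid-size heterozygous amplifications. HR-proficient (HRP) tumors, by
contrast, show relatively more of the ubiquitous CpG-transition mutational
background and retain large diploid or genome-doubled segments. `hrdsig`
operationalizes this contrast as a six-dimensional feature vector per tumor
and a linear decision rule over it.

The pipeline is:

1. **Channel classification.** Substitutions, indels and allele-specific
   copy-number segments are classified into the standard SBS-96, ID-83 and
   CN-48 schemas. These classifiers are pure functions of the record plus
   its local sequence context, so no reference genome is needed at
   classification time.
2. **Feature collapse.** Channel counts are collapsed into six features:
   `n_ct_g`, `n_cg_t` (substitution proportions), `del5_mh` (count of
   `5:Del:M:1..5` events), `loh_1_40`, `het3_9_10_40`, `het2_4_gt40`
   (segment proportions). Feature order is a fixed model contract.
3. **Classification.** Features are z-scored with training-set means and
   standard deviations, scored by a linear-kernel L2-regularized SVM, mapped
   to probabilities by a Platt sigmoid, and thresholded at 0.50 (a sample
   with probability exactly 0.50 is HRD).

The modeling assumptions are deliberately modest: the features are
approximately monotone evidence for or against HRD, a linear boundary in
z-scored feature space is adequate (supported by the clear two-class
separation in the feature principal components), and the training labels —
from genomic scar scores at the established thresholds (42 breast,
63 ovarian) or BRCA1/2 defects — are treated as ground truth.

## Channel schema conventions

* **SBS-96**: purine-reference records are reverse-complemented (mutated
  base, alternate base and both flanks) before naming, making
  classification strand-symmetric; this is verified exhaustively over all
  192 raw contexts.
* **ID-83**: 1 bp events are named by the pyrimidine of the affected base
  and the number of *additional* adjacent copies across both flanks
  (capped at 5). Longer events count whole adjacent copies of the event
  motif. Deletions of length L ≥ 2 with no whole adjacent copy but partial
  junction homology are microhomology channels, with
  MH = max(prefix match into the 3' flank, suffix match into the 5' flank),
  capped at min(L − 1, 5); repeat context takes precedence over
  microhomology. Events whose category cannot be settled by the available
  flank raise an error rather than guessing; 25 bp flanks settle every
  category. Complex indels (both inserted and deleted bases) are outside
  the schema and are dropped with a warning at read time, as are
  mitochondrial records.
* **CN-48**: zygosity is HomDel (TCN 0), LOH (minor 0, major ≥ 1) or HET
  (minor ≥ 1); TCN classes are 1/2/3-4/5-8/9+ and size bins are
  left-open/right-closed — (0,100kb], (100kb,1Mb], (1,10Mb], (10,40Mb],
  (40Mb,∞) — so a segment of exactly 40 Mb falls in 10–40 Mb, matching the
  inclusive "between 10 and 40 Mb" reading. HomDel uses the reduced bins
  (0,100kb], (100kb,1Mb], (1Mb,∞).

Segment coordinates follow the ASCAT-style 1-based inclusive convention by
default (size = end − start + 1); readers accept a `coord_convention`
argument for half-open inputs. All homozygous-deletion channels remain part
of the CN-48 catalog and therefore of the denominator of the CN proportion
features; CN features are normalized by segment count, not genome length —
both choices are fixed conventions of this implementation and are encoded
in the shipped channel→feature map (`inst/extdata/channel_feature_map.tsv`).
The `het3_9_10_40` grouping includes the 9+ TCN class ("TCN of at least 3");
`het2_4_gt40` includes classes 2 and 3-4 only.

## Feature engineering (channel enrichment)

Enrichment between labeled cohorts is assessed per channel with a two-sided
Fisher exact test. A Fisher test needs counts, not averaged proportions, so
the 2×2 table pools event counts within each group: (events in the channel
vs all other events of that channel class) × (HRD vs HRP). The volcano
x-axis, in contrast, is computed on group-mean *proportions*:
log2(mean HRD proportion / mean HRP proportion), with a pseudo-proportion ε
guarding zero means (default: half the smallest nonzero group mean of the
channel's class; configurable). Channels empty in both groups are inert
(p = 1, log2FC = 0). P values are Benjamini–Hochberg adjusted jointly
across all 227 channels by default; a per-class family is available because
the choice of family is a genuinely open convention — the joint family is
the stricter default for a single pooled volcano.

Selection applies both gates strictly: |log2FC| > 0.75 (WGS) or 0.25 (WES),
and −log10(adjusted p) > 3. Cross-assay consensus is the per-direction set
intersection. The six-feature map itself is fixed; the engineering module
is a diagnostic for verifying that a cohort reproduces the expected
enrichment structure, not a mechanism for re-deriving features.

## Model fitting choices

* **Scaling**: StandardScaler-style z-scoring fit on the full training set
  before cross-validation (the same convention for WGS and WES; `del5_mh`
  stays a raw count by default and the scaler absorbs its scale).
* **C selection**: grid {0.01, 0.1, 1, 10, 100}, stratified 10-fold CV,
  mean held-out AUC as the criterion, ties broken toward the smaller
  (stronger) regularization. Folds are a deterministic function of the
  seed. With fewer samples than folds in a class, the fold count is reduced
  with a warning; single-class training is an error.
* **Probabilities**: Platt sigmoid fit on pooled cross-validated decision
  values with Platt's regularized targets, optimized by BFGS. Fitting on
  out-of-fold decision values avoids the overconfidence of calibrating on
  resubstitution values; the regularized targets keep the fit finite when
  the training cohort is linearly separable, which the default synthetic
  conditions nearly are.
* **Reported weights**: the final refit weights plus the mean of per-fold
  weights across the CV folds (`tidy()` exposes both; `autoplot()` draws
  them). Class imbalance is not reweighted.
* **Threshold**: 0.50 stored on the model as the operating point; the
  decision rule is `probability >= threshold`. Alternative operating points
  (e.g. the 0.70 convention used by signature-based tools) are a `predict()`
  argument, not a refit.
* **Serialization**: versioned JSON with 17 significant digits, which
  round-trips IEEE doubles exactly; identical seeds therefore reproduce
  byte-identical model files.

AUC is computed as the midrank Mann–Whitney statistic and is tested against
a brute-force pairwise concordance count; evaluation reports sensitivity,
precision and F1 with HRD as the positive class, and reports AUC as missing
on single-class truth.

## The synthetic cohort generator

The generator defines the package's reference study conditions: labeled
cohorts whose channel statistics reproduce the qualitative HRD/HRP
enrichment directions — CpG transitions elevated in HRP, NpCpT C>G and
microhomology deletions in HRD, LOH 1–40 Mb and TCN 3–9 amplifications of
10–40 Mb in HRD, large TCN 2–4 heterozygous segments in HRP.

Per sample, a baseline channel probability vector (uniform within each
schema, with fivefold CpG-transition mass so substitution profiles resemble
a generic tumor background) is tilted multiplicatively by the class effect
sizes, renormalized, jittered with Dirichlet noise (concentration 500, i.e.
a few percent relative noise on common channels), and event counts are drawn
multinomially at a Poisson burden. Defaults: 2500 substitutions, 150 indels
and 60 segments per WGS sample (typical orders of magnitude for breast WGS)
and 80/10/40 for WES; effect sizes 2–3×, chosen once so that class-mean
log2 fold changes land near the WGS selection threshold (≈0.75–1.5) and the
volcano-selection behavior is genuinely exercised rather than saturated.

At `level = "records"` the generator emits concrete records on a toy genome
(3 chromosomes × 60 Mb): substitution contexts and indel junction sequences
are constructed to realize the assigned channel exactly — constrained
junction bases make the intended repeat count or microhomology length exact
— and half of all records are emitted on the purine strand to exercise
reverse-complement handling. Round-trip fidelity (generator → record →
classifier → intended channel) is tested across every channel.
`level = "catalog"` draws the identical channel counts (same RNG stream)
and skips record emission; the replicate studies (weight-sign agreement and
null selection across 100 seeds) run at catalog level, which is
distributionally identical and keeps the full test suite and the acceptance
script within a few minutes on one CPU. Study sizes used by the validation
suite: 100 + 100 training and 50 + 50 held-out samples for the headline
recovery run (records level), 100 seeded replicates for the sign and null
studies (catalog level).

What the generator does *not* emulate — and hence what passing tests cannot
certify about real data: mutational-signature mixtures beyond the six
feature groups, regional mutation-rate and replication-timing structure,
purity/subclonality, segmentation noise and wavy-coverage artifacts, real
exome capture geometry (targets are uniform random), and label noise in the
ground truth. Performance on the synthetic conditions is a correctness
check of the machinery, not a clinical performance estimate.

## Downsampling

WGS→WES downsampling keeps a substitution when its position falls in a
target interval (BED, 0-based half-open; merged and sorted on read), a
deletion when any deleted base overlaps, and a copy-number segment — with
its original coordinates and size — when it overlaps any target base.
Keeping whole segments reflects that CN-48 size bins describe genomic, not
captured, extent; exome-derived segmentation still estimates genomic
breakpoints. Restriction is idempotent and commutes byte-for-byte with
feature derivation, which is what makes "derive then restrict" pipelines
trustworthy. Chromosome-name dialects ("chr1" vs "1") are normalized on
both sides.

## Degenerate inputs and numerical corner cases

* Samples with zero events in a channel class get 0 for that class's
  proportion features and a `low_confidence` flag (with a warning), rather
  than being rejected; zero-mutation WES samples are common.
* Constant features in training keep scale 1 (with a warning) instead of
  dividing by zero.
* Probability 0/1 saturation in the Platt fit is clamped at 1e−12 inside
  the likelihood only.
* A probability exactly at threshold is HRD ("at least 0.50").
* Fisher tables with an empty channel in both groups short-circuit to
  p = 1 rather than testing a degenerate margin.

## Known limitations

* The classifier is as good as its training labels; scar-score thresholds
  and BRCA annotations are imperfect ground truth, and the package takes
  them as given.
* No pretrained clinical model is bundled; analyses start from cohorts the
  user supplies or simulates.
* Rearrangement-based evidence (structural-variant signatures) is out of
  scope by design, as is computing the LOH/TAI/LST scar score.
* VCF input requires a reference FASTA for flanking context; without one,
  use the TSV dialect that carries flanks per record.
* The ID-83 classifier requires flanks long enough to settle the category
  (25 bp always suffices) and refuses to guess otherwise.
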