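---
title: "Methods: episignature discovery, scoring and validation in episignr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, scoring and validation in episignr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episignr)
```

## The problem

A DNA methylation episignature is a set of CpG probes whose joint
methylation pattern separates carriers of pathogenic variants in one gene
from unaffected controls. In rare neurodevelopmental disorders — here the
motivating setting is a chromatin-remodeling disorder studied with a
handful of cases against a bank of controls and other-disorder cohorts —
such signatures serve three diagnostic purposes: reclassifying variants
of uncertain significance (VUS), screening unresolved cases for matches,
and detecting mosaic carriers, whose diluted signal falls between cases
and controls. `episignr` implements the full workflow and, because raw
patient methylation data are typically unavailable, ships a synthetic
cohort generator so that every claim the package makes is backed by a
test on data with known ground truth.

## Differential methylation model

Statistics are computed on M-values, `M = log2(beta / (1 - beta))` with
betas clipped to `[eps, 1 - eps]` (`eps = 1e-6`); the logit transform
approximately stabilizes the variance of methylation fractions. Effect
sizes are reported on the beta scale (`delta_beta` = mean case beta minus
mean control beta), the scale on which methylation differences are
conventionally quoted.

Each probe gets a linear model with a case/control indicator and optional
additive covariates. With so few cases, per-probe variance estimates are
noisy; they are therefore shrunk toward an empirical-Bayes prior: the
per-probe residual variances `s_g^2` (on `d_g` df) are modeled as scaled
F-draws around a prior `(d0, s0^2)` estimated by moment-matching of the
log-variances, with the prior df obtained from the inverse trigamma
function (Newton iteration, relative tolerance `1e-10`). The posterior
variance is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, the moderated t divides
the M-scale group effect by the posterior standard error, and p-values
use `d0 + d_g` df capped at the pooled residual df across probes. When
the log-variances show no excess dispersion the prior df is infinite and
the common variance is the arithmetic mean of the `s_g^2`, which makes
exactly-equal variances a fixed point: the moderated t then reduces to
the classic t. These conventions agree with the reference implementation
in `limma`, which the test suite uses as an independent cross-check only;
the moderation itself is authored here.

Multiple testing uses Benjamini–Hochberg throughout (per-probe q-values,
and again across DMR candidates). Probes with any missing beta among the
analysed samples are dropped — the package's stated NA policy — and
readers reject out-of-range values rather than clamping them.

### Probe selection

Defaults: `q_max = 0.01`, `delta_min = 0.05`, `max_probes = 1000`,
ranking by `|moderated t|` with lexicographic probe-id tie-breaks so
selection is invariant to row order. Published signature sizes (a few
hundred probes) are data-dependent outcomes, not targets; the defaults
are chosen so that a planted 0.10–0.15 beta shift at 14-vs-30 sample
sizes is recovered with both sensitivity and precision above 0.8, which
the acceptance tests verify.

## Classifier and MVP score

The classifier is a binary linear-kernel SVM, case versus pooled
controls + other-disorder samples, trained on the beta values of the
selected probes. Choices worth recording:

- **Linear kernel, cost C = 1.** Standard for the p >> n regime; both
  exposed as arguments.
- **Hand-implemented solver.** No SVM package is available in the target
  environment, so the L2-regularised squared-hinge primal is minimised
  with L-BFGS from a zero start (analytic gradient). The squared hinge
  makes the objective smooth; the solve is deterministic, and retraining
  reproduces weights to 1e-8, which a test asserts.
- **Platt calibration.** The decision values are mapped to [0, 1] by a
  sigmoid fitted with Platt's regularised targets
  `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, which keeps the fit finite even
  on separable training data. The calibrated output is the Methylation
  Variant Pathogenicity (MVP) score. The source study reports
  probability-like MVP scores without stating the calibration method;
  Platt scaling is this package's declared choice.
- **Beta input, not M.** Classification uses the same substrate as the
  heatmaps and MDS (methylation fractions); an `input_scale = "m"`
  switch is provided.
- **Training split.** All cases train; controls and each other-disorder
  cohort are split 75/25 stratified by cohort label, deterministic under
  the seed; cohorts with fewer than two samples go wholly to train with
  a warning. The held-out 25 % provide the specificity check.
- **Call threshold.** Screening flags MVP >= 0.5 by default; the
  threshold is exposed because "close to 1" in diagnostic practice is a
  policy decision, not a statistic.
- **One binary model per signature.** Multi-disorder classifier boards
  are reduced to independent binary signatures here; cross-signature
  responses are observable by scoring, not modeled.

Leave-one-out cross-validation re-runs the entire discovery path — probe
selection, partitioning, training — without the held-out case, then
scores it and records whether it joins the case branch when the
selected-probe dendrogram is cut in two. Rounds equal the number of
cases; at least three cases are required.

## Unsupervised structure

Heatmap ordering uses agglomerative clustering on Euclidean distances
over the selected probes' betas, Ward (`ward.D2`) linkage by default.
The linkage is not stated in the motivating study; Ward is the
convention for episignature heatmaps and is configurable. Samples are
sorted by id before clustering so results are independent of column
order.

The MDS embedding is classical Torgerson scaling: double-centred squared
distances, top-k eigenvectors scaled by root eigenvalues (via
`stats::cmdscale`), with each axis's sign fixed so its first nonzero
loading in sample-id order is positive — embeddings and tests are
therefore reproducible. Classical MDS reproduces intrinsically
2-D Euclidean configurations exactly, which the suite checks to 1e-9
against an eigendecomposition oracle. Mosaic intermediacy is assessed by
projecting samples onto the axis from the control centroid (0) to the
case centroid (1).

## DMR calling

The motivating study's DMR tool and parameters are unpublished, so the
package defines a transparent run-based caller rather than imitating an
unknown one: probes significant at `q <= 0.05` seed regions that extend
while consecutive significant probes lie within `maxgap = 1000` bp and
share direction; runs with at least `min_probes = 3` members are
emitted. Member one-sided z-scores (direction-aligned, so
mixed-direction regions cannot arise) are Stouffer-combined with equal
weights; region p-values are BH-adjusted across candidates. Region
bounds are 0-based half-open `[first probe, last probe + 1)`. Published
DMR counts are not reproducible targets; what the tests pin down is
recovery of planted probe clusters (interval Jaccard >= 0.8) and the
structural invariants of every emitted region.

## Context annotation

CpG context follows the island-distance definitions: island; shore
within 0–2 kb of an island boundary; shelf within 2–4 kb; inter-CGI
beyond, with distances measured to the nearest island edge on the same
chromosome (gap convention: the first base outside an island is at
distance 0). Gene context: promoter 0–1 kb upstream of a TSS
(strand-aware), promoter+ 1–5 kb upstream, CDS, intergenic — with
precedence in that order, so a probe upstream of one gene and inside the
CDS of another is called promoter; among same-category genes the nearest
TSS wins. UTRs are not modeled because the four-category scheme is taken
as defined. DMRs are annotated at their midpoint (a convention this
package declares; the source does not state one). Summaries report
integer percentages that sum to exactly 100 (half-away-from-zero
rounding, remainder assigned to the largest category). Interval
arithmetic uses GenomicRanges/IRanges; a base-R linear-scan oracle in
the tests confirms category-for-category agreement on random manifests.

## Cross-cohort comparison

Each cohort contributes its top `min(#DMPs at FDR < 0.05, 500)` probes,
ranked by q then `|t|` — the published analyses say "top 500 DMPs"
without a ranking key, so that key is a declared choice here. The
overlap matrix is deliberately asymmetric:
`entry(y, x) = 100 |top(y) ∩ top(x)| / |top(y)|`. The cohort tree
aggregates each cohort to per-probe median betas over the union of all
cohorts' top sets (whether published trees of this kind use per-cohort
sets or their union is ambiguous; the union is the declared choice) and
clusters the median vectors with Ward linkage. Only synthetic surrogate
cohorts ship with the package; published overlap percentages depend on
proprietary cohort databases and are out of reach by design.

## Clinical prevalence tables

Prevalences are computed against explicit responder denominators:
individuals with an unknown state for a feature never enter the
denominator. Percentages are rounded half away from zero to the nearest
integer, except exact half-integers, which keep one decimal (87.5 stays
87.5) — the convention of the motivating clinical table. That table's
own rounding is internally inconsistent for four rows (e.g. printing
83 where 36/43 rounds to 84, and 36.5 where the rule gives 37); the
package flags its rule rather than imitating the inconsistency, and the
acceptance test asserts only rows the rule reproduces. The packaged
fixture assigns per-individual states deterministically (present first,
then absent, then unknown, in individual order) so that every
series-level count matches the published table exactly; the joint
phenotype of any single synthetic individual is not meaningful — the
per-feature counts are the contract.

## Synthetic cohorts: what they emulate, and what they do not

`sim_config()` defaults state the simulated world once:

- **Design:** 14 discovery cases vs 30 controls (the fixture suite uses
  40 controls plus three 12-sample other-disorder cohorts, 3 validation
  cases, 3 unresolved carriers, 4 VUS non-carriers, and mosaic carriers
  at dilutions 0.3 and 0.1) — the inventory of the motivating study.
- **Background:** per-probe means drawn from a bimodal distribution
  (uniform on [0.1, 0.3] or [0.7, 0.9] with equal probability),
  mimicking the mostly-unmethylated/mostly-methylated split of array
  CpGs; individual betas are Beta(mean·precision, (1−mean)·precision)
  with `precision = 50`, a realistic array-level dispersion.
- **Signature:** 200 probes shifted by `mean_delta = 0.15` on the mean
  scale (0.10 in the recovery acceptance test; the true biological
  effect size is unpublished, so these defaults are chosen for
  testability), `hyper_fraction = 0.9` so the signature is predominantly
  hypermethylated while both directions remain testable; shifted means
  are clipped to [0.02, 0.98] and emitted betas to [0.001, 0.999].
- **Mosaics:** mean profile `f · case + (1 − f) · control` — the
  dilution model that makes mosaic carriers intermediate by
  construction.
- **Batch effects:** optional additive logit-scale shifts, off by
  default.
- **Determinism:** one global seed; per-sample and per-stage substreams
  are derived arithmetically (all below 2^31), so subsets are
  reproducible and repeated fixture generation is byte-identical.

Not emulated: probe cross-reactivity, SNP-affected probes, cell-type
composition, spatial correlation of background probes, and array
normalization artefacts. A green recovery test therefore establishes
that the pipeline's statistics behave as designed under the stated
noise model — not that any particular published probe list or DMR count
would be reproduced on real arrays, which the unavailable raw data
precludes.

## Numerical choices and degenerate inputs

- Logit clip `eps = 1e-6`; boundary betas are clipped, never errors.
- SVM: L-BFGS, `factr = 1e4`, zero start; Platt fit: BFGS, relative
  tolerance 1e-12, Platt's recommended intercept initialisation.
- Ties: probe selection breaks |t| ties by probe id; clustering sorts
  samples by id; MDS signs fixed by first nonzero loading; the integer
  percent remainder goes to the largest category (first on ties).
- Degenerate inputs: empty probe selection returns an empty set with a
  warning; an empty DMR list writes a header-only TSV; screening an
  empty id set returns an empty table; zero prevalence responders give
  `NA` percent with a warning; single-sample clustering and dims >= n
  MDS are errors.
- Model files are versioned JSON (`schema_version`), and scores
  round-trip exactly through serialization.

## Limitations

The DMR caller and calibration method stand in for unpublished
components and are documented as declared choices; covariate adjustment
is additive only (no surrogate-variable estimation); the simulator's
effect sizes are testability choices, not biological estimates; and the
packaged clinical fixture encodes published aggregate counts, not real
per-individual phenotypes.
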