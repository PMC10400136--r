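---
title: "Scar-based HRD calling and clinicogenomic outcome analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scar-based HRD calling and clinicogenomic outcome analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Homologous recombination deficient (HRD) tumours cannot repair double-strand
breaks by homologous recombination. Two consequences matter clinically.
First, error-prone backup repair leaves characteristic "scars" in the tumour
genome — loss-of-heterozygosity tracts, large-scale copy-number transitions,
telomeric allelic imbalance, and small deletions flanked by microhomology —
so HRD can be read off a segmented allele-specific copy-number profile even
when no causal mutation is found. Second, HRD tumours are preferentially
sensitive to platinum chemotherapy. In metastatic pancreatic cancer the
front-line choice is between a platinum-containing regimen (FOLFIRINOX) and
gemcitabine + nab-paclitaxel (GP), and current guidelines reach for
*BRCA1/2*/*PALB2* mutation status only; a scar-based HRD biomarker could
identify a larger platinum-sensitive population, including tumours whose HRD
has a non-genomic cause.

`hrdscar` implements that whole chain as a tested, reusable package: a
synthetic clinico-genomic cohort generator; scar-feature extraction; a
rule-based per-gene zygosity caller; a gradient-boosted HRD classifier
trained on genotype-derived labels; per-gene co-occurrence statistics; and a
left-truncated survival analysis of real-world overall survival (rwOS) and
time to next treatment (TTNT), stratified by biomarker and treatment. The
real clinico-genomic database this design emulates is proprietary, so the
package's simulator is a first-class component: it defines the statistical
conditions under which every downstream stage is validated.

# The synthetic cohort generator

The generator draws, per patient, a latent HRD state, an HRR-basket
genotype, a segmented copy-number profile with short variants, and a
clinical record. The latent state drives both the genomic scarring and the
differential treatment benefit; nothing downstream ever reads it (it is
emitted in a separate truth table used only by recovery tests).

**Genotypes.** HRD prevalence defaults to 9%. An HRD+ tumour is
"non-genomic" (wildtype across the 14-gene HRR basket BRCA1, BRCA2, ATM,
BARD1, BRIP1, CDK12, CHEK1, CHEK2, FANCL, PALB2, RAD51B, RAD51C, RAD51D,
RAD54L) with probability 0.37; otherwise one driver gene is drawn
(BRCA2-heavy weights, as in pancreatic cancer) and inactivated biallelically
through one of three mechanisms — deep deletion, two pathogenic hits, or a
pathogenic short variant under LOH — chosen with probabilities 0.2/0.3/0.5.
HRD− patients carry only background monoallelic pathogenic variants or
zygosity-unassessable rearrangements; biallelic basket inactivation implies
HRD in this generator. Disease ontologies (PDAC, PA, PACC, PASC, PBC) carry
relative HRD-prevalence multipliers (PACC ≈ 2.2×, PDAC ≈ 0.7×), solved so
the configured marginal prevalence is hit exactly even when an ontology
saturates at probability one.

**Profiles.** Each of 44 autosome arms (approximate GRCh38 arm lengths; sex
chromosomes excluded so the diploid-heterozygous baseline is unambiguous)
starts as a single (total 2, minor 1) segment. Scar events are overlaid at
genome-wide Poisson rates per class — interstitial focal LOH (16–45 Mb),
small LOH (3–12 Mb), interior copy gains that create large-scale
transitions, telomeric allelic-imbalance events, whole-arm LOH — with HRD+
rates several-fold the HRD− background (defaults: 11 vs 1.2 focal LOH, 13 vs
2 LST events, 8 vs 1.2 TAI events). Scarring is simulated directly at
segment level, not through a replication-mechanism model: the classifier
consumes features, not mechanisms. Deletion calls are drawn per sample (7 vs
2.5 expected), microhomology-flanked with probability 0.75 vs 0.15. Forced
overlays realise the genotype mechanisms (a 20 Mb LOH segment over the locus
of an "SV under LOH" gene; a 1 Mb total-copy-0 segment for deep deletions).

**Clinical records.** Survival is Weibull proportional hazards. Shape 1.35
was chosen because a single shape makes the design's anchor set mutually
consistent — median ≈ 14.8 months with 1-year ≈ 58% and 2-year ≈ 25%
survival in the best stratum — which an exponential cannot do. The
reference patient (GP arm, HRD−, average covariates) has median 5.1 months.
Hazard ratios: FOLFIRINOX main effect 0.86, HRD main effect 0.88, and a
FOLFIRINOX×HRD interaction of 0.43, so the latent stratum contrasts are 0.86
(HRD−) and 0.37 (HRD+). Under one proportional-hazards model not all four
published stratum medians can hold simultaneously; the hazard-ratio anchors
and the GP-arm medians were prioritised. Covariates (age, surgery, ECOG,
CA19-9 bin, biopsy tissue) act proportionally with centred contributions so
the baseline median is interpretable marginally. A parallel next-treatment
process at 1.35× the death hazard yields TTNT = min(next treatment, death),
so TTNT never exceeds rwOS on a record. Entry into the observable cohort
(the genomic-profiling report) happens an exponential mean-1-month delay
after first-line start; the true delay distribution of the emulated database
is unpublished, so this is a configurable package choice. Patients whose
follow-up ends before entry are flagged unobservable and excluded (with a
logged count) by every survival routine — the left-truncation selection.
ECOG and CA19-9 are missing completely at random at 25% and 32% (matching
the published missingness margins); MCAR is the assumption under which the
downstream random-sample imputation is exactly right.

# Scar features

All coordinates are 0-based half-open; a segment's length is `end − start`.
A profile must tile every arm exactly (validated, with the first offending
segment named). The feature vector is:

* **gLOH** — genome-wide focal LOH: summed length of LOH segments
  (minor copy 0, total ≥ 1; homozygous deletions are *not* LOH) divided by
  the interrogated genome, excluding segments spanning ≥ 90% of their arm.
  Whole-arm events usually reflect missegregation, not recombination-repair
  scarring.
* **n_loh_interstitial** — LOH segments > 15 Mb, unless the chromosome is
  LOH end to end.
* **n_lst** — large-scale state transitions: after merging same-state
  neighbours and dropping segments < 3 Mb, adjacent same-arm pairs in
  different allele-specific states with both lengths ≥ 10 Mb.
* **n_tai** — telomeric allelic imbalance: telomere-touching segments with
  unequal allele counts spanning less than their whole arm (so the event
  does not reach the centromere).
* **n_breakpoints** — state transitions per arm after merging.
* **mh_del_count**, **mh_del_fraction**, **median_del_len** — deletions
  ≥ 5 bp with ≥ 1 bp flanking microhomology; the fraction is over all
  deletions and defined as 0 when there are none.

The exact feature list behind the published signature is proprietary; this
set is the published scar-feature canon (HRD-LOH, LST with the standard
10 Mb/3 Mb parameters, TAI, gLOH) plus the microhomology-deletion indel
features, which is the documented design decision here. The configuration
seam (`scar_feature_names()`, the feature tibble interface) would admit a
binned genome-wide representation instead without touching the model code.

# Zygosity and biallelic status

Per gene and sample, three rules make a biallelic call: (1) a deep deletion
(a deep-deletion record, or a total-copy-0 segment at the gene locus — no
published copy-number threshold exists, so segment-level zero is used);
(2) two or more pathogenic alterations in the gene (phase is not modelled,
so *in trans* is not required — flagged in the documentation); (3) a
pathogenic short variant whose containing segment is LOH. Any firing rule
suffices; the lowest-numbered one is recorded as metadata only. A single
pathogenic short variant called heterozygous is monoallelic; a pathogenic
alteration whose zygosity cannot be assessed (rearrangement-only, or a
short variant with no heterozygosity call) is "unknown" — the conservative
reading; a gene with no pathogenic alteration is wildtype. Sample-level
labels collapse the 14 statuses into HRRwt / biallelic(+gene set) /
monoallelic-only / unknown-only. The 28-way truth table over
{0,1,2 pathogenic short variants} × zygosity situation × deep deletion ×
rearrangement is asserted in the test suite.

# The classifier

Training labels follow the published scheme: biallelic *BRCA1/2* are
positives, HRRwt samples negatives, everything else excluded (never entering
any fold — asserted). The model is an xgboost binary-logistic ensemble; the
published work specifies no hyperparameters, so ordinary small-data settings
are fixed in the configuration (depth 3, learning rate 0.1, 150 rounds,
row/column subsampling 0.9, single thread for determinism). Seeded
stratified 5-fold cross-validation produces an out-of-fold score for every
labelled sample; the final ensemble is refit on all labelled samples.

No decision-threshold rule is published. The default here selects the
smallest score achieving 95% specificity on the out-of-fold negative scores;
a prevalence-matching mode (calibrate the call rate to a target, e.g. 9%) is
provided as an alternative. A score exactly at the threshold is called
positive. Raw ensemble probabilities are used without recalibration. Two
properties of the label scheme are worth naming because they shape every
downstream number. First, the negatives are contaminated: non-genomic HRD+
tumours are HRRwt and hence labelled negative, which caps measurable
specificity and — usefully — pushes the 95%-specificity threshold above the
contaminating scar-positive scores, so the called prevalence self-calibrates
near truth. Second, every called stratum mixes true and false calls, so
stratified treatment effects measured on *calls* are attenuated toward the
null relative to the latent effects (the acceptance run shows ≈ 0.49 where
the latent stratum contrast is 0.37); the parameter-recovery suite, which
conditions on latent status, recovers the configured interaction to within
simulation error.

# Co-occurrence statistics

Per gene with any biallelic alteration, the 2×2 table of biallelic status
against signature call is tested with a two-tailed Fisher exact test —
implemented by hypergeometric enumeration (every table with the observed
margins whose probability does not exceed the observed one, with the
customary 1e-7 relative tie tolerance) and cross-checked in the tests
against both an independent log-binomial enumerator over all 135,751 tables
with total ≤ 40 and `stats::fisher.test`. Benjamini–Hochberg correction runs
across genes via `stats::p.adjust`; a plotting column caps p at 1e-10 and is
applied only after, never inside, the q-value computation. The reported odds
ratio is the sample cross-product estimate with a Haldane–Anscombe 0.5
correction when a cell is zero — a volcano-plot quantity, not an inferential
one. The landscape partition splits signature-positive samples by priority:
biallelic BRCA1/2/PALB2 > other biallelic HRR > non-biallelic alteration >
HRRwt; exhaustive and mutually exclusive by construction.

# Survival analysis

Kaplan–Meier estimation and Cox models use delayed-entry
(counting-process) risk sets throughout: a patient is at risk at time *t*
only if `entry < t ≤ time`. Estimation is delegated to the survival package
(`survfit`/`coxph` on `Surv(entry, time, event)`, Efron tie handling, Wald
95% intervals), cross-checked in the tests against a hand-written
product-limit estimator and an independent Newton–Raphson partial-likelihood
maximiser in the no-truncation limit. The curve median is the first time
S(t) ≤ 0.5 (undefined if never reached); landmark survival is the
right-continuous step-function value. Missing ECOG/CA19-9 are filled by
seeded random-sample imputation — a single uniform draw from the observed
values per missing cell, matching the stated method; non-missing cells are
never altered and imputed cells are flagged. Multiple imputation is out of
scope by design.

The stratified comparison mirrors the outcome figures: strata are
signature ±, their BRCA1/2/PALB2-mutant/wildtype sub-strata, the combined
either-positive biomarker and the dual-negative group; each row carries
per-arm n, events, median, 1-/2-year landmarks, and the FOLFIRINOX-vs-GP
hazard ratio from a stratum-restricted Cox model adjusted for age, surgery,
ECOG, CA19-9 and tissue (reference coding: ECOG 0, CA19-9 normal, pancreas
tissue, GP arm; age continuous). Stratum-restricted fits were chosen over a
single interaction model because the emulated figures present per-stratum
contrasts; an interaction model remains available through the Cox interface
(`cox_fit` accepts arbitrary formula terms). TTNT's event is operationalised
as the earlier of next-line start and death, censored with follow-up — the
source design never defines it. Strata whose arms lack events, or whose
partial likelihood diverges (monotone likelihood in small strata), are
flagged and reported without a hazard ratio.

# Numerical and reproducibility choices

One seed drives a run; per-stage seeds are derived deterministically (and
kept below 2^31), so cohorts, fold assignments, imputations and boosted
ensembles are byte-identical across reruns — the pipeline manifest records
MD5 checksums and the resolved configuration, and rerun identity is a tested
property. Degenerate inputs are handled explicitly: zero-patient cohorts
write valid header-only files; prevalence 0/1 and censoring rate 1 follow
their limiting behaviour; empty held-out score sets, all-missing covariates,
zero-event strata and zero-positive partitions raise or flag rather than
divide by zero.

# Problem sizes and what the tests do (and do not) show

The validation suite uses cohorts of 260–2,000 patients for pipeline and
classifier checks, 5,000 patients × 200 replicates for interaction-effect
recovery (mean recovered hazard ratio within 10% of the configured 0.4 with
Wald coverage between 0.90 and 0.98), and an 8,358-patient end-to-end run in
the acceptance script, mirroring the emulated genomic cohort's size. Passing
these tests shows the machinery is correct *under the generator's
assumptions*: MCAR missingness, proportional hazards with a Weibull
baseline, exponential entry delay, segment-level scar events with clean
tiling, and genotype-faithful variant calls. Real tumour profiles add
purity/ploidy distortion, segmentation error, subclonality and non-random
missingness, none of which the generator emulates — conclusions about real
cohorts require validation on real data. Known limitations, by design:
no purity/ploidy deconvolution, no germline/somatic distinction, no
propensity adjustment beyond the published covariate list, and raw
(uncalibrated) classifier probabilities.
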