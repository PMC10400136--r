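# hrdscar

Scar-based homologous recombination deficiency (HRD) calling and
clinicogenomic outcome analysis for pancreatic cancer cohorts.

HRD tumours repair double-strand breaks through error-prone backup pathways
and accumulate characteristic genomic scars — loss-of-heterozygosity (LOH)
tracts, large-scale state transitions (LST), telomeric allelic imbalance
(TAI), and microhomology-flanked deletions. Because HRD predicts benefit
from platinum chemotherapy, and because front-line pancreatic cancer therapy
is a choice between platinum-containing FOLFIRINOX and gemcitabine +
nab-paclitaxel (GP), a scar-based HRD signature read from routine
comprehensive genomic profiling can guide regimen selection beyond
*BRCA1/2*/*PALB2* mutation status alone.

`hrdscar` implements the full analysis chain for researchers studying such
biomarkers:

* a **synthetic clinico-genomic cohort simulator** (allele-specific
  copy-number segments on a chromosome-arm genome model, short variants with
  indel geometry, 14-gene HRR-basket genotypes, and survival outcomes with
  delayed study entry) — the real clinico-genomic databases this emulates
  are proprietary, so the simulator is the package's test bed and defines
  the statistical conditions for every claim;
* **scar-feature extraction**: genome-wide focal LOH
  (`gLOH = Σ |LOH segments| / interrogated genome`, excluding ≥90%-arm
  events), interstitial LOH counts (>15 Mb), LST (10 Mb flanks after 3 Mb
  smoothing), TAI, breakpoints, and microhomology-deletion features;
* a **rule-based zygosity caller**: biallelic = deep deletion ∨ ≥2
  pathogenic alterations ∨ pathogenic short variant under LOH; monoallelic =
  single heterozygous pathogenic short variant; otherwise unknown/wildtype;
* an **HRD classifier** (gradient-boosted trees) trained with biallelic
  *BRCA1/2* as positives and HRR-wildtype as negatives, seeded stratified
  cross-validation, and a 95%-specificity (or prevalence-matching) decision
  threshold;
* **co-occurrence statistics**: exact two-tailed Fisher tests of biallelic
  status against signature calls with Benjamini–Hochberg correction;
* **left-truncated survival analysis**: delayed-entry Kaplan–Meier,
  random-sample imputation, and covariate-adjusted Cox models for rwOS and
  TTNT, stratified by biomarker × treatment.

## Worked example

```r
library(hrdscar)
library(dplyr)

cfg    <- sim_config(n_patients = 2000, seed = 1)
cohort <- simulate_cohort(cfg)
cohort
#> <hrd_cohort>
#>   2000 patients, 114861 segments, 6124 variant records
#>   latent HRD+ : 188 (9.4%)

zyg   <- call_zygosity(cohort)
feats <- extract_features(cohort$segments, cohort$variants, cohort$genome)
model <- train_classifier(feats, build_training_labels(zyg$samples), seed = 1)
model
#> <hrdsig_model>
#>   trained on 55 positive / 1770 negative samples
#>   out-of-fold AUROC: 0.979; threshold 0.0027 (specificity mode)

calls <- predict_hrdsig(model, feats)
landscape_partition(zyg$samples, calls)
#> # A tibble: 4 × 3
#>   stratum                          n fraction
#> 1 biallelic BRCA1/2/PALB2         78   0.417
#> 2 other biallelic HRR             28   0.150
#> 3 non-biallelic HRR alteration     4   0.0214
#> 4 HRRwt                           77   0.412
```

The partition says 41% of signature-positive tumours carry no HRR-basket
alteration at all — the non-genomic HRD fraction the scar signature exists
to capture. Gene-level co-occurrence confirms the label genes and their
HRR neighbours:

```r
cooccurrence_test(zyg$statuses, calls) |> head(5)
#>   gene   n_bi_pos n_bi_neg odds_ratio        p        q
#> 1 BRCA2        48        0     1261   9.35e-53 1.03e-51
#> 2 PALB2        23        1      254.  1.30e-23 7.17e-23
#> 3 RAD51D        8        0      172.  5.09e- 9 1.87e- 8
#> 4 BRCA1         7        0      151.  5.64e- 8 1.55e- 7
#> 5 BARD1         7        1       70.5 4.15e- 7 9.13e- 7
```

Stratified outcomes (left-truncated, covariate-adjusted):

```r
bm  <- zyg$samples |> select(sample, core_mut) |>
  inner_join(select(calls, sample, call), by = "sample")
obs <- filter(cohort$clinical, observable)
stratified_comparison(obs, bm, "rwOS") |>
  filter(stratum %in% c("HRDsig+", "HRDsig-"))
#>   stratum folfirinox_n folfirinox_median  gp_n gp_median   ahr conf_low
#> 1 HRDsig+           96             13.0     79      6.59 0.366    0.239
#> 2 HRDsig-          836              5.41   771      4.77 0.886    0.789
```

Signature-positive patients roughly double their median rwOS on FOLFIRINOX
versus GP (adjusted hazard ratio 0.37), while signature-negative patients
gain little (aHR 0.89) — the predictive contrast the biomarker is built to
expose. `run_pipeline(cfg, out_dir)` executes the same chain end to end
with a checksummed manifest, and `report_summary(out_dir)` prints the
prevalence/landscape/co-occurrence/outcome summary. `autoplot()` methods
cover Kaplan–Meier curves, co-occurrence volcanoes and classifier score
distributions; fitted objects have broom-style `tidy()`/`glance()` methods.

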