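Package: hrdscar
Title: Scar-Based Homologous Recombination Deficiency Calling and
    Clinicogenomic Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a genomic scar based biomarker
    of homologous recombination deficiency (HRD) in tumour profiles. Provides
    a synthetic clinico-genomic cohort simulator (allele-specific copy-number
    segments, short variants with indel geometry, HRR-gene genotypes and
    survival outcomes with delayed study entry), scar feature extraction
    (genome-wide focal LOH, interstitial LOH segment counts, large-scale state
    transitions, telomeric allelic imbalance, microhomology deletion
    features), rule-based per-gene zygosity and biallelic status calling, a
    gradient-boosted HRD classifier trained on biallelic BRCA1/2 versus
    HRR-wildtype labels, per-gene co-occurrence statistics with FDR control,
    and left-truncated Kaplan-Meier and adjusted Cox analyses of real-world
    overall survival and time to next treatment stratified by biomarker and
    treatment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
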