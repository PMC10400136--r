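#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the cohort
#' simulator. Defaults encode the study conditions the package emulates: a
#' pancreatic-cancer clinico-genomic cohort in which a latent HRD state
#' (prevalence 9%) drives both genomic scarring and differential benefit from
#' platinum-containing first-line chemotherapy, and in which 37% of HRD+
#' tumours carry no alteration in the 14-gene HRR basket (non-genomic HRD).
#'
#' @param n_patients number of patients to simulate
#' @param hrd_prevalence marginal probability of latent HRD+ status
#' @param hrr_wildtype_given_hrd probability that an HRD+ tumour has no HRR
#'   basket alteration
#' @param gene_alteration_model tibble describing the HRR basket: `gene`,
#'   `weight` (relative probability that a genomically driven HRD+ tumour's
#'   driver is this gene), `monoallelic_rate` and `unknown_rate` (background
#'   per-gene rates, any patient, of a heterozygous pathogenic short variant
#'   and of a zygosity-unassessable alteration such as a rearrangement)
#' @param scar_effect_sizes named list with elements `hrd_pos` and `hrd_neg`,
#'   each a named list of genome-wide expected event counts
#'   (`focal_loh`, `small_loh`, `lst`, `tai`, `whole_arm_loh`, `n_del`) and
#'   the microhomology-flanking probability for deletions (`mh_prob`)
#' @param clinical_model named list of outcome-model parameters; see Details
#' @param ontology_model tibble `ontology`, `weight`, `hrd_multiplier`
#'   (relative HRD prevalence by disease ontology; multipliers are normalised
#'   so the marginal prevalence equals `hrd_prevalence`)
#' @param entry_delay_mean mean (months) of the exponential delay between
#'   first-line therapy start and genomic-profiling report (study entry;
#'   source of left truncation)
#' @param seed integer seed; identical config + seed gives byte-identical output
#'
#' @details
#' `clinical_model` fields (log hazard-ratio scale unless noted):
#' `baseline_median_months` (Weibull median for a reference patient: GP arm,
#' HRD−, age 66, no surgery, ECOG 0, normal CA19-9, pancreas biopsy),
#' `baseline_shape` (Weibull shape; >1 thins the tail relative to
#' exponential), `beta_treatment` (FOLFIRINOX vs GP main effect),
#' `beta_hrd` (HRD+ main effect), `beta_interaction` (FOLFIRINOX x HRD+
#' interaction; exp of it is the design's predictive effect),
#' `beta_age` (per year), `beta_surgery`, `beta_ecog1`, `beta_ecog2`,
#' `beta_ca19_mid`, `beta_ca19_high`, `beta_liver`, `beta_other_tissue`,
#' `ttnt_rate_ratio` (next-treatment hazard relative to death hazard),
#' `censoring_rate` (probability in [0,1] that follow-up ends before death for
#' the reference patient), `p_folfirinox`, `missing_ecog`, `missing_ca19`
#' (MCAR missingness rates).
#'
#' @return object of class `hrd_sim_config` (a named list)
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
#' cfg$hrd_prevalence
#' @export
sim_config <- function(n_patients = 1081,
                       hrd_prevalence = 0.09,
                       hrr_wildtype_given_hrd = 0.37,
                       gene_alteration_model = default_gene_alteration_model(),
                       scar_effect_sizes = default_scar_effects(),
                       clinical_model = default_clinical_model(),
                       ontology_model = default_ontology_model(),
                       entry_delay_mean = 1,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      hrd_prevalence = hrd_prevalence,
      hrr_wildtype_given_hrd = hrr_wildtype_given_hrd,
      gene_alteration_model = gene_alteration_model,
      scar_effect_sizes = scar_effect_sizes,
      clinical_model = utils::modifyList(default_clinical_model(), clinical_model),
      ontology_model = ontology_model,
      entry_delay_mean = entry_delay_mean,
      seed = as.integer(seed)
    ),
    class = "hrd_sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_gene_alteration_model <- function() {
  tibble(
    gene = hrr_genes(),
    ## driver-gene shares among genomically driven HRD+ tumours: BRCA2-heavy,
    ## as in pancreatic cancer
    weight = c(0.17, 0.45, 0.02, 0.04, 0.01, 0.01, 0.005, 0.01,
               0.005, 0.13, 0.02, 0.05, 0.04, 0.01),
    ## background monoallelic pathogenic short-variant rate per gene (any
    ## patient); ATM and CHEK2 carry most passenger heterozygous alterations
    monoallelic_rate = c(0.004, 0.006, 0.012, 0.002, 0.003, 0.002, 0.001,
                         0.008, 0.001, 0.003, 0.002, 0.002, 0.002, 0.001),
    ## background zygosity-unassessable (rearrangement) rate per gene
    unknown_rate = rep(0.0015, 14)
  )
}

#' @rdname sim_config
#' @export
default_scar_effects <- function() {
  list(
    hrd_pos = list(focal_loh = 11, small_loh = 4, lst = 13, tai = 8,
                   whole_arm_loh = 1.5, n_del = 7, mh_prob = 0.75),
    hrd_neg = list(focal_loh = 1.2, small_loh = 1.5, lst = 2, tai = 1.2,
                   whole_arm_loh = 1.0, n_del = 2.5, mh_prob = 0.15)
  )
}

#' @rdname sim_config
#' @export
default_clinical_model <- function() {
  list(
    baseline_median_months = 5.1,
    baseline_shape = 1.35,
    beta_treatment = log(0.86),
    beta_hrd = log(0.88),
    beta_interaction = log(0.37 / 0.86),
    beta_age = 0.012,
    beta_surgery = -0.30,
    beta_ecog1 = 0.30,
    beta_ecog2 = 0.80,
    beta_ca19_mid = 0.20,
    beta_ca19_high = 0.50,
    beta_liver = 0.30,
    beta_other_tissue = 0.10,
    ttnt_rate_ratio = 1.35,
    censoring_rate = 0.25,
    p_folfirinox = 0.52,
    missing_ecog = 0.25,
    missing_ca19 = 0.32
  )
}

#' @rdname sim_config
#' @export
default_ontology_model <- function() {
  tribble(
    ~ontology, ~weight, ~hrd_multiplier,
    "PDAC", 0.710, 0.70,
    "PA", 0.150, 1.55,
    "PACC", 0.018, 2.21,
    "PASC", 0.030, 1.20,
    "PBC", 0.092, 1.00
  )
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort(sprintf("invalid configuration: %s must be a probability in [0,1]", what))
    }
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    abort("invalid configuration: n_patients must be a nonnegative integer")
  }
  chk_prob(cfg$hrd_prevalence, "hrd_prevalence")
  chk_prob(cfg$hrr_wildtype_given_hrd, "hrr_wildtype_given_hrd")
  gm <- cfg$gene_alteration_model
  if (!setequal(gm$gene, hrr_genes())) {
    abort("gene_alteration_model must cover exactly the 14 HRR basket genes")
  }
  if (any(gm$weight < 0) || sum(gm$weight) <= 0) {
    abort("invalid configuration: gene weights must be nonnegative, not all zero")
  }
  chk_prob(gm$monoallelic_rate, "monoallelic_rate")
  chk_prob(gm$unknown_rate, "unknown_rate")
  for (cls in c("hrd_pos", "hrd_neg")) {
    eff <- cfg$scar_effect_sizes[[cls]]
    if (is.null(eff)) abort(sprintf("scar_effect_sizes$%s missing", cls))
    rates <- unlist(eff[setdiff(names(eff), "mh_prob")])
    if (any(rates < 0)) abort("invalid configuration: scar event rates must be >= 0")
    chk_prob(eff$mh_prob, sprintf("scar_effect_sizes$%s$mh_prob", cls))
  }
  cm <- cfg$clinical_model
  if (cm$baseline_median_months <= 0 || cm$baseline_shape <= 0) {
    abort("invalid configuration: baseline hazard parameters must be > 0")
  }
  chk_prob(cm$censoring_rate, "censoring_rate")
  chk_prob(cm$p_folfirinox, "p_folfirinox")
  chk_prob(cm$missing_ecog, "missing_ecog")
  chk_prob(cm$missing_ca19, "missing_ca19")
  om <- cfg$ontology_model
  if (any(om$weight < 0) || abs(sum(om$weight) - 1) > 1e-6) {
    abort("invalid configuration: ontology weights must sum to 1")
  }
  if (any(om$hrd_multiplier < 0)) {
    abort("invalid configuration: hrd_multiplier must be >= 0")
  }
  if (cfg$entry_delay_mean < 0) abort("invalid configuration: entry_delay_mean must be >= 0")
  invisible(cfg)
}

#' @export
print.hrd_sim_config <- function(x, ...) {
  cat("<hrd_sim_config>\n")
  cat(sprintf("  n_patients: %d  hrd_prevalence: %.3f  HRRwt|HRD+: %.2f  seed: %d\n",
              x$n_patients, x$hrd_prevalence, x$hrr_wildtype_given_hrd, x$seed))
  cat(sprintf("  interaction HR (FOLFIRINOX x HRD): %.3f\n",
              exp(x$clinical_model$beta_interaction)))
  invisible(x)
}

## deterministic per-stage seed derivation; keeps any derived seed < 2^31
stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 11L, profiles = 23L, clinical = 37L, impute = 53L,
            train = 71L, pipeline = 89L)
  (as.integer(seed) %% 20000000L) * 100L + offs[[stage]]
}
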