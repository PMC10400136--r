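#' Simulate clinical covariates and survival outcomes
#'
#' Draws per-patient clinical records from a Weibull proportional-hazards
#' model with a treatment-by-HRD interaction. For a reference patient (GP
#' arm, HRD−, age 66, no surgery, ECOG 0, normal CA19-9, pancreas biopsy) the
#' death time is Weibull with median `baseline_median_months` and shape
#' `baseline_shape`; covariates and the FOLFIRINOX/HRD terms act
#' proportionally on the hazard. A next-treatment event runs in parallel at
#' `ttnt_rate_ratio` times the death hazard; time to next treatment (TTNT) is
#' the earlier of next-treatment start and death, so TTNT never exceeds
#' overall survival on the same record. Follow-up ends at an independent
#' censoring time calibrated so the reference patient is censored before
#' death with probability `censoring_rate`.
#'
#' Study entry (the genomic-profiling report) occurs `entry_months` after
#' first-line start, drawn exponential with mean `entry_delay_mean`; patients
#' whose follow-up ends before entry are flagged `observable = FALSE` — they
#' would never be seen in a left-truncated real-world cohort and are excluded
#' (with a logged count) by the survival estimators. ECOG and CA19-9 are
#' missing completely at random at the configured rates.
#'
#' @param truth tibble with `patient_id` and `hrd_status` (and optionally
#'   `ontology`), as from [simulate_genotypes()]
#' @param config a [sim_config()] object
#' @return tibble of patient records (one row per patient)
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 3)
#' cl <- simulate_clinical(simulate_genotypes(cfg)$truth, cfg)
#' all(cl$ttnt_months <= cl$os_months)
#' @export
simulate_clinical <- function(truth, config) {
  validate_sim_config(config)
  withr::with_seed(stage_seed(config$seed, "clinical"), {
    n <- nrow(truth)
    cm <- config$clinical_model
    if (n == 0L) return(empty_clinical())
    hrd <- truth$hrd_status

    age <- round(pmin(95, pmax(30, rnorm(n, 66, 9))))
    sex <- sample(c("female", "male"), n, replace = TRUE)
    surgery <- runif(n) < 0.21
    ecog <- sample(c("0", "1", ">=2"), n, replace = TRUE,
                   prob = c(0.40, 0.48, 0.12))
    ca19 <- sample(c("normal", "<59xULN", ">59xULN"), n, replace = TRUE,
                   prob = c(0.15, 0.43, 0.42))
    tissue <- sample(c("liver", "pancreas", "other"), n, replace = TRUE,
                     prob = c(0.52, 0.29, 0.19))
    folf <- runif(n) < cm$p_folfirinox

    ## covariate contributions are centred at their expectations under the
    ## sampling design, so baseline_median_months is the median for a GP-arm
    ## HRD- patient with average covariates
    lp_cov <- cm$beta_age * (age - 66) +
      cm$beta_surgery * surgery +
      cm$beta_ecog1 * (ecog == "1") +
      cm$beta_ecog2 * (ecog == ">=2") +
      cm$beta_ca19_mid * (ca19 == "<59xULN") +
      cm$beta_ca19_high * (ca19 == ">59xULN") +
      cm$beta_liver * (tissue == "liver") +
      cm$beta_other_tissue * (tissue == "other")
    lp_cov_mean <- cm$beta_surgery * 0.21 +
      cm$beta_ecog1 * 0.48 + cm$beta_ecog2 * 0.12 +
      cm$beta_ca19_mid * 0.43 + cm$beta_ca19_high * 0.42 +
      cm$beta_liver * 0.52 + cm$beta_other_tissue * 0.19
    lp <- lp_cov - lp_cov_mean +
      cm$beta_treatment * folf +
      cm$beta_hrd * hrd +
      cm$beta_interaction * (folf & hrd)

    k <- cm$baseline_shape
    b <- cm$baseline_median_months / log(2)^(1 / k)
    t_death <- b * (rexp(n) / exp(lp))^(1 / k)
    t_next <- b * (rexp(n) / (exp(lp) * cm$ttnt_rate_ratio))^(1 / k)

    r <- cm$censoring_rate
    if (r >= 1) {
      t_cens <- runif(n, 0.1, 36)
      t_death <- pmax(t_death, t_cens + 0.1) # censoring_rate 1 -> no events
    } else if (r <= 0) {
      t_cens <- rep(Inf, n)
    } else {
      t_cens <- b * (rexp(n) / (r / (1 - r)))^(1 / k)
    }

    entry <- if (config$entry_delay_mean > 0) {
      rexp(n, 1 / config$entry_delay_mean)
    } else rep(0, n)

    os_months <- pmin(t_death, t_cens)
    os_event <- as.integer(t_death <= t_cens)
    ttnt_months <- pmin(t_next, t_death, t_cens)
    ttnt_event <- as.integer(pmin(t_next, t_death) <= t_cens)

    ecog[runif(n) < cm$missing_ecog] <- NA
    ca19[runif(n) < cm$missing_ca19] <- NA

    tibble(
      patient_id = truth$patient_id,
      ontology = truth$ontology %||% rep(NA_character_, n),
      age = age,
      sex = sex,
      treatment = ifelse(folf, "FOLFIRINOX", "GP"),
      surgery = surgery,
      ecog = ecog,
      ca19_9_bin = ca19,
      tissue = tissue,
      entry_months = entry,
      os_months = os_months,
      os_event = os_event,
      ttnt_months = ttnt_months,
      ttnt_event = ttnt_event,
      observable = os_months > entry
    )
  })
}

empty_clinical <- function() {
  tibble(patient_id = character(), ontology = character(), age = double(),
         sex = character(), treatment = character(), surgery = logical(),
         ecog = character(), ca19_9_bin = character(), tissue = character(),
         entry_months = double(), os_months = double(), os_event = integer(),
         ttnt_months = double(), ttnt_event = integer(), observable = logical())
}
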