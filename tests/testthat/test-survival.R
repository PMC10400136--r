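test_that("product-limit estimation matches hand-computed steps", {
  d <- data.frame(t = c(1, 2, 3), e = 1, entry = 0)
  km <- km_left_truncated(d, "t", "e", "entry")
  expect_equal(km$steps$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2) # first time S <= 0.5

  # no events: flat curve, median undefined
  d0 <- data.frame(t = c(1, 2, 3), e = 0, entry = 0)
  km0 <- km_left_truncated(d0, "t", "e", "entry")
  expect_true(all(km0$steps$surv == 1))
  expect_true(is.na(km0$median))
})

test_that("delayed entry changes risk sets the way the definition demands", {
  # second patient enters after the first event: first risk set has size 2
  d <- data.frame(t = c(2, 4, 6), e = 1, entry = c(0, 3, 0))
  km <- km_left_truncated(d, "t", "e", "entry")
  expect_equal(km$steps$n_risk[km$steps$time == 2], 2)
  expect_equal(km$steps$n_risk[km$steps$time == 4], 2)
  expect_equal(km$steps$surv, c(1 / 2, 1 / 4, 0))

  # a patient whose follow-up ends before entry is excluded and counted
  d2 <- data.frame(t = c(2, 1), e = 1, entry = c(0, 1.5))
  km2 <- km_left_truncated(d2, "t", "e", "entry")
  expect_equal(km2$n_excluded, 1)
  expect_equal(km2$n, 1)
})

test_that("no-truncation curves equal the classical estimator on random data", {
  withr::with_seed(314, {
    for (rep in 1:100) {
      n <- sample(10:60, 1)
      t <- round(rexp(n, 0.2), 2) + 0.01
      e <- rbinom(n, 1, 0.7)
      d <- data.frame(t = t, e = e, entry = 0)
      km <- km_left_truncated(d, "t", "e", "entry")
      ref <- oracle_km(t, e)
      got <- km$steps[km$steps$n_event > 0, c("time", "surv")]
      expect_equal(got$time, ref$time, label = paste("rep", rep))
      expect_equal(got$surv, ref$surv, tolerance = 1e-12,
                   label = paste("rep", rep))
    }
  })
})

test_that("landmark lookup is the right-continuous step function", {
  d <- data.frame(t = c(6, 12), e = 1, entry = 0)
  km <- km_left_truncated(d, "t", "e", "entry") # steps: (6,.5), (12,0)
  expect_equal(landmark_survival(km, 0), 1)
  expect_equal(landmark_survival(km, 5.99), 1)
  expect_equal(landmark_survival(km, 6), 0.5)
  expect_equal(landmark_survival(km, 11), 0.5)
  expect_equal(landmark_survival(km, 12), 0)
  expect_equal(landmark_survival(km, 99), 0)
  expect_error(landmark_survival(km, -1), ">= 0")
})

test_that("random-sample imputation is seeded, marginal-preserving and minimal", {
  rec <- tibble::tibble(
    ecog = c("0", "1", NA, "0", NA),
    ca19_9_bin = c("normal", NA, ">59xULN", "<59xULN", "normal")
  )
  a <- impute_missing(rec, seed = 5)
  b <- impute_missing(rec, seed = 5)
  expect_identical(a, b)
  expect_false(any(is.na(a$ecog)))
  # non-missing cells are untouched
  expect_equal(a$ecog[c(1, 2, 4)], rec$ecog[c(1, 2, 4)])
  expect_equal(a$ecog.imputed, is.na(rec$ecog))
  # no missing values -> identity
  full <- impute_missing(dplyr::slice(rec, 1), seed = 1)
  expect_equal(full$ecog, "0")
  expect_error(impute_missing(tibble::tibble(ecog = NA_character_,
                                             ca19_9_bin = "normal")),
               "entirely missing")

  # imputed draws follow the observed distribution (binomial oracle)
  donor <- tibble::tibble(ecog = c(rep("0", 50), rep("1", 50), NA),
                          ca19_9_bin = "normal")
  draws <- vapply(1:2000, function(s) {
    impute_missing(donor, seed = s)$ecog[101]
  }, character(1))
  p0 <- mean(draws == "0")
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("null-labelled groups give a hazard ratio near 1", {
  withr::with_seed(21, {
    n <- 600
    d <- tibble::tibble(
      entry_months = 0,
      os_months = rexp(n, 0.15),
      os_event = 1L,
      treatment = sample(c("GP", "FOLFIRINOX"), n, replace = TRUE)
    )
    fit <- cox_fit(d, "rwOS", covariates = "treatment")
    expect_lt(abs(fit$terms$hr - 1), 0.25)
    expect_true(fit$terms$conf_low < 1 && fit$terms$conf_high > 1)
    expect_equal(fit$terms$hr, exp(fit$terms$estimate))
    expect_true(fit$terms$conf_low < fit$terms$hr &&
                  fit$terms$hr < fit$terms$conf_high)
  })
})

test_that("no-truncation Cox coefficients match an independent Newton solver", {
  withr::with_seed(2718, {
    for (rep in 1:20) {
      n <- sample(60:150, 1)
      x1 <- rbinom(n, 1, 0.5)
      x2 <- rnorm(n)
      t <- rexp(n, 0.1 * exp(0.5 * x1 - 0.3 * x2))
      e <- rbinom(n, 1, 0.8)
      d <- tibble::tibble(entry_months = 0, os_months = t, os_event = e,
                          x1 = x1, x2 = x2)
      fit <- cox_fit(d, "rwOS", covariates = c("x1", "x2"))
      ref <- oracle_cox(t, e, cbind(x1, x2))
      expect_equal(unname(fit$terms$estimate), unname(ref), tolerance = 1e-6,
                   label = paste("rep", rep))
    }
  })
})

test_that("TTNT and rwOS never swap event columns", {
  cfg <- sim_config(n_patients = 500, seed = 41)
  cl <- simulate_clinical(simulate_genotypes(cfg)$truth, cfg)
  obs <- cl[cl$observable, ]
  os_fit <- cox_fit(obs, "rwOS", covariates = "treatment")
  ttnt_fit <- cox_fit(obs, "TTNT", covariates = "treatment")
  expect_equal(os_fit$n_events, sum(obs$os_event[obs$os_months > obs$entry_months]))
  expect_equal(ttnt_fit$n_events,
               sum(obs$ttnt_event[obs$ttnt_months > obs$entry_months]))
  expect_gt(ttnt_fit$n_events, os_fit$n_events) # next treatment precedes death
})

test_that("stratified comparison reports all strata with the design's columns", {
  cfg <- sim_config(n_patients = 2500, seed = 61)
  co_truth <- simulate_genotypes(cfg)
  cl <- simulate_clinical(co_truth$truth, cfg)
  bm <- tibble::tibble(
    sample = co_truth$truth$patient_id,
    call = ifelse(co_truth$truth$hrd_status, "positive", "negative"),
    core_mut = co_truth$truth$patient_id %in%
      co_truth$genotypes$patient_id[
        co_truth$genotypes$gene %in% c("BRCA1", "BRCA2", "PALB2")]
  )
  tab <- stratified_comparison(cl[cl$observable, ], bm, "rwOS")
  expect_true(all(c("HRDsig+", "HRDsig-", "HRDsig+ or BRCA1/2/PALB2mut",
                    "dual-negative") %in% tab$stratum))
  main <- tab[tab$stratum %in% c("HRDsig+", "HRDsig-"), ]
  expect_true(all(main$hr_estimable))
  # the design's predictive contrast: more FOLFIRINOX benefit when positive
  expect_lt(main$ahr[main$stratum == "HRDsig+"],
            main$ahr[main$stratum == "HRDsig-"])

  # single-stratum cohort: other rows absent, no crash
  one <- stratified_comparison(
    cl[cl$observable & cl$patient_id %in% bm$sample[bm$call == "negative"], ],
    bm, "rwOS")
  expect_false("HRDsig+" %in% one$stratum)
  expect_true("HRDsig-" %in% one$stratum)

  expect_error(stratified_comparison(cl[cl$observable, ], bm[-1, ], "rwOS"),
               "biomarker call")
})

test_that("interaction-effect recovery at the design point (HR 0.4)", {
  # one replicate here; the full 200-replicate recovery study runs in the
  # acceptance suite
  cfg <- sim_config(
    n_patients = 5000, seed = 77,
    clinical_model = list(beta_treatment = 0, beta_hrd = 0,
                          beta_interaction = log(0.4)))
  tr <- simulate_genotypes(cfg)$truth
  cl <- simulate_clinical(tr, cfg)
  d <- dplyr::inner_join(cl, tr[, c("patient_id", "hrd_status")],
                         by = "patient_id")
  d <- d[d$observable, ]
  d$hrd <- as.integer(d$hrd_status)
  fit <- cox_fit(d, "rwOS",
                 covariates = c("treatment * hrd", "age", "surgery", "ecog",
                                "ca19_9_bin", "tissue"))
  int <- fit$terms[grepl(":", fit$terms$term), ]
  expect_equal(nrow(int), 1)
  expect_lt(abs(int$hr - 0.4), 0.12)
})
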