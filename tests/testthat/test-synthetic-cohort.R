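test_that("degenerate prevalence configurations behave as specified", {
  cfg0 <- sim_config(n_patients = 100, hrd_prevalence = 0, seed = 1)
  g0 <- simulate_genotypes(cfg0)
  expect_false(any(g0$truth$hrd_status))

  cfg1 <- sim_config(n_patients = 100, hrd_prevalence = 1,
                     hrr_wildtype_given_hrd = 1, seed = 1)
  g1 <- simulate_genotypes(cfg1)
  expect_true(all(g1$truth$hrd_status))
  expect_true(all(g1$truth$hrr_wildtype))
  expect_equal(nrow(g1$genotypes), 0)
})

test_that("invalid probabilities are rejected at configuration time", {
  expect_error(sim_config(hrd_prevalence = 1.2), "probability")
  expect_error(sim_config(hrr_wildtype_given_hrd = -0.1), "probability")
  expect_error(
    sim_config(clinical_model = list(censoring_rate = 2)), "probability")
  expect_error(
    sim_config(clinical_model = list(baseline_median_months = -1)), "> 0")
})

test_that("genotype fractions converge to configured values (binomial oracle)", {
  cfg <- sim_config(n_patients = 20000, seed = 11)
  g <- simulate_genotypes(cfg)
  n <- nrow(g$truth)
  p_hat <- mean(g$truth$hrd_status)
  sd_prev <- sqrt(0.09 * 0.91 / n)
  expect_lt(abs(p_hat - 0.09), 3 * sd_prev)

  hrd <- g$truth[g$truth$hrd_status, ]
  wt_hat <- mean(hrd$hrr_wildtype)
  sd_wt <- sqrt(0.37 * 0.63 / nrow(hrd))
  expect_lt(abs(wt_hat - 0.37), 3 * sd_wt)
})

test_that("HRD- patients carry monoallelic or unknown alterations only", {
  cfg <- sim_config(n_patients = 5000, seed = 3)
  g <- simulate_genotypes(cfg)
  neg_ids <- g$truth$patient_id[!g$truth$hrd_status]
  neg_geno <- g$genotypes[g$genotypes$patient_id %in% neg_ids, ]
  expect_gt(nrow(neg_geno), 0)
  expect_false(any(neg_geno$biallelic))
  expect_true(all(neg_geno$mechanism %in% c("monoallelic", "unknown")))
})

test_that("profiles tile every arm contiguously and deterministically", {
  p1 <- simulate_profile(TRUE, seed = 7)
  p2 <- simulate_profile(TRUE, seed = 7)
  expect_identical(p1, p2)
  expect_silent(validate_profile(p1$segments))

  arms <- genome_arms(default_genome())
  covered <- sum(p1$segments$end - p1$segments$start)
  expect_equal(covered, sum(arms$arm_length))
})

test_that("zero scar rates give single diploid arms and no variants", {
  eff0 <- list(
    hrd_pos = list(focal_loh = 0, small_loh = 0, lst = 0, tai = 0,
                   whole_arm_loh = 0, n_del = 0, mh_prob = 0),
    hrd_neg = list(focal_loh = 0, small_loh = 0, lst = 0, tai = 0,
                   whole_arm_loh = 0, n_del = 0, mh_prob = 0)
  )
  p <- simulate_profile(TRUE, effects = eff0, seed = 1)
  expect_equal(nrow(p$segments), 44) # 22 autosomes x 2 arms
  expect_true(all(p$segments$total_cn == 2 & p$segments$minor_cn == 1))
  expect_equal(nrow(p$variants), 0)
})

test_that("HRD+ profiles carry more interstitial LOH segments than HRD-", {
  n_per <- 150
  pos <- vapply(seq_len(n_per), function(i) {
    p <- simulate_profile(TRUE, seed = 20000 + i)
    extract_features(p$segments, p$variants)$n_loh_interstitial
  }, numeric(1))
  neg <- vapply(seq_len(n_per), function(i) {
    p <- simulate_profile(FALSE, seed = 40000 + i)
    extract_features(p$segments, p$variants)$n_loh_interstitial
  }, numeric(1))
  expect_gt(mean(pos), mean(neg))
  expect_gt(stats::t.test(pos, neg)$statistic, 10)
})

test_that("clinical simulation respects its survival-time contracts", {
  cfg <- sim_config(n_patients = 2000, seed = 5)
  tr <- simulate_genotypes(cfg)$truth
  cl <- simulate_clinical(tr, cfg)
  expect_equal(nrow(cl), 2000)
  expect_true(all(cl$entry_months >= 0))
  expect_true(all(cl$ttnt_months <= cl$os_months))
  expect_true(all(cl$observable == (cl$os_months > cl$entry_months)))
  # configurable missingness lands near its MCAR rates
  expect_lt(abs(mean(is.na(cl$ecog)) - 0.25), 0.04)
  expect_lt(abs(mean(is.na(cl$ca19_9_bin)) - 0.32), 0.04)
})

test_that("censoring rate 1 yields no events", {
  cfg <- sim_config(n_patients = 200, seed = 5,
                    clinical_model = list(censoring_rate = 1))
  cl <- simulate_clinical(simulate_genotypes(cfg)$truth, cfg)
  expect_true(all(cl$os_event == 0))
})

test_that("null treatment effects leave the arms exchangeable", {
  cfg <- sim_config(
    n_patients = 4000, seed = 17,
    clinical_model = list(beta_treatment = 0, beta_interaction = 0))
  cl <- simulate_clinical(simulate_genotypes(cfg)$truth, cfg)
  obs <- cl[cl$observable, ]
  fit <- cox_fit(obs, "rwOS", covariates = "treatment")
  expect_gt(fit$terms$p[1], 0.01)
  expect_true(fit$terms$conf_low[1] < 1 && fit$terms$conf_high[1] > 1)
})

test_that("truncation-removal fraction is monotone in the entry-delay mean", {
  fr <- vapply(c(0.25, 1, 4), function(m) {
    cfg <- sim_config(n_patients = 3000, seed = 23, entry_delay_mean = m)
    cl <- simulate_clinical(simulate_genotypes(cfg)$truth, cfg)
    mean(!cl$observable)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("cohorts round-trip losslessly through the writers and readers", {
  cfg <- sim_config(n_patients = 40, seed = 31)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$segments, co$segments)
  expect_equal(back$variants, co$variants)
  expect_equal(back$clinical, co$clinical)
  expect_equal(back$truth, co$truth)
  expect_equal(back$genotypes, co$genotypes)
  expect_equal(nrow(back$clinical), 40)
  expect_false(anyDuplicated(back$clinical$patient_id) > 0)
})

test_that("an empty cohort writes valid header-only files", {
  cfg <- sim_config(n_patients = 0, seed = 1)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$clinical), 0)
  expect_equal(nrow(back$segments), 0)
  expect_named(back$segments,
               c("sample", "chrom", "start", "end", "total_cn", "minor_cn"))
})

test_that("identical config and seed give byte-identical cohort files", {
  cfg <- sim_config(n_patients = 25, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})
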