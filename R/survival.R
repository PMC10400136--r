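#' Left-truncated Kaplan-Meier estimation
#'
#' Product-limit estimator with delayed entry: a patient enters the risk set
#' only after their entry time (here, the genomic-profiling report relative
#' to first-line start), so the risk set at time t is
#' `{i : entry_i < t <= time_i}`. Patients whose follow-up ends at or before
#' entry can never be observed in such a design; they are removed and their
#' count recorded. Estimation is delegated to [survival::survfit()] on a
#' counting-process `Surv(entry, time, event)` object.
#'
#' @param data data frame of patient records
#' @param time,event,entry column names (strings) of the follow-up time,
#'   0/1 event indicator and entry time; `entry = NULL` means no truncation
#' @return object of class `km_curve`: list with `steps` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `median` (NA when the curve
#'   never reaches 0.5), `n`, `n_events`, `n_excluded`
#' @examples
#' d <- data.frame(t = c(1, 2, 3), e = 1, entry = 0)
#' km_left_truncated(d, "t", "e", "entry")$steps$surv # 2/3, 1/3, 0
#' @export
km_left_truncated <- function(data, time = "os_months", event = "os_event",
                              entry = "entry_months") {
  tt <- data[[time]]
  ev <- as.integer(data[[event]])
  en <- if (is.null(entry)) rep(0, nrow(data)) else data[[entry]]
  if (any(is.na(tt)) || any(is.na(ev)) || any(is.na(en))) {
    abort("times, events and entries must be non-missing")
  }
  if (any(en < 0)) abort("entry times must be >= 0")
  keep <- tt > en
  n_excluded <- sum(!keep)
  tt <- tt[keep]; ev <- ev[keep]; en <- en[keep]
  if (length(tt) == 0L) abort("no patients remain after left-truncation filtering")

  fit <- survival::survfit(survival::Surv(en, tt, ev) ~ 1)
  steps <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  med <- {
    i <- which(steps$surv <= 0.5 & steps$n_event > 0)
    if (length(i)) steps$time[min(i)] else NA_real_
  }
  structure(
    list(steps = steps, median = med, n = length(tt), n_events = sum(ev),
         n_excluded = n_excluded),
    class = "km_curve"
  )
}

#' Survival probability at a landmark time
#'
#' Evaluates the fitted step function S(t), right-continuous: the value at a
#' landmark is the survival just after the last step at or before it, and 1
#' before the first observed time.
#'
#' @param curve a [km_curve][km_left_truncated()]
#' @param t_months landmark time (months), >= 0
#' @return survival probability
#' @export
landmark_survival <- function(curve, t_months) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t_months < 0)) abort("landmark time must be >= 0")
  s <- c(1, curve$steps$surv)
  idx <- findInterval(t_months, curve$steps$time) + 1L
  s[idx]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, excluded (event before entry) = %d\n",
              x$n, x$n_events, x$n_excluded))
  cat(sprintf("  median: %s months\n",
              ifelse(is.na(x$median), "not reached", format(round(x$median, 2)))))
  invisible(x)
}

#' @rdname km_left_truncated
#' @param x,object a `km_curve`
#' @param ... unused
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @rdname km_left_truncated
#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_excluded = x$n_excluded,
         median = x$median, surv_12mo = landmark_survival(x, 12),
         surv_24mo = landmark_survival(x, 24))
}

#' @rdname km_left_truncated
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1), object$steps[, c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months from first-line start", y = "survival probability")
}

#' Random-sample imputation of missing clinical covariates
#'
#' Replaces each missing value of the given covariates with a uniform draw
#' from the observed values of that covariate, deterministically under the
#' seed. Non-missing cells are never altered; imputed cells are flagged in
#' companion `.imputed` columns.
#'
#' @param records clinical tibble
#' @param vars covariates allowed to be missing
#' @param seed integer seed
#' @return completed tibble with added `<var>.imputed` logical columns
#' @export
impute_missing <- function(records, vars = c("ecog", "ca19_9_bin"), seed = 1L) {
  withr::with_seed(seed, {
    out <- records
    for (v in vars) {
      x <- out[[v]]
      miss <- is.na(x)
      if (all(miss) && length(x) > 0) {
        abort(sprintf("covariate '%s' is entirely missing; cannot impute", v))
      }
      if (any(miss)) {
        x[miss] <- sample(x[!miss], sum(miss), replace = TRUE)
      }
      out[[v]] <- x
      out[[paste0(v, ".imputed")]] <- miss
    }
    out
  })
}

#' Adjusted Cox proportional-hazards fit with delayed entry
#'
#' Fits a Cox model on the left-truncation-adjusted partial likelihood
#' (counting-process risk sets, Efron tie handling) via
#' [survival::coxph()], after random-sample imputation of missing ECOG and
#' CA19-9. Categorical covariates are coded with reference levels ECOG "0",
#' CA19-9 "normal", tissue "pancreas" and treatment "GP"; age enters
#' continuous. Wald 95% confidence intervals.
#'
#' @param records clinical tibble (one row per patient)
#' @param endpoint `"rwOS"` (overall survival) or `"TTNT"` (time to next
#'   treatment)
#' @param covariates model terms beyond the endpoint; defaults to the
#'   adjustment set age + surgery + ECOG + CA19-9 + tissue plus `treatment`
#' @param seed imputation seed
#' @return object of class `hrdscar_cox`: list with `terms` tibble
#'   (term, estimate = log HR, hr, se, conf_low, conf_high, p), `n`,
#'   `n_events`, `n_excluded`, `endpoint`, `seed`, `converged`
#' @export
cox_fit <- function(records, endpoint = c("rwOS", "TTNT"),
                    covariates = c("treatment", "age", "surgery", "ecog",
                                   "ca19_9_bin", "tissue"),
                    seed = 1L) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "rwOS") c("os_months", "os_event") else
    c("ttnt_months", "ttnt_event")
  dat <- impute_missing(records,
                        vars = intersect(c("ecog", "ca19_9_bin"), covariates),
                        seed = seed)
  dat <- set_clinical_references(dat)
  keep <- dat[[cols[1]]] > dat$entry_months
  n_excluded <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  if (sum(dat[[cols[2]]]) < 1) abort("no events in the analysis set")

  fml <- as.formula(paste0(
    "survival::Surv(entry_months, ", cols[1], ", ", cols[2], ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    abort(paste0(
      "Cox model did not produce estimates for all terms (iterations: ",
      fit$iter, "); inspect collinearity or empty factor levels"))
  }
  sm <- summary(fit)
  z <- qnorm(0.975)
  terms <- tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "coef"],
    hr = exp(sm$coefficients[, "coef"]),
    se = sm$coefficients[, "se(coef)"],
    conf_low = exp(sm$coefficients[, "coef"] - z * sm$coefficients[, "se(coef)"]),
    conf_high = exp(sm$coefficients[, "coef"] + z * sm$coefficients[, "se(coef)"]),
    p = sm$coefficients[, "Pr(>|z|)"]
  )
  structure(
    list(terms = terms, n = nrow(dat), n_events = sum(dat[[cols[2]]]),
         n_excluded = n_excluded, endpoint = endpoint, seed = seed,
         converged = TRUE, fit = fit),
    class = "hrdscar_cox"
  )
}

set_clinical_references <- function(dat) {
  if ("treatment" %in% names(dat)) {
    dat$treatment <- factor(dat$treatment, levels = c("GP", "FOLFIRINOX"))
  }
  if ("ecog" %in% names(dat)) {
    dat$ecog <- factor(dat$ecog, levels = c("0", "1", ">=2"))
  }
  if ("ca19_9_bin" %in% names(dat)) {
    dat$ca19_9_bin <- factor(dat$ca19_9_bin,
                             levels = c("normal", "<59xULN", ">59xULN"))
  }
  if ("tissue" %in% names(dat)) {
    dat$tissue <- factor(dat$tissue, levels = c("pancreas", "liver", "other"))
  }
  dat
}

#' @export
print.hrdscar_cox <- function(x, ...) {
  cat(sprintf("<hrdscar_cox> endpoint %s: n = %d, events = %d\n",
              x$endpoint, x$n, x$n_events))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' @rdname cox_fit
#' @param x,object an `hrdscar_cox`
#' @param ... unused
#' @export
tidy.hrdscar_cox <- function(x, ...) x$terms

#' @rdname cox_fit
#' @export
glance.hrdscar_cox <- function(x, ...) {
  tibble(endpoint = x$endpoint, n = x$n, n_events = x$n_events,
         n_excluded = x$n_excluded, converged = x$converged)
}

#' Biomarker-by-treatment stratified outcome table
#'
#' Reproduces the stratified outcome design: within each biomarker stratum,
#' per-treatment-arm left-truncated Kaplan-Meier medians and 1-/2-year
#' landmark survival, plus the covariate-adjusted FOLFIRINOX-vs-GP hazard
#' ratio from a stratum-restricted Cox model. Strata: HRD signature +/-,
#' their BRCA1/2/PALB2-mutant and wildtype sub-strata, the combined
#' either-positive biomarker, and the dual-negative group. Strata with no
#' event in an arm are flagged and reported without a hazard ratio.
#'
#' @param clinical clinical tibble
#' @param biomarkers tibble `sample` (or `patient_id`), `call`
#'   (positive/negative), and logical `core_mut` (any BRCA1/2/PALB2
#'   alteration)
#' @param endpoint `"rwOS"` or `"TTNT"`
#' @param covariates adjustment covariates for the Cox model (treatment is
#'   added automatically)
#' @param seed imputation seed
#' @return tibble, one row per stratum: n per arm, medians, landmarks, aHR
#'   with CI and p
#' @export
stratified_comparison <- function(clinical, biomarkers,
                                  endpoint = c("rwOS", "TTNT"),
                                  covariates = c("age", "surgery", "ecog",
                                                 "ca19_9_bin", "tissue"),
                                  seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (!"sample" %in% names(biomarkers) && "patient_id" %in% names(biomarkers)) {
    biomarkers <- rename(biomarkers, sample = "patient_id")
  }
  dat <- inner_join(clinical, biomarkers, by = c(patient_id = "sample"))
  miss <- setdiff(clinical$patient_id, biomarkers$sample)
  if (length(miss)) {
    abort(sprintf("patient '%s' has no biomarker call", miss[1]))
  }
  pos <- dat$call == "positive"
  core <- dat$core_mut %in% TRUE
  strata <- list(
    "HRDsig+" = pos,
    "HRDsig-" = !pos,
    "HRDsig+ BRCA1/2/PALB2mut" = pos & core,
    "HRDsig- BRCA1/2/PALB2mut" = !pos & core,
    "HRDsig+ BRCA1/2/PALB2wt" = pos & !core,
    "HRDsig- BRCA1/2/PALB2wt" = !pos & !core,
    "HRDsig+ or BRCA1/2/PALB2mut" = pos | core,
    "dual-negative" = !pos & !core
  )
  cols <- if (endpoint == "rwOS") c("os_months", "os_event") else
    c("ttnt_months", "ttnt_event")

  purrr::imap_dfr(strata, function(sel, name) {
    d <- dat[sel, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    arm_stats <- function(arm) {
      da <- d[d$treatment == arm, , drop = FALSE]
      da <- da[da[[cols[1]]] > da$entry_months, , drop = FALSE]
      if (nrow(da) == 0L) {
        return(tibble(n = 0L, events = 0L, median = NA_real_,
                      surv_12mo = NA_real_, surv_24mo = NA_real_))
      }
      km <- km_left_truncated(da, cols[1], cols[2])
      tibble(n = km$n, events = km$n_events, median = km$median,
             surv_12mo = landmark_survival(km, 12),
             surv_24mo = landmark_survival(km, 24))
    }
    folf <- arm_stats("FOLFIRINOX")
    gp <- arm_stats("GP")
    estimable <- folf$events > 0 && gp$events > 0
    hr_row <- tibble(ahr = NA_real_, conf_low = NA_real_,
                     conf_high = NA_real_, p = NA_real_)
    if (estimable) {
      ## small strata can have monotone partial likelihoods; treat a
      ## non-converging fit as not estimable rather than reporting a
      ## runaway hazard ratio
      diverged <- FALSE
      cox <- tryCatch(
        withCallingHandlers(
          cox_fit(d, endpoint, covariates = c("treatment", covariates),
                  seed = seed),
          warning = function(w) {
            if (grepl("Ran out of iterations|infinite", conditionMessage(w))) {
              diverged <<- TRUE
            }
            invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
      if (diverged) cox <- NULL
      if (!is.null(cox)) {
        tr <- cox$terms[grepl("^treatment", cox$terms$term), ]
        if (nrow(tr) == 1L) {
          hr_row <- tibble(ahr = tr$hr, conf_low = tr$conf_low,
                           conf_high = tr$conf_high, p = tr$p)
        }
      }
      estimable <- !is.na(hr_row$ahr[1])
    }
    bind_cols(
      tibble(stratum = name, endpoint = endpoint),
      rename_with(folf, ~ paste0("folfirinox_", .x)),
      rename_with(gp, ~ paste0("gp_", .x)),
      hr_row,
      tibble(hr_estimable = estimable)
    )
  })
}
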