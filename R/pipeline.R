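#' Run the end-to-end analysis pipeline
#'
#' Executes simulate -> zygosity -> scar features -> train -> predict ->
#' co-occurrence -> outcomes on a synthetic cohort, writing every stage's
#' table under `out_dir` together with a manifest (package version, resolved
#' configuration, per-file MD5 checksums). All randomness derives from the
#' single seed in the configuration, split deterministically per stage, so a
#' rerun with the same configuration is byte-identical. A zero-patient
#' configuration exits cleanly after writing the (header-only) cohort files
#' and a manifest marking the run empty.
#'
#' @param config a [sim_config()]; its `seed` drives every stage
#' @param out_dir output directory
#' @param threshold_mode passed to [train_classifier()]
#' @return `out_dir`, invisibly; side effect: files + `manifest.json`
#' @export
run_pipeline <- function(config, out_dir,
                         threshold_mode = c("specificity", "prevalence")) {
  threshold_mode <- match.arg(threshold_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      write_manifest(out_dir, config, status = paste0("failed at stage: ", name))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config))
  stage("write_cohort", write_cohort(cohort, out_dir))

  if (config$n_patients == 0L) {
    write_manifest(out_dir, config, status = "empty cohort")
    message("empty cohort; nothing to analyse")
    return(invisible(out_dir))
  }

  zyg <- stage("zygosity", call_zygosity(cohort))
  readr::write_csv(zyg$statuses, file.path(out_dir, "allelic_status.csv"))
  readr::write_csv(zyg$samples, file.path(out_dir, "hrr_classes.csv"))

  feats <- stage("features",
                 extract_features(cohort$segments, cohort$variants, cohort$genome))
  readr::write_csv(feats, file.path(out_dir, "scar_features.csv"))

  labels <- build_training_labels(zyg$samples)
  readr::write_csv(labels, file.path(out_dir, "training_labels.csv"))
  bundle <- stage("train", train_classifier(
    feats, labels, seed = stage_seed(config$seed, "train"),
    threshold_mode = threshold_mode))
  save_model(bundle, file.path(out_dir, "hrdsig_model"))

  calls <- stage("predict", predict_hrdsig(bundle, feats))
  readr::write_csv(calls, file.path(out_dir, "hrdsig_calls.csv"))

  stage("cooccurrence", {
    cooc <- cooccurrence_test(zyg$statuses, calls)
    readr::write_tsv(as_tibble(cooc), file.path(out_dir, "cooccurrence.tsv"))
    part <- landscape_partition(zyg$samples, calls)
    readr::write_csv(part, file.path(out_dir, "landscape_partition.csv"))
  })

  stage("outcomes", {
    bm <- zyg$samples |>
      select("sample", "core_mut") |>
      inner_join(select(calls, "sample", "call"), by = "sample")
    obs <- cohort$clinical
    for (ep in c("rwOS", "TTNT")) {
      tab <- stratified_comparison(obs, bm, ep,
                                   seed = stage_seed(config$seed, "impute"))
      readr::write_tsv(tab, file.path(
        out_dir, sprintf("outcomes_%s.tsv", tolower(ep))))
    }
    for (grp in c("positive", "negative")) {
      ids <- bm$sample[bm$call == grp]
      d <- obs[obs$patient_id %in% ids & obs$os_months > obs$entry_months, ]
      if (nrow(d)) {
        km <- km_left_truncated(d)
        readr::write_csv(km$steps, file.path(
          out_dir, sprintf("km_rwos_hrdsig_%s.csv", grp)))
      }
    }
  })

  write_manifest(out_dir, config, status = "complete")
  message(sprintf("pipeline complete in %.1fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out_dir)
}

write_manifest <- function(out_dir, config, status) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  paths <- file.path(out_dir, files)
  manifest <- list(
    package = "hrdscar",
    version = as.character(utils::packageVersion("hrdscar")),
    status = status,
    seed = config$seed,
    config = config_to_list(config),
    files = lapply(setNames(paths, files), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

config_to_list <- function(config) {
  lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(as.data.frame(x)) else x
  })
}

#' Summarise a completed pipeline run
#'
#' Prints a human-readable summary of a [run_pipeline()] directory:
#' signature prevalence by disease ontology, the genomic landscape partition
#' of signature-positive samples, the strongest co-occurrence hits, and the
#' stratified outcome table. Regenerating the summary is read-only and
#' idempotent.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @return the summary lines, invisibly; printed as a side effect
#' @export
report_summary <- function(run_dir) {
  need <- c("manifest.json", "clinical.csv", "hrdsig_calls.csv",
            "landscape_partition.csv", "cooccurrence.tsv", "outcomes_rwos.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    abort(paste0("incomplete run; missing files: ", paste(missing, collapse = ", ")))
  }
  out <- character()
  say <- function(...) out <<- c(out, sprintf(...))

  clinical <- read_clinical(file.path(run_dir, "clinical.csv"))
  calls <- readr::read_csv(file.path(run_dir, "hrdsig_calls.csv"),
                           col_types = readr::cols())
  joined <- inner_join(clinical, calls, by = c(patient_id = "sample"))

  say("== HRD signature prevalence by ontology ==")
  prev <- joined |>
    group_by(.data$ontology) |>
    summarise(n = dplyr::n(), pos = sum(.data$call == "positive"),
              .groups = "drop") |>
    mutate(pct = compute_prevalence(.data$pos, .data$n))
  for (i in seq_len(nrow(prev))) {
    say("  %-6s %5.1f%%  (%d/%d)", prev$ontology[i], prev$pct[i],
        prev$pos[i], prev$n[i])
  }
  say("  overall %4.1f%%  (%d/%d)",
      compute_prevalence(sum(prev$pos), sum(prev$n)), sum(prev$pos), sum(prev$n))

  say("== Genomic landscape of HRDsig(+) samples ==")
  part <- readr::read_csv(file.path(run_dir, "landscape_partition.csv"),
                          col_types = readr::cols())
  if (sum(part$n) == 0) {
    say("  no positive samples")
  } else {
    for (i in seq_len(nrow(part))) {
      say("  %-30s %5.1f%%  (n=%d)", part$stratum[i],
          100 * part$fraction[i], part$n[i])
    }
  }

  say("== Top co-occurrence hits (biallelic vs HRDsig) ==")
  cooc <- readr::read_tsv(file.path(run_dir, "cooccurrence.tsv"),
                          col_types = readr::cols())
  if (nrow(cooc) == 0) {
    say("  no genes with biallelic alterations")
  } else {
    top <- head(arrange(cooc, .data$p), 5)
    for (i in seq_len(nrow(top))) {
      say("  %-8s OR %6.1f  p %.2e  q %.2e", top$gene[i], top$odds_ratio[i],
          top$p[i], top$q[i])
    }
  }

  say("== Stratified rwOS (FOLFIRINOX vs GP) ==")
  tab <- readr::read_tsv(file.path(run_dir, "outcomes_rwos.tsv"),
                         col_types = readr::cols())
  for (i in seq_len(nrow(tab))) {
    say("  %-28s median %5.1f vs %5.1f mo  aHR %s", tab$stratum[i],
        tab$folfirinox_median[i], tab$gp_median[i],
        ifelse(tab$hr_estimable[i],
               sprintf("%.2f (%.2f-%.2f)", tab$ahr[i], tab$conf_low[i],
                       tab$conf_high[i]),
               "not estimable"))
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
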