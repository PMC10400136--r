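#' Simulate HRR genotypes and latent HRD status
#'
#' Draws, for each patient, a disease ontology, a latent HRD status and a
#' genotype over the 14-gene HRR basket. HRD+ tumours are either genomically
#' driven (one driver gene carrying a biallelic alteration through one of the
#' three biallelic mechanisms: deep deletion, two pathogenic hits, or a
#' pathogenic short variant under LOH) or non-genomic (HRR-wildtype, with
#' probability `hrr_wildtype_given_hrd`). HRD− tumours never carry biallelic
#' basket alterations but may carry background monoallelic pathogenic short
#' variants or zygosity-unassessable rearrangements, which have no scar
#' effect.
#'
#' Per-ontology HRD prevalence is `hrd_prevalence * hrd_multiplier`,
#' with multipliers normalised so the marginal prevalence equals
#' `hrd_prevalence` exactly.
#'
#' @param config a [sim_config()] object
#' @return list with elements
#'   * `truth`: tibble `patient_id`, `ontology`, `hrd_status` (logical),
#'     `hrr_wildtype` (logical; no pathogenic basket alteration),
#'     `driver_gene` (NA for non-genomic / HRD−)
#'   * `genotypes`: sparse tibble of altered genes only: `patient_id`, `gene`,
#'     `altered`, `biallelic`, `mechanism`
#'     (deep_deletion / two_hits / sv_under_loh / monoallelic / unknown)
#' @examples
#' g <- simulate_genotypes(sim_config(n_patients = 20, seed = 7))
#' g$truth
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(stage_seed(config$seed, "genotypes"), {
    n <- config$n_patients
    ids <- sprintf("PT%05d", seq_len(n))
    if (n == 0L) {
      return(list(
        truth = tibble(patient_id = character(), ontology = character(),
                       hrd_status = logical(), hrr_wildtype = logical(),
                       driver_gene = character()),
        genotypes = empty_genotypes()
      ))
    }
    om <- config$ontology_model
    ontology <- sample(om$ontology, n, replace = TRUE, prob = om$weight)
    p_onto <- ontology_hrd_rates(om, config$hrd_prevalence)
    hrd <- runif(n) < p_onto[match(ontology, om$ontology)]

    non_genomic <- hrd & (runif(n) < config$hrr_wildtype_given_hrd)
    gm <- config$gene_alteration_model
    driver <- rep(NA_character_, n)
    genomic <- hrd & !non_genomic
    if (any(genomic)) {
      driver[genomic] <- sample(gm$gene, sum(genomic), replace = TRUE,
                                prob = gm$weight)
    }

    rows <- vector("list", 3L)
    ## driver biallelic events (a small fraction of drivers end up monoallelic:
    ## incomplete second hits)
    if (any(genomic)) {
      idx <- which(genomic)
      bial <- runif(length(idx)) < 0.95
      mech <- ifelse(bial,
                     sample(c("deep_deletion", "two_hits", "sv_under_loh"),
                            length(idx), replace = TRUE,
                            prob = c(0.2, 0.3, 0.5)),
                     "monoallelic")
      rows[[1L]] <- tibble(patient_id = ids[idx], gene = driver[idx],
                           altered = TRUE, biallelic = bial, mechanism = mech)
    }
    ## background monoallelic / unknown alterations; suppressed for
    ## non-genomic HRD+ patients so that the configured HRRwt-given-HRD
    ## fraction is the observed wildtype fraction
    eligible <- which(!non_genomic)
    if (length(eligible)) {
      bg <- purrr::pmap_dfr(
        list(gm$gene, gm$monoallelic_rate, gm$unknown_rate),
        function(g, mr, ur) {
          hit_m <- eligible[runif(length(eligible)) < mr]
          hit_u <- eligible[runif(length(eligible)) < ur]
          bind_rows(
            tibble(patient_id = ids[hit_m], gene = g, altered = TRUE,
                   biallelic = FALSE, mechanism = "monoallelic"),
            tibble(patient_id = ids[hit_u], gene = g, altered = TRUE,
                   biallelic = FALSE, mechanism = "unknown")
          )
        }
      )
      ## driver gene takes precedence over a background hit in the same gene
      if (!is.null(rows[[1L]]) && nrow(bg)) {
        bg <- anti_join(bg, rows[[1L]], by = c("patient_id", "gene"))
      }
      rows[[2L]] <- bg
    }
    genotypes <- bind_rows(rows)
    if (nrow(genotypes) == 0L) genotypes <- empty_genotypes()
    genotypes <- arrange(genotypes, .data$patient_id, .data$gene)

    altered_pt <- unique(genotypes$patient_id)
    truth <- tibble(
      patient_id = ids,
      ontology = ontology,
      hrd_status = hrd,
      hrr_wildtype = !(ids %in% altered_pt),
      driver_gene = driver
    )
    list(truth = truth, genotypes = genotypes)
  })
}

## Per-ontology HRD rates proportional to the multipliers, solved so the
## weighted marginal equals the target prevalence even when some ontologies
## saturate at probability 1 (e.g. prevalence near the extremes).
ontology_hrd_rates <- function(om, prevalence) {
  f <- function(c) sum(om$weight * pmin(1, c * om$hrd_multiplier))
  if (prevalence <= 0) return(rep(0, nrow(om)))
  lo <- 0
  hi <- 1
  while (f(hi) < prevalence && hi < 1e12) hi <- hi * 2
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < prevalence) lo <- mid else hi <- mid
  }
  pmin(1, hi * om$hrd_multiplier)
}

empty_genotypes <- function() {
  tibble(patient_id = character(), gene = character(), altered = logical(),
         biallelic = logical(), mechanism = character())
}
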