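#' Simulate a full clinico-genomic cohort
#'
#' Runs the three simulator stages (genotypes, copy-number profiles +
#' variants, clinical records) under deterministically derived per-stage
#' seeds, wiring the HRR genotypes into the genomic data: biallelic
#' "short variant under LOH" genotypes place a pathogenic variant at the gene
#' locus under a forced LOH segment, deep deletions place a total-copy-0
#' segment at the locus, two-hit genotypes emit two heterozygous pathogenic
#' variants, monoallelic genotypes one, and "unknown" genotypes a
#' rearrangement record.
#'
#' @param config a [sim_config()] object
#' @param genome genome model tibble
#' @return object of class `hrd_cohort`: a list with `config`, `genome`,
#'   `truth`, `genotypes`, `segments`, `variants`, `clinical`
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 5, seed = 2))
#' names(co)
#' @export
simulate_cohort <- function(config, genome = default_genome()) {
  validate_sim_config(config)
  gt <- simulate_genotypes(config)
  loci <- hrr_gene_loci()
  arms <- genome_arms(genome)

  seg_list <- list()
  var_list <- list()
  withr::with_seed(stage_seed(config$seed, "profiles"), {
    n <- config$n_patients
    ids <- gt$truth$patient_id
    for (i in seq_len(n)) {
      g_i <- gt$genotypes[gt$genotypes$patient_id == ids[i], ]
      g_i <- left_join(g_i, loci, by = "gene")
      force_loh <- g_i[g_i$mechanism == "sv_under_loh", c("chrom", "pos")]
      force_dd <- g_i[g_i$mechanism == "deep_deletion", c("chrom", "pos")]
      prof <- simulate_profile(
        gt$truth$hrd_status[i], genome, config$scar_effect_sizes,
        force_loh = if (nrow(force_loh)) force_loh else NULL,
        force_deep_del = if (nrow(force_dd)) force_dd else NULL,
        arms = arms
      )
      seg_i <- prof$segments
      seg_i$sample <- ids[i]
      seg_list[[i]] <- seg_i[, c("sample", "chrom", "start", "end",
                                 "total_cn", "minor_cn")]
      var_i <- prof$variants
      if (nrow(var_i)) var_i$sample <- ids[i]
      var_list[[i]] <- bind_rows(
        if (nrow(var_i)) var_i[, c("sample", "gene", "chrom", "pos", "class",
                                   "pathogenic", "del_length",
                                   "microhomology_len", "het_flag")],
        hrr_variant_records(ids[i], g_i)
      )
    }
  })
  segments <- if (length(seg_list)) bind_rows(seg_list) else empty_segments()
  variants <- if (length(var_list)) bind_rows(var_list) else empty_variants()
  clinical <- simulate_clinical(gt$truth, config)

  structure(
    list(config = config, genome = genome, truth = gt$truth,
         genotypes = gt$genotypes, segments = segments, variants = variants,
         clinical = clinical),
    class = "hrd_cohort"
  )
}

## realise a patient's HRR genotype as short-variant records
hrr_variant_records <- function(id, g) {
  if (nrow(g) == 0L) return(NULL)
  rows <- purrr::pmap_dfr(g, function(patient_id, gene, altered, biallelic,
                                      mechanism, chrom, pos) {
    base <- tibble(gene = gene, chrom = chrom, pos = pos, pathogenic = TRUE,
                   del_length = NA_integer_, microhomology_len = NA_integer_)
    switch(
      mechanism,
      deep_deletion = mutate(base, class = "deep_deletion", het_flag = NA),
      sv_under_loh = mutate(base, class = "SNV", het_flag = FALSE),
      two_hits = bind_rows(base, mutate(base, pos = pos + 5000)) |>
        mutate(class = "SNV", het_flag = TRUE),
      monoallelic = mutate(base, class = "SNV", het_flag = TRUE),
      unknown = mutate(base, class = "rearrangement", het_flag = NA)
    )
  })
  mutate(rows, sample = id, .before = 1) |>
    select("sample", "gene", "chrom", "pos", "class", "pathogenic",
           "del_length", "microhomology_len", "het_flag")
}

empty_segments <- function() {
  tibble(sample = character(), chrom = character(), start = double(),
         end = double(), total_cn = integer(), minor_cn = integer())
}

empty_variants <- function() {
  tibble(sample = character(), gene = character(), chrom = character(),
         pos = double(), class = character(), pathogenic = logical(),
         del_length = integer(), microhomology_len = integer(),
         het_flag = logical())
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat("<hrd_cohort>\n")
  cat(sprintf("  %d patients, %d segments, %d variant records\n",
              nrow(x$clinical), nrow(x$segments), nrow(x$variants)))
  cat(sprintf("  latent HRD+ : %d (%.1f%%)\n", sum(x$truth$hrd_status),
              100 * mean(x$truth$hrd_status)))
  invisible(x)
}

#' Write / read a simulated cohort as plain-text files
#'
#' `write_cohort()` emits four files in `out_dir`: `segments.seg` (tab
#' delimited: sample, chrom, start, end, total_cn, minor_cn; 0-based
#' half-open), `variants.tsv`, `clinical.csv` and `truth.csv` (latent truth;
#' held out of all analysis stages, used only for recovery checks).
#' `read_cohort()` reads them back; the round trip is lossless.
#'
#' @param cohort an `hrd_cohort`
#' @param out_dir output directory (created if needed)
#' @return `write_cohort()`: the paths, invisibly. `read_cohort()`: an
#'   `hrd_cohort` (without the config element).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))
  paths <- c(
    segments = file.path(out_dir, "segments.seg"),
    variants = file.path(out_dir, "variants.tsv"),
    clinical = file.path(out_dir, "clinical.csv"),
    truth = file.path(out_dir, "truth.csv"),
    genotypes = file.path(out_dir, "genotype_truth.csv")
  )
  readr::write_tsv(cohort$segments, paths["segments"])
  readr::write_tsv(cohort$variants, paths["variants"])
  readr::write_csv(cohort$clinical, paths["clinical"])
  readr::write_csv(cohort$truth, paths["truth"])
  readr::write_csv(cohort$genotypes, paths["genotypes"])
  invisible(paths)
}

#' @rdname write_cohort
#' @param dir directory holding the files written by `write_cohort()`
#' @param genome genome model the segments refer to
#' @export
read_cohort <- function(dir, genome = default_genome()) {
  structure(
    list(
      config = NULL,
      genome = genome,
      truth = readr::read_csv(
        file.path(dir, "truth.csv"),
        col_types = readr::cols(
          patient_id = "c", ontology = "c", hrd_status = "l",
          hrr_wildtype = "l", driver_gene = "c")),
      genotypes = readr::read_csv(
        file.path(dir, "genotype_truth.csv"),
        col_types = readr::cols(
          patient_id = "c", gene = "c", altered = "l", biallelic = "l",
          mechanism = "c")),
      segments = read_segments(file.path(dir, "segments.seg")),
      variants = read_variants(file.path(dir, "variants.tsv")),
      clinical = read_clinical(file.path(dir, "clinical.csv"))
    ),
    class = "hrd_cohort"
  )
}

#' Readers for the cohort file dialects
#'
#' SEG-like segment tables (tab delimited, 0-based half-open), short-variant
#' tables and clinical CSVs, with enforced column types.
#'
#' @param path file path
#' @return a tibble
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom = "c", start = "d", end = "d",
    total_cn = "i", minor_cn = "i"))
}

#' @rdname read_segments
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", gene = "c", chrom = "c", pos = "d", class = "c",
    pathogenic = "l", del_length = "i", microhomology_len = "i",
    het_flag = "l"))
}

#' @rdname read_segments
#' @export
read_clinical <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", ontology = "c", age = "d", sex = "c", treatment = "c",
    surgery = "l", ecog = "c", ca19_9_bin = "c", tissue = "c",
    entry_months = "d", os_months = "d", os_event = "i", ttnt_months = "d",
    ttnt_event = "i", observable = "l"))
}
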