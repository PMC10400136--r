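#' Is a short variant under LOH?
#'
#' A variant is under LOH when the copy-number segment containing its
#' position has minor copy number 0 and total copy number at least 1.
#' Homozygous-deletion segments (total 0) are not LOH; the loss of both
#' copies is handled by the deep-deletion biallelic rule instead.
#'
#' @param chrom,pos variant position (bp, 0-based)
#' @param segments single-sample segment tibble
#' @param genome genome model
#' @return logical
#' @export
variant_under_loh <- function(chrom, pos, segments, genome = default_genome()) {
  seg <- validate_profile(segments, genome)
  under_loh_lookup(chrom, pos, seg)
}

## same lookup without re-validation; callers guarantee a valid profile
under_loh_lookup <- function(chrom, pos, seg) {
  hit <- seg[seg$chrom == chrom & seg$start <= pos & pos < seg$end, ]
  if (nrow(hit) == 0L) {
    abort(sprintf("position %s:%s is outside the profile", chrom,
                  format(pos, scientific = FALSE)))
  }
  hit$minor_cn[1] == 0 && hit$total_cn[1] >= 1
}

#' Per-gene allelic status
#'
#' Applies the biallelic-calling rules to one gene of one sample:
#' 1. a deep deletion in the gene (a deep-deletion variant record, or a
#'    profile segment with total copy number 0 at the gene locus),
#' 2. two or more pathogenic alterations in the same gene,
#' 3. a pathogenic short variant under LOH.
#'
#' Any firing rule gives status `biallelic`; the lowest-numbered firing rule
#' is recorded as reporting metadata. Otherwise a single pathogenic short
#' variant called heterozygous is `monoallelic`; a pathogenic alteration
#' whose zygosity cannot be assessed (rearrangement-only, or a short variant
#' with no heterozygosity call) is `unknown`; a gene with no pathogenic
#' alteration is `wildtype`.
#'
#' Rule 2 counts any two or more pathogenic alterations without requiring
#' evidence that they are in trans (phase is not modelled).
#'
#' @param gene gene symbol
#' @param variants variant tibble for one sample (any genes; filtered here)
#' @param segments optional single-sample segment tibble; when absent, LOH
#'   overlap (rule 3) and segment-level deep deletions cannot fire
#' @param genome genome model
#' @param gene_locus optional `(chrom, pos)` override for the gene position;
#'   defaults to the packaged HRR locus table
#' @return one-row tibble: `gene`, `status`, `triggering_rule`
#'   (`"1"`, `"2"`, `"3"`, `"monoallelic"`, `"unknown"` or `"none"`)
#' @examples
#' v <- tibble::tibble(gene = "BRCA2", chrom = "13", pos = 32350000,
#'   class = "deep_deletion", pathogenic = TRUE, del_length = NA_integer_,
#'   microhomology_len = NA_integer_, het_flag = NA)
#' call_allelic_status("BRCA2", v)
#' @export
call_allelic_status <- function(gene, variants, segments = NULL,
                                genome = default_genome(), gene_locus = NULL) {
  v <- variants[!is.na(variants$gene) & variants$gene == gene &
                  variants$pathogenic %in% TRUE, , drop = FALSE]
  loc <- gene_locus %||% {
    l <- hrr_gene_loci()
    l[l$gene == gene, c("chrom", "pos")]
  }

  short <- v[v$class %in% c("SNV", "indel"), , drop = FALSE]
  rearr <- v[v$class == "rearrangement", , drop = FALSE]
  deep <- v[v$class == "deep_deletion", , drop = FALSE]

  deep_cn <- FALSE
  if (!is.null(segments) && nrow(loc) == 1L) {
    seg <- segments
    hit <- seg[seg$chrom == loc$chrom[1] & seg$start <= loc$pos[1] &
                 loc$pos[1] < seg$end, , drop = FALSE]
    deep_cn <- nrow(hit) > 0 && any(hit$total_cn == 0)
  }

  under_loh <- rep(FALSE, nrow(short))
  if (!is.null(segments) && nrow(short)) {
    for (i in seq_len(nrow(short))) {
      if (!is.na(short$chrom[i]) && !is.na(short$pos[i])) {
        under_loh[i] <- under_loh_lookup(short$chrom[i], short$pos[i],
                                         segments)
      }
    }
  }

  n_alt <- nrow(short) + nrow(rearr) # rule-2 count; deep deletion is rule 1
  status <- NULL
  rule <- "none"
  if (nrow(deep) > 0 || deep_cn) {
    status <- "biallelic"; rule <- "1"
  } else if (n_alt >= 2) {
    status <- "biallelic"; rule <- "2"
  } else if (any(under_loh)) {
    status <- "biallelic"; rule <- "3"
  } else if (nrow(short) == 1L && nrow(rearr) == 0L &&
             isTRUE(short$het_flag[1])) {
    status <- "monoallelic"; rule <- "monoallelic"
  } else if (n_alt > 0) {
    status <- "unknown"; rule <- "unknown"
  } else {
    status <- "wildtype"
  }
  tibble(gene = gene, status = status, triggering_rule = rule)
}

#' Sample-level HRR classification
#'
#' Collapses the 14 per-gene allelic statuses of one sample into the label
#' used for classifier training and landscape partitioning: `HRRwt` when all
#' genes are wildtype, otherwise `biallelic` (with the set of biallelically
#' altered genes), else `monoallelic-only`, else `unknown-only`.
#'
#' @param statuses tibble of per-gene statuses covering all 14 basket genes
#'   (`gene`, `status`)
#' @return one-row tibble: `hrr_class`, `biallelic_genes` (comma separated,
#'   `""` if none)
#' @export
classify_hrr_sample <- function(statuses) {
  missing <- setdiff(hrr_genes(), statuses$gene)
  if (length(missing)) {
    abort(paste0("statuses must cover all 14 HRR genes; missing: ",
                 paste(missing, collapse = ", ")))
  }
  st <- statuses[statuses$gene %in% hrr_genes(), ]
  bi <- sort(st$gene[st$status == "biallelic"])
  cls <- if (all(st$status == "wildtype")) {
    "HRRwt"
  } else if (length(bi)) {
    "biallelic"
  } else if (any(st$status == "monoallelic")) {
    "monoallelic-only"
  } else {
    "unknown-only"
  }
  tibble(hrr_class = cls, biallelic_genes = paste(bi, collapse = ","))
}

#' Cohort-wide zygosity calling
#'
#' Runs [call_allelic_status()] for every sample over the 14 HRR basket genes
#' (sparsely: genes without a pathogenic record in a sample are wildtype
#' without a profile lookup) and attaches the sample-level HRR class.
#'
#' @param cohort an `hrd_cohort`, or a list with `segments`, `variants`,
#'   `genome`
#' @return list with `statuses` (tibble sample, gene, status,
#'   triggering_rule; wildtype rows included) and `samples` (tibble sample,
#'   hrr_class, biallelic_genes, plus convenience flags `brca12_biallelic`,
#'   `core_mut`, `core_biallelic` for the BRCA1/2/PALB2 stratum)
#' @export
call_zygosity <- function(cohort) {
  genome <- cohort$genome %||% default_genome()
  variants <- cohort$variants
  segments <- cohort$segments
  samples <- unique(segments$sample)
  loci <- hrr_gene_loci()

  path <- variants[!is.na(variants$gene) & variants$pathogenic %in% TRUE &
                     variants$gene %in% hrr_genes(), , drop = FALSE]
  hit_samples <- unique(path$sample)
  seg_split <- split(
    segments[segments$sample %in% hit_samples, , drop = FALSE],
    segments$sample[segments$sample %in% hit_samples])
  var_split <- split(path, path$sample)

  called <- purrr::imap_dfr(var_split, function(v_s, s) {
    seg_s <- seg_split[[s]]
    genes_hit <- unique(v_s$gene)
    bind_rows(lapply(genes_hit, function(g) {
      call_allelic_status(g, v_s, seg_s, genome,
                          gene_locus = loci[loci$gene == g, c("chrom", "pos")])
    })) |> mutate(sample = s, .before = 1)
  })
  wildtype <- tidyr::expand_grid(sample = samples, gene = hrr_genes()) |>
    anti_join(called, by = c("sample", "gene")) |>
    mutate(status = "wildtype", triggering_rule = "none")
  statuses <- bind_rows(called, wildtype) |>
    arrange(match(.data$sample, samples), .data$gene)

  samples_tbl <- statuses |>
    group_by(.data$sample) |>
    summarise(
      all_wt = all(.data$status == "wildtype"),
      n_bi = sum(.data$status == "biallelic"),
      any_mono = any(.data$status == "monoallelic"),
      biallelic_genes = paste(sort(.data$gene[.data$status == "biallelic"]),
                              collapse = ","),
      brca12_biallelic = any(.data$status == "biallelic" &
                               .data$gene %in% c("BRCA1", "BRCA2")),
      core_mut = any(.data$status != "wildtype" &
                       .data$gene %in% core_hrd_genes()),
      core_biallelic = any(.data$status == "biallelic" &
                             .data$gene %in% core_hrd_genes()),
      .groups = "drop"
    ) |>
    mutate(hrr_class = case_when(
      .data$all_wt ~ "HRRwt",
      .data$n_bi > 0 ~ "biallelic",
      .data$any_mono ~ "monoallelic-only",
      TRUE ~ "unknown-only"
    )) |>
    select("sample", "hrr_class", "biallelic_genes", "brca12_biallelic",
           "core_mut", "core_biallelic") |>
    arrange(match(.data$sample, samples))
  list(statuses = statuses, samples = samples_tbl)
}
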