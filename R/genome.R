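#' Chromosome-arm genome model
#'
#' The scar features operate on a chromosome-arm genome model: each autosome
#' is split at the centromere into a p and a q arm, and segmented
#' allele-specific copy-number profiles tile every arm with 0-based half-open
#' segments. Sex chromosomes are excluded so that a diploid heterozygous
#' baseline (total 2, minor 1) is well defined everywhere.
#'
#' Arm lengths are approximate GRCh38 values rounded to 0.1 Mb; the
#' interrogated length (denominator of genome-wide focal LOH) is the sum of
#' all arm lengths.
#'
#' @return A tibble with one row per autosome: `chrom`, `p_length`,
#'   `q_length`, `length` (all bp). The total interrogated length is available
#'   via [interrogated_length()].
#' @examples
#' g <- default_genome()
#' sum(g$length) == interrogated_length(g)
#' @export
default_genome <- function() {
  tribble(
    ~chrom, ~cen_mb, ~len_mb,
    "1", 123.4, 249.0,
    "2", 93.9, 242.2,
    "3", 90.9, 198.3,
    "4", 50.0, 190.2,
    "5", 48.8, 181.5,
    "6", 59.8, 170.8,
    "7", 60.1, 159.3,
    "8", 45.2, 145.1,
    "9", 43.0, 138.4,
    "10", 39.8, 133.8,
    "11", 53.4, 135.1,
    "12", 35.5, 133.3,
    "13", 17.7, 114.4,
    "14", 17.2, 107.0,
    "15", 19.0, 102.0,
    "16", 36.8, 90.3,
    "17", 25.1, 83.3,
    "18", 18.5, 80.4,
    "19", 26.2, 58.6,
    "20", 28.1, 64.4,
    "21", 12.0, 46.7,
    "22", 15.0, 50.8
  ) |>
    transmute(
      chrom = .data$chrom,
      p_length = round(.data$cen_mb * 1e6),
      q_length = round((.data$len_mb - .data$cen_mb) * 1e6),
      length = .data$p_length + .data$q_length
    )
}

#' @rdname default_genome
#' @param genome a genome tibble as returned by [default_genome()]
#' @export
interrogated_length <- function(genome = default_genome()) {
  validate_genome(genome)
  sum(genome$length)
}

#' Validate a genome model
#'
#' Checks arm lengths are positive, chromosome names unique, and the stored
#' chromosome length equals p + q.
#'
#' @param genome genome tibble (`chrom`, `p_length`, `q_length`, `length`)
#' @return the genome, invisibly unchanged, or an error
#' @export
validate_genome <- function(genome) {
  need <- c("chrom", "p_length", "q_length", "length")
  if (!all(need %in% names(genome))) {
    abort(paste0("genome must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(genome$chrom) > 0) abort("duplicate chromosome names in genome")
  if (any(genome$p_length <= 0) || any(genome$q_length <= 0)) {
    abort("all arm lengths must be > 0")
  }
  if (any(genome$length != genome$p_length + genome$q_length)) {
    abort("chromosome length must equal p_length + q_length")
  }
  invisible(genome)
}

#' Arm table for a genome
#'
#' Expands a genome model into one row per arm with chromosome-scale
#' coordinates: the p arm spans `[0, p_length)`, the q arm
#' `[p_length, length)`.
#'
#' @inheritParams validate_genome
#' @return tibble: `chrom`, `arm` ("p"/"q"), `arm_start`, `arm_end`, `arm_length`
#' @export
genome_arms <- function(genome = default_genome()) {
  validate_genome(genome)
  bind_rows(
    transmute(genome, chrom = .data$chrom, arm = "p",
              arm_start = 0, arm_end = .data$p_length),
    transmute(genome, chrom = .data$chrom, arm = "q",
              arm_start = .data$p_length, arm_end = .data$length)
  ) |>
    mutate(arm_length = .data$arm_end - .data$arm_start) |>
    arrange(match(.data$chrom, genome$chrom), .data$arm)
}

#' The 14-gene homologous recombination repair basket
#'
#' Genes whose pathogenic alterations define HRR-mutant status; wildtype for
#' all fourteen defines HRRwt, the negative-label class for classifier
#' training. `hrr_gene_loci()` additionally gives each gene a representative
#' genomic position (approximate GRCh38 gene midpoints) used to intersect
#' short variants with copy-number segments.
#'
#' @return `hrr_genes()`: character vector of 14 gene symbols.
#' @export
hrr_genes <- function() {
  c("BRCA1", "BRCA2", "ATM", "BARD1", "BRIP1", "CDK12", "CHEK1",
    "CHEK2", "FANCL", "PALB2", "RAD51B", "RAD51C", "RAD51D", "RAD54L")
}

#' @rdname hrr_genes
#' @return `hrr_gene_loci()`: tibble `gene`, `chrom`, `pos` (bp).
#' @export
hrr_gene_loci <- function() {
  tribble(
    ~gene, ~chrom, ~pos,
    "BRCA1", "17", 43100000,
    "BRCA2", "13", 32350000,
    "ATM", "11", 108250000,
    "BARD1", "2", 214750000,
    "BRIP1", "17", 61700000,
    "CDK12", "17", 39500000,
    "CHEK1", "11", 125500000,
    "CHEK2", "22", 28700000,
    "FANCL", "2", 58200000,
    "PALB2", "16", 23620000,
    "RAD51B", "14", 67800000,
    "RAD51C", "17", 58690000,
    "RAD51D", "17", 35100000,
    "RAD54L", "1", 46250000
  )
}

## genes in NCCN decision use: biallelic status in any of these defines the
## "core" genomic biomarker stratum
core_hrd_genes <- function() c("BRCA1", "BRCA2", "PALB2")
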