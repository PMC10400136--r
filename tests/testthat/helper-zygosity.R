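# Shared machinery for the zygosity rule truth table.

# Profile with the gene locus (A:50Mb) inside an LOH, diploid-het, or
# homozygous-deletion segment.
zyg_profile <- function(kind = c("het", "loh", "deep")) {
  kind <- match.arg(kind)
  state <- switch(kind, het = c(2, 1), loh = c(2, 0), deep = c(0, 0))
  toy_profile(list("A:p" = list(c(0.4, 2, 1),
                                c(0.2, state[1], state[2]),
                                c(0.4, 2, 1))),
              toy_genome())
}

zyg_gene_locus <- tibble::tibble(chrom = "A", pos = 50e6)

# 28 rule combinations: pathogenic short-variant count {0,1,2} x
# single-variant zygosity situation x deep deletion x rearrangement.
zyg_cases <- local({
  grid0 <- expand.grid(n_short = 0, situation = "none",
                       deep = c(FALSE, TRUE), rearr = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  grid1 <- expand.grid(n_short = 1, situation = c("under_loh", "het", "indet"),
                       deep = c(FALSE, TRUE), rearr = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  grid2 <- expand.grid(n_short = 2,
                       situation = c("het_pair", "loh_pair", "indet_pair"),
                       deep = c(FALSE, TRUE), rearr = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  rbind(grid0, grid1, grid2)
})

# Hand-derived expectation for each case, straight from the three biallelic
# rules plus the monoallelic / unknown assignment wording.
zyg_expected <- function(case) {
  if (case$deep) return(c("biallelic", "1"))
  n_alt <- case$n_short + as.integer(case$rearr)
  if (n_alt >= 2) return(c("biallelic", "2"))
  if (case$n_short == 1 && case$situation == "under_loh") {
    return(c("biallelic", "3"))
  }
  if (case$n_short == 1 && case$situation == "het" && !case$rearr) {
    return(c("monoallelic", "monoallelic"))
  }
  if (n_alt > 0) return(c("unknown", "unknown"))
  c("wildtype", "none")
}

# Build the variant table for a case and run the caller.
zyg_run_case <- function(case) {
  profile <- zyg_profile(
    if (case$situation %in% c("under_loh", "loh_pair")) "loh" else "het")
  v <- list()
  if (case$n_short >= 1) {
    het_flag <- switch(case$situation,
                       under_loh = FALSE, het = TRUE, het_pair = TRUE,
                       loh_pair = FALSE, indet_pair = NA,
                       indet = NA)
    v <- c(v, list(make_variant(gene = "G1", chrom = "A", pos = 50e6,
                                class = "SNV", het_flag = het_flag)))
  }
  if (case$n_short == 2) {
    # second variant outside the altered segment, called heterozygous
    v <- c(v, list(make_variant(gene = "G1", chrom = "A", pos = 5e6,
                                class = "SNV", het_flag = TRUE)))
  }
  if (case$deep) {
    v <- c(v, list(make_variant(gene = "G1", chrom = "A", pos = 50e6,
                                class = "deep_deletion", het_flag = NA)))
  }
  if (case$rearr) {
    v <- c(v, list(make_variant(gene = "G1", chrom = "A", pos = 50e6,
                                class = "rearrangement", het_flag = NA)))
  }
  variants <- if (length(v)) dplyr::bind_rows(v) else make_variant()[0, ]
  call_allelic_status("G1", variants, profile, toy_genome(),
                      gene_locus = zyg_gene_locus)
}
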