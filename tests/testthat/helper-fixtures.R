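# Fixture builders: tiny hand-specified genomes and profiles.

# A three-chromosome genome (100 Mb arms on "A", asymmetric "B", small "C")
# for arithmetic tests where round numbers matter.
toy_genome <- function() {
  tibble::tibble(
    chrom = c("A", "B", "C"),
    p_length = c(100e6, 60e6, 20e6),
    q_length = c(100e6, 140e6, 30e6),
    length = p_length + q_length
  )
}

# Build a profile from per-arm segment specs. `spec` is a list keyed by
# "chrom:arm" with a matrix-like list of c(len_fraction, total, minor) rows;
# fractions within an arm must sum to 1. Unlisted arms become one diploid
# heterozygous segment.
toy_profile <- function(spec = list(), genome = toy_genome(), sample = "s1") {
  arms <- genome_arms(genome)
  rows <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    key <- paste0(a$chrom, ":", a$arm)
    if (!is.null(spec[[key]])) {
      parts <- spec[[key]]
      fr <- vapply(parts, `[`, numeric(1), 1)
      stopifnot(abs(sum(fr) - 1) < 1e-9)
      bounds <- a$arm_start + round(cumsum(c(0, fr)) * a$arm_length)
      bounds[length(bounds)] <- a$arm_end
      rows[[key]] <- tibble::tibble(
        sample = sample, chrom = a$chrom,
        start = bounds[-length(bounds)], end = bounds[-1],
        total_cn = as.integer(vapply(parts, `[`, numeric(1), 2)),
        minor_cn = as.integer(vapply(parts, `[`, numeric(1), 3))
      )
    } else {
      rows[[key]] <- tibble::tibble(
        sample = sample, chrom = a$chrom, start = a$arm_start, end = a$arm_end,
        total_cn = 2L, minor_cn = 1L
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Random valid profile on the toy genome: each arm carved into 1-6 segments
# with random states. Used for oracle-equivalence tests.
random_profile <- function(genome = toy_genome(), sample = "s1") {
  arms <- genome_arms(genome)
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    k <- sample.int(6, 1)
    cuts <- sort(runif(k - 1, a$arm_start, a$arm_end))
    bounds <- round(c(a$arm_start, cuts, a$arm_end))
    bounds <- unique(bounds)
    nseg <- length(bounds) - 1
    total <- sample(0:4, nseg, replace = TRUE, prob = c(.05, .15, .45, .25, .1))
    minor <- vapply(total, function(tc) sample(0:(tc %/% 2), 1), integer(1))
    tibble::tibble(sample = sample, chrom = a$chrom,
                   start = bounds[-length(bounds)], end = bounds[-1],
                   total_cn = as.integer(total), minor_cn = as.integer(minor))
  })
  dplyr::bind_rows(rows)
}

# Short-variant record builder with the full column set.
make_variant <- function(sample = "s1", gene = "BRCA2", chrom = "A",
                         pos = 50e6, class = "SNV", pathogenic = TRUE,
                         del_length = NA_integer_,
                         microhomology_len = NA_integer_, het_flag = NA) {
  tibble::tibble(sample = sample, gene = gene, chrom = chrom, pos = pos,
                 class = class, pathogenic = pathogenic,
                 del_length = as.integer(del_length),
                 microhomology_len = as.integer(microhomology_len),
                 het_flag = het_flag)
}
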