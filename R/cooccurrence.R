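#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value by enumeration of the hypergeometric
#' distribution over all tables with the observed margins: the p-value is the
#' sum of the probabilities of every table whose probability does not exceed
#' that of the observed table (with the customary `1 + 1e-7` relative
#' tolerance for ties). The reported odds ratio is the sample
#' (cross-product) estimate, with a Haldane-Anscombe 0.5 correction applied
#' only when a cell is zero; it is intended for volcano plotting, not
#' inference.
#'
#' @param table 2x2 integer matrix, or vector `c(a, b, c, d)` filled by row
#' @return list with `odds_ratio` and `p`
#' @examples
#' fisher_exact_two_tailed(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p # 2/252
#' @export
fisher_exact_two_tailed <- function(table) {
  x <- as.vector(t(table))
  if (length(x) != 4L) abort("table must be 2x2")
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("table entries must be nonnegative integers")
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  p <- if (n == 0L) 1 else {
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    pk <- dhyper(ks, c1, n - c1, r1)
    p_obs <- pk[ks == a]
    min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  }
  or <- if (any(x == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction (via [stats::p.adjust()]), with
#' input validation.
#'
#' @param pvalues numeric vector of p-values in \[0,1\]
#' @return q-values, same length and order
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0,1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-gene co-occurrence of biallelic alteration with the HRD signature
#'
#' For every gene with at least one biallelic alteration in the cohort,
#' builds the 2x2 table of biallelic status against HRD-signature call, runs
#' the two-tailed Fisher test, and adjusts across genes with
#' Benjamini-Hochberg. A plotting column caps p at 1e-10; the cap is applied
#' after, and never enters, the q-value computation.
#'
#' @param statuses per-sample per-gene status tibble
#'   ([call_zygosity()]`$statuses`)
#' @param calls HRD signature call tibble ([predict_hrdsig()])
#' @return tibble of class `hrdsig_cooccurrence`: `gene`, `n_bi_pos`,
#'   `n_bi_neg`, `n_wt_pos`, `n_wt_neg`, `odds_ratio`, `p`, `q`, `p_capped`
#' @export
cooccurrence_test <- function(statuses, calls) {
  joined <- inner_join(statuses, select(calls, "sample", "call"), by = "sample")
  if (nrow(joined) == 0L) abort("no samples shared between statuses and calls")
  genes <- joined |>
    filter(.data$status == "biallelic") |>
    distinct(.data$gene) |>
    pull()
  if (length(genes) == 0L) {
    return(structure(
      tibble(gene = character(), n_bi_pos = integer(), n_bi_neg = integer(),
             n_wt_pos = integer(), n_wt_neg = integer(), odds_ratio = double(),
             p = double(), q = double(), p_capped = double()),
      class = c("hrdsig_cooccurrence", "tbl_df", "tbl", "data.frame")))
  }
  res <- purrr::map_dfr(genes, function(g) {
    gg <- joined[joined$gene == g, ]
    bi <- gg$status == "biallelic"
    pos <- gg$call == "positive"
    tab <- c(sum(bi & pos), sum(bi & !pos), sum(!bi & pos), sum(!bi & !pos))
    ft <- fisher_exact_two_tailed(tab)
    tibble(gene = g, n_bi_pos = tab[1], n_bi_neg = tab[2], n_wt_pos = tab[3],
           n_wt_neg = tab[4], odds_ratio = ft$odds_ratio, p = ft$p)
  })
  res$q <- fdr_adjust(res$p)
  res$p_capped <- pmax(res$p, 1e-10)
  structure(arrange(res, .data$p),
            class = c("hrdsig_cooccurrence", class(res)))
}

#' Genomic landscape partition of signature-positive samples
#'
#' Partitions HRD-signature-positive samples into mutually exclusive strata
#' by descending genomic priority: biallelic BRCA1/BRCA2/PALB2, biallelic in
#' another HRR gene, non-biallelic (monoallelic or zygosity-unknown) HRR
#' alteration, and HRR wildtype. Fractions sum to 1 over positive samples;
#' an empty positive set returns zero counts with `NA` fractions.
#'
#' @param sample_classes [call_zygosity()]`$samples`
#' @param calls [predict_hrdsig()] output
#' @return tibble `stratum`, `n`, `fraction`
#' @export
landscape_partition <- function(sample_classes, calls) {
  joined <- inner_join(sample_classes, select(calls, "sample", "call"),
                       by = "sample")
  unjoined <- setdiff(calls$sample, sample_classes$sample)
  if (length(unjoined)) {
    abort(sprintf("sample '%s' has a signature call but no HRR status", unjoined[1]))
  }
  pos <- filter(joined, .data$call == "positive")
  strata <- c("biallelic BRCA1/2/PALB2", "other biallelic HRR",
              "non-biallelic HRR alteration", "HRRwt")
  lab <- with(pos, case_when(
    core_biallelic ~ strata[1],
    hrr_class == "biallelic" ~ strata[2],
    hrr_class %in% c("monoallelic-only", "unknown-only") ~ strata[3],
    TRUE ~ strata[4]
  ))
  n <- vapply(strata, function(s) sum(lab == s), integer(1), USE.NAMES = FALSE)
  tibble(
    stratum = strata,
    n = n,
    fraction = if (nrow(pos) == 0L) rep(NA_real_, 4) else n / nrow(pos)
  )
}

#' Prevalence as a printed percentage
#'
#' @param positives,total nonnegative counts, `total > 0`
#' @return `100 * positives / total`, rounded to one decimal
#' @examples
#' compute_prevalence(30, 151) # 19.9
#' @export
compute_prevalence <- function(positives, total) {
  if (any(total <= 0)) abort("total must be > 0")
  if (any(positives < 0) || any(positives > total)) {
    abort("positives must lie in [0, total]")
  }
  round(100 * positives / total, 1)
}

#' Volcano plot of co-occurrence results
#'
#' @param object an `hrdsig_cooccurrence` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.hrdsig_cooccurrence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = log2(.data$odds_ratio), y = -log10(.data$p_capped))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q < 0.05)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene),
                       data = ~ dplyr::filter(.x, .data$q < 0.05),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "log2 odds ratio (biallelic vs HRDsig+)",
                  y = "-log10 p (capped at 1e-10)", colour = "q < 0.05")
}
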