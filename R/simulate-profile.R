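#' Simulate one segmented allele-specific copy-number profile
#'
#' Generates a profile that tiles every chromosome arm with contiguous,
#' non-overlapping, 0-based half-open segments, starting from a diploid
#' heterozygous baseline (total 2, minor 1) and overlaying scar events drawn
#' at the configured genome-wide rates: interstitial focal LOH segments
#' (16-45 Mb), small LOH segments (3-12 Mb), copy-gain intervals that create
#' large-scale transitions, telomeric allelic-imbalance events, and whole-arm
#' LOH (the latter excluded from focal-LOH scoring downstream). HRD+ profiles
#' use the `hrd_pos` rates, HRD− the `hrd_neg` rates. Scarring is simulated
#' directly at segment level; no replication mechanism is modelled because
#' only the resulting features feed the classifier.
#'
#' A matching set of passenger deletion calls is drawn for the indel features:
#' each deletion is microhomology-flanked with probability `mh_prob`
#' (length >= 5 bp, flanking microhomology 1-7 bp), otherwise a short
#' non-microhomology deletion.
#'
#' @param hrd_status logical; which effect-size class to draw from
#' @param genome genome tibble ([default_genome()])
#' @param effects `scar_effect_sizes` list (see [sim_config()])
#' @param seed optional integer; when given, the draw is wrapped in
#'   [withr::with_seed()] so identical inputs give identical profiles
#' @param force_loh optional tibble `chrom`, `pos`: loci that must fall inside
#'   an LOH segment (used to realise "pathogenic short variant under LOH"
#'   biallelic genotypes); applied after random events
#' @param force_deep_del optional tibble `chrom`, `pos`: loci that must fall
#'   inside a homozygous-deletion (total 0) segment
#' @param arms precomputed [genome_arms()] table (an optimisation for
#'   cohort-scale callers; must match `genome`)
#' @return list with `segments` (tibble `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn`) and `variants` (passenger deletion tibble in the short-variant
#'   layout, `gene = NA`)
#' @examples
#' p <- simulate_profile(TRUE, seed = 42)
#' head(p$segments)
#' @export
simulate_profile <- function(hrd_status,
                             genome = default_genome(),
                             effects = default_scar_effects(),
                             seed = NULL,
                             force_loh = NULL,
                             force_deep_del = NULL,
                             arms = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_profile(
      hrd_status, genome, effects, seed = NULL,
      force_loh = force_loh, force_deep_del = force_deep_del, arms = arms
    )))
  }
  eff <- if (isTRUE(hrd_status)) effects$hrd_pos else effects$hrd_neg
  if (is.null(arms)) arms <- genome_arms(genome)

  ev <- draw_scar_events(arms, eff)
  ev <- rbind(ev, forced_events(force_loh, force_deep_del, genome))
  segments <- build_segments(arms, ev)
  variants <- draw_passenger_deletions(eff, genome)
  list(segments = segments, variants = variants)
}

## draw genome-wide scar events; plain data.frame of intervals + states, in
## application order (later rows win)
draw_scar_events <- function(arms, eff) {
  types <- c("focal_loh", "small_loh", "lst", "tai", "whole_arm_loh")
  counts <- vapply(types, function(t) rpois(1L, eff[[t]] %||% 0), integer(1))
  total <- sum(counts)
  ev <- data.frame(chrom = character(total), start = numeric(total),
                   end = numeric(total), total_cn = integer(total),
                   minor_cn = integer(total))
  if (total == 0L) return(ev)
  type <- rep(types, counts)
  ## events land on arms with probability proportional to arm length
  ai <- sample.int(nrow(arms), total, replace = TRUE, prob = arms$arm_length)
  for (i in seq_len(total)) {
    astart <- arms$arm_start[ai[i]]
    aend <- arms$arm_end[ai[i]]
    alen <- aend - astart
    iv <- switch(
      type[i],
      focal_loh = c(interstitial_interval(astart, aend, 16e6, 45e6),
                    sample(c(1L, 2L), 1, prob = c(0.3, 0.7)), 0L),
      small_loh = c(interstitial_interval(astart, aend, 3e6, 12e6),
                    sample(c(1L, 2L), 1, prob = c(0.3, 0.7)), 0L),
      lst = c(interstitial_interval(astart, aend, 12e6, 30e6), 3L, 1L),
      tai = {
        len <- runif(1, 5e6, 0.8 * alen)
        ## p arms carry the chromosome-start telomere, q arms the end one
        p_arm <- astart == 0
        st <- if (runif(1) < 0.6) c(3L, 1L) else c(2L, 0L)
        if (p_arm) c(astart, astart + len, st) else c(aend - len, aend, st)
      },
      whole_arm_loh = c(astart, aend, 2L, 0L)
    )
    ev$chrom[i] <- arms$chrom[ai[i]]
    ev$start[i] <- iv[1]
    ev$end[i] <- iv[2]
    ev$total_cn[i] <- iv[3]
    ev$minor_cn[i] <- iv[4]
  }
  ev
}

interstitial_interval <- function(astart, aend, lo, hi) {
  alen <- aend - astart
  len <- min(runif(1, lo, hi), 0.8 * alen)
  pad <- 0.02 * alen
  s <- runif(1, astart + pad, max(astart + pad, aend - pad - len))
  c(s, min(s + len, aend - pad))
}

forced_events <- function(force_loh, force_deep_del, genome) {
  mk <- function(df, half_width, total, minor) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    i <- match(df$chrom, genome$chrom)
    p_len <- genome$p_length[i]
    len <- genome$length[i]
    ## clip to the arm containing the locus (segments never cross the
    ## centromere)
    alo <- ifelse(df$pos < p_len, 0, p_len)
    ahi <- ifelse(df$pos < p_len, p_len, len)
    data.frame(chrom = df$chrom,
               start = pmax(alo, df$pos - half_width),
               end = pmin(ahi, df$pos + half_width),
               total_cn = total, minor_cn = minor)
  }
  out <- rbind(mk(force_loh, 10e6, 2L, 0L),
               mk(force_deep_del, 0.5e6, 0L, 0L))
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), total_cn = integer(0),
                      minor_cn = integer(0))
  }
  out
}

## overlay events on the diploid baseline, arm by arm; later events win
build_segments <- function(arms, ev) {
  n_arms <- nrow(arms)
  chrom_out <- vector("list", n_arms)
  start_out <- vector("list", n_arms)
  end_out <- vector("list", n_arms)
  total_out <- vector("list", n_arms)
  minor_out <- vector("list", n_arms)
  for (i in seq_len(n_arms)) {
    a_chrom <- arms$chrom[i]
    a_start <- arms$arm_start[i]
    a_end <- arms$arm_end[i]
    sel <- ev$chrom == a_chrom & ev$end > a_start & ev$start < a_end
    if (!any(sel)) {
      chrom_out[[i]] <- a_chrom
      start_out[[i]] <- a_start
      end_out[[i]] <- a_end
      total_out[[i]] <- 2L
      minor_out[[i]] <- 1L
      next
    }
    e <- ev[sel, , drop = FALSE]
    s <- pmax(e$start, a_start)
    en <- pmin(e$end, a_end)
    bp <- sort(unique(c(a_start, a_end, s, en)))
    lo <- bp[-length(bp)]
    hi <- bp[-1L]
    mid <- (lo + hi) / 2
    total <- rep(2L, length(mid))
    minor <- rep(1L, length(mid))
    for (j in seq_len(nrow(e))) {
      cover <- mid > s[j] & mid < en[j]
      total[cover] <- e$total_cn[j]
      minor[cover] <- e$minor_cn[j]
    }
    ## merge adjacent equal states
    k <- length(total)
    new_grp <- c(TRUE, total[-1] != total[-k] | minor[-1] != minor[-k])
    fi <- which(new_grp)
    li <- c(fi[-1] - 1L, k)
    chrom_out[[i]] <- rep(a_chrom, length(fi))
    start_out[[i]] <- lo[fi]
    end_out[[i]] <- hi[li]
    total_out[[i]] <- total[fi]
    minor_out[[i]] <- minor[fi]
  }
  out <- tibble(
    chrom = unlist(chrom_out),
    start = round(unlist(start_out)),
    end = round(unlist(end_out)),
    total_cn = unlist(total_out),
    minor_cn = unlist(minor_out)
  )
  out[out$end > out$start, , drop = FALSE]
}

draw_passenger_deletions <- function(eff, genome) {
  n <- rpois(1L, eff$n_del %||% 0)
  if (n == 0L) {
    return(tibble(gene = character(), chrom = character(), pos = double(),
                  class = character(), pathogenic = logical(),
                  del_length = integer(), microhomology_len = integer(),
                  het_flag = logical()))
  }
  is_mh <- runif(n) < (eff$mh_prob %||% 0)
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  tibble(
    gene = NA_character_,
    chrom = genome$chrom[ci],
    pos = floor(runif(n, 0, genome$length[ci])),
    class = "indel",
    pathogenic = FALSE,
    del_length = as.integer(ifelse(is_mh, 5L + rpois(n, 8), 1L + rpois(n, 1.2))),
    microhomology_len = as.integer(ifelse(is_mh, 1L + rpois(n, 1.5), 0L)),
    het_flag = TRUE
  )
}
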