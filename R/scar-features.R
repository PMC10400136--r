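#' Validate a segmented copy-number profile
#'
#' A valid profile tiles every chromosome arm of its genome with sorted,
#' contiguous, non-overlapping, 0-based half-open segments, never crosses a
#' centromere, and satisfies the copy-number invariants `end > start`,
#' `total_cn >= 0`, `0 <= minor_cn <= total_cn - minor_cn` (the minor allele
#' is the less frequent one). Works on single- or multi-sample segment
#' tables (column `sample` optional for a single profile).
#'
#' @param segments segment tibble: `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn` (+ optional `sample`)
#' @param genome genome model tibble
#' @return `segments`, invisibly sorted by (sample,) chrom, start; errors on
#'   the first offending segment otherwise
#' @examples
#' p <- simulate_profile(FALSE, seed = 1)
#' nrow(validate_profile(p$segments))
#' @export
validate_profile <- function(segments, genome = default_genome()) {
  validate_genome(genome)
  seg <- as_tibble(segments)
  if (!"sample" %in% names(seg)) seg$sample <- "sample1"
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(seg))) {
    abort(paste0("segments must have columns: ", paste(need, collapse = ", ")))
  }
  bad_chrom <- setdiff(unique(seg$chrom), genome$chrom)
  if (length(bad_chrom)) {
    abort(sprintf("segment chromosome '%s' not in genome", bad_chrom[1]))
  }
  seg_fmt <- function(r) {
    sprintf("%s:%s-%s (total %s, minor %s)", r$chrom,
            format(r$start, scientific = FALSE),
            format(r$end, scientific = FALSE), r$total_cn, r$minor_cn)
  }
  bad <- which(seg$end <= seg$start)
  if (length(bad)) abort(paste0("segment with end <= start: ", seg_fmt(seg[bad[1], ])))
  bad <- which(seg$total_cn < 0 | seg$minor_cn < 0)
  if (length(bad)) abort(paste0("negative copy number: ", seg_fmt(seg[bad[1], ])))
  bad <- which(seg$minor_cn > seg$total_cn - seg$minor_cn)
  if (length(bad)) {
    abort(paste0("minor_cn exceeds the major allele count: ", seg_fmt(seg[bad[1], ])))
  }

  seg <- arrange(seg, .data$sample, match(.data$chrom, genome$chrom), .data$start)
  ann <- annotate_arms(seg, genome)
  bad <- which(is.na(ann$arm))
  if (length(bad)) {
    abort(paste0("segment crosses a centromere or chromosome end: ",
                 seg_fmt(seg[bad[1], ])))
  }

  n <- nrow(ann)
  if (n > 0) {
    key <- paste(ann$sample, ann$chrom, ann$arm)
    first <- c(TRUE, key[-1] != key[-n])
    last <- c(first[-1], TRUE)
    ok <- (!first | ann$start == ann$arm_start) &
      (!last | ann$end == ann$arm_end) &
      (first | ann$start == c(0, ann$end[-n]))
    if (!all(ok)) {
      r <- ann[which(!ok)[1], ]
      abort(sprintf(
        "segments do not tile arm %s%s of sample %s (gap, overlap or missing telomeric/centromeric coverage; offending segment %s)",
        r$chrom, r$arm, r$sample, seg_fmt(r)))
    }
    arms_per_sample <- tapply(key[first], ann$sample[first], length)
    n_arms <- 2L * nrow(genome)
    short <- names(arms_per_sample)[arms_per_sample < n_arms]
    if (length(short)) {
      abort(sprintf("sample %s does not cover all %d arms", short[1], n_arms))
    }
  }
  invisible(seg)
}

## assign each segment to its arm; NA when it straddles the centromere
annotate_arms <- function(seg, genome) {
  seg |>
    left_join(genome, by = "chrom") |>
    mutate(
      arm = case_when(
        .data$end <= .data$p_length ~ "p",
        .data$start >= .data$p_length & .data$end <= .data$length ~ "q",
        TRUE ~ NA_character_
      ),
      arm_start = ifelse(.data$arm == "p", 0, .data$p_length),
      arm_end = ifelse(.data$arm == "p", .data$p_length, .data$length),
      arm_length = .data$arm_end - .data$arm_start,
      seg_length = .data$end - .data$start
    )
}

## vectorised run-length merge of adjacent segments with identical
## (total, minor) state within each (sample, chrom, arm); input must be
## sorted. Returns the annotated-column layout plus is_first/is_last flags.
merge_same_state <- function(ann) {
  n <- nrow(ann)
  if (n == 0) return(mutate(ann, is_first = logical(0), is_last = logical(0)))
  key <- paste(ann$sample, ann$chrom, ann$arm)
  new_run <- c(TRUE, key[-1] != key[-n] |
                 ann$total_cn[-1] != ann$total_cn[-n] |
                 ann$minor_cn[-1] != ann$minor_cn[-n])
  fi <- which(new_run)
  li <- c(fi[-1] - 1L, n)
  out <- ann[fi, ]
  out$end <- ann$end[li]
  out$seg_length <- out$end - out$start
  m <- nrow(out)
  mkey <- key[fi]
  out$is_first <- c(TRUE, mkey[-1] != mkey[-m])
  out$is_last <- c(out$is_first[-1], TRUE)
  out
}

#' Genome-wide focal LOH fraction
#'
#' gLOH is the fraction of the interrogated genome (sum of all arm lengths)
#' covered by focal LOH segments. An LOH segment has minor copy number 0 and
#' total copy number >= 1 (homozygous deletions are not LOH); segments
#' spanning at least 90% of their chromosome arm are considered whole-arm
#' events and excluded, as they usually reflect mitotic missegregation rather
#' than recombination-repair scarring.
#'
#' @inheritParams validate_profile
#' @return tibble `sample`, `gloh` (fraction in \[0,1\])
#' @examples
#' p <- simulate_profile(TRUE, seed = 5)
#' compute_gloh(p$segments)
#' @export
compute_gloh <- function(segments, genome = default_genome()) {
  seg <- validate_profile(segments, genome)
  gloh_impl(annotate_arms(seg, genome), genome)
}

gloh_impl <- function(ann, genome) {
  total_len <- interrogated_length(genome)
  contrib <- ifelse(
    ann$minor_cn == 0 & ann$total_cn >= 1 &
      ann$seg_length < 0.9 * ann$arm_length,
    ann$seg_length, 0)
  sum_by_sample(ann$sample, contrib, "gloh") |>
    mutate(gloh = .data$gloh / total_len)
}

## rowsum-based per-sample aggregation keeping every sample (factor levels)
sum_by_sample <- function(sample, value, name) {
  f <- factor(sample, levels = unique(sample))
  v <- rowsum(as.numeric(value), f)
  out <- tibble(sample = rownames(v), x = as.numeric(v[, 1]))
  names(out)[2] <- name
  out
}

#' Large-scale state transitions
#'
#' Counts, per arm, adjacent segment pairs in different allele-specific
#' copy-number states where both segments are at least `min_seg` long, after
#' first merging adjacent same-state segments and discarding segments shorter
#' than `smooth_below` (short interstitial fragments are treated as noise and
#' the flanking segments become adjacent).
#'
#' @inheritParams validate_profile
#' @param min_seg minimum length (bp) of both flanking segments; default 10 Mb
#' @param smooth_below segments shorter than this (bp) are dropped before
#'   counting; default 3 Mb
#' @return tibble `sample`, `n_lst`
#' @export
count_lst <- function(segments, genome = default_genome(),
                      min_seg = 10e6, smooth_below = 3e6) {
  seg <- validate_profile(segments, genome)
  merged <- merge_same_state(annotate_arms(seg, genome))
  lst_impl(seg, merged, min_seg, smooth_below)
}

lst_impl <- function(seg, merged, min_seg = 10e6, smooth_below = 3e6) {
  m <- merged[merged$seg_length >= smooth_below, , drop = FALSE]
  n <- nrow(m)
  is_lst <- logical(n)
  if (n > 1) {
    key <- paste(m$sample, m$chrom, m$arm)
    same_arm <- key[-1] == key[-n]
    differs <- m$total_cn[-1] != m$total_cn[-n] |
      m$minor_cn[-1] != m$minor_cn[-n]
    long_pair <- m$seg_length[-1] >= min_seg & m$seg_length[-n] >= min_seg
    is_lst <- c(FALSE, same_arm & differs & long_pair)
  }
  res <- sum_by_sample(m$sample, is_lst, "n_lst")
  all_s <- tibble(sample = unique(seg$sample))
  out <- left_join(all_s, res, by = "sample")
  out$n_lst <- as.integer(dplyr::coalesce(out$n_lst, 0))
  out
}

#' Scar feature extraction
#'
#' Computes the named feature vector fed to the HRD classifier from a
#' validated profile and its short-variant calls:
#' * `gloh` — genome-wide focal LOH fraction ([compute_gloh()])
#' * `n_loh_interstitial` — LOH segments longer than 15 Mb, excluding
#'   chromosomes that are LOH end to end
#' * `n_lst` — large-scale state transitions ([count_lst()])
#' * `n_tai` — telomeric allelic imbalance: telomere-touching segments with
#'   unequal allele counts that span less than their whole arm (so they do
#'   not reach the centromere)
#' * `n_breakpoints` — transitions between adjacent same-arm segments after
#'   merging equal states
#' * `mh_del_count` — deletions >= 5 bp with >= 1 bp flanking microhomology
#' * `mh_del_fraction` — fraction of all deletions that are
#'   microhomology-flanked (0 when there are no deletions)
#' * `median_del_len` — median deletion length (0 when none)
#'
#' @inheritParams validate_profile
#' @param variants short-variant tibble for the same sample(s); deletions are
#'   `class == "indel"` records with `del_length >= 1`
#' @return tibble with one row per sample, columns in the fixed order above
#' @examples
#' p <- simulate_profile(TRUE, seed = 8)
#' extract_features(p$segments, p$variants)
#' @export
extract_features <- function(segments, variants = NULL,
                             genome = default_genome()) {
  seg <- validate_profile(segments, genome)
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- empty_variants()
  }
  if (!"sample" %in% names(variants)) variants$sample <- seg$sample[1]
  extra <- setdiff(unique(variants$sample), unique(seg$sample))
  if (length(extra)) {
    abort(sprintf("variants carry sample '%s' absent from the profile", extra[1]))
  }

  ann <- annotate_arms(seg, genome)
  gloh <- gloh_impl(ann, genome)

  ## interstitial LOH: >15 Mb LOH segments unless the chromosome is LOH
  ## end to end
  is_loh <- ann$minor_cn == 0 & ann$total_cn >= 1
  chrom_key <- paste(ann$sample, ann$chrom)
  whole_chrom <- stats::ave(is_loh, chrom_key, FUN = all) > 0
  loh_int <- sum_by_sample(
    ann$sample, is_loh & ann$seg_length > 15e6 & !whole_chrom,
    "n_loh_interstitial")

  merged <- merge_same_state(ann)
  lst <- lst_impl(seg, merged)

  tai_flag <- ((merged$arm == "p" & merged$is_first) |
                 (merged$arm == "q" & merged$is_last)) &
    merged$minor_cn != merged$total_cn - merged$minor_cn &
    merged$seg_length < merged$arm_length
  tai <- sum_by_sample(merged$sample, tai_flag, "n_tai")
  bkp <- sum_by_sample(merged$sample, !merged$is_first, "n_breakpoints")

  dels <- variants |>
    filter(.data$class == "indel", !is.na(.data$del_length),
           .data$del_length >= 1)
  indel <- dels |>
    group_by(.data$sample) |>
    summarise(
      mh_del_count = sum(.data$del_length >= 5 &
                           dplyr::coalesce(.data$microhomology_len, 0L) >= 1),
      mh_del_fraction = mh_del_count / dplyr::n(),
      median_del_len = stats::median(.data$del_length),
      .groups = "drop"
    )

  gloh |>
    left_join(loh_int, by = "sample") |>
    left_join(lst, by = "sample") |>
    left_join(tai, by = "sample") |>
    left_join(bkp, by = "sample") |>
    left_join(indel, by = "sample") |>
    mutate(
      n_loh_interstitial = as.integer(.data$n_loh_interstitial),
      n_tai = as.integer(.data$n_tai),
      n_breakpoints = as.integer(.data$n_breakpoints),
      mh_del_count = as.integer(dplyr::coalesce(.data$mh_del_count, 0L)),
      mh_del_fraction = dplyr::coalesce(.data$mh_del_fraction, 0),
      median_del_len = dplyr::coalesce(as.double(.data$median_del_len), 0)
    ) |>
    select("sample", "gloh", "n_loh_interstitial", "n_lst", "n_tai",
           "n_breakpoints", "mh_del_count", "mh_del_fraction", "median_del_len")
}

#' Names of the scar features, in classifier column order
#' @return character vector
#' @export
scar_feature_names <- function() {
  c("gloh", "n_loh_interstitial", "n_lst", "n_tai", "n_breakpoints",
    "mh_del_count", "mh_del_fraction", "median_del_len")
}
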