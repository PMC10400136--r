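test_that("profile validation accepts clean profiles and names offenders", {
  g <- toy_genome()
  p <- toy_profile(genome = g)
  expect_silent(validate_profile(p, g))

  overlap <- toy_profile(list("A:p" = list(c(0.5, 2, 1), c(0.5, 3, 1))), g)
  overlap$start[2] <- overlap$start[2] - 5e6 # now overlaps its neighbour
  expect_error(validate_profile(overlap, g), "tile")

  gap <- toy_profile(list("A:p" = list(c(0.5, 2, 1), c(0.5, 3, 1))), g)
  gap$end[1] <- gap$end[1] - 1e6
  expect_error(validate_profile(gap, g), "tile")

  bad_minor <- p
  bad_minor$minor_cn[1] <- 3L # total is 2
  expect_error(validate_profile(bad_minor, g), "minor")

  neg <- p
  neg$total_cn[1] <- -1L
  expect_error(validate_profile(neg, g), "negative")

  straddle <- toy_profile(genome = g)
  straddle <- straddle[!(straddle$chrom == "A"), ]
  straddle <- dplyr::bind_rows(
    straddle,
    tibble::tibble(sample = "s1", chrom = "A", start = 0, end = 200e6,
                   total_cn = 2L, minor_cn = 1L))
  expect_error(validate_profile(straddle, g), "centromere")
})

test_that("gLOH arithmetic matches forced examples", {
  g <- toy_genome() # interrogated length 450 Mb
  # no LOH at all
  expect_equal(compute_gloh(toy_profile(genome = g), g)$gloh, 0)

  # one 30 Mb focal LOH segment on A:p (fraction 0.3 of a 100 Mb arm)
  p <- toy_profile(list("A:p" = list(c(0.35, 2, 1), c(0.30, 2, 0), c(0.35, 2, 1))), g)
  expect_equal(compute_gloh(p, g)$gloh, 30e6 / 450e6)

  # an LOH segment covering 95% of an arm is excluded as whole-arm
  p95 <- toy_profile(list("A:p" = list(c(0.95, 2, 0), c(0.05, 2, 1))), g)
  expect_equal(compute_gloh(p95, g)$gloh, 0)

  # homozygous deletions are not LOH
  pdel <- toy_profile(list("A:p" = list(c(0.35, 2, 1), c(0.30, 0, 0), c(0.35, 2, 1))), g)
  expect_equal(compute_gloh(pdel, g)$gloh, 0)
})

test_that("gLOH is monotone in focal LOH and drops on whole-arm conversion", {
  g <- toy_genome()
  base <- toy_profile(list("A:p" = list(c(0.4, 2, 1), c(0.2, 2, 0), c(0.4, 2, 1))), g)
  more <- toy_profile(list(
    "A:p" = list(c(0.4, 2, 1), c(0.2, 2, 0), c(0.4, 2, 1)),
    "B:q" = list(c(0.3, 2, 1), c(0.25, 1, 0), c(0.45, 2, 1))), g)
  expect_gt(compute_gloh(more, g)$gloh, compute_gloh(base, g)$gloh)

  # converting the focal segment to >=90% of its arm removes its contribution
  widened <- toy_profile(list(
    "A:p" = list(c(0.05, 2, 1), c(0.92, 2, 0), c(0.03, 2, 1)),
    "B:q" = list(c(0.3, 2, 1), c(0.25, 1, 0), c(0.45, 2, 1))), g)
  only_b <- toy_profile(list(
    "B:q" = list(c(0.3, 2, 1), c(0.25, 1, 0), c(0.45, 2, 1))), g)
  expect_equal(compute_gloh(widened, g)$gloh, compute_gloh(only_b, g)$gloh)
  expect_lt(compute_gloh(widened, g)$gloh, compute_gloh(more, g)$gloh)
})

test_that("LST counting matches forced examples", {
  g <- toy_genome()
  expect_equal(count_lst(toy_profile(genome = g), g)$n_lst, 0)

  # one arm split into two 50 Mb halves of different total CN -> 1 transition
  p <- toy_profile(list("A:p" = list(c(0.5, 2, 1), c(0.5, 3, 1))), g)
  expect_equal(count_lst(p, g)$n_lst, 1)

  # a sub-3Mb fragment between two long segments is smoothed away; the
  # flanking segments share a state so no transition remains
  p2 <- toy_profile(list("A:p" = list(c(0.49, 2, 1), c(0.02, 5, 1), c(0.49, 2, 1))), g)
  expect_equal(count_lst(p2, g)$n_lst, 0)

  # both flanks must be >= 10 Mb
  p3 <- toy_profile(list("C:p" = list(c(0.45, 2, 1), c(0.55, 3, 1))), g) # 9/11 Mb
  expect_equal(count_lst(p3, g)$n_lst, 0)
})

test_that("LST and interstitial-LOH counts equal brute-force oracles on random profiles", {
  withr::with_seed(424, {
    for (rep in 1:25) {
      p <- random_profile()
      expect_equal(count_lst(p, toy_genome())$n_lst,
                   oracle_lst(p, toy_genome()), label = paste("lst rep", rep))
      f <- extract_features(p, genome = toy_genome())
      expect_equal(f$n_loh_interstitial, oracle_loh_count(p, toy_genome()),
                   label = paste("loh rep", rep))
    }
  })
})

test_that("telomeric allelic imbalance requires a telomere and spares whole arms", {
  g <- toy_genome()
  # telomeric imbalance on A:p start, interstitial imbalance elsewhere
  p <- toy_profile(list(
    "A:p" = list(c(0.2, 3, 1), c(0.8, 2, 1)),        # telomeric gain -> TAI
    "A:q" = list(c(0.3, 2, 1), c(0.3, 3, 1), c(0.4, 2, 1)), # interstitial, no
    "B:q" = list(c(0.6, 2, 1), c(0.4, 2, 0))         # q-telomeric LOH -> TAI
  ), g)
  expect_equal(extract_features(p, genome = g)$n_tai, 2)

  # whole-arm imbalance does not count
  pw <- toy_profile(list("A:p" = list(c(1, 3, 1))), g)
  expect_equal(extract_features(pw, genome = g)$n_tai, 0)
})

test_that("feature extraction handles the all-diploid and indel cases", {
  g <- toy_genome()
  f0 <- extract_features(toy_profile(genome = g), genome = g)
  expect_equal(f0$gloh, 0)
  expect_equal(f0$n_loh_interstitial + f0$n_lst + f0$n_tai + f0$n_breakpoints, 0)
  expect_equal(f0$mh_del_fraction, 0) # defined as 0 with no deletions
  expect_equal(f0$median_del_len, 0)

  # 4 deletions, 3 microhomology-flanked
  dels <- dplyr::bind_rows(
    make_variant(gene = NA, class = "indel", pathogenic = FALSE,
                 del_length = 8, microhomology_len = 2),
    make_variant(gene = NA, class = "indel", pathogenic = FALSE,
                 del_length = 12, microhomology_len = 1),
    make_variant(gene = NA, class = "indel", pathogenic = FALSE,
                 del_length = 6, microhomology_len = 3),
    make_variant(gene = NA, class = "indel", pathogenic = FALSE,
                 del_length = 2, microhomology_len = 0)
  )
  f <- extract_features(toy_profile(genome = g), dels, genome = g)
  expect_equal(f$mh_del_count, 3)
  expect_equal(f$mh_del_fraction, 0.75)
  expect_equal(f$median_del_len, 7)
})

test_that("three hand-built 20 Mb interstitial LOH segments count as three", {
  g <- toy_genome()
  p <- toy_profile(list(
    "A:p" = list(c(0.2, 2, 1), c(0.2, 2, 0), c(0.6, 2, 1)),
    "A:q" = list(c(0.5, 2, 1), c(0.2, 1, 0), c(0.3, 2, 1)),
    "B:q" = list(c(0.1, 2, 1), c(1 / 7, 2, 0), c(0.9 - 1 / 7, 2, 1)) # 20 Mb LOH
  ), g)
  expect_equal(extract_features(p, genome = g)$n_loh_interstitial,
               oracle_loh_count(p, g))
  expect_equal(oracle_loh_count(p, g), 3)
})

test_that("feature extraction is invariant to input segment order", {
  withr::with_seed(77, {
    p <- random_profile()
    shuffled <- p[sample.int(nrow(p)), ]
    expect_equal(extract_features(shuffled, genome = toy_genome()),
                 extract_features(p, genome = toy_genome()))
  })
})

test_that("variants with a foreign sample id are rejected", {
  p <- toy_profile(genome = toy_genome())
  v <- make_variant(sample = "someone-else")
  expect_error(extract_features(p, v, genome = toy_genome()), "sample")
})
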