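test_that("MIE detection matches the brute-force assortment oracle on all 27 trios", {
  grid <- expand.grid(f = 0:2, m = 0:2, o = 0:2)
  got <- mendelian_consistent(grid$f, grid$m, grid$o)
  want <- mapply(assortment_oracle, grid$f, grid$m, grid$o)
  expect_equal(got, unname(want))
  # and the canonical cases read right
  expect_false(mendelian_consistent(0L, 0L, 1L)) # de novo pattern
  expect_true(mendelian_consistent(1L, 0L, 1L))
  expect_false(mendelian_consistent(1L, 2L, 0L)) # obligate alt lost
})

test_that("detect_mies skips missing/filtered genotypes and honours targets", {
  sites <- dplyr::bind_rows(
    make_site(pos = 100, gt_f = 0L, gt_m = 0L, gt_o = 1L), # MIE
    make_site(pos = 200, gt_f = 1L, gt_m = 0L, gt_o = 1L), # Mendelian
    make_site(pos = 300, gt_f = NA_integer_, gt_m = 0L, gt_o = 1L), # missing
    make_site(pos = 5000, gt_f = 0L, gt_m = 0L, gt_o = 1L) # outside target
  )
  target <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  mies <- detect_mies(sites, target)
  expect_equal(mies$pos, 100)
  rep <- attr(mies, "skip_report")
  expect_equal(unname(rep["outside_target"]), 1)
  expect_equal(unname(rep["missing_genotype"]), 1)
  expect_equal(unname(rep["tested"]), 2)

  # a quality-filtered genotype is skipped, not treated as missing
  sites$filtered_father <- c(TRUE, FALSE, FALSE, FALSE)
  mies2 <- detect_mies(sites, target)
  expect_equal(nrow(mies2), 0)
  expect_equal(unname(attr(mies2, "skip_report")["filtered_genotype"]), 1)
})

test_that("depth ratio is 1 for identical tracks and ~0.5 over a deletion", {
  set.seed(21)
  base <- rpois(5e4, 150)
  depths <- list(father = list(chr1 = base), offspring = list(chr1 = base))
  gm <- c(father = 150, offspring = 150)
  expect_equal(
    depth_ratio(depths, "chr1", 0, 5e4, "father", "offspring", gm), 1
  )
  half <- base
  half[10001:20000] <- rbinom(10000, base[10001:20000], 0.5)
  depths$offspring$chr1 <- half
  r <- depth_ratio(depths, "chr1", 10000, 20000, "father", "offspring", gm)
  expect_lt(abs(r - 0.5), 0.02)
  expect_error(
    depth_ratio(list(a = list(chr1 = rep(0L, 10)), b = list(chr1 = rep(0L, 10))),
      "chr1", 0, 10, "a", "b", c(a = 1, b = 1)),
    "undefined"
  )
})

test_that("classification follows the decision table", {
  flat <- list(chr1 = rep(150L, 4000))
  half <- list(chr1 = rep(75L, 4000))
  gm <- c(father = 150, mother = 150, offspring = 150)
  run <- function(gt_f, gt_m, gt_o, df = flat, dm = flat, do = flat) {
    mie <- make_site(pos = 2000, gt_f = gt_f, gt_m = gt_m, gt_o = gt_o)
    cl <- classify_mies(mie, list(father = df, mother = dm, offspring = do), gm)
    as.character(cl$category)
  }
  # novel offspring allele at copy-neutral depth
  expect_equal(run(0L, 0L, 1L), "DENOVO_SNV")
  # obligate maternal allele lost, copy-neutral: conversion signature
  expect_equal(run(1L, 2L, 0L), "CNIV")
  # mother and offspring at half depth: hemizygous deletion inherited
  expect_equal(run(0L, 2L, 0L, dm = half, do = half), "HDIV")
  expect_equal(run(2L, 0L, 2L, df = half, do = half), "HDIV")
  # offspring alone at half depth: de novo CNV
  expect_equal(run(0L, 2L, 0L, do = half), "DENOVO_CNV")
  # inconsistent flag combination is surfaced, not dropped
  expect_equal(run(1L, 2L, 0L, df = half, dm = half), "UNCLASSIFIED")
  expect_equal(run(1L, 2L, 0L, df = half), "UNCLASSIFIED")
})

test_that("classification records ratios and half flags", {
  flat <- list(chr1 = rep(150L, 4000))
  half <- list(chr1 = rep(75L, 4000))
  gm <- c(father = 150, mother = 150, offspring = 150)
  mie <- make_site(pos = 2000, gt_f = 0L, gt_m = 2L, gt_o = 0L)
  cl <- classify_mies(mie, list(father = flat, mother = half, offspring = half), gm)
  expect_true(cl$half_mother && cl$half_offspring && !cl$half_father)
  expect_equal(cl$ratio_father_offspring, 0.5)
  expect_equal(cl$ratio_mother_offspring, 1)
})

test_that("half-depth segmentation recovers injected deletions", {
  set.seed(31)
  L <- 2e5
  d <- rpois(L, 150)
  # 35 kb deletion at [100000, 135000)
  d[100001:135000] <- rbinom(35000, d[100001:135000], 0.5)
  segs <- segment_half_depth(list(chr1 = as.integer(d)), genome_mean = 150)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$start - 1e5), 1000)
  expect_lt(abs(segs$end - 135000), 1000)
  # clean track: no segments
  expect_equal(
    nrow(segment_half_depth(list(chr1 = as.integer(rpois(L, 150))), 150)), 0
  )
  # 11 kb offspring-only deletion flagged as a segment
  d2 <- rpois(L, 150)
  d2[50001:61000] <- rbinom(11000, d2[50001:61000], 0.5)
  segs2 <- segment_half_depth(list(chr1 = as.integer(d2)), genome_mean = 150)
  expect_equal(nrow(segs2), 1)
  expect_lt(abs(segs2$start - 50000), 1000)
})

test_that("simulated MIEs never fall inside the repeat mask", {
  cfg <- sim_config(genome_length = 1e6, conversion_events = 20,
    mu_denovo = 1e-6, seed = 17)
  res <- run_trio_pipeline(cfg)
  if (nrow(res$classified) > 0) {
    expect_false(any(in_regions(
      res$classified$chrom, res$classified$pos, res$sim$repeat_mask
    )))
  }
  # exhaustiveness: every MIE got exactly one category
  expect_false(any(is.na(res$classified$category)))
})
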