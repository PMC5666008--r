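test_that("depth bounds: constant depth, outlier clamping, Poisson closed form", {
  b <- compute_depth_bounds(list(x = rep(100, 1000)), premin = 15)
  expect_equal(b$mean, 100)
  expect_equal(b$sd, 0)
  expect_equal(c(b$lower, b$upper), c(100, 100))

  # extreme pileup excluded from the moments by the pre-clamp
  b2 <- compute_depth_bounds(list(x = c(rep(90, 999), 10000)),
    premin = 15, premax = 512)
  expect_equal(b2$mean, 90)
  expect_equal(b2$sd, 0)

  set.seed(1)
  d <- rpois(1e5, 150)
  b3 <- compute_depth_bounds(list(x = d), premin = 15, premax = 512)
  expect_lt(abs(b3$mean - 150) / 150, 0.02)
  expect_lt(abs(b3$sd - sqrt(150)) / sqrt(150), 0.02)
  expect_lt(abs(b3$lower - (150 - 3 * sqrt(150))) / 150, 0.02)

  expect_error(compute_depth_bounds(list(x = rep(5, 10)), premin = 15), "premin")
})

test_that("depth filter removes sites outside any member's own bounds", {
  depths <- list(
    father = list(chr1 = rep(100L, 50)),
    mother = list(chr1 = rep(100L, 50)),
    offspring = list(chr1 = c(rep(100L, 20), 300L, rep(100L, 29)))
  )
  bounds <- tibble::tibble(
    individual = c("father", "mother", "offspring"),
    mean = 100, sd = 10, lower = 70, upper = 130, premin = 15, premax = 512
  )
  removed <- filter_depth(depths, bounds)
  expect_equal(nrow(removed), 1)
  expect_equal(c(removed$start, removed$end), c(20, 21))

  # all at mean: nothing removed
  depths$offspring$chr1 <- rep(100L, 50)
  expect_equal(nrow(filter_depth(depths, bounds)), 0)
})

test_that("depth filter removal fraction matches an inclusion-exclusion oracle", {
  set.seed(42)
  n <- 2e5
  depths <- list(
    father = list(chr1 = rpois(n, 150)),
    mother = list(chr1 = rpois(n, 150)),
    offspring = list(chr1 = rpois(n, 150))
  )
  bounds <- compute_depth_bounds(depths, premin = 15, premax = 512)
  removed <- region_length(filter_depth(depths, bounds))
  # per-member tail probability of Poisson(150) beyond mean +/- 3 sigma,
  # combined across three independent members
  b <- bounds[1, ]
  p1 <- ppois(ceiling(b$lower) - 1, 150) + # P(X < lower)
    ppois(floor(b$upper), 150, lower.tail = FALSE) # P(X > upper)
  p_any <- 1 - (1 - p1)^3
  expect_lt(abs(removed / n - p_any), 3 * sqrt(p_any * (1 - p_any) / n) + 5e-4)
})

test_that("strand-balance filter boundary is inclusive at 10/10", {
  ok <- make_site(rf = 5L, rr = 5L, af = 5L, ar = 5L) # 10 fwd / 10 rev
  expect_equal(nrow(filter_read_balance(ok)), 0)
  bad <- make_site(rf = 4L, rr = 40L, af = 5L, ar = 10L) # 9 forward in all
  rm <- filter_read_balance(bad)
  expect_equal(nrow(rm), 1)
  expect_equal(c(rm$start, rm$end), c(1000, 1001))
})

test_that("indel filter pads symmetrically and merges", {
  one <- filter_indels(tibble::tibble(chrom = "chr1", pos = 1000))
  expect_equal(c(one$start, one$end), c(950, 1051))
  two <- filter_indels(tibble::tibble(chrom = "chr1", pos = c(1000, 1040)))
  expect_equal(nrow(two), 1)
  expect_equal(c(two$start, two$end), c(950, 1091))
  # k isolated indels remove exactly 101k bp
  set.seed(3)
  pos <- seq(1000, by = 500, length.out = 40)
  expect_equal(
    region_length(filter_indels(tibble::tibble(chrom = "chr1", pos = pos))),
    101 * 40
  )
})

test_that("allele/strand-bias filter follows the published rule table", {
  # het carrier A:(18 fwd, 0 rev) vs G:(19 fwd, 22 rev): discarded
  bias <- make_site(gt_o = 1L, rf = 18L, rr = 0L, af = 19L, ar = 22L)
  rm <- filter_allele_strand_bias(bias)
  expect_equal(nrow(rm), 1)
  expect_equal(c(rm$start, rm$end), c(990, 1011))
  # het carrier A:(20,12) / G:(15,18): retained
  good <- make_site(gt_o = 1L, rf = 20L, rr = 12L, af = 15L, ar = 18L)
  expect_equal(nrow(filter_allele_strand_bias(good)), 0)
  # hom-alt carrier evaluated on AF/AR only
  homalt <- make_site(gt_f = 2L, gt_m = 2L, gt_o = 2L,
    rf = 0L, rr = 0L, af = 60L, ar = 70L)
  expect_equal(nrow(filter_allele_strand_bias(homalt)), 0)
  homalt_bad <- make_site(gt_f = 0L, gt_m = 0L, gt_o = 2L,
    rf = 0L, rr = 0L, af = 60L, ar = 0L)
  expect_equal(nrow(filter_allele_strand_bias(homalt_bad)), 1)
  # hom-ref sites are never carriers
  homref <- make_site(gt_o = 0L, rf = 80L, rr = 0L, af = 0L, ar = 0L)
  expect_equal(nrow(filter_allele_strand_bias(homref)), 0)
})

test_that("read-end filter threshold is exclusive above 10", {
  near <- make_site(gt_o = 1L, mde = 5)
  rm <- filter_read_ends(near)
  expect_equal(nrow(rm), 1)
  expect_equal(c(rm$start, rm$end), c(990, 1011))
  far <- make_site(gt_o = 1L, mde = 11)
  expect_equal(nrow(filter_read_ends(far)), 0)
})

test_that("target building: identity, mask arithmetic, union accounting", {
  genome <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  none <- build_target_regions(genome)
  expect_equal(region_length(none$target), 1e6)

  mask <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  masked <- build_target_regions(genome, repeat_mask = mask)
  expect_equal(region_length(masked$target), 9e5)

  set.seed(8)
  removals <- list(a = random_regions(1e5, 30, 400),
    b = random_regions(1e5, 30, 400))
  g2 <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  built <- build_target_regions(g2, removals)
  union_bp <- built$report$bp_removed[built$report$filter == "union_removed"]
  expect_equal(region_length(built$target) + union_bp, 1e5)
  # per-filter bp counted per filter (overlaps double-counted by design)
  expect_gte(sum(built$report$bp_removed[built$report$filter %in% c("a", "b")]),
    union_bp)
  expect_error(build_target_regions(genome, list(all = genome)), "empty")
})

test_that("target building is idempotent, order-independent and monotone", {
  set.seed(13)
  genome <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  a <- random_regions(1e5, 20, 300)
  b <- random_regions(1e5, 20, 300)
  t_ab <- build_target_regions(genome, list(a = a, b = b))$target
  t_ba <- build_target_regions(genome, list(b = b, a = a))$target
  expect_equal(t_ab, t_ba)
  # idempotence: filtering the target again with the same removals
  again <- build_target_regions(t_ab, list(a = a, b = b))$target
  expect_equal(again, t_ab)
  # monotonicity: adding a filter never increases T
  t_a <- build_target_regions(genome, list(a = a))$target
  expect_lte(region_length(t_ab), region_length(t_a))
})
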