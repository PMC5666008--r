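test_that("validation verdicts: FP, somatic, germline, untestable", {
  cand <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 300, 400),
    gt_father = 0L, gt_mother = 0L, gt_offspring = 1L
  )
  conf <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 300),
    sanger_father = c(0L, 0L, 1L),
    sanger_mother = 0L,
    sanger_blood = c(1L, 1L, 1L),
    sanger_hair = c(1L, 0L, 1L)
  )
  v <- validate_candidates(cand, conf)
  expect_equal(v$records$verdict,
    c("confirmed_germline", "somatic", "false_positive", "untestable"))
  expect_equal(v$fp_rate, 1 / 3)
  expect_equal(v$n_untestable, 1L)
  # 8 contradictions among 40 testable -> 0.2
  cand40 <- tibble::tibble(chrom = "chr1", pos = 1:40,
    gt_father = 0L, gt_mother = 0L, gt_offspring = 1L)
  conf40 <- tibble::tibble(chrom = "chr1", pos = 1:40,
    sanger_father = 0L, sanger_mother = 0L,
    sanger_blood = c(rep(0L, 8), rep(1L, 32)), sanger_hair = c(rep(0L, 8), rep(1L, 32)))
  expect_equal(validate_candidates(cand40, conf40)$fp_rate, 0.2)
  # zero contradictions
  conf40$sanger_blood <- 1L
  conf40$sanger_hair <- 1L
  expect_equal(validate_candidates(cand40, conf40)$fp_rate, 0)
  # unknown site in confirmation table -> hard error
  expect_error(
    validate_candidates(cand, dplyr::mutate(conf, pos = pos + 1)),
    "absent"
  )
})

test_that("corrected germline count and range reproduce the published arithmetic", {
  g <- germline_count(45, 0.2, 1, n_untestable = 5)
  expect_equal(c(g$point, g$min, g$max), c(35, 31, 36))
  expect_equal(germline_count(45, 0, 0)$point, 45)
  # fully-testable subset: 40 candidates at the exact 8/40 rate
  g2 <- germline_count(40, 8 / 40, 1)
  expect_equal(g2$point, 31)
  expect_error(germline_count(2, 1, 2), "exceed")
})

test_that("rate arithmetic: per-generation, per-year, exclusions", {
  mu_g <- per_generation_rate(35, 1.182e9)
  expect_equal(signif(mu_g, 3), 1.48e-8)
  expect_equal(signif(per_generation_rate(31, 1.182e9), 3), 1.31e-8)
  expect_equal(signif(per_generation_rate(36, 1.182e9), 3), 1.52e-8)
  expect_equal(per_generation_rate(0, 1e9), 0)
  expect_equal(signif(per_year_rate(mu_g, 24), 2), 6.2e-10)
  expect_equal(per_year_rate(1e-8, 1), 1e-8)
  expect_equal(signif(per_year_rate(1.2e-8, 20), 2), 6.0e-10)
  # false negatives inflate the rate by 1/(1 - FN)
  expect_equal(per_generation_rate(35, 1.182e9, fn_rate = 0.5), 2 * mu_g)
  expect_equal(signif(alternative_rate_with_exclusions(45, 2, 9, 1.170e9), 3),
    1.45e-8)
  expect_equal(
    alternative_rate_with_exclusions(45, 0, 9, 1.182e9),
    per_generation_rate(45 - 9, 1.182e9)
  )
  expect_error(alternative_rate_with_exclusions(45, 45, 9, 1.170e9))
})

test_that("phylogenetic rate handles ancestral polymorphism and is monotone", {
  p1 <- phylogenetic_rate(d = 0.012, t = 6e6, g = 20, ne = 1e4)
  expect_equal(signif(p1$mu_per_generation, 3), 1.88e-8)
  expect_equal(signif(p1$mu_per_year, 2), 9.4e-10)
  p2 <- phylogenetic_rate(d = 0.012, t = 6e6, g = 20, ne = 1e5)
  expect_equal(signif(p2$mu_per_generation, 3), 1.20e-8)
  expect_equal(signif(p2$mu_per_year, 2), 6.0e-10)
  # Ne = 0 limit: d / (2t)
  p0 <- phylogenetic_rate(d = 0.012, t = 6e6, g = 20, ne = 0)
  expect_equal(p0$mu_per_year, 0.012 / (2 * 6e6))
  # monotone decreasing in Ne, t, g
  expect_gt(p1$mu_per_generation, p2$mu_per_generation)
  expect_gt(p1$mu_per_year,
    phylogenetic_rate(0.012, 8e6, 20, 1e4)$mu_per_year)
  expect_gt(p1$mu_per_generation / 20,
    phylogenetic_rate(0.012, 6e6, 30, 1e4)$mu_per_generation / 30)
})

test_that("CpG fraction matches a direct positional scan", {
  ref <- list(chr1 = "AACGTTACGA")
  # CpG dinucleotide at 0-based [2,3]; positions 2 and 3 are CpG; 7 and 8 too
  res <- cpg_fraction(tibble::tibble(chrom = "chr1", pos = c(2, 3, 7, 8, 0, 5)), ref)
  expect_equal(res$n_cpg, 4L)
  expect_equal(res$fraction, 4 / 6)
  # all-AT reference: fraction 0
  expect_equal(
    cpg_fraction(tibble::tibble(chrom = "chr1", pos = 0:5),
      list(chr1 = "ATATATAT"))$fraction, 0
  )
  # brute-force scan on a generated reference
  set.seed(2)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  pos <- sample(0:499, 100)
  scan <- vapply(pos, function(p) {
    s <- substring(seq, p, p + 2) # 1-based window around 0-based p
    substr(s, 2, 3) == "CG" || substr(s, 1, 2) == "CG"
  }, logical(1))
  got <- cpg_fraction(tibble::tibble(chrom = "chr1", pos = pos),
    list(chr1 = seq))
  expect_equal(got$n_cpg, sum(scan))
  expect_warning(
    cpg_fraction(tibble::tibble(chrom = "chrX", pos = 1), list(chr1 = "ACGT")),
    "without reference"
  )
})

test_that("estimate_rate assembles counts and exposes tidy/glance", {
  est <- estimate_rate(45, 0.2, 1, 1.182e9, 24, n_untestable = 5)
  expect_s3_class(est, "rate_estimate")
  expect_equal(est$n_germline, 35)
  expect_equal(signif(est$mu_per_generation, 3), 1.48e-8)
  expect_equal(signif(est$mu_per_year, 2), 6.2e-10)
  td <- tidy(est)
  expect_equal(td$estimate[td$term == "n_germline"], 35)
  expect_equal(td$low[td$term == "mu_per_generation"],
    per_generation_rate(31, 1.182e9))
  gl <- glance(est)
  expect_equal(gl$n_fp, 9)
  expect_equal(gl$parental_age, 24)
  # phylo tidiers
  tp <- tidy(phylogenetic_rate(0.012, 6e6, 20, 1e4))
  expect_equal(nrow(tp), 2)
})
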