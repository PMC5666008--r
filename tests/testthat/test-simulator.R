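quiet_cfg <- function(...) {
  sim_config(
    mu_denovo = 0, n_somatic = 0, conversion_events = 0,
    hemizygous_deletions = data.frame(parent = character(), length = double()),
    denovo_deletions = double(), repeat_fraction = 0, ...
  )
}

test_that("config invariants are enforced", {
  expect_error(sim_config(snv_density = 0.0005, heterozygosity = 0.001),
    "heterozygosity")
  expect_error(sim_config(coverage_father = 0), "coverage")
  expect_error(sim_config(genome_length = 1e4, denovo_deletions = 5000), "10x")
  expect_error(sim_config(hemizygous_deletions =
    data.frame(parent = "uncle", length = 100)))
})

test_that("with all event rates zero the offspring is Mendelian everywhere", {
  sim <- simulate_trio(quiet_cfg(genome_length = 2e5, seed = 5))
  tg <- true_genotypes(sim)
  expect_true(all(mendelian_consistent(
    tg$gt_father, tg$gt_mother, tg$gt_offspring
  )))
  expect_equal(nrow(true_mies(sim)), 0)
})

test_that("germline de novo counts are Poisson with mean 2*mu*L", {
  mu <- 1e-6
  L <- 1e6
  counts <- vapply(1:10, function(s) {
    sim2 <- simulate_trio(sim_config(
      genome_length = L, mu_denovo = mu, n_somatic = 0,
      conversion_events = 0, denovo_deletions = double(),
      hemizygous_deletions = data.frame(parent = character(), length = double()),
      repeat_fraction = 0, seed = s
    ))
    nrow(sim2$truth$denovo_snvs)
  }, numeric(1))
  lambda <- 10 * 2 * mu * L # pooled over seeds
  expect_gte(sum(counts), qpois(0.005, lambda))
  expect_lte(sum(counts), qpois(0.995, lambda))
  # origin recorded for every event
  sim <- simulate_trio(sim_config(genome_length = L, mu_denovo = mu, seed = 1))
  expect_true(all(sim$truth$denovo_snvs$origin %in% c("father", "mother")))
})

test_that("parental variant density and Ti/Tv match their targets", {
  sim <- simulate_trio(quiet_cfg(genome_length = 1e7, seed = 2))
  s <- sim$sites
  n_var_father <- sum(s$f1 + s$f2 > 0)
  expect_gt(n_var_father, 11800 * 0.95)
  expect_lt(n_var_father, 11800 * 1.05)
  is_ti <- paste0(s$ref, s$alt) %in% c("AG", "GA", "CT", "TC")
  carrier <- s$f1 + s$f2 > 0
  titv <- sum(is_ti & carrier) / sum(!is_ti & carrier)
  expect_lt(abs(titv - 1.98), 0.05)
  # heterozygosity among father's variants
  het_frac <- mean((s$f1 + s$f2)[carrier] == 1)
  expect_lt(abs(het_frac - 0.00076 / 0.00118), 0.03)
})

test_that("depth conservation holds at every simulated site", {
  sim <- simulate_trio(small_cfg(2e5, seed = 3))
  obs <- simulate_observations(sim)
  s <- obs$site_obs
  for (ind in c("father", "mother", "offspring")) {
    expect_equal(
      s[[paste0("rf_", ind)]] + s[[paste0("rr_", ind)]] +
        s[[paste0("af_", ind)]] + s[[paste0("ar_", ind)]],
      s[[paste0("dp_", ind)]]
    )
  }
})

test_that("hemizygous intervals halve the depth and Poisson moments hold", {
  cfg <- sim_config(
    genome_length = 2e5, coverage_mother = 150, depth_dispersion = Inf,
    hemizygous_deletions = data.frame(parent = "mother", length = 20000),
    denovo_deletions = double(), conversion_events = 0, mu_denovo = 0,
    n_somatic = 0, repeat_fraction = 0, seed = 9
  )
  sim <- simulate_trio(cfg)
  obs <- simulate_observations(sim)
  del <- sim$truth$hemizygous_deletions
  d <- obs$depth$mother$chr1
  in_del <- (del$start[1] + 1):del$end[1]
  expect_lt(abs(mean(d[in_del]) - 75), 75 * 0.05)
  out_del <- setdiff(seq_along(d), in_del)
  expect_lt(abs(mean(d[out_del]) - 150), 150 * 0.02)
  # Poisson: variance ~ mean outside deletions
  expect_lt(abs(var(d[out_del]) / mean(d[out_del]) - 1), 0.05)
  # offspring inherited the deletion
  expect_lt(abs(mean(obs$depth$offspring$chr1[in_del]) - 75), 75 * 0.05)
})

test_that("base_error = 0 gives zero alternate reads at hom-ref sites", {
  cfg <- sim_config(genome_length = 1e5, base_error = 0, seed = 4,
    mu_denovo = 0, n_somatic = 0, conversion_events = 0,
    hemizygous_deletions = data.frame(parent = character(), length = double()),
    denovo_deletions = double(), repeat_fraction = 0)
  sim <- simulate_trio(cfg)
  obs <- simulate_observations(sim)
  s <- obs$site_obs
  homref <- sim$sites$f1 + sim$sites$f2 == 0
  expect_true(all(s$af_father[homref] + s$ar_father[homref] == 0))
})

test_that("genotype caller matches direct likelihood evaluation", {
  e <- 0.001
  res <- call_genotypes(
    data.frame(dp = c(100L, 30L, 4L, 0L), alt = c(0L, 15L, 1L, 0L)),
    base_error = e
  )
  # brute-force likelihood oracle
  oracle <- function(dp, alt) {
    ll <- dbinom(alt, dp, c(e, 0.5, 1 - e), log = TRUE)
    o <- order(ll, decreasing = TRUE)
    list(gt = o[1] - 1L, qual = 10 * (ll[o[1]] - ll[o[2]]) / log(10))
  }
  o1 <- oracle(100, 0)
  expect_equal(res$gt[1], 0L)
  expect_equal(res$qual[1], o1$qual)
  expect_gt(res$qual[1], 100)
  expect_false(res$filtered[1])
  o2 <- oracle(30, 15)
  expect_equal(res$gt[2], 1L)
  expect_equal(res$qual[2], o2$qual)
  o3 <- oracle(4, 1)
  expect_equal(res$gt[3], o3$gt)
  expect_true(res$filtered[3]) # gap far below threshold
  expect_true(is.na(res$gt[4])) # zero depth: missing, not filtered
})

test_that("binomial thinning scales depth and is self-consistent", {
  sim <- simulate_trio(small_cfg(2e5,
    coverage_father = 120, coverage_mother = 120, coverage_offspring = 120,
    seed = 6))
  obs <- simulate_observations(sim)
  expect_identical(subsample_observations(obs, 1), obs)
  q <- subsample_observations(obs, 0.25, seed = 1)
  expect_lt(abs(mean(q$depth$father$chr1) - 30), 1)
  s <- q$site_obs
  expect_equal(
    s$rf_father + s$rr_father + s$af_father + s$ar_father, s$dp_father
  )
  # thinning twice by 0.5 ~ once by 0.25 in distribution
  h2 <- subsample_observations(
    subsample_observations(obs, 0.5, seed = 2), 0.5, seed = 3
  )
  m1 <- mean(q$depth$offspring$chr1)
  m2 <- mean(h2$depth$offspring$chr1)
  expect_lt(abs(m1 - m2), 0.5)
})

test_that("event placement fails loudly when intervals cannot fit", {
  expect_error(
    simulate_trio(sim_config(
      genome_length = 1e5,
      hemizygous_deletions = data.frame(
        parent = rep("father", 30), length = rep(10000, 30)
      ),
      seed = 1
    )),
    "unplaceable"
  )
})
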