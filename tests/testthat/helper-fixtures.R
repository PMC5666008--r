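# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A minimal trio site row with explicit genotypes and counts.
make_site <- function(pos = 1000, gt_f = 0L, gt_m = 0L, gt_o = 1L,
                      chrom = "chr1", ref = "A", alt = "G",
                      dp = 150L, rf = 40L, rr = 40L, af = 35L, ar = 35L,
                      mde = 25) {
  row <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  for (ind in c("father", "mother", "offspring")) {
    row[[paste0("gt_", ind)]] <- c(father = gt_f, mother = gt_m, offspring = gt_o)[[ind]]
    row[[paste0("dp_", ind)]] <- dp
    row[[paste0("rf_", ind)]] <- rf
    row[[paste0("rr_", ind)]] <- rr
    row[[paste0("af_", ind)]] <- af
    row[[paste0("ar_", ind)]] <- ar
    row[[paste0("mde_", ind)]] <- mde
  }
  row
}

# Brute-force Mendelian assortment oracle: enumerate one allele from each
# parent's genotype and compare multisets with the offspring genotype.
assortment_oracle <- function(f, m, o) {
  alleles <- function(g) if (g == 0) c(0, 0) else if (g == 1) c(0, 1) else c(1, 1)
  off <- sort(alleles(o))
  for (a in alleles(f)) {
    for (b in alleles(m)) {
      if (identical(sort(c(a, b)), off)) return(TRUE)
    }
  }
  FALSE
}

# Per-base bitmap oracle for interval algebra on small genomes.
bitmap_of <- function(regions, L) {
  bits <- rep(FALSE, L)
  regions <- region_set(regions)
  for (i in seq_len(nrow(regions))) {
    if (regions$end[i] > regions$start[i]) {
      bits[(regions$start[i] + 1):regions$end[i]] <- TRUE
    }
  }
  bits
}

# A config with study-like rates but events scaled to a small test genome.
small_cfg <- function(genome_length = 1e5, ...) {
  args <- list(...)
  defaults <- list(
    genome_length = genome_length,
    hemizygous_deletions = data.frame(
      parent = c("father", "mother"), length = c(4000, 7000)
    ),
    denovo_deletions = 2000
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

random_regions <- function(L, n, max_len = 50, chrom = "chr1") {
  start <- sample.int(L, n) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = pmin(start + len, L))
}
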