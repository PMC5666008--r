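#' Simulate sequencing observations for a trio
#'
#' Generates per-base depth tracks and strand-resolved allele counts at every
#' variant site for father, mother and offspring (blood tissue). Per-base
#' depth is negative binomial around the configured coverage (Poisson when
#' `depth_dispersion = Inf`) and is halved inside an individual's hemizygous
#' intervals by binomial thinning. At each variant site the depth is read off
#' the track at that base, alternate-allele reads are binomial in the
#' individual's true allele dosage with `base_error` miscalls, and reads
#' split evenly between forward and reverse strands, giving the four counts
#' RF, RR, AF, AR with `RF + RR + AF + AR = DP` by construction.
#'
#' @param sim A `trio_sim` from [simulate_trio()].
#' @param seed Optional override of the observation-stage seed.
#' @return A list of class `trio_obs`: `depth` (per individual, per
#'   chromosome integer vectors), `site_obs` (wide tibble with per-individual
#'   `dp_*`, `rf_*`, `rr_*`, `af_*`, `ar_*` and mean distance-to-read-end
#'   `mde_*` columns), and `config`.
#' @examples
#' sim <- simulate_trio(sim_config(genome_length = 1e5, seed = 2))
#' obs <- simulate_observations(sim)
#' head(obs$site_obs)
#' @export
simulate_observations <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "trio_sim"))
  cfg <- sim$config
  set.seed(seed %||% derive_seed(cfg$seed, "observations"))
  L <- cfg$genome_length
  chroms <- sim$genome$chrom
  cov <- c(
    father = cfg$coverage_father, mother = cfg$coverage_mother,
    offspring = cfg$coverage_offspring
  )
  dels <- list(
    father = sim$deletions$father, mother = sim$deletions$mother,
    offspring = sim$deletions$offspring
  )

  depth <- purrr::map(names(cov), function(ind) {
    stats::setNames(lapply(chroms, function(ch) {
      d <- if (is.finite(cfg$depth_dispersion)) {
        stats::rnbinom(L, size = cfg$depth_dispersion, mu = cov[[ind]])
      } else {
        stats::rpois(L, cov[[ind]])
      }
      dv <- dels[[ind]]
      dv <- dv[dv$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(dv))) {
        idx <- (dv$start[i] + 1):dv$end[i]
        d[idx] <- stats::rbinom(length(idx), d[idx], 0.5)
      }
      as.integer(d)
    }), chroms)
  })
  names(depth) <- names(cov)

  s <- sim$sites
  frac <- site_allele_fractions(sim)
  site_obs <- tibble::tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt)
  for (ind in names(cov)) {
    dp <- depth_at(depth[[ind]], s$chrom, s$pos)
    counts <- draw_strand_counts(dp, frac[[ind]], cfg$base_error)
    site_obs[[paste0("dp_", ind)]] <- dp
    site_obs[[paste0("rf_", ind)]] <- counts$rf
    site_obs[[paste0("rr_", ind)]] <- counts$rr
    site_obs[[paste0("af_", ind)]] <- counts$af
    site_obs[[paste0("ar_", ind)]] <- counts$ar
    site_obs[[paste0("mde_", ind)]] <- mean_dist_to_end(dp, cfg$read_length)
  }

  out <- list(config = cfg, depth = depth, site_obs = site_obs)
  class(out) <- "trio_obs"
  out
}

# Alternate-allele fraction of each individual's observable copies.
site_allele_fractions <- function(sim) {
  gt <- true_genotypes(sim, tissue = "blood")
  list(
    father = gt$gt_father / 2,
    mother = gt$gt_mother / 2,
    offspring = gt$gt_offspring / 2
  )
}

depth_at <- function(depth_ind, chrom, pos) {
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- depth_ind[[ch]][pos[sel] + 1]
  }
  out
}

draw_strand_counts <- function(dp, f_alt, base_error) {
  p_alt <- f_alt * (1 - base_error) + (1 - f_alt) * base_error
  alt <- stats::rbinom(length(dp), dp, p_alt)
  ref <- dp - alt
  af <- stats::rbinom(length(dp), alt, 0.5)
  rf <- stats::rbinom(length(dp), ref, 0.5)
  list(rf = rf, rr = ref - rf, af = af, ar = alt - af)
}

# Mean distance of covering reads to their nearer read end. Distances are
# ~Uniform(0, read_length/2); the mean over dp reads is taken from its
# normal approximation and clamped to the support.
mean_dist_to_end <- function(dp, read_length) {
  half <- read_length / 2
  m <- half / 2 + stats::rnorm(length(dp)) * sqrt(half^2 / 12 / pmax(dp, 1))
  m <- pmin(pmax(m, 0), half)
  m[dp == 0] <- NA_real_
  m
}

#' Genotype calling from allele counts
#'
#' Calls genotypes at biallelic sites from depth and alternate-read counts
#' with a three-component binomial likelihood (hom-ref with error rate `e`,
#' het at 1/2, hom-alt at `1 - e`). The quality score is the phred-scaled gap
#' between the best and second-best genotype likelihood; calls whose gap
#' falls below the genotype-appropriate threshold (default 200 for
#' heterozygous, 100 for homozygous calls) are flagged `filtered`.
#' Zero-depth sites get a missing (`NA`) genotype, distinct from filtered.
#'
#' @param tbl Data frame with columns `dp` (depth) and `alt` (alternate-read
#'   count).
#' @param base_error Per-read error probability used in the likelihood.
#' @param het_pl_threshold,hom_pl_threshold Minimum phred gap for het / hom
#'   calls.
#' @return `tbl` with columns `gt` (0/1/2 alternate copies, `NA` if no
#'   depth), `qual` (phred gap) and `filtered` (logical).
#' @examples
#' call_genotypes(data.frame(dp = c(100, 30, 4), alt = c(0, 15, 1)))
#' @export
call_genotypes <- function(tbl, base_error = 0.001,
                           het_pl_threshold = 200, hom_pl_threshold = 100) {
  stopifnot(all(c("dp", "alt") %in% names(tbl)),
    het_pl_threshold >= 0, hom_pl_threshold >= 0)
  tbl <- tibble::as_tibble(tbl)
  p <- c(base_error, 0.5, 1 - base_error)
  ll <- vapply(p, function(pp) {
    stats::dbinom(tbl$alt, tbl$dp, pp, log = TRUE)
  }, numeric(nrow(tbl)))
  ll <- matrix(ll, ncol = 3)
  best <- max.col(ll, ties.method = "first")
  ll_sorted_gap <- apply(ll, 1, function(r) {
    o <- sort(r, decreasing = TRUE)
    o[1] - o[2]
  })
  qual <- 10 * ll_sorted_gap / log(10)
  gt <- as.integer(best - 1L)
  thr <- ifelse(gt == 1L, het_pl_threshold, hom_pl_threshold)
  filtered <- qual < thr
  gt[tbl$dp == 0] <- NA_integer_
  qual[tbl$dp == 0] <- NA_real_
  filtered[tbl$dp == 0] <- NA
  tbl$gt <- gt
  tbl$qual <- qual
  tbl$filtered <- filtered
  tbl
}

#' Assemble the trio site table with genotype calls
#'
#' Runs [call_genotypes()] on each individual's counts and returns the wide
#' per-site table used by the filtering and MIE stages.
#'
#' @param obs A `trio_obs`.
#' @inheritParams call_genotypes
#' @return The `site_obs` tibble with added `gt_*`, `qual_*`, `filtered_*`
#'   columns per individual.
#' @export
trio_sites <- function(obs, base_error = NULL,
                       het_pl_threshold = 200, hom_pl_threshold = 100) {
  stopifnot(inherits(obs, "trio_obs"))
  base_error <- base_error %||% obs$config$base_error
  s <- obs$site_obs
  for (ind in c("father", "mother", "offspring")) {
    calls <- call_genotypes(
      tibble::tibble(
        dp = s[[paste0("dp_", ind)]],
        alt = s[[paste0("af_", ind)]] + s[[paste0("ar_", ind)]]
      ),
      base_error = base_error,
      het_pl_threshold = het_pl_threshold,
      hom_pl_threshold = hom_pl_threshold
    )
    s[[paste0("gt_", ind)]] <- calls$gt
    s[[paste0("qual_", ind)]] <- calls$qual
    s[[paste0("filtered_", ind)]] <- calls$filtered
  }
  s
}

#' Binomial thinning of observations to a lower coverage
#'
#' Retains each read independently with probability `fraction`, both in the
#' per-base depth tracks and in the four strand-resolved counts at every
#' site, preserving the depth-conservation invariant. `fraction = 1` returns
#' the observations unchanged.
#'
#' @param obs A `trio_obs`.
#' @param fraction Retention probability in (0, 1].
#' @param seed Seed for the thinning draws.
#' @return A thinned `trio_obs`.
#' @export
subsample_observations <- function(obs, fraction, seed = 1L) {
  stopifnot(inherits(obs, "trio_obs"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(obs)
  set.seed(seed)
  obs$depth <- purrr::map(obs$depth, function(per_chrom) {
    purrr::map(per_chrom, function(d) {
      as.integer(stats::rbinom(length(d), d, fraction))
    })
  })
  s <- obs$site_obs
  for (ind in c("father", "mother", "offspring")) {
    for (f in c("rf", "rr", "af", "ar")) {
      col <- paste0(f, "_", ind)
      s[[col]] <- stats::rbinom(nrow(s), s[[col]], fraction)
    }
    s[[paste0("dp_", ind)]] <- s[[paste0("rf_", ind)]] + s[[paste0("rr_", ind)]] +
      s[[paste0("af_", ind)]] + s[[paste0("ar_", ind)]]
  }
  obs$site_obs <- s
  obs
}

#' Windowed depth track
#'
#' Averages an individual's per-base depth into fixed windows, as a
#' 0-based half-open 4-column table suitable for TSV export.
#'
#' @param obs A `trio_obs`.
#' @param individual `"father"`, `"mother"` or `"offspring"`.
#' @param bin_bp Window size in bp.
#' @return Tibble: chrom, start, end, depth (mean per-base depth in window).
#' @export
depth_track <- function(obs, individual, bin_bp = 1000) {
  stopifnot(inherits(obs, "trio_obs"))
  per_chrom <- obs$depth[[individual]]
  purrr::map_dfr(names(per_chrom), function(ch) {
    d <- per_chrom[[ch]]
    n <- length(d)
    starts <- seq(0, n - 1, by = bin_bp)
    ends <- pmin(starts + bin_bp, n)
    idx <- findInterval(seq_len(n) - 1, starts)
    means <- as.numeric(tapply(d, idx, mean))
    tibble::tibble(chrom = ch, start = starts, end = ends, depth = means)
  })
}

#' Simulate read-pair fragments for parental-origin phasing
#'
#' For each query position, draws paired-end fragments from one of the
#' offspring's two haplotypes (chosen at random) that physically cover the
#' position, and records the alleles the fragment's two reads would observe
#' at offspring variant sites, with `base_error` miscalls.
#'
#' @param sim A `trio_sim`.
#' @param positions Tibble with `chrom`, `pos` (0-based) query positions,
#'   typically de novo SNV candidates.
#' @param n_per_site Fragments drawn per query position (default matches
#'   the physical fragment coverage of a deeply sequenced site).
#' @param seed Seed for fragment placement.
#' @return Tibble: fragment_id, chrom, start, end, hap ("pat"/"mat"), and a
#'   list-column `alleles` of tibbles (pos, allele) for covered variant sites.
#' @export
simulate_fragments <- function(sim, positions, n_per_site = 75, seed = NULL) {
  stopifnot(inherits(sim, "trio_sim"))
  cfg <- sim$config
  set.seed(seed %||% derive_seed(cfg$seed, "fragments"))
  rl <- cfg$read_length
  s <- sim$sites
  rows <- purrr::pmap_dfr(
    list(positions$chrom, positions$pos), function(ch, p) {
      ins <- sample(cfg$insert_sizes, n_per_site, replace = TRUE)
      start <- floor(stats::runif(n_per_site, pmax(0, p - ins + 1), p + 1))
      tibble::tibble(
        chrom = ch, start = start, end = start + ins,
        hap = sample(c("pat", "mat"), n_per_site, replace = TRUE)
      )
    }
  )
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      fragment_id = integer(), chrom = character(), start = double(),
      end = double(), hap = character(), alleles = list()
    ))
  }
  rows$fragment_id <- seq_len(nrow(rows))
  rows$alleles <- purrr::pmap(
    list(rows$chrom, rows$start, rows$end, rows$hap),
    function(ch, st, en, hap) {
      # paired-end: only the two read windows observe bases
      covered <- s$chrom == ch &
        ((s$pos >= st & s$pos < st + rl) | (s$pos >= en - rl & s$pos < en))
      if (!any(covered)) return(tibble::tibble(pos = double(), allele = integer()))
      al <- if (hap == "pat") s$pat[covered] else s$mat[covered]
      flip <- stats::runif(length(al)) < cfg$base_error
      al[flip] <- 1L - al[flip]
      tibble::tibble(pos = s$pos[covered], allele = as.integer(al))
    }
  )
  rows[, c("fragment_id", "chrom", "start", "end", "hap", "alleles")]
}
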