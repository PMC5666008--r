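#' Simulate a trio of diploid genomes with ground truth
#'
#' Draws two diploid parents from a shared population variant pool, forms the
#' offspring by Mendelian transmission (one haplotype per parent per
#' chromosome), and injects the event classes the downstream analysis is
#' built to recover: germline de novo SNVs (Poisson per haploid
#' transmission), blood-only somatic SNVs, allelic-conversion tracts
#' (one offspring haplotype overwritten by its homolog), inherited hemizygous
#' deletions (carried by a parent on the transmitted haplotype), and de novo
#' deletions in the offspring only. All injected intervals are mutually
#' non-overlapping; placement is retried a bounded number of times before
#' failing.
#'
#' The returned object carries the full site table (per-haplotype alleles for
#' every individual), the per-individual deletion intervals, a simulated
#' repeat mask, and a `truth` list recording every injected event with its
#' parental origin.
#'
#' @param config A [sim_config()].
#' @return A list of class `trio_sim` with elements `config`, `sites`
#'   (tibble: chrom, pos, ref, alt, f1, f2, m1, m2, pat, mat, somatic),
#'   `deletions` (per-individual region tibbles), `repeat_mask`,
#'   `genome` (whole-genome region set), `truth`, and optionally `reference`
#'   (per-chromosome base strings).
#' @examples
#' sim <- simulate_trio(sim_config(genome_length = 2e5, seed = 3))
#' nrow(sim$sites)
#' sim$truth$denovo_snvs
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$genome_length
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

  set.seed(derive_seed(cfg$seed, "parents"))
  d_pop <- cfg$snv_density * cfg$pop_density_factor
  q_carrier <- 1 / cfg$pop_density_factor
  p_het <- cfg$heterozygosity / cfg$snv_density

  sites <- purrr::map_dfr(chroms, function(ch) {
    n_pop <- stats::rbinom(1, L, d_pop)
    pos <- sort(sample.int(L, n_pop)) - 1
    tibble::tibble(chrom = ch, pos = pos)
  })
  n <- nrow(sites)

  # ref/alt alleles with the configured Ti/Tv and GC-weighted ref base
  alleles <- draw_ref_alt(n, cfg$titv_ratio, cfg$gc_content)
  sites$ref <- alleles$ref
  sites$alt <- alleles$alt

  draw_parent <- function(n) {
    variant <- stats::runif(n) < q_carrier
    het <- variant & stats::runif(n) < p_het
    hom <- variant & !het
    h1 <- integer(n)
    h2 <- integer(n)
    h1[hom] <- 1L
    h2[hom] <- 1L
    flip <- stats::runif(n) < 0.5
    h1[het & flip] <- 1L
    h2[het & !flip] <- 1L
    list(h1 = h1, h2 = h2)
  }
  fa <- draw_parent(n)
  mo <- draw_parent(n)
  sites$f1 <- fa$h1
  sites$f2 <- fa$h2
  sites$m1 <- mo$h1
  sites$m2 <- mo$h2

  # Mendelian transmission: one haplotype per parent per chromosome.
  set.seed(derive_seed(cfg$seed, "transmission"))
  t_f <- sample(1:2, cfg$n_chromosomes, replace = TRUE)
  t_m <- sample(1:2, cfg$n_chromosomes, replace = TRUE)
  names(t_f) <- names(t_m) <- chroms
  ci <- match(sites$chrom, chroms)
  sites$pat <- ifelse(t_f[ci] == 1, sites$f1, sites$f2)
  sites$mat <- ifelse(t_m[ci] == 1, sites$m1, sites$m2)
  sites$somatic <- FALSE

  # Place all event intervals without mutual overlap.
  set.seed(derive_seed(cfg$seed, "events"))
  placer <- interval_placer(chroms, L)
  tract_len <- pmax(1, round(stats::rexp(cfg$conversion_events,
    rate = 1 / cfg$conversion_tract_mean_bp
  )))
  tracts <- placer$place(tract_len, "conversion tract")
  tracts$donor <- sample(c("pat", "mat"), nrow(tracts), replace = TRUE)

  hemi <- cfg$hemizygous_deletions
  hemi_iv <- placer$place(hemi$length, "hemizygous deletion")
  hemi_iv$parent <- hemi$parent

  dn_iv <- placer$place(cfg$denovo_deletions, "de novo deletion")
  dn_iv$hap <- sample(c("pat", "mat"), nrow(dn_iv), replace = TRUE)

  # Allelic conversion: within each tract, the donor haplotype overwrites
  # the other one, producing loss of heterozygosity in the offspring.
  for (i in seq_len(nrow(tracts))) {
    in_tract <- sites$chrom == tracts$chrom[i] &
      sites$pos >= tracts$start[i] & sites$pos < tracts$end[i]
    if (tracts$donor[i] == "pat") {
      sites$mat[in_tract] <- sites$pat[in_tract]
    } else {
      sites$pat[in_tract] <- sites$mat[in_tract]
    }
  }

  # Germline de novo SNVs: fresh positions, Poisson per haploid transmission.
  set.seed(derive_seed(cfg$seed, "denovo"))
  dn <- purrr::map_dfr(c("father", "mother"), function(origin) {
    k <- stats::rpois(1, cfg$mu_denovo * L * cfg$n_chromosomes)
    if (k == 0) {
      return(tibble::tibble(
        chrom = character(), pos = double(), origin = character()
      ))
    }
    tibble::tibble(
      chrom = sample(chroms, k, replace = TRUE),
      pos = floor(stats::runif(k, 0, L)),
      origin = origin
    )
  })
  dn <- fresh_positions(dn, sites, rbind(hemi_iv[, 1:3], dn_iv[, 1:3]), L)
  som <- tibble::tibble(
    chrom = sample(chroms, cfg$n_somatic, replace = TRUE),
    pos = floor(stats::runif(cfg$n_somatic, 0, L))
  )
  som <- fresh_positions(som, dplyr::bind_rows(sites[, 1:2], dn[, 1:2]),
    rbind(hemi_iv[, 1:3], dn_iv[, 1:3]), L)

  new_rows <- function(df, pat, mat, somatic) {
    if (nrow(df) == 0) return(NULL)
    al <- draw_ref_alt(nrow(df), cfg$titv_ratio, cfg$gc_content)
    tibble::tibble(
      chrom = df$chrom, pos = df$pos, ref = al$ref, alt = al$alt,
      f1 = 0L, f2 = 0L, m1 = 0L, m2 = 0L,
      pat = pat, mat = mat, somatic = somatic
    )
  }
  dn_rows <- NULL
  if (nrow(dn) > 0) {
    dn_rows <- new_rows(dn, pat = as.integer(dn$origin == "father"),
      mat = as.integer(dn$origin == "mother"), somatic = FALSE)
    dn$ref <- dn_rows$ref
    dn$alt <- dn_rows$alt
  }
  som_rows <- new_rows(som, pat = 0L, mat = 0L, somatic = TRUE)
  sites <- dplyr::arrange(
    dplyr::bind_rows(sites, dn_rows, som_rows),
    .data$chrom, .data$pos
  )

  # Per-individual hemizygous intervals. The deleted haplotype is the
  # transmitted one, so parent and offspring share the one-copy state.
  del_father <- region_set(hemi_iv[hemi_iv$parent == "father", 1:3])
  del_mother <- region_set(hemi_iv[hemi_iv$parent == "mother", 1:3])
  off_hemi <- hemi_iv[, c("chrom", "start", "end")]
  off_hemi$hap <- as.character(ifelse(hemi_iv$parent == "father", "pat", "mat"))
  off_del <- dplyr::bind_rows(off_hemi, dn_iv[, c("chrom", "start", "end", "hap")])

  # Repeat mask: random intervals covering repeat_fraction of the genome.
  set.seed(derive_seed(cfg$seed, "repeats"))
  mask <- simulate_repeat_mask(chroms, L, cfg$repeat_fraction)

  reference <- NULL
  if (cfg$reference) {
    set.seed(derive_seed(cfg$seed, "reference"))
    reference <- stats::setNames(lapply(chroms, function(ch) {
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
        prob = c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
          cfg$gc_content / 2, (1 - cfg$gc_content) / 2))
      idx <- sites$pos[sites$chrom == ch] + 1
      base[idx] <- sites$ref[sites$chrom == ch]
      paste(base, collapse = "")
    }), chroms)
  }

  out <- list(
    config = cfg,
    sites = sites,
    transmitted = list(father = t_f, mother = t_m),
    deletions = list(
      father = del_father,
      mother = del_mother,
      offspring = region_set(off_del[, 1:3]),
      offspring_hap = tibble::as_tibble(off_del)
    ),
    repeat_mask = mask,
    genome = tibble::tibble(chrom = chroms, start = 0, end = L),
    reference = reference,
    truth = list(
      denovo_snvs = tibble::as_tibble(dn),
      somatic_snvs = tibble::as_tibble(som),
      conversion_tracts = tibble::as_tibble(tracts),
      hemizygous_deletions = tibble::as_tibble(hemi_iv),
      denovo_deletions = tibble::as_tibble(dn_iv)
    )
  )
  class(out) <- "trio_sim"
  out
}

# ref base GC-weighted; alt is a transition with probability titv/(titv+1),
# otherwise a uniform transversion.
draw_ref_alt <- function(n, titv, gc) {
  if (n == 0) return(list(ref = character(), alt = character()))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  is_ti <- stats::runif(n) < titv / (titv + 1)
  alt <- character(n)
  alt[is_ti] <- transition[ref[is_ti]]
  if (any(!is_ti)) {
    pick <- stats::runif(sum(!is_ti)) < 0.5
    alt[!is_ti] <- purrr::map2_chr(ref[!is_ti], pick, function(r, p) tv[[r]][1 + p])
  }
  list(ref = ref, alt = alt)
}

# Sequential non-overlapping placement with bounded retries.
interval_placer <- function(chroms, L, max_tries = 100) {
  placed <- tibble::tibble(chrom = character(), start = double(), end = double())
  place <- function(lengths, what) {
    out <- vector("list", length(lengths))
    for (i in seq_along(lengths)) {
      len <- lengths[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(chroms, 1)
        s <- floor(stats::runif(1, 0, L - len))
        cand <- tibble::tibble(chrom = ch, start = s, end = s + len)
        if (region_length(region_intersect(placed, cand)) == 0) {
          placed <<- dplyr::bind_rows(placed, cand)
          out[[i]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("unplaceable ", what, " after ", max_tries, " retries")
    }
    dplyr::bind_rows(out) %||%
      tibble::tibble(chrom = character(), start = double(), end = double())
  }
  list(place = function(lengths, what) {
    if (length(lengths) == 0) {
      return(tibble::tibble(chrom = character(), start = double(), end = double()))
    }
    place(lengths, what)
  })
}

# Resample positions that collide with existing variant sites or intervals.
fresh_positions <- function(df, existing, intervals, L, max_tries = 100) {
  if (nrow(df) == 0) return(df)
  key <- function(d) paste(d$chrom, d$pos)
  for (try in seq_len(max_tries)) {
    bad <- key(df) %in% key(existing) | duplicated(key(df))
    if (nrow(intervals) > 0) {
      bad <- bad | in_regions(df$chrom, df$pos, intervals)
    }
    if (!any(bad)) return(df)
    df$pos[bad] <- floor(stats::runif(sum(bad), 0, L))
  }
  stop("could not place de novo positions off existing sites")
}

simulate_repeat_mask <- function(chroms, L, fraction, mean_len = 500) {
  if (fraction <= 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  purrr::map_dfr(chroms, function(ch) {
    n_iv <- max(1, round(fraction * L / mean_len))
    len <- pmax(50, round(stats::rexp(n_iv, 1 / mean_len)))
    start <- floor(stats::runif(n_iv, 0, L - len))
    region_set(tibble::tibble(chrom = ch, start = start, end = start + len))
  })
}

#' True trio genotypes implied by a simulation
#'
#' Computes, for every variant site, the genotype each individual would show
#' to a perfect assay: the number of alternate alleles among the copies that
#' individual actually carries. Inside a hemizygous interval only the
#' surviving haplotype contributes, so a one-copy individual reports a
#' homozygous genotype for its single allele (as a caller would).
#'
#' @param sim A `trio_sim`.
#' @param tissue `"blood"` (includes somatic variants, as heterozygous) or
#'   `"hair"` (germline only) for the offspring.
#' @return Tibble: chrom, pos, ref, alt, gt_father, gt_mother, gt_offspring
#'   (0/1/2 alternate-allele dosage as observed), plus per-individual copy
#'   number columns cn_father, cn_mother, cn_offspring.
#' @export
true_genotypes <- function(sim, tissue = c("blood", "hair")) {
  tissue <- match.arg(tissue)
  s <- sim$sites
  alleles_of <- function(h1, h2, in_del, surviving) {
    # dosage scaled to a diploid-style call: hemizygous => 0 or 2
    dose <- h1 + h2
    gt <- dose
    gt[in_del] <- 2L * surviving[in_del]
    gt
  }
  in_f <- in_regions(s$chrom, s$pos, sim$deletions$father)
  in_m <- in_regions(s$chrom, s$pos, sim$deletions$mother)
  # father's deleted haplotype is the transmitted one; surviving is the other
  t_f <- sim$transmitted$father[s$chrom]
  t_m <- sim$transmitted$mother[s$chrom]
  surv_f <- ifelse(t_f == 1, s$f2, s$f1)
  surv_m <- ifelse(t_m == 1, s$m2, s$m1)
  gt_f <- alleles_of(s$f1, s$f2, in_f, surv_f)
  gt_m <- alleles_of(s$m1, s$m2, in_m, surv_m)

  oh <- sim$deletions$offspring_hap
  pat_del <- rep(FALSE, nrow(s))
  mat_del <- rep(FALSE, nrow(s))
  if (nrow(oh) > 0) {
    pat_del <- in_regions(s$chrom, s$pos, oh[oh$hap == "pat", 1:3])
    mat_del <- in_regions(s$chrom, s$pos, oh[oh$hap == "mat", 1:3])
  }
  pat <- s$pat
  mat <- s$mat
  if (tissue == "blood" && any(s$somatic)) {
    # somatic variants sit on one haplotype of the blood lineage
    pat[s$somatic] <- 1L
  }
  gt_o <- pat + mat
  gt_o[pat_del] <- 2L * mat[pat_del]
  gt_o[mat_del] <- 2L * pat[mat_del]

  tibble::tibble(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    gt_father = as.integer(gt_f), gt_mother = as.integer(gt_m),
    gt_offspring = as.integer(gt_o),
    cn_father = ifelse(in_f, 1L, 2L),
    cn_mother = ifelse(in_m, 1L, 2L),
    cn_offspring = ifelse(pat_del | mat_del, 1L, 2L)
  )
}
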