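#' Validate de novo candidates against confirmation genotypes
#'
#' Compares the trio's sequencing genotypes at each de novo candidate with
#' independent confirmation genotypes (e.g. Sanger resequencing of blood and
#' hair-follicle DNA). A candidate is a false positive when the confirmation
#' genotypes contradict the de novo call (the offspring's blood lacks the
#' novel allele, or a parent carries it); it is somatic when the call stands
#' in blood but the hair-follicle genotype differs (mesoderm vs ectoderm
#' lineage split); otherwise it is confirmed germline. Candidates without
#' confirmation genotypes are untestable.
#'
#' @param candidates Tibble of de novo candidates with `chrom`, `pos`,
#'   `gt_father`, `gt_mother`, `gt_offspring`.
#' @param confirmation Tibble with `chrom`, `pos`, `sanger_father`,
#'   `sanger_mother`, `sanger_blood`, `sanger_hair` (alternate-allele
#'   counts). Rows must match candidate sites.
#' @return List: `records` (candidates plus `verdict`), `fp_rate`
#'   (false positives / testable), `n_testable`, `n_fp`, `n_somatic`,
#'   `n_untestable`.
#' @export
validate_candidates <- function(candidates, confirmation) {
  candidates <- tibble::as_tibble(candidates)
  confirmation <- tibble::as_tibble(confirmation)
  key_c <- paste(candidates$chrom, candidates$pos)
  key_s <- paste(confirmation$chrom, confirmation$pos)
  if (!all(key_s %in% key_c)) {
    stop("confirmation table references sites absent from the candidates")
  }
  m <- match(key_c, key_s)
  conf <- confirmation[m, ]
  testable <- !is.na(m) & !is.na(conf$sanger_blood) &
    !is.na(conf$sanger_father) & !is.na(conf$sanger_mother)
  still_denovo <- testable & conf$sanger_blood >= 1L &
    conf$sanger_father == 0L & conf$sanger_mother == 0L
  somatic <- still_denovo & !is.na(conf$sanger_hair) &
    conf$sanger_hair != conf$sanger_blood
  verdict <- dplyr::case_when(
    !testable ~ "untestable",
    !still_denovo ~ "false_positive",
    somatic ~ "somatic",
    TRUE ~ "confirmed_germline"
  )
  candidates$verdict <- verdict
  n_test <- sum(testable)
  n_fp <- sum(verdict == "false_positive")
  list(
    records = candidates,
    fp_rate = if (n_test > 0) n_fp / n_test else NA_real_,
    n_testable = n_test,
    n_fp = n_fp,
    n_somatic = sum(verdict == "somatic"),
    n_untestable = sum(verdict == "untestable")
  )
}

#' Corrected germline de novo count with range
#'
#' Point estimate: candidates minus the projected false positives
#' (`round(n * fp_rate)`) minus somatic calls. The range treats the
#' untestable candidates pessimistically (all false positives) and
#' optimistically (all true), with the observed false positives
#' (`round((n - n_untestable) * fp_rate)`) subtracted in both.
#'
#' @param n_candidates Number of de novo candidates.
#' @param fp_rate False-positive rate among testable candidates, in `[0, 1]`.
#' @param n_somatic Somatic calls among the candidates.
#' @param n_untestable Candidates without confirmation genotypes.
#' @return Tibble: point, min, max (germline counts).
#' @examples
#' germline_count(45, 0.2, 1, n_untestable = 5) # point 35, range 31-36
#' @export
germline_count <- function(n_candidates, fp_rate, n_somatic, n_untestable = 0) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, n_untestable <= n_candidates)
  n_fp_point <- round(n_candidates * fp_rate)
  n_fp_obs <- round((n_candidates - n_untestable) * fp_rate)
  point <- n_candidates - n_fp_point - n_somatic
  lo <- n_candidates - n_untestable - n_fp_obs - n_somatic
  hi <- n_candidates - n_fp_obs - n_somatic
  if (point < 0 || lo < 0) stop("corrections exceed the candidate count")
  tibble::tibble(point = point, min = lo, max = hi)
}

#' Per-generation germline mutation rate
#'
#' `mu_g = n_germline / (2 * T)`: de novo SNVs per site per generation over
#' a diploid target of `T` bp.
#'
#' @param n_germline Corrected germline de novo SNV count.
#' @param target_size Target genomic size `T` in bp.
#' @param fn_rate False-negative rate; the rate is divided by `1 - fn_rate`
#'   when nonzero.
#' @return Rate per site per generation.
#' @examples
#' per_generation_rate(35, 1.182e9) # 1.48e-8
#' @export
per_generation_rate <- function(n_germline, target_size, fn_rate = 0) {
  stopifnot(target_size > 0, fn_rate >= 0, fn_rate < 1)
  n_germline / (2 * target_size) / (1 - fn_rate)
}

#' Per-year germline mutation rate
#'
#' Divides the per-generation rate by the mean parental age at conception.
#'
#' @param mu_g Rate per site per generation.
#' @param parental_age Parental age(s) at conception in years; a vector is
#'   averaged.
#' @return Rate per site per year.
#' @examples
#' per_year_rate(per_generation_rate(35, 1.182e9), 24) # ~0.62e-9
#' @export
per_year_rate <- function(mu_g, parental_age) {
  age <- mean(parental_age)
  stopifnot(age > 0)
  mu_g / age
}

#' Phylogenetic mutation rate with ancestral-polymorphism correction
#'
#' Under neutrality the expected pairwise divergence between two species is
#' `d = 2 * mu_y * t + 4 * Ne * g * mu_y`: substitutions accumulated over
#' both lineages since the split at time `t`, plus the expected coalescent
#' depth of the ancestral polymorphism (`2 Ne` generations of `g` years on
#' each lineage). Solving for the yearly rate gives
#' `mu_y = d / (2 t + 4 Ne g)` and `mu_g = mu_y * g`.
#'
#' @param d Pairwise sequence divergence (substitutions per site).
#' @param t Divergence time in years.
#' @param g Generation time in years.
#' @param ne Ancestral effective population size (diploid individuals);
#'   `ne = 0` gives the uncorrected `d / (2 t)` limit.
#' @return A list of class `phylo_rate`: `mu_per_year`, `mu_per_generation`,
#'   and the input parameters.
#' @examples
#' phylogenetic_rate(d = 0.012, t = 6e6, g = 20, ne = 1e4) # 1.88e-8 per gen
#' @export
phylogenetic_rate <- function(d, t, g, ne) {
  stopifnot(d > 0, t > 0, g > 0, ne >= 0)
  mu_y <- d / (2 * t + 4 * ne * g)
  out <- list(
    mu_per_year = mu_y, mu_per_generation = mu_y * g,
    d = d, t = t, g = g, ne = ne
  )
  class(out) <- "phylo_rate"
  out
}

#' @export
print.phylo_rate <- function(x, ...) {
  cat(sprintf(
    "<phylo_rate> d=%g, t=%g yr, g=%g yr, Ne=%g\n  %.3g /site/generation | %.2g /site/year\n",
    x$d, x$t, x$g, x$ne, signif(x$mu_per_generation, 3), signif(x$mu_per_year, 2)
  ))
  invisible(x)
}

#' Fraction of de novo SNVs at CpG sites
#'
#' A site is CpG when its reference dinucleotide context (the site with the
#' next base, or the previous base with the site) reads CG; hypermutability
#' of methylated CpG makes this fraction a standard sanity check on de novo
#' calls.
#'
#' @param positions Tibble with `chrom`, `pos` (0-based).
#' @param reference Named list/character vector of per-chromosome reference
#'   strings.
#' @return Tibble: n_cpg, n_total, fraction (sites lacking context are
#'   excluded with a warning).
#' @export
cpg_fraction <- function(positions, reference) {
  positions <- tibble::as_tibble(positions)
  have <- positions$chrom %in% names(reference)
  if (!all(have)) {
    warning(sum(!have), " site(s) without reference context excluded")
    positions <- positions[have, ]
  }
  is_cpg <- purrr::map2_lgl(positions$chrom, positions$pos, function(ch, p) {
    ref <- reference[[ch]]
    after <- substr(ref, p + 1, p + 2) # 0-based pos and next base
    before <- if (p >= 1) substr(ref, p, p + 1) else ""
    after == "CG" || before == "CG"
  })
  tibble::tibble(
    n_cpg = sum(is_cpg), n_total = nrow(positions),
    fraction = if (nrow(positions) > 0) mean(is_cpg) else NA_real_
  )
}

#' Mutation rate after excluding flagged candidates
#'
#' Recomputes the per-generation rate after removing candidates that fall in
#' regions excluded post hoc (e.g. known segmental duplications), keeping
#' the false-positive count from the primary analysis, over a correspondingly
#' reduced target size.
#'
#' @param n_candidates Original candidate count.
#' @param n_excluded Candidates removed by the exclusion.
#' @param n_fp False-positive count carried over from the primary analysis.
#' @param target_size_adjusted Reduced target size in bp.
#' @return Rate per site per generation.
#' @examples
#' alternative_rate_with_exclusions(45, 2, 9, 1.170e9) # 1.45e-8
#' @export
alternative_rate_with_exclusions <- function(n_candidates, n_excluded, n_fp,
                                             target_size_adjusted) {
  stopifnot(n_excluded <= n_candidates, target_size_adjusted > 0)
  num <- n_candidates - n_excluded - n_fp
  if (num < 0) stop("exclusions and false positives exceed the candidate count")
  num / (2 * target_size_adjusted)
}

#' Full corrected rate estimate for a trio
#'
#' Combines the candidate count, validation outcome, target size and
#' parental age into per-generation and per-year germline mutation rates
#' with a count range from the untestable candidates.
#'
#' @param n_candidates De novo SNV candidates inside the target regions.
#' @param fp_rate False-positive rate from validation.
#' @param n_somatic Somatic calls among the candidates.
#' @param target_size Target genomic size `T` in bp.
#' @param parental_age Parental age(s) at conception (years; averaged).
#' @param n_untestable Candidates without confirmation genotypes.
#' @param fn_rate False-negative rate (default 0).
#' @return A list of class `rate_estimate` with the counts, corrections and
#'   derived rates.
#' @examples
#' estimate_rate(45, 0.2, 1, 1.182e9, 24, n_untestable = 5)
#' @export
estimate_rate <- function(n_candidates, fp_rate, n_somatic, target_size,
                          parental_age, n_untestable = 0, fn_rate = 0) {
  counts <- germline_count(n_candidates, fp_rate, n_somatic, n_untestable)
  mu_g <- per_generation_rate(counts$point, target_size, fn_rate)
  out <- list(
    n_candidates = n_candidates,
    fp_rate = fp_rate,
    n_fp = round(n_candidates * fp_rate),
    n_somatic = n_somatic,
    n_untestable = n_untestable,
    fn_rate = fn_rate,
    n_germline = counts$point,
    n_germline_min = counts$min,
    n_germline_max = counts$max,
    target_size = target_size,
    parental_age = mean(parental_age),
    mu_per_generation = mu_g,
    mu_per_generation_min = per_generation_rate(counts$min, target_size, fn_rate),
    mu_per_generation_max = per_generation_rate(counts$max, target_size, fn_rate),
    mu_per_year = per_year_rate(mu_g, parental_age)
  )
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate>\n")
  cat(sprintf(
    "  candidates %d | FP rate %.3g (-%d) | somatic -%d | germline %d [%d, %d]\n",
    x$n_candidates, x$fp_rate, x$n_fp, x$n_somatic,
    x$n_germline, x$n_germline_min, x$n_germline_max
  ))
  cat(sprintf(
    "  target %.4g bp | %.3g /site/generation [%.3g, %.3g] | %.2g /site/year (age %g)\n",
    x$target_size, x$mu_per_generation, x$mu_per_generation_min,
    x$mu_per_generation_max, x$mu_per_year, x$parental_age
  ))
  invisible(x)
}
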