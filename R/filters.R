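#' Depth bounds for the read-depth filter
#'
#' Computes each individual's mean and standard deviation of per-base depth
#' after clamping to a plausible pre-range (sites with depth outside
#' `[premin, premax]` are excluded from the moments, since extreme pileups
#' distort them), and sets the acceptance window to mean +/- 3 sigma, floored
#' at zero.
#'
#' @param depths Either a named list (one numeric vector, or list of
#'   per-chromosome vectors, per individual) or a single numeric vector.
#' @param premin Minimum depth(s) admitted into the moment computation; a
#'   single value or a named vector per individual (e.g. father/mother 15,
#'   offspring 18).
#' @param premax Maximum depth admitted into the moment computation.
#' @param n_sigma Half-width of the acceptance window in standard deviations.
#' @return Tibble: individual, mean, sd, lower, upper, premin, premax.
#' @examples
#' compute_depth_bounds(list(father = rpois(1e4, 150)), premin = 15)
#' @export
compute_depth_bounds <- function(depths, premin = 15, premax = 512, n_sigma = 3) {
  if (is.numeric(depths)) depths <- list(all = depths)
  stopifnot(premax > max(premin))
  inds <- names(depths)
  purrr::map_dfr(inds, function(ind) {
    pm <- if (length(premin) > 1) premin[[ind]] else premin
    d <- depths[[ind]]
    if (is.list(d)) d <- unlist(d, use.names = FALSE)
    d <- d[d >= pm & d <= premax]
    if (length(d) == 0) stop("no sites within [premin, premax] for ", ind)
    m <- mean(d)
    s <- stats::sd(d)
    if (is.na(s)) s <- 0
    tibble::tibble(
      individual = ind, mean = m, sd = s,
      lower = max(0, m - n_sigma * s), upper = m + n_sigma * s,
      premin = pm, premax = premax
    )
  })
}

#' Read-depth filter
#'
#' Removes every base at which any trio member's depth falls outside that
#' member's own `[lower, upper]` window from [compute_depth_bounds()].
#'
#' @param depths Named list per individual; each element either a numeric
#'   vector (single chromosome named "chr1") or a named list of
#'   per-chromosome vectors.
#' @param bounds Tibble from [compute_depth_bounds()] with one row per
#'   individual in `depths`.
#' @return Region set (tibble) of removed intervals.
#' @export
filter_depth <- function(depths, bounds) {
  stopifnot(all(names(depths) %in% bounds$individual))
  removed <- purrr::map_dfr(names(depths), function(ind) {
    b <- bounds[bounds$individual == ind, ]
    d <- depths[[ind]]
    if (!is.list(d)) d <- list(chr1 = d)
    purrr::map_dfr(names(d), function(ch) {
      out <- d[[ch]] < b$lower | d[[ch]] > b$upper
      runs_to_regions(out, ch)
    })
  })
  region_set(removed)
}

# logical vector over positions 0..n-1 -> region tibble of TRUE runs
runs_to_regions <- function(flag, chrom) {
  if (!any(flag)) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

#' Mapped-read strand-balance filter
#'
#' Removes sites unless every trio member has at least `min_per_strand`
#' forward reads and `min_per_strand` reverse reads (the boundary is
#' inclusive).
#'
#' @param sites Trio site table with `rf_*`, `rr_*`, `af_*`, `ar_*` columns.
#' @param min_per_strand Minimum reads per strand per individual.
#' @return Region set of removed single-base intervals.
#' @export
filter_read_balance <- function(sites, min_per_strand = 10) {
  bad <- rep(FALSE, nrow(sites))
  for (ind in c("father", "mother", "offspring")) {
    fwd <- sites[[paste0("rf_", ind)]] + sites[[paste0("af_", ind)]]
    rev <- sites[[paste0("rr_", ind)]] + sites[[paste0("ar_", ind)]]
    bad <- bad | fwd < min_per_strand | rev < min_per_strand
  }
  region_set(tibble::tibble(
    chrom = sites$chrom[bad], start = sites$pos[bad], end = sites$pos[bad] + 1
  ))
}

#' Indel-proximity filter
#'
#' Removes each annotated indel position together with `pad` bp on either
#' side (an isolated indel removes a 2*pad + 1 bp interval).
#'
#' @param indels Tibble with `chrom`, `pos` (0-based indel positions).
#' @param pad Symmetric padding in bp.
#' @return Region set of removed intervals (merged where pads overlap).
#' @export
filter_indels <- function(indels, pad = 50) {
  if (nrow(indels) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  region_set(tibble::tibble(
    chrom = indels$chrom,
    start = pmax(0, indels$pos - pad),
    end = indels$pos + pad + 1
  ))
}

#' Allelic and strand bias filter
#'
#' A variant site must be supported on both strands: each heterozygous
#' carrier needs at least one read in all four classes RF, RR, AF, AR, and a
#' homozygous-alternate carrier (which is not expected to show reference
#' reads) needs AF >= 1 and AR >= 1. Failing sites are removed with `pad` bp
#' on either side.
#'
#' @param sites Trio site table with genotype (`gt_*`) and strand count
#'   columns.
#' @param pad Symmetric padding in bp.
#' @return Region set of removed intervals.
#' @export
filter_allele_strand_bias <- function(sites, pad = 10) {
  bad <- rep(FALSE, nrow(sites))
  for (ind in c("father", "mother", "offspring")) {
    gt <- sites[[paste0("gt_", ind)]]
    rf <- sites[[paste0("rf_", ind)]]
    rr <- sites[[paste0("rr_", ind)]]
    af <- sites[[paste0("af_", ind)]]
    ar <- sites[[paste0("ar_", ind)]]
    het_bad <- !is.na(gt) & gt == 1L & (rf < 1 | rr < 1 | af < 1 | ar < 1)
    hom_bad <- !is.na(gt) & gt == 2L & (af < 1 | ar < 1)
    bad <- bad | het_bad | hom_bad
  }
  region_set(tibble::tibble(
    chrom = sites$chrom[bad],
    start = pmax(0, sites$pos[bad] - pad),
    end = sites$pos[bad] + pad + 1
  ))
}

#' Read-end proximity filter
#'
#' Removes variant sites whose supporting reads sit too close to the read
#' ends (mean distance to the nearer read end at most `max_mean_dist` bp in
#' any variant carrier), together with `pad` bp on either side. Such sites
#' are typical of alignments truncated at contig gaps.
#'
#' @param sites Trio site table with `gt_*` and `mde_*` (mean
#'   distance-to-read-end) columns.
#' @param max_mean_dist Threshold on the mean distance (exclusive above).
#' @param pad Symmetric padding in bp.
#' @return Region set of removed intervals.
#' @export
filter_read_ends <- function(sites, max_mean_dist = 10, pad = 10) {
  bad <- rep(FALSE, nrow(sites))
  for (ind in c("father", "mother", "offspring")) {
    gt <- sites[[paste0("gt_", ind)]]
    mde <- sites[[paste0("mde_", ind)]]
    bad <- bad | (!is.na(gt) & gt >= 1L & !is.na(mde) & mde <= max_mean_dist)
  }
  region_set(tibble::tibble(
    chrom = sites$chrom[bad],
    start = pmax(0, sites$pos[bad] - pad),
    end = sites$pos[bad] + pad + 1
  ))
}

#' Build high-confidence target regions
#'
#' Subtracts the union of all filter removals and the repeat mask from the
#' genome, and reports per-filter removal (each filter's bp counted against
#' the whole genome, overlaps between filters counted in each, as removal
#' percentages are conventionally quoted) alongside the final retained
#' fraction.
#'
#' @param genome Region set covering the whole analysable genome.
#' @param removals Named list of region sets, one per filter.
#' @param repeat_mask Optional region set of repeat intervals to exclude.
#' @return List with `target` (region set) and `report` (tibble: filter,
#'   bp_removed, pct; final row `retained`).
#' @export
build_target_regions <- function(genome, removals = list(), repeat_mask = NULL) {
  genome <- region_set(genome)
  g_len <- region_length(genome)
  if (!is.null(repeat_mask)) removals <- c(removals, list(repeat_mask = repeat_mask))
  target <- genome
  union_removed <- tibble::tibble(chrom = character(), start = double(), end = double())
  report <- purrr::map_dfr(names(removals), function(nm) {
    rm_in_genome <- region_intersect(region_set(removals[[nm]]), genome)
    union_removed <<- region_union(union_removed, rm_in_genome)
    tibble::tibble(
      filter = nm,
      bp_removed = region_length(rm_in_genome),
      pct = 100 * region_length(rm_in_genome) / g_len
    )
  })
  target <- region_subtract(genome, union_removed)
  t_len <- region_length(target)
  if (t_len == 0) stop("target regions are empty after filtering")
  report <- dplyr::bind_rows(
    report,
    tibble::tibble(filter = "union_removed",
      bp_removed = region_length(union_removed),
      pct = 100 * region_length(union_removed) / g_len),
    tibble::tibble(filter = "retained", bp_removed = t_len, pct = 100 * t_len / g_len)
  )
  list(target = target, report = report)
}
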