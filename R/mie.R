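#' Mendelian consistency of a biallelic genotype trio
#'
#' A trio genotype configuration is Mendelian-consistent when the offspring
#' genotype can be assembled from one allele of the father's genotype and
#' one of the mother's. With genotypes coded as alternate-allele counts
#' (0/1/2), this reduces to `(F==2) + (M==2) <= O <= (F>=1) + (M>=1)`.
#'
#' @param gt_father,gt_mother,gt_offspring Integer vectors of alternate
#'   allele counts (0, 1, 2); `NA` propagates.
#' @return Logical vector: is each trio consistent?
#' @examples
#' mendelian_consistent(0L, 0L, 1L) # de novo pattern: FALSE
#' mendelian_consistent(1L, 0L, 1L) # inherited het: TRUE
#' @export
mendelian_consistent <- function(gt_father, gt_mother, gt_offspring) {
  lo <- (gt_father == 2L) + (gt_mother == 2L)
  hi <- (gt_father >= 1L) + (gt_mother >= 1L)
  gt_offspring >= lo & gt_offspring <= hi
}

#' Detect Mendelian inheritance errors in a trio site table
#'
#' Flags each biallelic site whose offspring genotype is inconsistent with
#' every assortment of the parental alleles. Sites with a missing or
#' quality-filtered genotype in any member are skipped (never imputed) and
#' counted; sites outside the target regions are dropped.
#'
#' @param sites Trio site table with `gt_father`, `gt_mother`,
#'   `gt_offspring` columns (and optionally `filtered_*` flags).
#' @param target_regions Optional region set restricting the analysis.
#' @return Tibble of MIE rows (subset of `sites`), with attribute
#'   `skip_report`: a named vector counting sites skipped for missing or
#'   filtered genotypes, and sites outside the targets.
#' @export
detect_mies <- function(sites, target_regions = NULL) {
  sites <- tibble::as_tibble(sites)
  n0 <- nrow(sites)
  outside <- 0L
  if (!is.null(target_regions)) {
    keep <- in_regions(sites$chrom, sites$pos, target_regions)
    outside <- sum(!keep)
    sites <- sites[keep, ]
  }
  missing <- is.na(sites$gt_father) | is.na(sites$gt_mother) |
    is.na(sites$gt_offspring)
  filtered <- rep(FALSE, nrow(sites))
  for (ind in c("father", "mother", "offspring")) {
    fc <- sites[[paste0("filtered_", ind)]]
    if (!is.null(fc)) filtered <- filtered | (!is.na(fc) & fc)
  }
  usable <- !missing & !filtered
  s <- sites[usable, ]
  mie <- !mendelian_consistent(s$gt_father, s$gt_mother, s$gt_offspring)
  out <- s[mie, ]
  attr(out, "skip_report") <- c(
    input_sites = n0, outside_target = outside,
    missing_genotype = sum(missing), filtered_genotype = sum(filtered & !missing),
    tested = sum(usable), mies = sum(mie)
  )
  out
}

#' Normalised pairwise depth ratio in a window
#'
#' Ratio of individual `b`'s depth to individual `a`'s in a window, each
#' first normalised by its genome-wide mean, so a copy-neutral window gives
#' ~1 and a hemizygous deletion in `b` alone gives ~0.5.
#'
#' @param depths Named list of per-chromosome depth vectors per individual.
#' @param chrom,start,end Window (0-based half-open).
#' @param a,b Individual names (denominator / numerator).
#' @param genome_means Named vector of genome-wide mean depths.
#' @return A single ratio.
#' @export
depth_ratio <- function(depths, chrom, start, end, a, b, genome_means) {
  wa <- window_mean_depth(depths[[a]], chrom, start, end)
  wb <- window_mean_depth(depths[[b]], chrom, start, end)
  if (wa == 0 || wb == 0) stop("zero coverage in window; depth ratio undefined")
  (wb / genome_means[[b]]) / (wa / genome_means[[a]])
}

window_mean_depth <- function(depth_ind, chrom, start, end) {
  d <- depth_ind[[chrom]]
  lo <- max(0, start) + 1
  hi <- min(length(d), end)
  if (hi < lo) stop("window outside depth track")
  mean(d[lo:hi])
}

#' Classify MIEs into the four inheritance/depth categories
#'
#' Each MIE is assigned per-individual half-depth flags from the normalised
#' depth of a window centred on the site (normalised depth at most
#' `half_threshold`, the midpoint between one and two copies, counts as
#' "half"), then classified in fixed order:
#'
#' 1. the offspring carries an allele absent from both parents and no member
#'    is at half depth: de novo SNV (`DENOVO_SNV`);
#' 2. all offspring alleles are present in a parent and no member is at half
#'    depth: copy-number-neutral inherited variant (`CNIV`, the allelic
#'    conversion signature);
#' 3. the offspring and exactly one parent are at half depth: hemizygous
#'    deletion inherited variant (`HDIV`);
#' 4. only the offspring is at half depth: de novo CNV (`DENOVO_CNV`).
#'
#' Any other flag combination (for example both parents at half depth but
#' not the offspring) is reported as `UNCLASSIFIED`, never dropped.
#'
#' @param mies MIE tibble from [detect_mies()].
#' @param depths Named list of per-chromosome depth vectors per individual.
#' @param genome_means Named vector of genome-wide mean depths (typically
#'   the `mean` column of [compute_depth_bounds()]).
#' @param window_bp Width of the depth window centred on each site.
#' @param half_threshold Normalised depth at or below which a window is
#'   called "half" (one copy).
#' @return `mies` with columns `norm_depth_father/mother/offspring`,
#'   `half_father/mother/offspring`, `ratio_father_offspring`,
#'   `ratio_mother_offspring`, and `category`.
#' @export
classify_mies <- function(mies, depths, genome_means, window_bp = 1000,
                          half_threshold = 0.75) {
  mies <- tibble::as_tibble(mies)
  n <- nrow(mies)
  norm <- list()
  for (ind in c("father", "mother", "offspring")) {
    norm[[ind]] <- vapply(seq_len(n), function(i) {
      w <- window_mean_depth(
        depths[[ind]], mies$chrom[i],
        mies$pos[i] - window_bp %/% 2, mies$pos[i] + window_bp %/% 2
      )
      w / genome_means[[ind]]
    }, numeric(1))
    mies[[paste0("norm_depth_", ind)]] <- norm[[ind]]
    mies[[paste0("half_", ind)]] <- norm[[ind]] <= half_threshold
  }
  mies$ratio_father_offspring <- norm$offspring / norm$father
  mies$ratio_mother_offspring <- norm$offspring / norm$mother

  hf <- mies$half_father
  hm <- mies$half_mother
  ho <- mies$half_offspring
  novel <- offspring_has_novel_allele(
    mies$gt_father, mies$gt_mother, mies$gt_offspring
  )
  category <- rep("UNCLASSIFIED", n)
  category[novel & !hf & !hm & !ho] <- "DENOVO_SNV"
  category[!novel & !hf & !hm & !ho] <- "CNIV"
  category[ho & xor(hf, hm)] <- "HDIV"
  category[ho & !hf & !hm] <- "DENOVO_CNV"
  mies$category <- factor(
    category,
    levels = c("DENOVO_SNV", "CNIV", "HDIV", "DENOVO_CNV", "UNCLASSIFIED")
  )
  mies
}

# Does the offspring carry an allele with zero copies in both parents?
offspring_has_novel_allele <- function(gt_father, gt_mother, gt_offspring) {
  alt_novel <- gt_offspring >= 1L & gt_father == 0L & gt_mother == 0L
  ref_novel <- gt_offspring <= 1L & gt_father == 2L & gt_mother == 2L
  alt_novel | ref_novel
}

#' Segment half-depth (one-copy) intervals from a depth track
#'
#' Scans an individual's depth in fixed windows, classifies each window as
#' "half" when its normalised depth is at most `half_threshold`, and merges
#' maximal runs of half windows (runs separated by a single window are
#' joined) into candidate deletion segments.
#'
#' @param depth_ind Named list of per-chromosome depth vectors for one
#'   individual.
#' @param genome_mean The individual's genome-wide mean depth.
#' @param window_bp Scanning window in bp.
#' @param half_threshold Normalised depth at or below which a window counts
#'   as half.
#' @param min_length Minimum segment length in bp to report.
#' @return Region set of candidate one-copy segments.
#' @export
segment_half_depth <- function(depth_ind, genome_mean, window_bp = 1000,
                               half_threshold = 0.75, min_length = 2000) {
  segs <- purrr::map_dfr(names(depth_ind), function(ch) {
    d <- depth_ind[[ch]]
    n <- length(d)
    starts <- seq(0, n - 1, by = window_bp)
    ends <- pmin(starts + window_bp, n)
    wm <- vapply(seq_along(starts), function(i) {
      mean(d[(starts[i] + 1):ends[i]])
    }, numeric(1)) / genome_mean
    half <- wm <= half_threshold
    if (!any(half)) {
      return(tibble::tibble(chrom = character(), start = double(), end = double()))
    }
    iv <- tibble::tibble(chrom = ch, start = starts[half], end = ends[half])
    # merge runs split by a single normal window
    merged <- region_set(tibble::tibble(
      chrom = iv$chrom, start = pmax(0, iv$start - window_bp / 2),
      end = iv$end + window_bp / 2
    ))
    merged$start <- pmin(pmax(merged$start + window_bp / 2, 0), merged$end)
    merged$end <- pmax(merged$end - window_bp / 2, merged$start)
    merged
  })
  segs <- region_set(segs)
  segs[segs$end - segs$start >= min_length, ]
}
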