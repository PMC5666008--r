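#' Parentally informative heterozygous sites near a de novo SNV
#'
#' A site is informative when the offspring is heterozygous and there is
#' exactly one way to attribute its two alleles to the parents (e.g. father
#' hom-ref, mother hom-alt: the reference allele must be paternal and the
#' alternate maternal). At such sites a read carrying a known allele reveals
#' which parental haplotype it came from.
#'
#' @param sites Trio site table with `gt_*` columns (alternate-allele
#'   counts).
#' @param denovo_chrom,denovo_pos Location of the de novo candidate.
#' @param max_distance Maximum distance (bp) from the de novo site;
#'   typically the fragment length.
#' @return Tibble of informative sites: chrom, pos, father_allele,
#'   mother_allele (0 = reference, 1 = alternate; which allele each parent
#'   contributed to the offspring).
#' @export
informative_sites <- function(sites, denovo_chrom, denovo_pos,
                              max_distance = 500) {
  s <- tibble::as_tibble(sites)
  s <- s[s$chrom == denovo_chrom &
    abs(s$pos - denovo_pos) <= max_distance &
    s$pos != denovo_pos, ]
  s <- s[!is.na(s$gt_father) & !is.na(s$gt_mother) & !is.na(s$gt_offspring) &
    s$gt_offspring == 1L, ]
  if (nrow(s) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = double(),
      father_allele = integer(), mother_allele = integer()
    ))
  }
  # assignment (a from father, b from mother) with {a, b} = {0, 1}
  ref_f <- s$gt_father <= 1L & s$gt_mother >= 1L # father->0, mother->1
  alt_f <- s$gt_father >= 1L & s$gt_mother <= 1L # father->1, mother->0
  unique_assign <- xor(ref_f, alt_f)
  s <- s[unique_assign, ]
  ref_f <- ref_f[unique_assign]
  tibble::tibble(
    chrom = s$chrom, pos = s$pos,
    father_allele = ifelse(ref_f, 0L, 1L),
    mother_allele = ifelse(ref_f, 1L, 0L)
  )
}

#' Assign parental origin to a de novo SNV from fragment evidence
#'
#' Fragments observing the de novo (alternate) allele at the candidate site
#' vote for a parent through every informative site they also cover: the
#' fragment's allele there matches either the paternally or maternally
#' contributed allele. A unanimous vote assigns the origin; no votes or any
#' conflict leaves the call unassigned (conservative policy).
#'
#' @param denovo A one-row tibble/list with `chrom` and `pos`.
#' @param fragments Fragment table from [simulate_fragments()] (columns
#'   chrom, start, end, alleles list-column of (pos, allele)).
#' @param info Informative-site table from [informative_sites()].
#' @return Tibble: chrom, pos, origin ("father"/"mother"/"unassigned"),
#'   n_support (votes for the winning parent), n_conflict.
#' @export
assign_origin <- function(denovo, fragments, info) {
  votes <- character()
  if (nrow(fragments) > 0 && nrow(info) > 0) {
    for (i in seq_len(nrow(fragments))) {
      al <- fragments$alleles[[i]]
      if (fragments$chrom[i] != denovo$chrom) next
      j <- match(denovo$pos, al$pos)
      if (is.na(j) || al$allele[j] != 1L) next # must carry the de novo allele
      hit <- dplyr::inner_join(al, info, by = "pos")
      if (nrow(hit) == 0) next
      votes <- c(votes,
        ifelse(hit$allele == hit$father_allele, "father", "mother"))
    }
  }
  n_f <- sum(votes == "father")
  n_m <- sum(votes == "mother")
  origin <- if (n_f > 0 && n_m == 0) "father"
  else if (n_m > 0 && n_f == 0) "mother"
  else "unassigned"
  tibble::tibble(
    chrom = denovo$chrom, pos = denovo$pos, origin = origin,
    n_support = max(n_f, n_m), n_conflict = min(n_f, n_m)
  )
}

#' Phase a set of de novo candidates
#'
#' Convenience wrapper running [informative_sites()] and [assign_origin()]
#' for every candidate.
#'
#' @param candidates Tibble with `chrom`, `pos` of de novo SNV candidates.
#' @param fragments Fragment table covering the candidates.
#' @param sites Trio site table (for informative-site lookup).
#' @param max_distance Search radius for informative sites.
#' @return Tibble of origin calls, one row per candidate.
#' @export
phase_denovo <- function(candidates, fragments, sites, max_distance = 500) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = double(), origin = character(),
      n_support = integer(), n_conflict = integer()
    ))
  }
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    dn <- candidates[i, ]
    info <- informative_sites(sites, dn$chrom, dn$pos, max_distance)
    assign_origin(dn, fragments, info)
  })
}

#' Paternal fraction of assigned de novo SNVs
#'
#' @param origin_calls Tibble with an `origin` column.
#' @param conf_level Level of the binomial confidence interval.
#' @return Tibble: n_father, n_mother, n_assigned, fraction, conf_low,
#'   conf_high.
#' @examples
#' paternal_fraction(data.frame(origin = c(rep("father", 11), rep("mother", 4))))
#' @export
paternal_fraction <- function(origin_calls, conf_level = 0.95) {
  n_f <- sum(origin_calls$origin == "father")
  n_m <- sum(origin_calls$origin == "mother")
  n <- n_f + n_m
  if (n == 0) stop("no assigned origin calls; paternal fraction undefined")
  bt <- stats::binom.test(n_f, n, conf.level = conf_level)
  tibble::tibble(
    n_father = n_f, n_mother = n_m, n_assigned = n,
    fraction = n_f / n,
    conf_low = bt$conf.int[1], conf_high = bt$conf.int[2]
  )
}
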