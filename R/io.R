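#' Write a trio site table as VCF
#'
#' Emits a minimal VCF v4.2 with one sample column per trio member and
#' FORMAT fields GT, DP and SB (the four strand-resolved allele depths
#' RF,RR,AF,AR; standard AD is strand-collapsed, hence the custom field,
#' declared in the header). Internal 0-based positions become 1-based POS.
#'
#' @param sites Trio site table with `gt_*`, `dp_*` and strand count
#'   columns.
#' @param path Output path.
#' @param sample_names Names for the three sample columns.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(sites, path,
                           sample_names = c("father", "mother", "offspring")) {
  gt_string <- function(gt) {
    dplyr::case_when(
      is.na(gt) ~ "./.", gt == 0L ~ "0/0", gt == 1L ~ "0/1", TRUE ~ "1/1"
    )
  }
  cols <- c("father", "mother", "offspring")
  samples <- vapply(cols, function(ind) {
    paste0(
      gt_string(sites[[paste0("gt_", ind)]]), ":",
      sites[[paste0("dp_", ind)]], ":",
      sites[[paste0("rf_", ind)]], ",", sites[[paste0("rr_", ind)]], ",",
      sites[[paste0("af_", ind)]], ",", sites[[paste0("ar_", ind)]]
    )
  }, character(nrow(sites)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=denovotrio",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0('##FORMAT=<ID=SB,Number=4,Type=Integer,Description=',
      '"Strand-resolved allele depths: RF,RR,AF,AR">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample_names), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos + 1, ".", sites$ref, sites$alt, ".", ".", ".",
    "GT:DP:SB", samples[, 1], samples[, 2], samples[, 3],
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trio VCF into a site table
#'
#' Parses a three-sample VCF (via `vcfR`) carrying GT, DP and the SB
#' strand-resolved allele-depth field as written by [write_trio_vcf()].
#' Positions are converted to 0-based; multi-allelic records are skipped and
#' counted in the `skipped_multiallelic` attribute.
#'
#' @param path VCF path.
#' @param sample_names The three sample columns, in father/mother/offspring
#'   order.
#' @return Trio site tibble with chrom, pos, ref, alt and per-individual
#'   `gt_*`, `dp_*`, `rf_*`, `rr_*`, `af_*`, `ar_*` columns.
#' @export
read_trio_vcf <- function(path,
                          sample_names = c("father", "mother", "offspring")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (!all(sample_names %in% colnames(v@gt))) {
    stop("VCF is missing sample column(s): ",
      paste(setdiff(sample_names, colnames(v@gt)), collapse = ", "))
  }
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  keep <- !multi
  out <- tibble::tibble(
    chrom = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]) - 1,
    ref = fix$REF[keep], alt = fix$ALT[keep]
  )
  gt_code <- function(x) {
    dplyr::case_when(
      x %in% c("0/0", "0|0") ~ 0L,
      x %in% c("0/1", "1/0", "0|1", "1|0") ~ 1L,
      x %in% c("1/1", "1|1") ~ 2L,
      TRUE ~ NA_integer_
    )
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP")
  sb <- vcfR::extract.gt(v, element = "SB")
  for (i in seq_along(sample_names)) {
    ind <- c("father", "mother", "offspring")[i]
    sm <- sample_names[i]
    out[[paste0("gt_", ind)]] <- gt_code(gt[keep, sm])
    out[[paste0("dp_", ind)]] <- as.integer(dp[keep, sm])
    sb4 <- stringr::str_split_fixed(sb[keep, sm], ",", 4)
    out[[paste0("rf_", ind)]] <- as.integer(sb4[, 1])
    out[[paste0("rr_", ind)]] <- as.integer(sb4[, 2])
    out[[paste0("af_", ind)]] <- as.integer(sb4[, 3])
    out[[paste0("ar_", ind)]] <- as.integer(sb4[, 4])
  }
  attr(out, "skipped_multiallelic") <- n_multi
  out
}

#' Read and write BED3 interval files
#'
#' BED is 0-based half-open, matching the internal convention; overlapping
#' intervals are merged on load into a canonical region set.
#'
#' @param path File path.
#' @param regions Region table to write.
#' @return `read_bed()`: a region set tibble; `write_bed()`: `path`,
#'   invisibly.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(), end = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  if (any(x$end <= x$start)) stop("BED interval with end <= start in ", path)
  region_set(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  regions <- region_set(regions)
  readr::write_tsv(regions, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write 4-column depth tracks
#'
#' TSV with header `chrom, start, end, depth`, 0-based half-open intervals.
#'
#' @param path File path.
#' @param track Depth track tibble.
#' @return `read_depth_tsv()`: a tibble; `write_depth_tsv()`: `path`,
#'   invisibly.
#' @export
read_depth_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), depth = readr::col_double()
  ), progress = FALSE)
  if (any(x$end <= x$start)) stop("depth interval with end <= start in ", path)
  x
}

#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "depth")], path,
    progress = FALSE)
  invisible(path)
}
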