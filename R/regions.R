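#' Region sets: sorted, disjoint, half-open genomic intervals
#'
#' A region set is a tibble with columns `chrom`, `start`, `end` describing
#' 0-based half-open intervals `[start, end)`. [region_set()] normalises any
#' interval table into this canonical form: intervals are sorted, overlapping
#' or bookended intervals are merged, and empty intervals are dropped.
#' Interval arithmetic is delegated to `IRanges`.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). `chrom` may be omitted when a single `chrom` value is given.
#' @param chrom Chromosome name used when `x` lacks a `chrom` column.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted and disjoint.
#' @examples
#' region_set(data.frame(chrom = "chr1", start = c(0, 50), end = c(60, 100)))
#' @export
region_set <- function(x, chrom = NULL) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  x <- tibble::as_tibble(x)
  if (!"chrom" %in% names(x)) {
    if (is.null(chrom)) stop("region table needs a `chrom` column or a `chrom` argument")
    x$chrom <- chrom
  }
  stopifnot(all(c("start", "end") %in% names(x)))
  if (any(x$end < x$start)) stop("interval with end < start")
  x <- dplyr::filter(x, .data$end > .data$start)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  parts <- split(x, x$chrom)
  out <- purrr::map_dfr(names(parts), function(ch) {
    ir <- IRanges::reduce(.rs_to_iranges(parts[[ch]]))
    tibble::tibble(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  dplyr::arrange(out, .data$chrom, .data$start)
}

# 0-based half-open -> IRanges (1-based closed)
.rs_to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)
}

.rs_binop <- function(a, b, op) {
  a <- region_set(a)
  b <- region_set(b)
  chroms <- switch(op,
    union = union(a$chrom, b$chrom),
    intersect = intersect(a$chrom, b$chrom),
    setdiff = unique(a$chrom)
  )
  purrr::map_dfr(sort(chroms), function(ch) {
    ia <- .rs_to_iranges(dplyr::filter(a, .data$chrom == ch))
    ib <- .rs_to_iranges(dplyr::filter(b, .data$chrom == ch))
    ir <- switch(op,
      union = IRanges::union(ia, ib),
      intersect = IRanges::intersect(ia, ib),
      setdiff = IRanges::setdiff(ia, ib)
    )
    if (length(ir) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
}

#' Interval arithmetic on region sets
#'
#' Set union, intersection and difference of two region sets, and the total
#' number of bases covered by one. All coordinates are 0-based half-open.
#'
#' @param a,b Region tables (coerced through [region_set()]).
#' @return A normalised region tibble; `region_length()` returns a number (bp).
#' @examples
#' a <- region_set(data.frame(chrom = "chr1", start = 0, end = 100))
#' b <- region_set(data.frame(chrom = "chr1", start = 40, end = 60))
#' region_subtract(a, b)
#' region_length(region_union(a, b))
#' @export
region_union <- function(a, b) region_set(.rs_binop(a, b, "union"))

#' @rdname region_union
#' @export
region_intersect <- function(a, b) region_set(.rs_binop(a, b, "intersect"))

#' @rdname region_union
#' @export
region_subtract <- function(a, b) region_set(.rs_binop(a, b, "setdiff"))

#' @rdname region_union
#' @export
region_length <- function(a) {
  a <- region_set(a)
  sum(a$end - a$start)
}

#' Test positions for membership in a region set
#'
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param regions A region table.
#' @return Logical vector: is each position inside `regions`?
#' @export
in_regions <- function(chrom, pos, regions) {
  regions <- region_set(regions)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ir <- .rs_to_iranges(dplyr::filter(regions, .data$chrom == ch))
    q <- IRanges::IRanges(start = pos[sel] + 1, width = 1)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}
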