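#' Expected adjacent distance under uniform placement
#'
#' If `n` points fall uniformly on a region of `L` bp, the expected spacing
#' between adjacent points is `L / n`.
#'
#' @param n Number of points (at least 2).
#' @param L Region length in bp.
#' @return Expected adjacent distance in bp.
#' @examples
#' expected_adjacent_distance(476, 1.17e9) # ~2.46e6
#' @export
expected_adjacent_distance <- function(n, L) {
  stopifnot(n >= 2, L > 0)
  L / n
}

#' Bootstrap confidence interval for adjacent distances
#'
#' Simulates `reps` placements of `n` uniform points on `[0, L)`, pools the
#' `n - 1` adjacent gaps of every replicate, and returns the symmetric
#' `level` percentile interval of the pooled gap distribution. Deterministic
#' given `seed`. For uniform placement the gaps are approximately
#' exponential with mean `L / n`, so the interval brackets the exponential
#' quantiles `-log(1 - (1-level)/2) * L/n` and `-log((1-level)/2) * L/n`.
#'
#' @param n Number of points per replicate (at least 2).
#' @param L Region length in bp.
#' @param reps Bootstrap replicates.
#' @param level Confidence level in (0, 1).
#' @param seed Seed for the placements.
#' @return A list of class `distance_null`: `n`, `L`, `expected`, `lower`,
#'   `upper`, `level`, `reps`, `seed`.
#' @examples
#' bootstrap_distance_ci(10, 1e5, reps = 200, seed = 1)
#' @export
bootstrap_distance_ci <- function(n, L, reps = 10000, level = 0.99, seed = 1L) {
  stopifnot(n >= 2, L > 0, reps >= 1, level > 0, level < 1)
  set.seed(seed)
  gaps <- vapply(seq_len(reps), function(i) {
    p <- sort(stats::runif(n, 0, L))
    diff(p)
  }, numeric(n - 1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(as.vector(gaps), c(alpha, 1 - alpha), names = FALSE)
  out <- list(
    n = n, L = L, expected = expected_adjacent_distance(n, L),
    lower = q[1], upper = q[2], level = level, reps = reps, seed = seed
  )
  class(out) <- "distance_null"
  out
}

#' @export
print.distance_null <- function(x, ...) {
  cat(sprintf(
    "<distance_null> n=%d on L=%.4g bp: expected gap %.4g bp; %g%% CI [%.4g, %.4g] (%d reps)\n",
    x$n, x$L, x$expected, 100 * x$level, x$lower, x$upper, x$reps
  ))
  invisible(x)
}

#' Cluster copy-number-neutral variants into conversion events
#'
#' Single-linkage chaining per chromosome: consecutive positions with gap at
#' most `threshold` bp join one putative allelic-conversion event; isolated
#' positions form singleton events. Gaps across chromosomes are never
#' clustered.
#'
#' @param cnivs Tibble with `chrom`, `pos` columns (CNIV sites), or a
#'   numeric vector of positions on one chromosome.
#' @param threshold Maximum gap (bp) joining two adjacent sites, typically
#'   the lower bound of the bootstrap null interval.
#' @return Tibble: event_id, chrom, start, end, n_members, span (end - start
#'   over member positions).
#' @examples
#' cluster_cnivs(c(100, 200, 50000), threshold = 17500)
#' @export
cluster_cnivs <- function(cnivs, threshold) {
  cnivs <- as_position_table(cnivs)
  if (nrow(cnivs) == 0) {
    return(tibble::tibble(
      event_id = integer(), chrom = character(), start = double(),
      end = double(), n_members = integer(), span = double()
    ))
  }
  cnivs <- dplyr::arrange(cnivs, .data$chrom, .data$pos)
  new_event <- c(TRUE, diff(cnivs$pos) > threshold |
    cnivs$chrom[-1] != cnivs$chrom[-nrow(cnivs)])
  cnivs$event_id <- cumsum(new_event)
  dplyr::summarise(
    dplyr::group_by(cnivs, .data$event_id, .data$chrom),
    start = min(.data$pos), end = max(.data$pos) + 1,
    n_members = dplyr::n(), span = max(.data$pos) - min(.data$pos),
    .groups = "drop"
  )
}

#' Nearest-neighbour adjacency profile
#'
#' For each cutoff, counts how many positions have their nearest same-
#' chromosome neighbour within that many bp.
#'
#' @param cnivs Position table (`chrom`, `pos`) or numeric vector.
#' @param cutoffs Distances in bp.
#' @return Tibble: cutoff, count, fraction.
#' @export
adjacency_profile <- function(cnivs, cutoffs = c(100, 1000, 17500)) {
  cnivs <- as_position_table(cnivs)
  nn <- nearest_neighbour_distances(cnivs)
  purrr::map_dfr(cutoffs, function(cut) {
    k <- sum(nn <= cut, na.rm = TRUE)
    tibble::tibble(cutoff = cut, count = k, fraction = k / length(nn))
  })
}

nearest_neighbour_distances <- function(cnivs) {
  cnivs <- dplyr::arrange(as_position_table(cnivs), .data$chrom, .data$pos)
  unlist(lapply(split(cnivs$pos, cnivs$chrom), function(p) {
    if (length(p) < 2) return(rep(NA_real_, length(p)))
    g <- diff(p)
    pmin(c(Inf, g), c(g, Inf))
  }), use.names = FALSE)
}

as_position_table <- function(x) {
  if (is.numeric(x)) {
    return(tibble::tibble(chrom = "chr1", pos = as.numeric(x)))
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "pos") %in% names(x)))
  x[, c("chrom", "pos")]
}
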