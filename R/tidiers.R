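#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One row per quantity: term, estimate, low, high.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("n_germline", "mu_per_generation", "mu_per_year"),
    estimate = c(x$n_germline, x$mu_per_generation, x$mu_per_year),
    low = c(x$n_germline_min, x$mu_per_generation_min,
      x$mu_per_generation_min / x$parental_age),
    high = c(x$n_germline_max, x$mu_per_generation_max,
      x$mu_per_generation_max / x$parental_age)
  )
}

#' @rdname tidy.rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$n_candidates, fp_rate = x$fp_rate, n_fp = x$n_fp,
    n_somatic = x$n_somatic, n_untestable = x$n_untestable,
    n_germline = x$n_germline, target_size = x$target_size,
    parental_age = x$parental_age,
    mu_per_generation = x$mu_per_generation, mu_per_year = x$mu_per_year
  )
}

#' Tidy a phylogenetic rate
#'
#' @param x A `phylo_rate`.
#' @param ... Unused.
#' @return Tibble with one row per rate scale.
#' @export
tidy.phylo_rate <- function(x, ...) {
  tibble::tibble(
    term = c("mu_per_generation", "mu_per_year"),
    estimate = c(x$mu_per_generation, x$mu_per_year)
  )
}

#' @rdname tidy.phylo_rate
#' @export
glance.phylo_rate <- function(x, ...) {
  tibble::tibble(
    d = x$d, t = x$t, g = x$g, ne = x$ne,
    mu_per_generation = x$mu_per_generation, mu_per_year = x$mu_per_year
  )
}

#' Tidy the uniform-placement distance null
#'
#' @param x A `distance_null`.
#' @param ... Unused.
#' @return One-row tibble with the analytic mean and bootstrap interval.
#' @export
tidy.distance_null <- function(x, ...) {
  tibble::tibble(
    n = x$n, L = x$L, expected = x$expected,
    lower = x$lower, upper = x$upper, level = x$level, reps = x$reps
  )
}
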