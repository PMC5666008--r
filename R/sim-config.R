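#' Configuration for the synthetic trio simulator
#'
#' Bundles every knob of the generative model behind [simulate_trio()] and
#' [simulate_observations()] and validates their ranges. Defaults emulate a
#' deeply sequenced great-ape trio: parental SNV density 0.118% with
#' autosomal heterozygosity 0.076%, a transition/transversion ratio of 1.98,
#' ~150x coverage per individual, and rare structural events (allelic
#' conversion tracts, inherited hemizygous deletions, de novo microdeletions
#' under 6 kb).
#'
#' @param genome_length Bases per synthetic autosome.
#' @param n_chromosomes Number of autosomes.
#' @param snv_density Fraction of sites at which a parent carries a variant.
#' @param heterozygosity Fraction of sites heterozygous in a parent; must not
#'   exceed `snv_density`.
#' @param titv_ratio Target transition/transversion ratio of parental variants.
#' @param mu_denovo Germline de novo SNV rate per site per haploid
#'   transmission (expected de novo count is `2 * mu_denovo * genome`).
#' @param n_somatic Somatic de novo SNVs present in the offspring's blood
#'   lineage only (absent from hair-follicle DNA).
#' @param conversion_events Number of allelic-conversion tracts laid onto the
#'   offspring. Default scales the genome by 2.6e-7 events/bp, the density
#'   implied by ~306 events over a 1.17 Gb target.
#' @param conversion_tract_mean_bp Mean conversion tract length; tract
#'   lengths are exponential with this mean (literature range 55-290 bp).
#' @param hemizygous_deletions Data frame with columns `parent`
#'   ("father"/"mother") and `length` (bp): one-copy deletions carried by a
#'   parent on the transmitted haplotype, hence inherited by the offspring.
#' @param denovo_deletions Numeric vector of deletion lengths present in the
#'   offspring only (default a 3 kb microdeletion).
#' @param coverage_father,coverage_mother,coverage_offspring Mean read depth.
#' @param base_error Per-read probability that the reported allele is wrong.
#' @param depth_dispersion Negative-binomial size parameter of per-bp depth;
#'   `Inf` gives pure Poisson depth. Real short-read depth is overdispersed,
#'   and the default of 20 keeps half-depth (hemizygous) regions inside the
#'   mean +/- 3 sigma depth filter, as observed depth histograms do.
#' @param repeat_fraction Fraction of the genome covered by the simulated
#'   repeat mask.
#' @param pop_density_factor Parents draw their variants from a shared
#'   "population" site set of density `snv_density * pop_density_factor`, so
#'   co-variant sites agree on ref/alt alleles.
#' @param gc_content GC fraction of the generated reference string (used only
#'   when `reference = TRUE`, for CpG annotation).
#' @param reference Generate an explicit reference base string per chromosome?
#' @param read_length Read length used for read-end distances and fragment
#'   coverage.
#' @param insert_sizes Paired-end insert sizes for simulated fragments.
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(genome_length = 1e5, seed = 7)
#' cfg$snv_density
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 1,
                       snv_density = 0.00118,
                       heterozygosity = 0.00076,
                       titv_ratio = 1.98,
                       mu_denovo = 1.48e-8,
                       n_somatic = 1,
                       conversion_events = NULL,
                       conversion_tract_mean_bp = 170,
                       hemizygous_deletions = data.frame(
                         parent = c("father", "mother"),
                         length = c(20000, 35000)
                       ),
                       denovo_deletions = 3000,
                       coverage_father = 150,
                       coverage_mother = 150,
                       coverage_offspring = 150,
                       base_error = 0.001,
                       depth_dispersion = 20,
                       repeat_fraction = 0.1,
                       pop_density_factor = 1.5,
                       gc_content = 0.4,
                       reference = FALSE,
                       read_length = 101,
                       insert_sizes = c(300, 500),
                       seed = 1L) {
  total <- genome_length * n_chromosomes
  if (is.null(conversion_events)) conversion_events <- round(2.6e-7 * total)
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    snv_density = snv_density,
    heterozygosity = heterozygosity,
    titv_ratio = titv_ratio,
    mu_denovo = mu_denovo,
    n_somatic = as.integer(n_somatic),
    conversion_events = as.integer(conversion_events),
    conversion_tract_mean_bp = conversion_tract_mean_bp,
    hemizygous_deletions = tibble::as_tibble(hemizygous_deletions),
    denovo_deletions = as.numeric(denovo_deletions),
    coverage_father = coverage_father,
    coverage_mother = coverage_mother,
    coverage_offspring = coverage_offspring,
    base_error = base_error,
    depth_dispersion = depth_dispersion,
    repeat_fraction = repeat_fraction,
    pop_density_factor = pop_density_factor,
    gc_content = gc_content,
    reference = isTRUE(reference),
    read_length = read_length,
    insert_sizes = insert_sizes,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  rates <- c(
    cfg$snv_density, cfg$heterozygosity, cfg$mu_denovo, cfg$base_error,
    cfg$repeat_fraction, cfg$gc_content
  )
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$heterozygosity > cfg$snv_density) {
    stop("heterozygosity cannot exceed snv_density")
  }
  if (any(c(cfg$coverage_father, cfg$coverage_mother, cfg$coverage_offspring) <= 0)) {
    stop("coverage must be positive")
  }
  if (cfg$genome_length < 1) stop("genome_length must be positive")
  dels <- c(cfg$hemizygous_deletions$length, cfg$denovo_deletions)
  if (length(dels) > 0 && cfg$genome_length < 10 * max(dels)) {
    stop("genome_length must be at least 10x the largest deletion")
  }
  if (nrow(cfg$hemizygous_deletions) > 0 &&
    !all(cfg$hemizygous_deletions$parent %in% c("father", "mother"))) {
    stop("hemizygous_deletions$parent must be 'father' or 'mother'")
  }
  if (cfg$depth_dispersion <= 0) stop("depth_dispersion must be positive")
  if (cfg$pop_density_factor < 1) stop("pop_density_factor must be >= 1")
  if (cfg$snv_density * cfg$pop_density_factor > 1) {
    stop("snv_density * pop_density_factor must not exceed 1")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d x %.3g bp | SNV density %.5f | het %.5f | Ti/Tv %.2f\n",
    x$n_chromosomes, x$genome_length, x$snv_density, x$heterozygosity, x$titv_ratio
  ))
  cat(sprintf(
    "  mu_denovo %.3g /site/transmission | somatic %d | conversions %d (mean tract %g bp)\n",
    x$mu_denovo, x$n_somatic, x$conversion_events, x$conversion_tract_mean_bp
  ))
  cat(sprintf(
    "  coverage F/M/O %g/%g/%g | base error %g | dispersion %g | seed %d\n",
    x$coverage_father, x$coverage_mother, x$coverage_offspring,
    x$base_error, x$depth_dispersion, x$seed
  ))
  invisible(x)
}

# Deterministic per-stage child seed below 2^31.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 997) %% 2147483587 + 1)
}
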