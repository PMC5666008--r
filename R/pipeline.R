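#' Truth-level MIE table for a simulation
#'
#' Applies the Mendelian-assortment rule to the noise-free genotypes of a
#' simulated trio and labels every true MIE with the event class that caused
#' it (de novo/somatic SNV, conversion tract, inherited hemizygous deletion,
#' de novo deletion). This is the reference labelling against which the
#' noisy pipeline's recall and precision are measured.
#'
#' @param sim A `trio_sim`.
#' @return Tibble: chrom, pos, gt columns, and `category` (factor with the
#'   four event classes plus `UNCLASSIFIED`).
#' @export
true_mies <- function(sim) {
  tg <- true_genotypes(sim, tissue = "blood")
  mie <- !mendelian_consistent(tg$gt_father, tg$gt_mother, tg$gt_offspring)
  tg <- tg[mie, ]
  tr <- sim$truth
  key <- paste(tg$chrom, tg$pos)
  cat_lab <- rep("UNCLASSIFIED", nrow(tg))
  in_iv <- function(iv) {
    if (nrow(iv) == 0) rep(FALSE, nrow(tg)) else in_regions(tg$chrom, tg$pos, iv)
  }
  cat_lab[in_iv(tr$conversion_tracts[, c("chrom", "start", "end")])] <- "CNIV"
  cat_lab[in_iv(tr$hemizygous_deletions[, c("chrom", "start", "end")])] <- "HDIV"
  cat_lab[in_iv(tr$denovo_deletions[, c("chrom", "start", "end")])] <- "DENOVO_CNV"
  dn_key <- paste(tr$denovo_snvs$chrom, tr$denovo_snvs$pos)
  som_key <- paste(tr$somatic_snvs$chrom, tr$somatic_snvs$pos)
  cat_lab[key %in% c(dn_key, som_key)] <- "DENOVO_SNV"
  tg$category <- factor(
    cat_lab,
    levels = c("DENOVO_SNV", "CNIV", "HDIV", "DENOVO_CNV", "UNCLASSIFIED")
  )
  tg
}

#' Confirmation ("Sanger-like") genotypes for candidate sites
#'
#' Returns the noise-free genotypes of father, mother, offspring blood and
#' offspring hair at the requested sites, in the layout expected by
#' [validate_candidates()]. In the simulator the confirmation assay is
#' exact, so validation verdicts reflect the truth.
#'
#' @param sim A `trio_sim`.
#' @param candidates Tibble with `chrom`, `pos`.
#' @return Tibble: chrom, pos, sanger_father, sanger_mother, sanger_blood,
#'   sanger_hair.
#' @export
confirmation_table <- function(sim, candidates) {
  blood <- true_genotypes(sim, tissue = "blood")
  hair <- true_genotypes(sim, tissue = "hair")
  key_b <- paste(blood$chrom, blood$pos)
  m <- match(paste(candidates$chrom, candidates$pos), key_b)
  tibble::tibble(
    chrom = candidates$chrom, pos = candidates$pos,
    sanger_father = blood$gt_father[m],
    sanger_mother = blood$gt_mother[m],
    sanger_blood = blood$gt_offspring[m],
    sanger_hair = hair$gt_offspring[m]
  )
}

#' Run the full trio analysis on a simulated dataset
#'
#' Executes every stage end to end: simulate genomes and observations, call
#' genotypes, build high-confidence target regions from the five filters
#' plus the repeat mask, detect and classify MIEs, cluster CNIVs into
#' conversion events against the bootstrap null, phase de novo candidates,
#' validate them against the confirmation genotypes, and estimate corrected
#' mutation rates.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param parental_age Parental age(s) at conception in years.
#' @param premin,premax Depth pre-clamp for [compute_depth_bounds()]
#'   (`premin` may be a named vector per individual).
#' @param window_bp,half_threshold Depth-window classification parameters.
#' @param clustering_reps,clustering_level Bootstrap null parameters.
#' @param clustering_threshold Optional explicit clustering threshold (bp);
#'   default is the bootstrap interval's lower bound.
#' @param out_dir Optional directory: writes VCF, BEDs, depth tracks, MIE
#'   and event tables, origin calls, the filter report and a summary JSON.
#' @return A list of class `trio_pipeline_result` with elements `sim`,
#'   `obs`, `sites`, `bounds`, `target`, `report`, `mies`, `classified`,
#'   `null_model`, `events`, `origins`, `validation`, `rate`, `summary`.
#' @export
run_trio_pipeline <- function(config,
                              parental_age = 24,
                              premin = c(father = 15, mother = 15, offspring = 18),
                              premax = 512,
                              window_bp = 1000,
                              half_threshold = 0.75,
                              clustering_reps = 2000,
                              clustering_level = 0.99,
                              clustering_threshold = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_trio(config)
  obs <- simulate_observations(sim)
  sites <- trio_sites(obs)

  bounds <- compute_depth_bounds(obs$depth, premin = premin, premax = premax)
  genome_means <- stats::setNames(bounds$mean, bounds$individual)
  removals <- list(
    depth = filter_depth(obs$depth, bounds),
    read_balance = filter_read_balance(sites),
    allele_strand_bias = filter_allele_strand_bias(sites),
    read_ends = filter_read_ends(sites)
  )
  built <- build_target_regions(sim$genome, removals, sim$repeat_mask)
  target <- built$target

  mies <- detect_mies(sites, target)
  classified <- classify_mies(mies, obs$depth, genome_means,
    window_bp = window_bp, half_threshold = half_threshold)

  cnivs <- classified[classified$category == "CNIV", c("chrom", "pos")]
  null_model <- NULL
  threshold <- clustering_threshold
  if (nrow(cnivs) >= 2) {
    null_model <- bootstrap_distance_ci(
      n = nrow(cnivs), L = region_length(target),
      reps = clustering_reps, level = clustering_level,
      seed = derive_seed(config$seed, "bootstrap")
    )
    if (is.null(threshold)) threshold <- null_model$lower
  }
  events <- cluster_cnivs(cnivs, threshold %||% 0)

  candidates <- classified[classified$category == "DENOVO_SNV", ]
  fragments <- simulate_fragments(sim, candidates[, c("chrom", "pos")])
  origins <- phase_denovo(candidates[, c("chrom", "pos")], fragments, sites,
    max_distance = max(config$insert_sizes))

  confirmation <- confirmation_table(sim, candidates)
  validation <- if (nrow(candidates) > 0) {
    validate_candidates(
      candidates[, c("chrom", "pos", "gt_father", "gt_mother", "gt_offspring")],
      confirmation
    )
  } else {
    list(records = candidates, fp_rate = 0, n_testable = 0, n_fp = 0,
      n_somatic = 0, n_untestable = 0)
  }
  fp_rate <- if (is.na(validation$fp_rate)) 0 else validation$fp_rate
  rate <- estimate_rate(
    n_candidates = nrow(candidates), fp_rate = fp_rate,
    n_somatic = validation$n_somatic, target_size = region_length(target),
    parental_age = parental_age, n_untestable = validation$n_untestable
  )

  summary <- list(
    seed = config$seed,
    genome_bp = config$genome_length * config$n_chromosomes,
    target_bp = region_length(target),
    target_fraction = region_length(target) /
      (config$genome_length * config$n_chromosomes),
    n_sites = nrow(sites),
    n_mies = nrow(classified),
    categories = as.list(table(classified$category)),
    n_conversion_events = nrow(events),
    clustering_threshold = threshold,
    n_assigned_father = sum(origins$origin == "father"),
    n_assigned_mother = sum(origins$origin == "mother"),
    fp_rate = fp_rate,
    n_somatic = validation$n_somatic,
    n_germline = rate$n_germline,
    mu_per_generation = rate$mu_per_generation,
    mu_per_year = rate$mu_per_year
  )

  out <- list(
    sim = sim, obs = obs, sites = sites, bounds = bounds,
    target = target, report = built$report, mies = mies,
    classified = classified, null_model = null_model, events = events,
    origins = origins, validation = validation, rate = rate,
    summary = summary
  )
  class(out) <- "trio_pipeline_result"

  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.trio_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<trio_pipeline_result>\n")
  cat(sprintf("  target %.4g bp (%.1f%% of genome) | %d MIEs\n",
    s$target_bp, 100 * s$target_fraction, s$n_mies))
  cats <- unlist(s$categories)
  cat("  categories:", paste(names(cats), cats, sep = "=", collapse = " "), "\n")
  cat(sprintf("  conversion events %d | germline %d | %.3g /site/generation\n",
    s$n_conversion_events, s$n_germline, s$mu_per_generation))
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trio_vcf(res$sites, p("trio.vcf"))
  write_bed(res$target, p("target_regions.bed"))
  if (nrow(res$sim$repeat_mask) > 0) {
    write_bed(res$sim$repeat_mask, p("repeat_mask.bed"))
  }
  for (ind in c("father", "mother", "offspring")) {
    write_depth_tsv(depth_track(res$obs, ind), p(paste0("depth_", ind, ".tsv")))
  }
  readr::write_tsv(res$report, p("filter_report.tsv"), progress = FALSE)
  cls <- res$classified
  cls$category <- as.character(cls$category)
  readr::write_tsv(
    cls[, c("chrom", "pos", "ref", "alt", "gt_father", "gt_mother",
      "gt_offspring", "norm_depth_father", "norm_depth_mother",
      "norm_depth_offspring", "category")],
    p("mie_table.tsv"), progress = FALSE
  )
  readr::write_tsv(res$events, p("conversion_events.tsv"), progress = FALSE)
  readr::write_tsv(res$origins, p("origin_calls.tsv"), progress = FALSE)
  if (!is.null(res$null_model)) {
    jsonlite::write_json(tidy(res$null_model), p("null_model.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$summary, p("summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
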