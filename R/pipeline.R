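#' Run the full analysis pipeline on a dataset
#'
#' Chains the analysis stages: build the ASV-by-strain copy matrix from the
#' reference alleles, deconvolve every sample's ASV counts into per-strain
#' reads (restricted to the inoculated strains), convert Ct values to total
#' 16S copies, apply sample QC (bacterial load and sequencing depth), and
#' compute relative/absolute abundances with per-sample detection limits.
#'
#' @param dataset a `pe_dataset` from [simulate_experiment()] or
#'   [read_dataset()] (needs `reference`, `design`, `counts`, `qpcr`).
#' @param curve a [qpcr_curve()]; defaults to the dataset's own curve when
#'   present.
#' @param ct_max,min_known_reads QC thresholds (see [qc_filter()]).
#' @param denominator reads denominator (see [compute_abundances()]).
#' @param open_community fit all reference strains instead of the
#'   inoculated set.
#' @param weighting deconvolution residual weighting (see
#'   [infer_strain_counts()]); default `"poisson"`.
#' @param verbose log per-stage counts.
#' @return list of class `pe_pipeline`: `cm`, `samples` (per-sample reads,
#'   Ct, QC status), `qc` (removed samples with reasons), `abundance`
#'   (an `abundance_table` over retained samples), `deconv` (assignments).
#' @export
run_pipeline <- function(dataset, curve = NULL, ct_max = 26.53,
                         min_known_reads = 100,
                         denominator = c("known", "total"),
                         open_community = FALSE, weighting = "poisson",
                         verbose = FALSE) {
  denominator <- match.arg(denominator)
  for (el in c("reference", "design", "counts", "qpcr"))
    if (is.null(dataset[[el]])) stop2("dataset lacks element: ", el)
  curve <- curve %||% dataset$cfg$curve %||% qpcr_curve()
  cm <- build_copy_matrix(dataset$reference)
  log_msg <- function(...) if (verbose) message(...)
  log_msg("copy matrix: ", length(cm$asv_ids), " ASVs x ",
          length(cm$strain_ids), " strains")
  dec <- deconvolve_samples(dataset$counts, cm, dataset$design,
                            open_community = open_community,
                            weighting = weighting)
  samples <- merge(dec$samples, dataset$qpcr, by = "sample_id")
  samples <- merge(samples,
                   dataset$design$samples[, c("sample_id", "combination",
                                              "treatment", "dropout_strain")],
                   by = "sample_id")
  qc <- qc_filter(samples, ct_max = ct_max,
                  min_known_reads = min_known_reads)
  log_msg("QC: ", nrow(qc$removed), " of ", nrow(samples),
          " samples removed")
  assigned <- dec$assigned[dec$assigned$sample_id %in%
                             qc$retained$sample_id, , drop = FALSE]
  tab <- compute_abundances(qc$retained, assigned, curve,
                            denominator = denominator)
  structure(list(cm = cm, samples = samples, qc = qc, abundance = tab,
                 deconv = dec, curve = curve),
            class = "pe_pipeline")
}

#' Compare pipeline estimates with simulation ground truth
#'
#' Computes, per retained sample, the Pearson correlation between true and
#' estimated relative strain abundances, and per focal strain the recovery
#' of the seeded priority-effect strength (median estimated strength across
#' combinations vs the scenario's `strength_map`).
#'
#' @param pipeline a [run_pipeline()] result.
#' @param dataset the `pe_dataset` the pipeline was run on (must carry
#'   `truth` and `cfg`).
#' @return list with `sample_r` (data.frame `sample_id`, `r`), `strength`
#'   (data.frame `strain_id`, `true_strength`, `est_strength`, `error`),
#'   and `summary` (named vector: `min_sample_r`, `median_sample_r`,
#'   `max_strength_error`, `strength_cor`).
#' @export
validate_run <- function(pipeline, dataset) {
  if (is.null(dataset$truth)) stop2("dataset carries no ground truth")
  tab <- as.data.frame(pipeline$abundance)
  truth <- dataset$truth$truth
  key <- paste(truth$sample_id, truth$strain_id)
  tot <- tapply(truth$abundance, truth$sample_id, sum)
  true_rel <- truth$abundance / as.numeric(tot[truth$sample_id])
  tab$true_rel <- true_rel[match(paste(tab$sample_id, tab$strain_id), key)]
  rs <- vapply(split(tab, tab$sample_id), function(d) {
    if (nrow(d) < 3L || sd(d$true_rel) == 0 || sd(d$rel_abundance) == 0)
      return(NA_real_)
    stats::cor(d$true_rel, d$rel_abundance)
  }, numeric(1))
  sample_r <- data.frame(sample_id = names(rs), r = as.numeric(rs),
                         stringsAsFactors = FALSE)
  st <- strength_table(pipeline$abundance, dataset$design)
  est <- tapply(st$strength, st$strain_id, median)
  strength <- data.frame(
    strain_id = names(est),
    true_strength = as.numeric(dataset$cfg$strength_map[names(est)]),
    est_strength = as.numeric(est), stringsAsFactors = FALSE)
  strength$error <- strength$est_strength - strength$true_strength
  summary <- c(
    min_sample_r = min(sample_r$r, na.rm = TRUE),
    median_sample_r = median(sample_r$r, na.rm = TRUE),
    max_strength_error = max(abs(strength$error)),
    strength_cor = if (sd(strength$true_strength) > 0)
      stats::cor(strength$true_strength, strength$est_strength) else NA_real_)
  list(sample_r = sample_r, strength = strength, summary = summary)
}
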