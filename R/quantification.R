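#' qPCR standard curve configuration
#'
#' The curve maps a cycle threshold to 16S rRNA gene copies per gut via
#' `copies = 10^((ct - intercept) / slope) * dilution_factor *
#' volume_scaling`. The defaults (slope -3.4 Ct per log10 copies, i.e.
#' ~96% efficiency; intercept 38; 0.1x template dilution; 30 uL elution
#' scaling) are documented placeholders for a lab-specific standard curve
#' and should be replaced by calibrated values for real data.
#'
#' @param slope Ct change per log10 copies; must be negative.
#' @param intercept Ct at one copy of template in the reaction.
#' @param dilution_factor template dilution factor (10 for 0.1x template).
#' @param volume_scaling reaction-to-gut volume scaling (e.g. elution
#'   volume / template volume).
#' @return list of class `qpcr_curve`.
#' @export
qpcr_curve <- function(slope = -3.4, intercept = 38, dilution_factor = 10,
                       volume_scaling = 30) {
  if (!is.finite(slope) || slope >= 0)
    stop2("qPCR slope must be negative (Ct per log10 copies)")
  if (dilution_factor <= 0 || volume_scaling <= 0)
    stop2("dilution_factor and volume_scaling must be positive")
  structure(list(slope = slope, intercept = intercept,
                 dilution_factor = dilution_factor,
                 volume_scaling = volume_scaling),
            class = "qpcr_curve")
}

#' Convert Ct values to 16S gene copies per gut
#'
#' @param ct numeric vector of cycle thresholds; `NA` encodes an
#'   undetermined reaction and yields 0 copies.
#' @param curve a [qpcr_curve()].
#' @return numeric vector of copies; attribute `undetermined` marks NA
#'   inputs.
#' @examples
#' ct_to_copies(24.4, qpcr_curve()) # 10^4 * 300 = 3e6
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  copies <- 10^((ct - curve$intercept) / curve$slope) *
    curve$dilution_factor * curve$volume_scaling
  und <- is.na(ct)
  copies[und] <- 0
  attr(copies, "undetermined") <- und
  copies
}

#' Sample quality control on bacterial load and sequencing depth
#'
#' Removes samples with low total 16S copies (Ct strictly above `ct_max` or
#' undetermined) or shallow sequencing (known reads strictly below
#' `min_known_reads`). Boundary samples (Ct exactly `ct_max`, exactly
#' `min_known_reads` known reads) are retained. Each removed sample carries
#' exactly one primary reason; load failures take precedence over depth.
#'
#' @param samples data.frame with at least `sample_id`, `ct` (NA =
#'   undetermined) and `known_reads`.
#' @param ct_max maximum retained Ct (default 26.53).
#' @param min_known_reads minimum retained known-read count (default 100).
#' @return list with `retained` (subset of `samples`) and `removed`
#'   (subset plus a `reason` column, `"ct"` or `"depth"`).
#' @export
qc_filter <- function(samples, ct_max = 26.53, min_known_reads = 100) {
  stopifnot(all(c("sample_id", "ct", "known_reads") %in% names(samples)))
  bad_ct <- is.na(samples$ct) | samples$ct > ct_max
  bad_depth <- samples$known_reads < min_known_reads
  removed <- samples[bad_ct | bad_depth, , drop = FALSE]
  removed$reason <- ifelse(bad_ct[bad_ct | bad_depth], "ct", "depth")
  retained <- samples[!(bad_ct | bad_depth), , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}

#' Relative and absolute strain abundances with detection limits
#'
#' Combines deconvolved read assignments with qPCR totals: relative
#' abundance is the fraction of reads assigned to a strain; absolute
#' abundance is relative abundance times the sample's total 16S copies; the
#' per-sample detection limit is the copy equivalent of a single read
#' (total copies / reads). Absolute abundances strictly below the detection
#' limit are marked undetected and set to exactly 1 (not 0, not NA), the
#' convention that keeps log10 transforms finite with 0 meaning
#' "undetected".
#'
#' @param samples per-sample data.frame with `sample_id`, `ct`,
#'   `known_reads`, `total_reads` (samples should already have passed
#'   [qc_filter()]).
#' @param assigned long data.frame `sample_id`, `strain_id`,
#'   `assigned_reads` (from [deconvolve_samples()]).
#' @param curve a [qpcr_curve()].
#' @param denominator reads denominator for relative abundance and the
#'   detection limit: `"known"` (default; reads matching reference ASVs,
#'   consistent with the closed-community fit) or `"total"` (all reads).
#' @return long data.frame of class `abundance_table`: `sample_id`,
#'   `strain_id`, `assigned_reads`, `rel_abundance`, `abs_abundance`,
#'   `detection_limit`, `detected`, plus per-sample `total_copies`.
#' @export
compute_abundances <- function(samples, assigned, curve,
                               denominator = c("known", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(curve, "qpcr_curve"))
  samples <- samples[samples$sample_id %in% unique(assigned$sample_id), ,
                     drop = FALSE]
  assigned <- assigned[assigned$sample_id %in% samples$sample_id, ,
                       drop = FALSE]
  total_copies <- ct_to_copies(samples$ct, curve)
  reads_den <- if (denominator == "known") samples$known_reads else
    samples$total_reads
  if (any(reads_den == 0))
    stop2("sample(s) with zero reads in denominator reached ",
          "compute_abundances; run qc_filter first")
  i <- match(assigned$sample_id, samples$sample_id)
  rel <- assigned$assigned_reads / reads_den[i]
  abs_ab <- rel * total_copies[i]
  limit <- total_copies[i] / reads_den[i]
  detected <- abs_ab >= limit
  abs_ab[!detected] <- 1
  out <- data.frame(
    sample_id = assigned$sample_id, strain_id = assigned$strain_id,
    assigned_reads = assigned$assigned_reads,
    rel_abundance = rel, abs_abundance = abs_ab,
    detection_limit = limit, detected = detected,
    total_copies = total_copies[i], stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  out
}
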