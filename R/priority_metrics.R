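# Join the abundance table with per-sample arrival-order roles.
abundance_with_roles <- function(tab, design) {
  roles <- sample_strain_roles(design)
  merge(as.data.frame(tab), roles, by = c("sample_id", "strain_id"))
}

# Full-community sequential samples (AB/BA, no dropout) for one strain and
# optionally one combination.
focal_subset <- function(tab, design, strain, combination = NULL,
                         detected_only = FALSE) {
  d <- abundance_with_roles(tab, design)
  d <- d[d$strain_id == strain & d$role %in% c("first", "late") &
           is.na(d$dropout_strain), , drop = FALSE]
  if (!is.null(combination)) d <- d[d$combination == combination, ,
                                    drop = FALSE]
  if (detected_only) d <- d[d$detected, , drop = FALSE]
  d
}

#' Priority-effect strength of a strain in one community combination
#'
#' The strength is the log10 ratio of the strain's median absolute abundance
#' when it arrived as a firstcomer (Day 0, treatment AB or BA depending on
#' which community carries it) versus as a latecomer (Day 3). Zero means no
#' priority effect. Medians are taken over all retained bees of the relevant
#' sequential treatments, including undetected values stored as 1 (the
#' plotting/log-transform convention); single-community positive controls
#' and dropout treatments are excluded. Both medians are strictly positive
#' by the undetected-as-1 rule, so the ratio is always defined.
#'
#' @param tab an `abundance_table` (see [compute_abundances()]).
#' @param design a `pe_design`.
#' @param strain focal strain id (must be private to one community of the
#'   combination; shared strains have no first/late contrast).
#' @param combination combination number.
#' @param include_undetected include undetected (=1) values in the medians
#'   (default TRUE); `FALSE` restricts to detected samples.
#' @return data.frame with `strain_id`, `combination`, `median_first`,
#'   `median_late`, `strength`, `n_first`, `n_late`.
#' @export
priority_effect_strength <- function(tab, design, strain, combination,
                                     include_undetected = TRUE) {
  d <- focal_subset(tab, design, strain, combination,
                    detected_only = !include_undetected)
  if (nrow(d) == 0L)
    stop2("strain ", strain, " is not a firstcomer/latecomer in any ",
          "sequential sample of combination ", combination,
          " (not in either inoculum, or shared between communities)")
  first <- d$abs_abundance[d$role == "first"]
  late <- d$abs_abundance[d$role == "late"]
  if (!length(first) || !length(late))
    stop2("need at least one bee in each of the AB and BA treatments")
  data.frame(strain_id = strain, combination = combination,
             median_first = median(first), median_late = median(late),
             strength = log10(median(first) / median(late)),
             n_first = length(first), n_late = length(late),
             stringsAsFactors = FALSE)
}

#' Priority-effect strength for every focal strain and combination
#'
#' @inheritParams priority_effect_strength
#' @return data.frame, one row per focal strain x combination.
#' @export
strength_table <- function(tab, design, include_undetected = TRUE) {
  focal <- design$strains$strain_id[design$strains$focal]
  ks <- unique(design$combinations$combination)
  rows <- list()
  for (s in focal) for (k in ks)
    rows[[length(rows) + 1L]] <-
      priority_effect_strength(tab, design, s, k, include_undetected)
  do.call(rbind, rows)
}

#' Colonization frequency by arrival order with Fisher's exact test
#'
#' Percentage of samples in which the strain was detected among firstcomer
#' vs latecomer bees (full-community sequential treatments, pooled across
#' combinations unless one is given), with a two-sided Fisher exact test on
#' the 2x2 detected-by-arrival table.
#'
#' @inheritParams priority_effect_strength
#' @param combination optional combination number; default pools all.
#' @return list with `percent_first`, `percent_late`, `n_first`, `n_late`,
#'   `detected_first`, `detected_late`, `p` (NA with a flag if a group is
#'   empty).
#' @export
colonization_frequency <- function(tab, design, strain, combination = NULL) {
  d <- focal_subset(tab, design, strain, combination)
  n1 <- sum(d$role == "first"); n2 <- sum(d$role == "late")
  d1 <- sum(d$detected[d$role == "first"])
  d2 <- sum(d$detected[d$role == "late"])
  if (n1 == 0L || n2 == 0L)
    return(list(percent_first = NA_real_, percent_late = NA_real_,
                n_first = n1, n_late = n2, detected_first = d1,
                detected_late = d2, p = NA_real_, insufficient = TRUE))
  p <- fisher.test(matrix(c(d1, n1 - d1, d2, n2 - d2), nrow = 2),
                   alternative = "two.sided")$p.value
  list(percent_first = 100 * d1 / n1, percent_late = 100 * d2 / n2,
       n_first = n1, n_late = n2, detected_first = d1, detected_late = d2,
       p = p, insufficient = FALSE)
}

#' Wilcoxon contrast of absolute abundance by arrival order
#'
#' Two-sided Wilcoxon rank-sum test of absolute abundance between
#' firstcomer and latecomer samples in which the strain was detected.
#'
#' @inheritParams colonization_frequency
#' @return list with `p`, `n_first`, `n_late`, `insufficient` flag (TRUE
#'   when either detected group is empty).
#' @export
abundance_contrast <- function(tab, design, strain, combination = NULL) {
  d <- focal_subset(tab, design, strain, combination, detected_only = TRUE)
  x <- d$abs_abundance[d$role == "first"]
  y <- d$abs_abundance[d$role == "late"]
  if (!length(x) || !length(y))
    return(list(p = NA_real_, n_first = length(x), n_late = length(y),
                insufficient = TRUE))
  p <- if (length(unique(c(x, y))) == 1L) 1 else
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
  list(p = p, n_first = length(x), n_late = length(y), insufficient = FALSE)
}

#' Arrival-order contrasts for all focal strains with BH correction
#'
#' @inheritParams colonization_frequency
#' @param adjust apply Benjamini-Hochberg correction across strains.
#' @return data.frame with per-strain Fisher and Wilcoxon results and
#'   (optionally) BH-adjusted p-values.
#' @export
contrast_table <- function(tab, design, combination = NULL, adjust = TRUE) {
  focal <- design$strains$strain_id[design$strains$focal]
  rows <- lapply(focal, function(s) {
    cf <- colonization_frequency(tab, design, s, combination)
    ac <- abundance_contrast(tab, design, s, combination)
    data.frame(strain_id = s, percent_first = cf$percent_first,
               percent_late = cf$percent_late, n_first = cf$n_first,
               n_late = cf$n_late, fisher_p = cf$p, wilcox_p = ac$p,
               wilcox_n_first = ac$n_first, wilcox_n_late = ac$n_late,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$fisher_p_adj <- p.adjust(out$fisher_p, method = "BH")
    out$wilcox_p_adj <- p.adjust(out$wilcox_p, method = "BH")
  }
  out
}

#' Per-sample summed abundance of a species, one- vs two-strain treatments
#'
#' Sums absolute abundance over the conspecific strains inoculated into each
#' sample (undetected strains contribute 1) and contrasts samples where one
#' strain of the species was inoculated (single-community controls) against
#' samples with both strains (sequential treatments), by two-sided Wilcoxon
#' test. Equal totals indicate the species reaches carrying capacity
#' regardless of how many conspecific strains compete for it.
#'
#' @inheritParams priority_effect_strength
#' @param species species id.
#' @return list with `per_sample` (data.frame `sample_id`, `n_strains`,
#'   `total_abundance`), `median_one`, `median_two`, `p`.
#' @export
species_totals <- function(tab, design, species) {
  strains <- design$strains$strain_id[design$strains$species_id == species]
  d <- abundance_with_roles(tab, design)
  d <- d[d$strain_id %in% strains & is.na(d$dropout_strain), , drop = FALSE]
  agg <- aggregate(abs_abundance ~ sample_id, data = d, FUN = sum)
  nst <- aggregate(strain_id ~ sample_id, data = d,
                   FUN = function(x) length(unique(x)))
  per <- data.frame(sample_id = agg$sample_id,
                    n_strains = nst$strain_id[match(agg$sample_id,
                                                    nst$sample_id)],
                    total_abundance = agg$abs_abundance,
                    stringsAsFactors = FALSE)
  one <- per$total_abundance[per$n_strains == 1L]
  two <- per$total_abundance[per$n_strains == 2L]
  p <- if (length(one) && length(two))
    suppressWarnings(wilcox.test(one, two))$p.value else NA_real_
  list(per_sample = per,
       median_one = if (length(one)) median(one) else NA_real_,
       median_two = if (length(two)) median(two) else NA_real_, p = p)
}

#' Dropout rescue percentage for a latecomer strain
#'
#' Positions the strain's median abundance in the dropout treatment (its
#' conspecific firstcomer omitted) between its median as a latecomer in the
#' full community (0%) and as a firstcomer (100%):
#' `100 * (med_dropout - med_late) / (med_first - med_late)`.
#' Only samples in which the strain was above the detection limit enter the
#' medians. The percentage is invariant to rescaling all three medians.
#'
#' @inheritParams priority_effect_strength
#' @return data.frame with `strain_id`, `med_first`, `med_late`,
#'   `med_dropout`, `rescue_percent`, `n_first`, `n_late`, `n_dropout`,
#'   `undefined` flag (TRUE when `med_first == med_late` or a group is
#'   empty).
#' @export
rescue_percent <- function(tab, design, strain) {
  d <- abundance_with_roles(tab, design)
  d <- d[d$strain_id == strain & d$detected, , drop = FALSE]
  sp_of <- setNames(design$strains$species_id, design$strains$strain_id)
  full <- d[is.na(d$dropout_strain), , drop = FALSE]
  drop <- d[!is.na(d$dropout_strain) & d$role == "late" &
              sp_of[d$dropout_strain] == sp_of[[strain]], , drop = FALSE]
  first <- full$abs_abundance[full$role == "first"]
  late <- full$abs_abundance[full$role == "late"]
  dropv <- drop$abs_abundance
  out <- data.frame(strain_id = strain,
                    med_first = if (length(first)) median(first) else NA,
                    med_late = if (length(late)) median(late) else NA,
                    med_dropout = if (length(dropv)) median(dropv) else NA,
                    rescue_percent = NA_real_,
                    n_first = length(first), n_late = length(late),
                    n_dropout = length(dropv), undefined = TRUE,
                    stringsAsFactors = FALSE)
  if (!anyNA(out[, c("med_first", "med_late", "med_dropout")]) &&
      out$med_first != out$med_late) {
    out$rescue_percent <- 100 * (out$med_dropout - out$med_late) /
      (out$med_first - out$med_late)
    out$undefined <- FALSE
  }
  out
}

#' Spearman correlation of total bacterial load with strain richness
#'
#' Correlates each sample's total 16S copies with its number of detected
#' strains (average-rank tie handling). A strong positive correlation would
#' indicate that richer communities carry more bacteria; independence
#' supports colonization to a fixed carrying capacity.
#'
#' @param tab an `abundance_table`.
#' @return list with `rho`, `p`, `n` and a `constant` flag (TRUE with NA
#'   estimates when either variable is constant).
#' @export
load_richness_correlation <- function(tab) {
  d <- as.data.frame(tab)
  load <- tapply(d$total_copies, d$sample_id, function(x) x[1])
  rich <- tapply(d$detected, d$sample_id, sum)
  if (length(load) < 3L) stop2("need at least 3 samples")
  if (length(unique(load)) == 1L || length(unique(rich)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = length(load),
                constant = TRUE))
  ct <- suppressWarnings(cor.test(as.numeric(load), as.numeric(rich),
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(load),
       constant = FALSE)
}
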