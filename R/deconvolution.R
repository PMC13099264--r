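#' Infer per-strain read counts from an ASV count vector
#'
#' Solves the constrained least-squares problem
#' \deqn{\hat s = \arg\min_{s \ge 0} \| M_c s - y \|_2}
#' where \eqn{M_c} is the copy matrix restricted to the candidate strains
#' (the strains inoculated into the sample) and \eqn{y} the observed counts
#' of the reference ASVs. The non-negativity constraint is enforced with the
#' Lawson--Hanson active-set algorithm, since negative strain counts are
#' physically meaningless. Each strain unit \eqn{s_i} is a genome-equivalent
#' contributing as many reads as its 16S copy number, so
#' `assigned_reads[i] = s_i * copy_total[i]`, rescaled to sum to the number
#' of known reads (reads matching any reference ASV). Counts of ASVs absent
#' from the copy matrix accumulate into `unknown_reads` and take no part in
#' the fit.
#'
#' @param asv_counts named non-negative numeric vector; names are matched
#'   first against `cm$asv_ids`, then against `cm$sequences`; unmatched
#'   entries are counted as unknown reads.
#' @param cm a [build_copy_matrix()] result.
#' @param candidates character vector of strain ids to fit (subset of
#'   `cm$strain_ids`); strains not listed always receive zero.
#' @param allow_ambiguous if the candidate submatrix is column-rank
#'   deficient, error (default) or return the active-set solution flagged as
#'   ambiguous.
#' @param weighting residual weighting scheme: `"none"` (ordinary
#'   unweighted least squares on counts) or `"poisson"`
#'   (inverse-count-variance weights `1 / max(y_a, 1)`, i.e. Pearson
#'   residuals under Poisson counting noise). Unweighted residuals let
#'   small relative misfits on high-count ASVs -- e.g. from per-ASV
#'   amplification-efficiency differences -- outweigh the few reads on a
#'   rare strain's private ASV and zero that strain out; Poisson weighting
#'   compares residuals on the scale of their sampling noise and keeps rare
#'   strains identifiable. No per-ASV efficiency factors are estimated
#'   under either scheme.
#' @param weights optional positive per-ASV weight vector (same order as
#'   `cm$asv_ids`) applied as row weights \eqn{\sqrt{w}}; overrides
#'   `weighting`.
#' @return list of class `deconv_result`: `strain_units`, `assigned_reads`
#'   (both named by candidate strain), `residual_norm`, `known_reads`,
#'   `unknown_reads`, `ambiguous`, `all_zero` flags.
#' @examples
#' ref <- data.frame(
#'   strain_id = c("X", "X", "Y", "Y"), species_id = "sp", genus = "g",
#'   sequence = c("AAC", "CCA", "CCA", "GGA"), copies = c(2L, 1L, 2L, 1L))
#' cm <- build_copy_matrix(ref)
#' y <- setNames(as.numeric(cm$M %*% c(100, 50)), cm$asv_ids)
#' infer_strain_counts(y, cm, c("X", "Y"))
#' @export
infer_strain_counts <- function(asv_counts, cm, candidates,
                                allow_ambiguous = FALSE,
                                weighting = c("none", "poisson"),
                                weights = NULL) {
  weighting <- match.arg(weighting)
  candidates <- sort(unique(as.character(candidates)))
  unknown_ids <- setdiff(candidates, cm$strain_ids)
  if (length(unknown_ids))
    stop2("candidate strain(s) not in copy matrix: ",
          paste(unknown_ids, collapse = ", "))
  if (any(asv_counts < 0)) stop2("ASV counts must be non-negative")
  nm <- names(asv_counts)
  if (is.null(nm)) stop2("asv_counts must be named by ASV id or sequence")
  idx <- match(nm, cm$asv_ids)
  by_seq <- is.na(idx)
  idx[by_seq] <- match(nm[by_seq], cm$sequences)
  known <- sum(asv_counts[!is.na(idx)])
  unknown <- sum(asv_counts[is.na(idx)])

  y <- numeric(length(cm$asv_ids))
  ok <- !is.na(idx)
  y[idx[ok]] <- y[idx[ok]] + asv_counts[ok]

  Mc <- cm$M[, candidates, drop = FALSE]
  storage.mode(Mc) <- "double"
  ambiguous <- qr(Mc)$rank < ncol(Mc)
  if (ambiguous && !allow_ambiguous)
    stop2("candidate submatrix is rank deficient (strains not separable); ",
          "set allow_ambiguous = TRUE to get a flagged solution")
  if (is.null(weights) && weighting == "poisson")
    weights <- 1 / pmax(y, 1)
  if (!is.null(weights)) {
    if (length(weights) != nrow(Mc) || any(weights <= 0))
      stop2("weights must be positive, one per ASV row")
    sw <- sqrt(weights)
    Mw <- Mc * sw
    yw <- y * sw
  } else {
    Mw <- Mc
    yw <- y
  }

  all_zero <- all(y == 0)
  if (all_zero) {
    warning("all reference-ASV counts are zero; returning zero solution")
    s <- setNames(numeric(ncol(Mc)), candidates)
  } else {
    s <- setNames(nnls_solve(Mw, yw)$x, candidates)
  }
  assigned <- s * cm$copy_totals[candidates]
  if (sum(assigned) > 0) assigned <- assigned * known / sum(assigned)
  structure(
    list(strain_units = s, assigned_reads = assigned,
         residual_norm = sqrt(sum((Mc %*% s - y)^2)),
         known_reads = known, unknown_reads = unknown,
         ambiguous = ambiguous, all_zero = all_zero),
    class = "deconv_result"
  )
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("deconvolution:", x$known_reads, "known /", x$unknown_reads,
      "unknown reads; residual", format(x$residual_norm, digits = 4), "\n")
  print(round(x$assigned_reads, 2))
  invisible(x)
}

#' Exhaustive grid oracle for the deconvolution objective
#'
#' Minimizes \eqn{\|M_c s - y\|_2} over a non-negative grid by exhaustive
#' enumeration. Intended as an independent test oracle for
#' [infer_strain_counts()] on small systems only.
#'
#' @inheritParams infer_strain_counts
#' @param grid_step grid resolution in strain units.
#' @param expand search-box inflation beyond the data-derived upper bound.
#' @return list with `strain_units` (grid optimum) and `objective`
#'   (sum of squared residuals at the optimum).
#' @export
brute_force_oracle <- function(asv_counts, cm, candidates, grid_step,
                               expand = 1.25) {
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) > 3)
    stop2("grid oracle supports at most 3 candidate strains")
  nm <- names(asv_counts)
  idx <- match(nm, cm$asv_ids)
  by_seq <- is.na(idx)
  idx[by_seq] <- match(nm[by_seq], cm$sequences)
  y <- numeric(length(cm$asv_ids))
  ok <- !is.na(idx)
  y[idx[ok]] <- y[idx[ok]] + asv_counts[ok]
  Mc <- cm$M[, candidates, drop = FALSE]
  storage.mode(Mc) <- "double"
  upper <- vapply(seq_len(ncol(Mc)), function(j) {
    pos <- Mc[, j] > 0
    expand * max(y[pos] / Mc[pos, j])
  }, numeric(1))
  axes <- lapply(upper, function(u) seq(0, max(u, grid_step), by = grid_step))
  G <- as.matrix(expand.grid(axes))
  resid <- G %*% t(Mc)
  resid <- sweep(resid, 2, y)
  obj <- rowSums(resid^2)
  k <- which.min(obj)
  list(strain_units = setNames(as.numeric(G[k, ]), candidates),
       objective = obj[k])
}

#' Deconvolve every sample of an experiment
#'
#' Applies [infer_strain_counts()] to each column of an ASV count matrix,
#' restricting candidates to the strains inoculated into that sample
#' (closed-community fit) unless `open_community = TRUE`, in which case all
#' reference strains are fitted.
#'
#' @param counts numeric matrix, ASVs (rows, named by ASV id or sequence) x
#'   samples (columns, named by sample id).
#' @param cm a `copy_matrix`.
#' @param design an experiment design as returned by [generate_design()].
#' @param open_community fit all reference strains instead of the inoculated
#'   set.
#' @param weighting residual weighting (see [infer_strain_counts()]); the
#'   pipeline default is `"poisson"`, which keeps rare latecomer strains
#'   identifiable in the presence of per-ASV amplification bias.
#' @param ... passed to [infer_strain_counts()].
#' @return list with `assigned` (long data.frame: `sample_id`, `strain_id`,
#'   `assigned_reads`, `strain_units`) and `samples` (per-sample
#'   `known_reads`, `unknown_reads`, `total_reads`, `residual_norm`).
#' @export
deconvolve_samples <- function(counts, cm, design, open_community = FALSE,
                               weighting = "poisson", ...) {
  inoc <- sample_inocula(design)
  out_assigned <- vector("list", ncol(counts))
  out_samples <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    cand <- if (open_community) cm$strain_ids else {
      stopifnot(sid %in% names(inoc))
      inoc[[sid]]
    }
    res <- infer_strain_counts(counts[, j], cm, cand,
                               weighting = weighting, ...)
    out_assigned[[j]] <- data.frame(
      sample_id = sid, strain_id = names(res$assigned_reads),
      assigned_reads = as.numeric(res$assigned_reads),
      strain_units = as.numeric(res$strain_units),
      stringsAsFactors = FALSE)
    out_samples[[j]] <- data.frame(
      sample_id = sid, known_reads = res$known_reads,
      unknown_reads = res$unknown_reads,
      total_reads = res$known_reads + res$unknown_reads,
      residual_norm = res$residual_norm, stringsAsFactors = FALSE)
  }
  list(assigned = do.call(rbind, out_assigned),
       samples = do.call(rbind, out_samples))
}
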