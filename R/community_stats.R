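#' Sample-by-strain matrix of log10 absolute abundance
#'
#' Pivots an abundance table to a wide matrix of log10(16S copies).
#' Undetected entries (stored as exactly 1) become 0; strains never
#' inoculated into a sample are also 0. Values below 1 violate the
#' undetected-as-1 contract and raise an error.
#'
#' @param tab an `abundance_table`.
#' @return numeric matrix, samples x strains.
#' @export
log_abundance_matrix <- function(tab) {
  d <- as.data.frame(tab)
  if (any(d$abs_abundance < 1))
    stop2("absolute abundances below 1 found; undetected values must be ",
          "stored as 1 (upstream contract violation)")
  samples <- unique(d$sample_id)
  strains <- sort(unique(d$strain_id))
  m <- matrix(0, nrow = length(samples), ncol = length(strains),
              dimnames = list(samples, strains))
  m[cbind(match(d$sample_id, samples), match(d$strain_id, strains))] <-
    log10(d$abs_abundance)
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on non-negative
#' sample profiles (here typically log10 abundances). A pair of all-zero
#' samples is defined as distance 0 with a warning. Bray-Curtis is a
#' semi-metric; the triangle inequality is not guaranteed.
#'
#' @param m non-negative numeric matrix, samples x features.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  if (any(m < 0)) stop2("Bray-Curtis requires non-negative input")
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(!is.finite(d))) {
    warning("all-zero sample pair(s); their dissimilarity is set to 0")
    d[!is.finite(d)] <- 0
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities (Gower matrix) and
#' eigendecomposes; axes are ordered by eigenvalue and negative eigenvalues
#' (possible for semi-metrics like Bray-Curtis) are reported, not dropped.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param k number of axes to return (default all n - 1).
#' @return list with `points` (samples x axes) and `eig` (all eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop2("dissimilarity matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop2("diagonal must be zero")
  n <- nrow(d)
  if (is.null(k)) k <- n - 1L
  # cmdscale warns when fewer than k eigenvalues are positive; the full
  # eigenvalue vector (including zeros/negatives) is returned regardless
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  pts <- fit$points
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig)
}

# One-way PERMANOVA sums of squares from a squared-dissimilarity matrix.
# group_idx: list of integer index vectors, one per group.
permanova_ss <- function(D2, group_idx) {
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (idx in group_idx)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA with permutation p-value and omega-squared effect size
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components, forms the pseudo-F statistic
#' \eqn{F = (SS_B / (a-1)) / (SS_W / (n-a))}, and assesses it against
#' `n_permutations` random relabelings:
#' \eqn{p = (1 + \#\{F_{perm} \ge F\}) / (1 + n_{perm})}. The
#' bias-corrected effect size is
#' \eqn{\omega^2 = (SS_B - (a-1) MS_W) / (SS_T + MS_W)}, which shrinks the
#' raw \eqn{R^2 = SS_B / SS_T} towards zero under the null.
#'
#' @param d dissimilarity matrix (square symmetric, zero diagonal).
#' @param groups factor or vector of group labels, one per sample; at least
#'   two groups with at least two samples each.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed; permutation p-values are bit-reproducible
#'   given (d, groups, seed, n_permutations).
#' @return list of class `permanova_result`: `F`, `R2`, `omega2`, `p`,
#'   `ss` (total/within/between), `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d))
    stop2("one group label per sample required")
  tabn <- table(groups)
  if (length(tabn) < 2L) stop2("need at least two groups")
  if (any(tabn < 2L)) stop2("every group needs at least two samples")
  if (missing(seed)) stop2("seed is required for reproducible permutations")
  n <- nrow(d)
  a <- length(tabn)
  D2 <- d^2
  obs_idx <- split(seq_len(n), groups)
  ss <- permanova_ss(D2, obs_idx)
  ms_within <- ss["within"] / (n - a)
  f_obs <- (ss["between"] / (a - 1)) / ms_within
  r2 <- ss["between"] / ss["total"]
  omega2 <- (ss["between"] - (a - 1) * ms_within) /
    (ss["total"] + ms_within)
  sizes <- as.integer(tabn)
  grp_sizes <- rep(seq_len(a), sizes)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      # random relabeling: the first size_1 shuffled samples form group 1, etc.
      perm <- sample.int(n)
      idx <- split(perm, grp_sizes)
      ssb <- permanova_ss(D2, idx)
      f_perm <- (ssb["between"] / (a - 1)) / (ssb["within"] / (n - a))
      if (f_perm >= f_obs) exceed <- exceed + 1L
    }
  })
  structure(list(
    F = unname(f_obs), R2 = unname(r2), omega2 = unname(omega2),
    p = (1 + exceed) / (1 + n_permutations),
    ss = unname(ss), df = c(between = a - 1, within = n - a),
    n_permutations = n_permutations, seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one-way, %d permutations): F = %.3f, R2 = %.3f, omega2 = %.3f, p = %.4g\n",
    x$n_permutations, x$F, x$R2, x$omega2, x$p))
  invisible(x)
}

#' Gamma log-link mixed model of abundance on arrival order
#'
#' Fits `abs_abundance ~ order + (1 | combination)` with a Gamma
#' distribution and log link (appropriate for positive continuous
#' abundances; the undetected-as-1 rule keeps the response positive) for a
#' single focal strain across full-community samples. Arrival order has
#' levels `first` (reference), `second` (latecomer) and `only`
#' (single-community control); a negative, significant `second` coefficient
#' indicates reduced colonization when arriving late.
#'
#' @inheritParams priority_effect_strength
#' @return list with `coefficients` (data.frame: term, estimate (natural
#'   log scale), std_error, z, p), `converged`, `messages`, and the fitted
#'   `model`.
#' @export
gamma_glmm <- function(tab, design, strain) {
  d <- abundance_with_roles(tab, design)
  d <- d[d$strain_id == strain & is.na(d$dropout_strain) &
           d$role %in% c("first", "late", "only"), , drop = FALSE]
  if (length(unique(d$combination)) < 2L)
    stop2("grouping factor needs >= 2 community combinations")
  d$order <- factor(ifelse(d$role == "late", "second", d$role),
                    levels = c("first", "second", "only"))
  d$combination <- factor(d$combination)
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(abs_abundance ~ order + (1 | combination), data = d,
                  family = stats::Gamma(link = "log")),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error"))
    return(list(coefficients = NULL, converged = FALSE,
                messages = conditionMessage(fit), model = NULL))
  sm <- summary(fit)$coefficients
  # Gamma-family merMod summaries report "t value" and no p-column (the
  # dispersion is estimated); use Wald z on the asymptotic normal scale
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- est / se
  co <- data.frame(term = rownames(sm), estimate = est, std_error = se,
                   z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE,
                   row.names = NULL)
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  list(coefficients = co, converged = conv, messages = msgs, model = fit)
}
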