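#' Scenario configuration for synthetic sequential-colonization experiments
#'
#' Defines the full set of study conditions emulated by the generator: a
#' 12-species community (2 *Bombilactobacillus*, 4 *Lactobacillus*, 6
#' *Bifidobacterium* species), 22 strains (the two *Bombilactobacillus*
#' species carry a single strain shared between communities; every other
#' species carries two strains, one per community), six community
#' combinations obtained by shuffling strains between communities A and B,
#' four treatments (A, B = single-community controls inoculated on Day 0;
#' AB, BA = sequential inoculation on Day 0 and Day 3) with ~10 bees each,
#' per-strain latecomer suppression (the seeded priority-effect strength,
#' log10 units), per-ASV amplification bias, multinomial read sampling, and
#' Gaussian Ct noise on the qPCR readout.
#'
#' @param seed integer master seed; every stage derives its own stream from
#'   it, so a scenario is fully reproducible.
#' @param bees_per_treatment bees per cage (default 10).
#' @param n_combinations community combinations (default 6).
#' @param depth sequencing reads per sample (default 1e4).
#' @param carrying_capacity median total 16S copies per gut (default 1e8).
#' @param load_sdlog lognormal sd (natural log) of the total load.
#' @param dirichlet_alpha symmetric Dirichlet concentration for species
#'   shares (moderate evenness at the default 5).
#' @param strength optional scalar: sets the same log10 latecomer
#'   suppression for every focal strain (e.g. `strength = 3` gives the
#'   strong-dominance scenario). When `NULL`, the default `strength_map`
#'   spreads per-strain suppressions evenly over \[0.5, 1.6\], the range
#'   over which latecomer abundances stay above the per-sample detection
#'   limit at the default depth (stronger suppression censors the latecomer
#'   below the detection limit, as observed for several strains in real
#'   data, and its strength is then not point-recoverable).
#' @param strength_map named numeric vector of per-strain log10 suppressions
#'   for the 20 focal strains; overrides `strength`.
#' @param strength_noise_sd per-bee lognormal noise (sd on the log10 scale)
#'   on latecomer suppression.
#' @param snp_divergence SNPs separating conspecific strains in the variant
#'   allele (default 2).
#' @param alleles_range range of 16S alleles per strain.
#' @param allele_len_range allele length range in nt.
#' @param efficiency_bias_sd sd (natural log) of the fixed per-ASV
#'   amplification-efficiency factor.
#' @param unknown_read_frac expected fraction of reads emitted as ASVs
#'   absent from the reference.
#' @param n_unknown_asvs number of junk ASVs carrying the unknown reads.
#' @param qpcr_noise_sd Gaussian noise on Ct, in cycles.
#' @param curve a [qpcr_curve()] used both to emit Ct values and (by the
#'   pipeline) to invert them.
#' @param include_dropout add dropout treatments (firstcomer community with
#'   one focal strain omitted) in combination 1, both reciprocal directions,
#'   for `dropout_species`.
#' @param dropout_species species ids receiving dropout treatments.
#' @param rescue_level expected fractional recovery of a latecomer towards
#'   the firstcomer level when its conspecific firstcomer is dropped
#'   (0 = no rescue, 1 = full rescue; default 0.3).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            bees_per_treatment = 10,
                            n_combinations = 6,
                            depth = 1e4,
                            carrying_capacity = 1e8,
                            load_sdlog = 0.5,
                            dirichlet_alpha = 5,
                            strength = NULL,
                            strength_map = NULL,
                            strength_noise_sd = 0.3,
                            snp_divergence = 2,
                            alleles_range = c(2L, 4L),
                            allele_len_range = c(1200L, 1550L),
                            efficiency_bias_sd = 0.05,
                            unknown_read_frac = 0.02,
                            n_unknown_asvs = 5,
                            qpcr_noise_sd = 0.3,
                            curve = qpcr_curve(),
                            include_dropout = TRUE,
                            dropout_species = c("Lact_sp01", "Bifi_sp01",
                                                "Bifi_sp02"),
                            rescue_level = 0.3) {
  species <- species_layout()
  strains <- strain_layout(species)
  focal <- strains$strain_id[strains$focal]
  if (is.null(strength_map)) {
    strength_map <- if (!is.null(strength))
      setNames(rep(strength, length(focal)), focal)
    else
      setNames(seq(0.5, 1.6, length.out = length(focal)), focal)
  }
  missing_strength <- setdiff(focal, names(strength_map))
  if (length(missing_strength))
    stop2("strength_map lacks focal strain(s): ",
          paste(missing_strength, collapse = ", "))
  stopifnot(bees_per_treatment >= 1, n_combinations >= 1, depth >= 1,
            carrying_capacity > 0, snp_divergence >= 0,
            all(dropout_species %in% species$species_id))
  structure(list(
    seed = as.integer(seed), species = species, strains = strains,
    bees_per_treatment = bees_per_treatment,
    n_combinations = n_combinations, depth = depth,
    carrying_capacity = carrying_capacity, load_sdlog = load_sdlog,
    dirichlet_alpha = dirichlet_alpha, strength_map = strength_map,
    strength_noise_sd = strength_noise_sd,
    snp_divergence = as.integer(snp_divergence),
    alleles_range = as.integer(alleles_range),
    allele_len_range = as.integer(allele_len_range),
    efficiency_bias_sd = efficiency_bias_sd,
    unknown_read_frac = unknown_read_frac,
    n_unknown_asvs = as.integer(n_unknown_asvs),
    qpcr_noise_sd = qpcr_noise_sd, curve = curve,
    include_dropout = include_dropout, dropout_species = dropout_species,
    rescue_level = rescue_level
  ), class = "scenario_config")
}

# Fixed 12-species community layout (2/4/6 per genus).
species_layout <- function() {
  data.frame(
    species_id = c(sprintf("Bomb_sp%02d", 1:2), sprintf("Lact_sp%02d", 1:4),
                   sprintf("Bifi_sp%02d", 1:6)),
    genus = rep(c("Bombilactobacillus", "Lactobacillus", "Bifidobacterium"),
                times = c(2, 4, 6)),
    n_strains = rep(c(1L, 2L), times = c(2, 10)),
    stringsAsFactors = FALSE
  )
}

# 22 strains: shared (1-strain) species first, then 2 strains per focal
# species; focal = strains private to one community in any combination.
strain_layout <- function(species) {
  rows <- lapply(seq_len(nrow(species)), function(i) {
    data.frame(species_id = species$species_id[i], genus = species$genus[i],
               slot = seq_len(species$n_strains[i]),
               focal = species$n_strains[i] == 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$strain_id <- sprintf("STR%02d", seq_len(nrow(out)))
  out[, c("strain_id", "species_id", "genus", "slot", "focal")]
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_snps <- function(seq, n_snps) {
  if (n_snps == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_snps)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a synthetic strain reference
#'
#' Draws random full-length 16S alleles (1200--1550 nt) for every strain.
#' Conspecific strains share all alleles except one variant allele that
#' differs by `snp_divergence` SNPs, so each strain owns at least one
#' private ASV (discriminable, full-rank copy matrix) while conspecifics
#' also share ASVs, exercising the non-trivial part of the deconvolution.
#' Deterministic under the scenario seed.
#'
#' @param cfg a [scenario_config()].
#' @return strain allele table (see [load_allele_fasta()]).
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed * 10L + 1L, {
    out <- list()
    for (i in seq_len(nrow(cfg$species))) {
      sp <- cfg$species[i, ]
      strains <- cfg$strains[cfg$strains$species_id == sp$species_id, ]
      n_all <- sample(seq(cfg$alleles_range[1], cfg$alleles_range[2]), 1)
      lens <- sample(seq(cfg$allele_len_range[1], cfg$allele_len_range[2]),
                     n_all, replace = TRUE)
      base <- vapply(lens, random_dna, character(1))
      copies <- sample(1:2, n_all, replace = TRUE)
      for (j in seq_len(nrow(strains))) {
        alle <- base
        if (j == 2L) alle[1] <- mutate_snps(base[1], cfg$snp_divergence)
        out[[length(out) + 1L]] <- data.frame(
          strain_id = strains$strain_id[j], species_id = sp$species_id,
          genus = sp$genus, sequence = alle, copies = copies,
          stringsAsFactors = FALSE)
      }
    }
    merge_alleles(do.call(rbind, out))
  })
}

# Six binary shuffle vectors over the focal species with pairwise Hamming
# distance in [4, 6]. A focal strain keeps its community between two
# combinations when its species' flip is equal, and switches otherwise; the
# number of background species replaced is then (distance - 1) or
# (n_focal - distance) respectively, so bounding the distance on both sides
# guarantees >= 3 replaced species, i.e. a background differing by >= 6
# strains -- above the 5-strain design rule.
shuffle_vectors <- function(n_comb, n_focal, min_dist = 4L, max_dist = 6L) {
  acc <- matrix(0L, nrow = 0, ncol = n_focal)
  tries <- 0L
  while (nrow(acc) < n_comb) {
    cand <- sample(0:1, n_focal, replace = TRUE)
    d <- if (nrow(acc) == 0) integer(0) else
      rowSums(acc != matrix(cand, nrow(acc), n_focal, byrow = TRUE))
    if (all(d >= min_dist & d <= max_dist)) acc <- rbind(acc, cand)
    tries <- tries + 1L
    if (tries > 100000L) stop2("could not satisfy shuffle constraints")
  }
  unname(acc)
}

#' Verify the background-difference design rule
#'
#' For every focal strain and every pair of community combinations, counts
#' the strains by which the rest of the strain's community (its background,
#' 11 strains) differs between the two combinations (symmetric difference).
#'
#' @param design a `pe_design`.
#' @return the minimum background difference over all focal strains and
#'   combination pairs (the design targets >= 5).
#' @export
design_background_check <- function(design) {
  combos <- design$combinations
  focal <- design$strains$strain_id[design$strains$focal]
  ks <- unique(combos$combination)
  community_of <- function(k, strain) {
    ck <- combos[combos$combination == k, ]
    if (strain %in% ck$strain_A) ck$strain_A else ck$strain_B
  }
  worst <- Inf
  for (s in focal) for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (i >= j) next
    b1 <- setdiff(community_of(ks[i], s), s)
    b2 <- setdiff(community_of(ks[j], s), s)
    worst <- min(worst, length(setdiff(b1, b2)) + length(setdiff(b2, b1)))
  }
  worst
}

#' Generate the experimental design
#'
#' Builds the community combinations (which strain of each focal species
#' sits in community A vs B, shuffled so each strain meets a background
#' differing by at least five strains across combinations), the cage/sample
#' table for the four treatments, and optional dropout treatments in which
#' one focal firstcomer strain is omitted from the Day-0 inoculum while the
#' full latecomer community arrives on Day 3.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `pe_design` with `species`, `strains`,
#'   `combinations` (combination x species: `strain_A`, `strain_B`) and
#'   `samples` (`sample_id`, `bee_id`, `combination`, `treatment`,
#'   `dropout_strain`).
#' @export
generate_design <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed * 10L + 2L, {
    focal_sp <- cfg$species$species_id[cfg$species$n_strains == 2L]
    flips <- shuffle_vectors(cfg$n_combinations, length(focal_sp))
    combos <- list()
    for (k in seq_len(cfg$n_combinations)) {
      for (i in seq_len(nrow(cfg$species))) {
        sp <- cfg$species$species_id[i]
        st <- cfg$strains$strain_id[cfg$strains$species_id == sp]
        if (length(st) == 1L) {
          a <- b <- st
        } else {
          f <- flips[k, match(sp, focal_sp)]
          a <- st[1L + f]; b <- st[2L - f]
        }
        combos[[length(combos) + 1L]] <- data.frame(
          combination = k, species_id = sp, strain_A = a, strain_B = b,
          stringsAsFactors = FALSE)
      }
    }
    combos <- do.call(rbind, combos)
    samples <- list()
    add_cage <- function(k, trt, drop) {
      tag <- if (is.na(drop)) trt else paste0(trt, "drop", drop)
      for (b in seq_len(cfg$bees_per_treatment)) {
        sid <- sprintf("C%d_%s_b%02d", k, tag, b)
        samples[[length(samples) + 1L]] <<- data.frame(
          sample_id = sid, bee_id = sid, combination = k, treatment = trt,
          dropout_strain = drop, stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(cfg$n_combinations))
      for (trt in c("A", "B", "AB", "BA")) add_cage(k, trt, NA_character_)
    if (cfg$include_dropout) {
      c1 <- combos[combos$combination == 1L, ]
      for (sp in cfg$dropout_species) {
        row <- c1[c1$species_id == sp, ]
        add_cage(1L, "AB", row$strain_A)  # firstcomer (community A) dropped
        add_cage(1L, "BA", row$strain_B)  # firstcomer (community B) dropped
      }
    }
    structure(list(species = cfg$species, strains = cfg$strains,
                   combinations = combos,
                   samples = do.call(rbind, samples)),
              class = "pe_design")
  })
}

# Day-0 / Day-3 strain sets per sample.
sample_day_sets <- function(design) {
  combos <- design$combinations
  out <- vector("list", nrow(design$samples))
  names(out) <- design$samples$sample_id
  for (i in seq_len(nrow(design$samples))) {
    s <- design$samples[i, ]
    ck <- combos[combos$combination == s$combination, ]
    A <- ck$strain_A; B <- ck$strain_B
    day0 <- switch(s$treatment, A = A, B = B, AB = A, BA = B)
    day3 <- switch(s$treatment, A = character(0), B = character(0),
                   AB = B, BA = A)
    if (!is.na(s$dropout_strain)) day0 <- setdiff(day0, s$dropout_strain)
    out[[i]] <- list(day0 = unique(day0), day3 = unique(day3))
  }
  out
}

#' Candidate (inoculated) strains per sample
#'
#' @param design a `pe_design`.
#' @return named list, sample id to character vector of inoculated strains.
#' @export
sample_inocula <- function(design) {
  lapply(sample_day_sets(design), function(d) sort(union(d$day0, d$day3)))
}

#' Arrival-order role of every inoculated strain in every sample
#'
#' Roles: `"only"` (single-community control), `"first"` / `"late"`
#' (sequential treatments), `"shared"` (strain present in both inocula of a
#' sequential treatment, i.e. the non-focal species). Dropped strains are
#' absent and carry no row.
#'
#' @param design a `pe_design`.
#' @return data.frame `sample_id`, `strain_id`, `role`, `combination`,
#'   `treatment`, `dropout_strain`.
#' @export
sample_strain_roles <- function(design) {
  dsets <- sample_day_sets(design)
  rows <- vector("list", nrow(design$samples))
  for (i in seq_len(nrow(design$samples))) {
    s <- design$samples[i, ]
    d <- dsets[[s$sample_id]]
    strains <- union(d$day0, d$day3)
    role <- vapply(strains, function(x) {
      in0 <- x %in% d$day0; in3 <- x %in% d$day3
      if (in0 && in3) "shared"
      else if (in0 && length(d$day3) == 0L) "only"
      else if (in0) "first" else "late"
    }, character(1))
    rows[[i]] <- data.frame(
      sample_id = s$sample_id, strain_id = strains, role = unname(role),
      combination = s$combination, treatment = s$treatment,
      dropout_strain = s$dropout_strain, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate ground-truth absolute abundances
#'
#' Observation model for the end-point (Day 10) community: per bee the total
#' load is lognormal around the carrying capacity; species shares are
#' symmetric-Dirichlet; within a species colonized by a firstcomer/latecomer
#' pair the latecomer's share is the firstcomer's share times
#' `10^(-strength + noise)`; a sole strain (control, shared species) takes
#' the whole species share; in a dropout treatment the orphaned latecomer
#' reaches `rescue_level + (1 - rescue_level) * 10^(-strength + noise)` of
#' its species share. Strain weights are renormalized so per-sample strain
#' abundances sum exactly to the total load. Colonization dynamics are not
#' simulated -- only the outcome distribution the analysis assumes.
#'
#' @param design a `pe_design`.
#' @param cfg the matching [scenario_config()].
#' @return list of class `pe_truth`: `truth` (long data.frame `sample_id`,
#'   `strain_id`, `abundance` in 16S copies) and `totals` (`sample_id`,
#'   `total_copies`).
#' @export
simulate_abundances <- function(design, cfg) {
  stopifnot(inherits(design, "pe_design"), inherits(cfg, "scenario_config"))
  roles <- sample_strain_roles(design)
  sp_of <- setNames(design$strains$species_id, design$strains$strain_id)
  n_sp <- nrow(design$species)
  with_seed(cfg$seed * 10L + 3L, {
    truth <- vector("list", nrow(design$samples))
    totals <- numeric(nrow(design$samples))
    by_sample <- split(roles, roles$sample_id)
    for (i in seq_len(nrow(design$samples))) {
      sid <- design$samples$sample_id[i]
      r <- by_sample[[sid]]
      total <- rlnorm(1, log(cfg$carrying_capacity), cfg$load_sdlog)
      shares <- setNames(rdirichlet1(n_sp, cfg$dirichlet_alpha),
                         design$species$species_id)
      w <- setNames(numeric(nrow(r)), r$strain_id)
      for (sp in unique(sp_of[r$strain_id])) {
        members <- r[sp_of[r$strain_id] == sp, ]
        share <- shares[[sp]]
        if (nrow(members) == 1L) {
          m <- members[1, ]
          if (m$role == "late" && !is.na(m$dropout_strain) &&
              sp_of[[m$dropout_strain]] == sp) {
            q <- 10^(-cfg$strength_map[[m$strain_id]] +
                       rnorm(1, 0, cfg$strength_noise_sd))
            # latecomer level q/(1+q) moved rescue_level of the way up to
            # the firstcomer level 1/(1+q)
            w[m$strain_id] <- share *
              (q + cfg$rescue_level * (1 - q)) / (1 + q)
          } else {
            w[m$strain_id] <- share
          }
        } else {
          first <- members$strain_id[members$role == "first"]
          late <- members$strain_id[members$role == "late"]
          stopifnot(length(first) == 1L, length(late) == 1L)
          q <- 10^(-cfg$strength_map[[late]] +
                     rnorm(1, 0, cfg$strength_noise_sd))
          w[first] <- share / (1 + q)
          w[late] <- share * q / (1 + q)
        }
      }
      ab <- w / sum(w) * total
      truth[[i]] <- data.frame(sample_id = sid, strain_id = names(ab),
                               abundance = as.numeric(ab),
                               stringsAsFactors = FALSE)
      totals[i] <- total
    }
    structure(list(truth = do.call(rbind, truth),
                   totals = data.frame(
                     sample_id = design$samples$sample_id,
                     total_copies = totals, stringsAsFactors = FALSE)),
              class = "pe_truth")
  })
}

#' Simulate ASV count tables and qPCR readings from ground truth
#'
#' Expected ASV read mass is \eqn{\sum_i t_i (M_{ai}/c_i) b_a}: truth in 16S
#' copies divided by the strain's total copy number (genome equivalents)
#' times its per-allele copy profile, times a fixed per-ASV lognormal
#' amplification-efficiency factor. Reads are multinomial at the configured
#' depth, with a configurable fraction routed to junk ASVs absent from the
#' reference. Ct values follow the configured standard curve on the true
#' total load plus Gaussian cycle noise.
#'
#' @param truth a [simulate_abundances()] result.
#' @param reference the strain allele table the truth was simulated for.
#' @param cfg the matching [scenario_config()].
#' @return list of class `pe_reads`: `counts` (integer matrix, ASV ids x
#'   sample ids, with per-row sequences in `attr(counts, "sequences")`),
#'   `qpcr` (`sample_id`, `ct`) and `bias` (per reference ASV).
#' @export
simulate_reads_and_qpcr <- function(truth, reference, cfg) {
  stopifnot(inherits(truth, "pe_truth"), inherits(cfg, "scenario_config"))
  cm <- build_copy_matrix(reference)
  with_seed(cfg$seed * 10L + 4L, {
    n_ref <- length(cm$asv_ids)
    bias <- exp(rnorm(n_ref, 0, cfg$efficiency_bias_sd))
    unk_seqs <- vapply(rep(1200L, cfg$n_unknown_asvs), random_dna,
                       character(1))
    unk_ids <- sprintf("UNK%02d", seq_len(cfg$n_unknown_asvs))
    sample_ids <- unique(truth$truth$sample_id)
    counts <- matrix(0L, nrow = n_ref + cfg$n_unknown_asvs,
                     ncol = length(sample_ids),
                     dimnames = list(c(cm$asv_ids, unk_ids), sample_ids))
    # per-genome allele profile: M[a,i] / copy_total[i]
    P <- sweep(cm$M, 2, cm$copy_totals, "/")
    tr <- split(truth$truth, truth$truth$sample_id)
    f <- cfg$unknown_read_frac
    for (sid in sample_ids) {
      t_i <- setNames(tr[[sid]]$abundance, tr[[sid]]$strain_id)
      v <- setNames(numeric(length(cm$strain_ids)), cm$strain_ids)
      v[names(t_i)] <- t_i
      mass <- as.numeric(P %*% v) * bias
      p <- c(mass / sum(mass) * (1 - f),
             rep(f / cfg$n_unknown_asvs, cfg$n_unknown_asvs))
      counts[, sid] <- rmultinom(1, cfg$depth, p)[, 1]
    }
    scaling <- cfg$curve$dilution_factor * cfg$curve$volume_scaling
    tot <- truth$totals[match(sample_ids, truth$totals$sample_id), ]
    ct <- cfg$curve$intercept +
      cfg$curve$slope * log10(tot$total_copies / scaling) +
      rnorm(length(sample_ids), 0, cfg$qpcr_noise_sd)
    attr(counts, "sequences") <- setNames(c(cm$sequences, unk_seqs),
                                          c(cm$asv_ids, unk_ids))
    structure(list(counts = counts,
                   qpcr = data.frame(sample_id = sample_ids, ct = ct,
                                     stringsAsFactors = FALSE),
                   bias = setNames(bias, cm$asv_ids)),
              class = "pe_reads")
  })
}

#' Simulate a complete synthetic experiment
#'
#' Chains [generate_reference()], [generate_design()],
#' [simulate_abundances()] and [simulate_reads_and_qpcr()].
#'
#' @param cfg a [scenario_config()].
#' @return list of class `pe_dataset` with `cfg`, `reference`, `design`,
#'   `truth`, `counts`, `qpcr`.
#' @export
simulate_experiment <- function(cfg = scenario_config()) {
  reference <- generate_reference(cfg)
  design <- generate_design(cfg)
  truth <- simulate_abundances(design, cfg)
  reads <- simulate_reads_and_qpcr(truth, reference, cfg)
  structure(list(cfg = cfg, reference = reference, design = design,
                 truth = truth, counts = reads$counts, qpcr = reads$qpcr),
            class = "pe_dataset")
}
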