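test_that("generation is deterministic under the seed", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  d1 <- tempfile(); d2 <- tempfile()
  write_reference(r1, d1); write_reference(r2, d2)
  expect_identical(readLines(file.path(d1, "reference.fasta")),
                   readLines(file.path(d2, "reference.fasta")))
  unlink(c(d1, d2), recursive = TRUE)

  ds1 <- simulate_experiment(cfg)
  ds2 <- simulate_experiment(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$qpcr, ds2$qpcr)

  # a different seed changes counts but not the design structure
  cfg3 <- scenario_config(seed = 43, bees_per_treatment = 4,
                          n_combinations = 2, depth = 2000)
  ds3 <- simulate_experiment(cfg3)
  expect_false(identical(ds3$counts, ds1$counts))
  expect_identical(dim(ds3$design$samples), dim(ds1$design$samples))
  expect_identical(ds3$design$samples$treatment, ds1$design$samples$treatment)
})

test_that("the reference emulates the 12-species / 22-strain community", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  expect_equal(length(unique(ref$strain_id)), 22)
  expect_equal(length(unique(ref$species_id)), 12)
  genus_counts <- table(unique(ref[, c("species_id", "genus")])$genus)
  expect_equal(as.integer(genus_counts[c("Bombilactobacillus",
                                         "Lactobacillus",
                                         "Bifidobacterium")]), c(2, 4, 6))
  expect_true(all(nchar(ref$sequence) >= 1000 & nchar(ref$sequence) <= 1600))
  expect_true(all(ref$copies >= 1))
})

test_that("the design balances arrival order and shuffles backgrounds", {
  ds <- get_ds_default()
  roles <- sample_strain_roles(ds$design)
  full <- roles[is.na(roles$dropout_strain), ]
  focal <- ds$design$strains$strain_id[ds$design$strains$focal]
  per_treatment <- unique(full[, c("strain_id", "combination", "treatment",
                                   "role")])
  for (s in focal[c(1, 7, 20)]) {
    mine <- per_treatment[per_treatment$strain_id == s, ]
    # one firstcomer and one latecomer cage per combination
    expect_equal(sum(mine$role == "first"), 6)
    expect_equal(sum(mine$role == "late"), 6)
    expect_equal(sum(mine$role == "only"), 6)
  }
  # every focal strain's background differs by >= 5 strains across combos
  expect_gte(design_background_check(ds$design), 5)
})

test_that("dropout cages omit the firstcomer strain but keep its partner", {
  ds <- get_ds_small()
  design <- ds$design
  drop_samples <- design$samples[!is.na(design$samples$dropout_strain), ]
  expect_gt(nrow(drop_samples), 0)
  dsets <- strainPriority:::sample_day_sets(design)
  strains <- design$strains
  for (i in seq_len(nrow(drop_samples))) {
    s <- drop_samples[i, ]
    dd <- dsets[[s$sample_id]]
    # dropped strain is in neither inoculum
    expect_false(s$dropout_strain %in% c(dd$day0, dd$day3))
    # its conspecific partner arrives on Day 3
    sp <- strains$species_id[strains$strain_id == s$dropout_strain]
    partner <- setdiff(strains$strain_id[strains$species_id == sp],
                       s$dropout_strain)
    expect_true(partner %in% dd$day3)
  }
})

test_that("ground truth conserves totals and species shares", {
  ds <- get_ds_small()
  tr <- ds$truth
  sums <- tapply(tr$truth$abundance, tr$truth$sample_id, sum)
  tot <- setNames(tr$totals$total_copies, tr$totals$sample_id)
  expect_equal(as.numeric(sums), as.numeric(tot[names(sums)]),
               tolerance = 1e-12)
  expect_true(all(tr$truth$abundance >= 0))
})

test_that("a null generator shows no priority effect", {
  cfg <- scenario_config(seed = 9, strength = 0, include_dropout = FALSE)
  design <- generate_design(cfg)
  truth <- simulate_abundances(design, cfg)
  tab <- truth_abundance_table(list(truth = truth, design = design))
  st <- strength_table(tab, design)
  per_strain <- tapply(st$strength, st$strain_id, median)
  # 10 bees x 6 combinations per strain: log10 ratio within +/- 0.2
  expect_true(all(abs(per_strain) < 0.2))
})

test_that("read sampling converges to the copy-weighted expectation", {
  cfg <- scenario_config(seed = 5, bees_per_treatment = 1,
                         n_combinations = 1, depth = 1e7,
                         efficiency_bias_sd = 0, unknown_read_frac = 0,
                         qpcr_noise_sd = 0, include_dropout = FALSE)
  ds <- simulate_experiment(cfg)
  cm <- build_copy_matrix(ds$reference)
  sid <- ds$design$samples$sample_id[ds$design$samples$treatment == "AB"][1]
  tr <- ds$truth$truth[ds$truth$truth$sample_id == sid, ]
  v <- setNames(numeric(length(cm$strain_ids)), cm$strain_ids)
  v[tr$strain_id] <- tr$abundance
  mass <- as.numeric(sweep(cm$M, 2, cm$copy_totals, "/") %*% v)
  expected <- mass / sum(mass)
  observed <- ds$counts[cm$asv_ids, sid] / sum(ds$counts[cm$asv_ids, sid])
  big <- expected >= 0.02
  expect_true(any(big))
  expect_lt(max(abs(observed[big] - expected[big]) / expected[big]), 0.01)
})

test_that("single strain with one allele puts all reads in one ASV", {
  cfg <- scenario_config(seed = 6, bees_per_treatment = 1,
                         n_combinations = 1, efficiency_bias_sd = 0,
                         unknown_read_frac = 0, include_dropout = FALSE)
  ref <- data.frame(strain_id = "STR01", species_id = "Bomb_sp01",
                    genus = "Bombilactobacillus",
                    sequence = strrep("ACGT", 300), copies = 4L)
  truth <- structure(list(
    truth = data.frame(sample_id = "s1", strain_id = "STR01",
                       abundance = 1e8),
    totals = data.frame(sample_id = "s1", total_copies = 1e8)),
    class = "pe_truth")
  reads <- simulate_reads_and_qpcr(truth, ref, cfg)
  counts <- reads$counts[, "s1"]
  expect_equal(sum(counts > 0), 1)
  expect_equal(sum(counts), cfg$depth)
})

test_that("unknown-read fraction is respected", {
  cfg <- scenario_config(seed = 8, bees_per_treatment = 2,
                         n_combinations = 1, unknown_read_frac = 0.05,
                         include_dropout = FALSE)
  ds <- simulate_experiment(cfg)
  cm <- build_copy_matrix(ds$reference)
  known <- colSums(ds$counts[cm$asv_ids, ])
  frac <- known / colSums(ds$counts)
  # binomial error around 1 - 0.05 at depth 1e4
  expect_true(all(abs(frac - 0.95) < 0.01))
})

test_that("qPCR readout inverts through the standard curve", {
  cfg <- scenario_config(seed = 10, bees_per_treatment = 2,
                         n_combinations = 1, qpcr_noise_sd = 0,
                         include_dropout = FALSE)
  ds <- simulate_experiment(cfg)
  est <- ct_to_copies(ds$qpcr$ct, cfg$curve)
  truth <- ds$truth$totals$total_copies[match(ds$qpcr$sample_id,
                                              ds$truth$totals$sample_id)]
  expect_equal(as.numeric(est), truth, tolerance = 1e-6)
})
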