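# Build a minimal abundance table for chosen (sample, strain) cells.
make_tab <- function(sample_id, strain_id, abs_abundance, detected = TRUE) {
  out <- data.frame(sample_id = sample_id, strain_id = strain_id,
                    assigned_reads = NA_real_, rel_abundance = NA_real_,
                    abs_abundance = abs_abundance,
                    detection_limit = 0,
                    detected = rep_len(detected, length(sample_id)),
                    total_copies = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  out
}

# Sample ids in which `strain` plays `role` (full community, combination k).
role_samples <- function(design, strain, role, k = 1, n = 3) {
  r <- sample_strain_roles(design)
  r <- r[r$strain_id == strain & r$role == role & r$combination == k &
           is.na(r$dropout_strain), ]
  head(r$sample_id, n)
}

test_that("priority-effect strength is the log10 ratio of medians", {
  design <- get_ds_small()$design
  strain <- "STR03"
  first <- role_samples(design, strain, "first")
  late <- role_samples(design, strain, "late")
  tab <- rbind(make_tab(first, strain, c(1e7, 1e7, 1e6)),
               make_tab(late, strain, c(1, 1, 1e3), detected = FALSE))
  r <- priority_effect_strength(tab, design, strain, 1)
  expect_equal(r$median_first, 1e7)
  expect_equal(r$median_late, 1)
  expect_equal(r$strength, 7)
  expect_equal(c(r$n_first, r$n_late), c(3L, 3L))

  # simple ratio and the no-effect zero point
  tab2 <- rbind(make_tab(first[1], strain, 1e7),
                make_tab(late[1], strain, 1e4))
  expect_equal(priority_effect_strength(tab2, design, strain, 1)$strength, 3)
  tab3 <- rbind(make_tab(first[1], strain, 5e5),
                make_tab(late[1], strain, 5e5))
  expect_equal(priority_effect_strength(tab3, design, strain, 1)$strength, 0)

  # restricting to detected samples leaves no latecomer group here
  expect_error(priority_effect_strength(tab, design, strain, 1,
                                        include_undetected = FALSE),
               "at least one bee")
})

test_that("shared strains have no first/late contrast and error", {
  design <- get_ds_small()$design
  # STR01 is a shared (single-strain species) strain
  tab <- make_tab(design$samples$sample_id[1], "STR01", 1e6)
  expect_error(priority_effect_strength(tab, design, "STR01", 1),
               "not a firstcomer")
})

test_that("conspecific partners hold mirrored roles in every sequential sample", {
  design <- get_ds_small()$design
  roles <- sample_strain_roles(design)
  seq_full <- roles[roles$treatment %in% c("AB", "BA") &
                      is.na(roles$dropout_strain), ]
  strains <- design$strains
  for (sp in unique(strains$species_id[strains$focal])) {
    pair <- strains$strain_id[strains$species_id == sp]
    a <- seq_full[seq_full$strain_id == pair[1], ]
    b <- seq_full[seq_full$strain_id == pair[2], ]
    m <- merge(a, b, by = "sample_id")
    expect_true(all((m$role.x == "first") == (m$role.y == "late")))
  }
})

test_that("colonization frequency and Fisher test match enumeration", {
  design <- get_ds_small()$design
  strain <- "STR03"
  # complete separation at n = 10 per group: classic two-sided exact p
  p_sep <- fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  expect_equal(p_sep, fisher_enum_p(10, 10, 0, 10), tolerance = 1e-9)
  expect_equal(p_sep, 2 / choose(20, 10), tolerance = 1e-6)

  # random 2x2 tables with group sizes <= 10 agree with the oracle
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    d1 <- sample(0:n1, 1); d2 <- sample(0:n2, 1)
    expect_equal(fisher.test(matrix(c(d1, n1 - d1, d2, n2 - d2), 2))$p.value,
                 fisher_enum_p(d1, n1, d2, n2), tolerance = 1e-7)
  }

  # identical detection patterns give p = 1 and equal percentages
  first <- role_samples(design, strain, "first", n = 4)
  late <- role_samples(design, strain, "late", n = 4)
  tab <- rbind(make_tab(first, strain, c(1e6, 1e6, 1, 1),
                        detected = c(TRUE, TRUE, FALSE, FALSE)),
               make_tab(late, strain, c(1e6, 1e6, 1, 1),
                        detected = c(TRUE, TRUE, FALSE, FALSE)))
  cf <- colonization_frequency(tab, design, strain)
  expect_equal(cf$percent_first, cf$percent_late)
  expect_equal(cf$p, 1)
})

test_that("Wilcoxon contrast matches full enumeration for small groups", {
  expect_equal(suppressWarnings(wilcox.test(c(2, 4, 6), c(1, 3, 5)))$p.value,
               wilcox_enum_p(c(2, 4, 6), c(1, 3, 5)), tolerance = 1e-9)
  set.seed(12)
  for (i in 1:15) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    v <- sample(1000, n1 + n2)  # distinct values: exact test applies
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(wilcox.test(x, y)$p.value, wilcox_enum_p(x, y),
                 tolerance = 1e-9)
  }
  # identical groups are a tie -> p = 1
  design <- get_ds_small()$design
  first <- role_samples(design, "STR03", "first", n = 2)
  late <- role_samples(design, "STR03", "late", n = 2)
  tab <- rbind(make_tab(first, "STR03", c(5, 5)),
               make_tab(late, "STR03", c(5, 5)))
  expect_equal(abundance_contrast(tab, design, "STR03")$p, 1)
  # empty detected group is flagged, not an error
  tab2 <- rbind(make_tab(first, "STR03", c(5, 6)),
                make_tab(late, "STR03", c(1, 1), detected = FALSE))
  expect_true(abundance_contrast(tab2, design, "STR03")$insufficient)
})

test_that("Benjamini-Hochberg matches the hand step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_equal(bh_enum(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(p.adjust(p, "BH"), bh_enum(p), tolerance = 1e-12)
  }
})

test_that("species totals sum conspecific strains", {
  design <- get_ds_small()$design
  roles <- sample_strain_roles(design)
  # a control sample holds one Lact_sp01 strain; a sequential sample both
  only <- roles[roles$strain_id == "STR03" & roles$role == "only", ][1, ]
  seqs <- roles[roles$strain_id == "STR03" & roles$role == "first", ][1, ]
  tab <- rbind(make_tab(only$sample_id, "STR03", 5e6),
               make_tab(seqs$sample_id, "STR03", 3e6),
               make_tab(seqs$sample_id, "STR04", 2e6))
  st <- species_totals(tab, design, "Lact_sp01")
  per <- st$per_sample
  expect_equal(per$total_abundance[per$sample_id == only$sample_id], 5e6)
  expect_equal(per$total_abundance[per$sample_id == seqs$sample_id], 5e6)
  expect_equal(st$median_one, st$median_two)
})

test_that("one- and two-strain species totals agree on generator truth", {
  # compare relative species shares (summed conspecific truth / total) so
  # the bee-to-bee lognormal load variation does not mask the invariant
  ds <- get_ds_default()
  tr <- ds$truth$truth
  tot <- ds$truth$totals
  sp_of <- setNames(ds$design$strains$species_id,
                    ds$design$strains$strain_id)
  trt <- setNames(ds$design$samples$treatment, ds$design$samples$sample_id)
  drop <- setNames(ds$design$samples$dropout_strain,
                   ds$design$samples$sample_id)
  tr <- tr[is.na(drop[tr$sample_id]), ]
  rel <- tr$abundance / tot$total_copies[match(tr$sample_id,
                                               tot$sample_id)]
  key <- paste(tr$sample_id, sp_of[tr$strain_id])
  share <- tapply(rel, key, sum)
  meta <- do.call(rbind, strsplit(names(share), " "))
  focal_sp <- unique(sp_of[ds$design$strains$strain_id[ds$design$strains$focal]])
  diffs <- vapply(focal_sp, function(sp) {
    v <- share[meta[, 2] == sp]
    one <- v[trt[meta[meta[, 2] == sp, 1]] %in% c("A", "B")]
    two <- v[trt[meta[meta[, 2] == sp, 1]] %in% c("AB", "BA")]
    abs(median(one) - median(two)) / median(one)
  }, numeric(1))
  expect_lt(median(diffs), 0.10)
  expect_lt(max(diffs), 0.25)
})

test_that("rescue percent interpolates between latecomer and firstcomer", {
  ds <- get_ds_small()
  design <- ds$design
  # the dropout species' community-B strain is rescued when the community-A
  # conspecific is dropped
  c1 <- design$combinations[design$combinations$combination == 1, ]
  spA <- c1$strain_A[c1$species_id == "Lact_sp01"]
  spB <- c1$strain_B[c1$species_id == "Lact_sp01"]
  roles <- sample_strain_roles(design)
  rB <- roles[roles$strain_id == spB, ]
  first <- head(rB$sample_id[rB$role == "first" & is.na(rB$dropout_strain)], 3)
  late <- head(rB$sample_id[rB$role == "late" & is.na(rB$dropout_strain)], 3)
  dropped <- head(rB$sample_id[rB$role == "late" &
                                 !is.na(rB$dropout_strain) &
                                 rB$dropout_strain == spA], 3)
  expect_equal(length(dropped), 3L)
  base <- function(vd) rbind(make_tab(first, spB, c(1e7, 1e7, 1e7)),
                             make_tab(late, spB, c(1e5, 1e5, 1e5)),
                             make_tab(dropped, spB, vd))
  # boundary: dropout at the latecomer level -> 0%
  expect_equal(rescue_percent(base(rep(1e5, 3)), design, spB)$rescue_percent, 0)
  # boundary: dropout at the firstcomer level -> 100%
  expect_equal(rescue_percent(base(rep(1e7, 3)), design, spB)$rescue_percent,
               100)
  # midpoint formula: (5.05e6 - 1e5) / (1e7 - 1e5) = 50%
  r <- rescue_percent(base(rep(5.05e6, 3)), design, spB)
  expect_equal(r$rescue_percent, 50)
  # invariant to rescaling all abundances
  tab10 <- base(rep(5.05e6, 3))
  tab10$abs_abundance <- tab10$abs_abundance * 10
  expect_equal(rescue_percent(tab10, design, spB)$rescue_percent, 50)
  # undefined when firstcomer and latecomer medians coincide
  flat <- rbind(make_tab(first, spB, rep(1e6, 3)),
                make_tab(late, spB, rep(1e6, 3)),
                make_tab(dropped, spB, rep(1e6, 3)))
  expect_true(rescue_percent(flat, design, spB)$undefined)
})

test_that("seeded rescue level is recovered from the synthetic experiment", {
  ds <- get_ds_default()
  pl <- get_pl_default()
  c1 <- ds$design$combinations[ds$design$combinations$combination == 1, ]
  got <- vapply(ds$cfg$dropout_species, function(sp) {
    pair <- c(c1$strain_A[c1$species_id == sp], c1$strain_B[c1$species_id == sp])
    rs <- vapply(pair, function(s)
      rescue_percent(pl$abundance, ds$design, s)$rescue_percent, numeric(1))
    mean(rs)
  }, numeric(1))
  # generator seeds a 30% rescue towards the firstcomer level
  expect_true(all(got > 5 & got < 70))
  expect_lt(abs(mean(got) - 100 * ds$cfg$rescue_level), 15)
})

test_that("Spearman load-richness correlation uses average ranks", {
  # rank arithmetic example: ranks (1,2,3,4) vs (1,3,2,4) -> rho = 0.8
  tab <- rbind(
    make_tab(rep("s1", 1), "A", 2, detected = TRUE),
    make_tab(rep("s2", 3), c("A", "B", "C"), 2, detected = TRUE),
    make_tab(rep("s3", 2), c("A", "B"), 2, detected = TRUE),
    make_tab(rep("s4", 4), c("A", "B", "C", "D"), 2, detected = TRUE))
  tab$total_copies <- c(1e6, rep(2e6, 3), rep(3e6, 2), rep(4e6, 4))
  r <- load_richness_correlation(tab)
  expect_equal(r$rho, 0.8, tolerance = 1e-9)
  # perfectly monotone and reversed pairs
  tab2 <- tab
  tab2$total_copies <- c(1e6, rep(3e6, 3), rep(2e6, 2), rep(4e6, 4))
  expect_equal(load_richness_correlation(tab2)$rho, 1)
  tab3 <- tab
  tab3$total_copies <- c(4e6, rep(2e6, 3), rep(3e6, 2), rep(1e6, 4))
  expect_equal(load_richness_correlation(tab3)$rho, -1)
  # constant load is flagged
  tab4 <- tab
  tab4$total_copies <- 1e6
  expect_true(load_richness_correlation(tab4)$constant)
})
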