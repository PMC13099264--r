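#!/usr/bin/env Rscript
# Stage 3: strain-level priority-effect statistics on the strong-dominance
# experiment: strength per strain x combination, colonization frequency
# (Fisher) and abundance contrasts (Wilcoxon, BH-corrected), species
# totals, dropout rescue percentages, and the load-richness correlation.

library(strainPriority)

ds <- read_dataset("results/data/strong")
pl <- run_pipeline(ds)
out <- "results/tables/strong"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

st <- strength_table(pl$abundance, ds$design)
write.table(st, file.path(out, "priority_strength.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("strength: %d strain x combination values, min %.2f, median %.2f",
                nrow(st), min(st$strength), median(st$strength)))

ct <- contrast_table(pl$abundance, ds$design)
write.table(ct, file.path(out, "arrival_contrasts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("colonization frequency: %d/%d strains with Fisher p < 0.05 (BH)",
                sum(ct$fisher_p_adj < 0.05, na.rm = TRUE), nrow(ct)))

sp_rows <- lapply(unique(ds$design$strains$species_id), function(sp) {
  r <- species_totals(pl$abundance, ds$design, sp)
  data.frame(species_id = sp, median_one = r$median_one,
             median_two = r$median_two, wilcox_p = r$p)
})
write.table(do.call(rbind, sp_rows), file.path(out, "species_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

c1 <- ds$design$combinations[ds$design$combinations$combination == 1, ]
resc <- do.call(rbind, lapply(ds$cfg$dropout_species, function(sp) {
  pair <- c(c1$strain_A[c1$species_id == sp],
            c1$strain_B[c1$species_id == sp])
  do.call(rbind, lapply(pair, function(s)
    rescue_percent(pl$abundance, ds$design, s)))
}))
write.table(resc, file.path(out, "dropout_rescue.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("dropout rescue: %d strains, rescue %% range [%.1f, %.1f]",
                nrow(resc), min(resc$rescue_percent, na.rm = TRUE),
                max(resc$rescue_percent, na.rm = TRUE)))

lr <- load_richness_correlation(pl$abundance)
jsonlite::write_json(lr, file.path(out, "load_richness.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("load vs richness: Spearman rho = %.3f (p = %.3g, n = %d)",
                lr$rho, lr$p, lr$n))
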