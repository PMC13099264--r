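#' Write a strain reference as FASTA plus manifest CSV
#'
#' Emits one FASTA record per unique allele and a manifest mapping record
#' ids to strain/species/genus labels and copy numbers.
#'
#' @param reference strain allele table.
#' @param dir output directory (created if needed).
#' @return invisible list with `fasta` and `manifest` paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sprintf("A%04d", seq_len(nrow(reference)))
  ss <- Biostrings::DNAStringSet(reference$sequence)
  names(ss) <- rec
  fasta <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(ss, fasta, width = 80)
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(record_id = rec, strain_id = reference$strain_id,
                       species_id = reference$species_id,
                       genus = reference$genus, copies = reference$copies,
                       stringsAsFactors = FALSE),
            manifest, row.names = FALSE, quote = FALSE)
  invisible(list(fasta = fasta, manifest = manifest))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits exactly the plain-text formats the pipeline consumes: reference
#' FASTA + manifest CSV, ASV count TSV (asv_id, sequence, one column per
#' sample), qPCR CSV, sample metadata CSV, community combination CSV,
#' ground-truth TSVs and a scenario YAML.
#'
#' @param dataset a `pe_dataset`.
#' @param dir output directory.
#' @return invisible `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(dataset$reference, dir)
  seqs <- attr(dataset$counts, "sequences")
  cdf <- data.frame(asv_id = rownames(dataset$counts),
                    sequence = unname(seqs[rownames(dataset$counts)]),
                    dataset$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(cdf, file.path(dir, "asv_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(dataset$qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(dataset$design$samples, file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$design$combinations, file.path(dir, "combinations.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$design$species, file.path(dir, "species.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$design$strains, file.path(dir, "strains.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$truth)) {
    write.table(dataset$truth$truth, file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dataset$truth$totals, file.path(dir, "truth_totals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dataset$cfg)) {
    cfg <- dataset$cfg
    scal <- cfg[setdiff(names(cfg), c("species", "strains", "curve",
                                      "strength_map"))]
    scal$curve <- unclass(cfg$curve)
    scal$strength_map <- as.list(cfg$strength_map)
    yaml::write_yaml(scal, file.path(dir, "scenario.yaml"),
                     precision = 15)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `pe_dataset` (with `truth`/`cfg` when present on disk).
#' @export
read_dataset <- function(dir) {
  need <- c("reference.fasta", "manifest.csv", "asv_counts.tsv", "qpcr.csv",
            "metadata.csv", "combinations.csv", "species.csv", "strains.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop2("missing dataset file: ", file.path(dir, f))
  reference <- load_allele_fasta(file.path(dir, "reference.fasta"),
                                 read.csv(file.path(dir, "manifest.csv"),
                                          stringsAsFactors = FALSE))
  cdf <- read.delim(file.path(dir, "asv_counts.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, setdiff(names(cdf), c("asv_id", "sequence")),
                          drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cdf$asv_id
  attr(counts, "sequences") <- setNames(cdf$sequence, cdf$asv_id)
  samples <- read.csv(file.path(dir, "metadata.csv"),
                      stringsAsFactors = FALSE)
  samples$dropout_strain <- as.character(samples$dropout_strain)
  samples$dropout_strain[samples$dropout_strain %in% c("", "NA")] <-
    NA_character_
  design <- structure(list(
    species = read.csv(file.path(dir, "species.csv"),
                       stringsAsFactors = FALSE),
    strains = read.csv(file.path(dir, "strains.csv"),
                       stringsAsFactors = FALSE),
    combinations = read.csv(file.path(dir, "combinations.csv"),
                            stringsAsFactors = FALSE),
    samples = samples), class = "pe_design")
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv")))
    truth <- structure(list(
      truth = read.delim(file.path(dir, "truth.tsv"),
                         stringsAsFactors = FALSE),
      totals = read.delim(file.path(dir, "truth_totals.tsv"),
                          stringsAsFactors = FALSE)), class = "pe_truth")
  cfg <- NULL
  if (file.exists(file.path(dir, "scenario.yaml"))) {
    y <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
    cfg <- scenario_config(
      seed = y$seed, bees_per_treatment = y$bees_per_treatment,
      n_combinations = y$n_combinations, depth = y$depth,
      carrying_capacity = y$carrying_capacity, load_sdlog = y$load_sdlog,
      dirichlet_alpha = y$dirichlet_alpha,
      strength_map = unlist(y$strength_map),
      strength_noise_sd = y$strength_noise_sd,
      snp_divergence = y$snp_divergence,
      alleles_range = unlist(y$alleles_range),
      allele_len_range = unlist(y$allele_len_range),
      efficiency_bias_sd = y$efficiency_bias_sd,
      unknown_read_frac = y$unknown_read_frac,
      n_unknown_asvs = y$n_unknown_asvs, qpcr_noise_sd = y$qpcr_noise_sd,
      curve = do.call(qpcr_curve, y$curve),
      include_dropout = y$include_dropout,
      dropout_species = unlist(y$dropout_species),
      rescue_level = y$rescue_level)
  }
  structure(list(cfg = cfg, reference = reference, design = design,
                 truth = truth, counts = counts,
                 qpcr = read.csv(file.path(dir, "qpcr.csv"),
                                 stringsAsFactors = FALSE)),
            class = "pe_dataset")
}

#' Write an identifiability report as JSON
#'
#' @param report a [check_identifiability()] result.
#' @param path output path.
#' @return invisible `path`.
#' @export
write_identifiability_json <- function(report, path) {
  jsonlite::write_json(
    list(full_rank = report$full_rank, rank = report$rank,
         per_strain = report$per_strain),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
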