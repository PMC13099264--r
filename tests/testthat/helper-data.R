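# Shared fixtures, built once per session and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small scenario for unit tests: 2 combinations x 4 treatments x 4 bees
# (+ dropout cages), depth 2000.
small_cfg <- function() {
  scenario_config(seed = 42, bees_per_treatment = 4, n_combinations = 2,
                  depth = 2000)
}

get_ds_small <- function() cached("ds_small", simulate_experiment(small_cfg()))

get_pl_small <- function() cached("pl_small", run_pipeline(get_ds_small()))

# Full default scenario (the parameter-recovery study conditions).
get_ds_default <- function()
  cached("ds_default", simulate_experiment(scenario_config(seed = 1)))

get_pl_default <- function() cached("pl_default", run_pipeline(get_ds_default()))

# Strong firstcomer dominance: uniform latecomer suppression of 3 log10.
get_ds_strong <- function()
  cached("ds_strong", simulate_experiment(scenario_config(seed = 1,
                                                          strength = 3)))

get_pl_strong <- function() cached("pl_strong", run_pipeline(get_ds_strong()))

# Strong suppression sequenced deeply enough that latecomers stay above the
# detection limit (depth 1e5), for uncensored strength recovery.
get_ds_strong_deep <- function()
  cached("ds_strong_deep",
         simulate_experiment(scenario_config(seed = 2, strength = 3,
                                             depth = 1e5)))

get_pl_strong_deep <- function()
  cached("pl_strong_deep", run_pipeline(get_ds_strong_deep()))

# Abundance table taken directly from simulation ground truth (no reads, no
# qPCR): isolates downstream statistics from deconvolution noise.
truth_abundance_table <- function(ds) {
  tr <- ds$truth$truth
  tot <- ds$truth$totals
  total <- tot$total_copies[match(tr$sample_id, tot$sample_id)]
  out <- data.frame(sample_id = tr$sample_id, strain_id = tr$strain_id,
                    assigned_reads = NA_real_,
                    rel_abundance = tr$abundance / total,
                    abs_abundance = pmax(tr$abundance, 1),
                    detection_limit = 0,
                    detected = TRUE, total_copies = total,
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  out
}

# A tiny two-strain reference with one shared allele, matching a
# hand-checkable 3x2 copy matrix [[2,0],[1,2],[0,1]] after lexicographic
# row ordering.
shared_allele_ref <- function() {
  data.frame(
    strain_id = c("X", "X", "Y", "Y"),
    species_id = c("sp1", "sp1", "sp1", "sp1"),
    genus = "G",
    sequence = c("AAC", "CCA", "CCA", "GGA"),
    copies = c(2L, 1L, 2L, 1L),
    stringsAsFactors = FALSE)
}

# Minimal per-sample table accepted by qc_filter / compute_abundances.
make_samples <- function(sample_id, ct, known_reads,
                         total_reads = known_reads) {
  data.frame(sample_id = sample_id, ct = ct, known_reads = known_reads,
             total_reads = total_reads, stringsAsFactors = FALSE)
}
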