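#' Load strain 16S allele sequences from FASTA plus a manifest
#'
#' Reads one FASTA record per 16S rRNA allele copy (or per unique allele when
#' the manifest carries an explicit `copies` column) and attaches strain,
#' species and genus labels from a manifest table. Identical sequences within
#' one strain are merged and their copy counts summed, so the number of
#' identical records encodes the gene copy number when no explicit count is
#' given.
#'
#' @param path path to a FASTA file of full-length 16S rRNA allele sequences.
#' @param manifest data frame with columns `record_id`, `strain_id`,
#'   `species_id`, `genus` and optionally `copies` (positive integers;
#'   defaults to 1 per record).
#' @return A strain allele table: a `data.frame` with one row per unique
#'   allele per strain and columns `strain_id`, `species_id`, `genus`,
#'   `sequence` (uppercase ACGT), `copies`.
#' @examples
#' ref <- generate_reference(scenario_config(seed = 1))
#' td <- tempfile(); dir.create(td)
#' paths <- write_reference(ref, td)
#' ref2 <- load_allele_fasta(paths$fasta, read.csv(paths$manifest))
#' identical(ref$sequence, ref2$sequence)
#' @export
load_allele_fasta <- function(path, manifest) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop2("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  required <- c("record_id", "strain_id", "species_id", "genus")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop2("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  hit <- match(ids, manifest$record_id)
  if (anyNA(hit))
    stop2("FASTA record(s) missing from manifest: ",
          paste(ids[is.na(hit)], collapse = ", "))
  sq <- toupper(as.character(seqs))
  bad <- grepl("[^ACGT]", sq)
  if (any(bad))
    stop2("non-ACGT characters (ambiguity codes not allowed) in record(s): ",
          paste(ids[bad], collapse = ", "))
  copies <- if ("copies" %in% names(manifest)) manifest$copies[hit] else 1L
  copies[is.na(copies)] <- 1L
  if (any(copies < 1)) stop2("allele copy numbers must be >= 1")
  alleles <- data.frame(
    strain_id  = as.character(manifest$strain_id[hit]),
    species_id = as.character(manifest$species_id[hit]),
    genus      = as.character(manifest$genus[hit]),
    sequence   = sq,
    copies     = as.integer(copies),
    stringsAsFactors = FALSE
  )
  merge_alleles(alleles)
}

# Collapse identical sequences within a strain, summing copies; canonical
# ordering by strain_id then sequence.
merge_alleles <- function(alleles) {
  key <- paste(alleles$strain_id, alleles$sequence, sep = "\r")
  cp <- tapply(alleles$copies, key, sum)
  first <- alleles[!duplicated(key), , drop = FALSE]
  first$copies <- as.integer(cp[paste(first$strain_id, first$sequence,
                                      sep = "\r")])
  first <- first[order(first$strain_id, first$sequence), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Build the ASV-by-strain 16S copy-number matrix
#'
#' Collapses identical allele sequences across strains into ASV classes (one
#' class per distinct sequence) and records, for every strain, how many 16S
#' gene copies it contributes to each class. The column sum for a strain is
#' its total 16S copy number. ASV identity is exact sequence equality; rows
#' are ordered lexicographically by sequence and ASV ids assigned in that
#' order, columns alphabetically by strain id, so the matrix is reproducible
#' regardless of input order.
#'
#' @param strains a strain allele table as returned by
#'   [load_allele_fasta()] or [generate_reference()].
#' @return An object of class `copy_matrix`: a list with `M` (integer matrix,
#'   ASVs x strains), `asv_ids`, `strain_ids`, `sequences` (per ASV row) and
#'   `copy_totals` (per strain).
#' @export
build_copy_matrix <- function(strains) {
  if (!is.data.frame(strains) || nrow(strains) == 0L)
    stop2("need at least one strain with at least one allele")
  strains <- merge_alleles(strains)
  seqs <- sort(unique(strains$sequence))
  sids <- sort(unique(strains$strain_id))
  M <- matrix(0L, nrow = length(seqs), ncol = length(sids),
              dimnames = list(NULL, sids))
  a <- match(strains$sequence, seqs)
  i <- match(strains$strain_id, sids)
  for (k in seq_len(nrow(strains)))
    M[a[k], i[k]] <- M[a[k], i[k]] + strains$copies[k]
  asv_ids <- sprintf("ASV%04d", seq_along(seqs))
  rownames(M) <- asv_ids
  stopifnot(all(rowSums(M) > 0), all(colSums(M) > 0))
  structure(
    list(M = M, asv_ids = asv_ids, strain_ids = sids,
         sequences = seqs, copy_totals = colSums(M)),
    class = "copy_matrix"
  )
}

#' @export
print.copy_matrix <- function(x, ...) {
  cat("copy_matrix:", length(x$asv_ids), "ASV classes x",
      length(x$strain_ids), "strains\n")
  cat("16S copy totals per strain:",
      paste0(x$strain_ids, "=", x$copy_totals, collapse = ", "), "\n")
  invisible(x)
}

#' SNP distance between two sequences (alignment-free)
#'
#' Hamming distance for equal-length sequences; for unequal lengths, the
#' number of mismatches over the shared prefix plus the length difference.
#' Diagnostic only (no alignment).
#'
#' @param s1,s2 DNA sequences as character scalars.
#' @return integer distance.
#' @export
snp_distance <- function(s1, s2) {
  r1 <- charToRaw(s1); r2 <- charToRaw(s2)
  n <- min(length(r1), length(r2))
  sum(r1[seq_len(n)] != r2[seq_len(n)]) + abs(length(r1) - length(r2))
}

#' Check that strains are discriminable within a community
#'
#' For a given community (subset of strains co-inoculated into the same
#' bees), reports per strain whether it owns at least one ASV unique to it
#' within the community, the minimum SNP distance from any of its alleles to
#' the nearest allele of a co-member, and whether the community submatrix of
#' the copy matrix has full column rank (the condition under which noiseless
#' deconvolution is exact).
#'
#' @param cm a [build_copy_matrix()] result.
#' @param community character vector of strain ids (subset of
#'   `cm$strain_ids`).
#' @return list with `per_strain` (data.frame: `strain_id`,
#'   `has_unique_asv`, `min_snp_distance`, `identifiable`), `full_rank`
#'   (logical) and `rank` (integer).
#' @export
check_identifiability <- function(cm, community) {
  community <- sort(unique(as.character(community)))
  unknown <- setdiff(community, cm$strain_ids)
  if (length(unknown))
    stop2("unknown strain id(s): ", paste(unknown, collapse = ", "))
  sub <- cm$M[, community, drop = FALSE]
  rk <- qr(sub)$rank
  full_rank <- rk == length(community)
  per <- lapply(community, function(s) {
    mine <- sub[, s] > 0
    others <- sub[, setdiff(community, s), drop = FALSE]
    unique_asv <- any(mine & rowSums(others) == 0)
    # compare only discriminating variants: alleles shared with a
    # co-member are the same sequence (distance 0) and carry no signal
    min_snp <- NA_integer_
    if (ncol(others) > 0) {
      my_seqs <- cm$sequences[mine & rowSums(others) == 0]
      other_seqs <- cm$sequences[rowSums(others) > 0 & !mine]
      if (length(my_seqs) && length(other_seqs)) {
        d <- outer(my_seqs, other_seqs, Vectorize(snp_distance))
        min_snp <- as.integer(min(d))
      }
    }
    data.frame(strain_id = s, has_unique_asv = unique_asv,
               min_snp_distance = min_snp,
               identifiable = unique_asv || full_rank,
               stringsAsFactors = FALSE)
  })
  list(per_strain = do.call(rbind, per), full_rank = full_rank, rank = rk)
}

#' Write / read a copy matrix as TSV
#'
#' Serializes the ASV-by-strain copy matrix as a TSV with `asv_id` and
#' `sequence` columns followed by one integer column per strain.
#'
#' @param cm a `copy_matrix`.
#' @param path output (input) TSV path.
#' @return `write_copy_matrix` returns `path` invisibly; `read_copy_matrix`
#'   returns a `copy_matrix`.
#' @export
write_copy_matrix <- function(cm, path) {
  df <- data.frame(asv_id = cm$asv_ids, sequence = cm$sequences,
                   cm$M, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_copy_matrix
#' @export
read_copy_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, setdiff(names(df), c("asv_id", "sequence")),
                    drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- df$asv_id
  structure(
    list(M = M, asv_ids = df$asv_id, strain_ids = colnames(M),
         sequences = df$sequence, copy_totals = colSums(M)),
    class = "copy_matrix"
  )
}
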