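#' Column dialect for intensity tables
#'
#' Long-format intensity exports differ in their column headers depending on
#' the search engine and its version. A dialect maps the canonical column
#' names used throughout this package to the headers found in a file. The
#' default dialect is the package's own canonical long format.
#'
#' @param analyte_id,protein_id,group,replicate,intensity,sample_type column
#'   headers in the file for each canonical field.
#' @return A named character vector of class `flip_dialect`.
#' @export
flip_dialect <- function(analyte_id = "analyte_id",
                         protein_id = "protein_id",
                         group = "group",
                         replicate = "replicate",
                         intensity = "intensity",
                         sample_type = "sample_type") {
  d <- c(analyte_id = analyte_id, protein_id = protein_id, group = group,
         replicate = replicate, intensity = intensity,
         sample_type = sample_type)
  class(d) <- "flip_dialect"
  d
}

#' Read a long-format intensity table
#'
#' Parses one measured intensity per row (peptide for LiP samples, protein for
#' tryptic controls). Rows with missing, non-positive or non-numeric
#' intensities are dropped and counted; zero and negative intensities are
#' treated as missing, never imputed.
#'
#' @param path path to a TSV or CSV file (separator inferred from extension,
#'   override with `sep`).
#' @param dialect a [flip_dialect()] mapping canonical columns to file headers.
#' @param sep field separator; `NULL` infers `","` for `.csv`, tab otherwise.
#' @return A data frame with columns `analyte_id`, `protein_id`, `group`,
#'   `replicate`, `intensity`, `sample_type`, with attribute `n_skipped`
#'   giving the number of dropped rows.
#' @export
read_intensity_table <- function(path, dialect = flip_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    analyte_id  = raw[[dialect[["analyte_id"]]]],
    protein_id  = raw[[dialect[["protein_id"]]]],
    group       = raw[[dialect[["group"]]]],
    replicate   = raw[[dialect[["replicate"]]]],
    intensity   = raw[[dialect[["intensity"]]]],
    sample_type = raw[[dialect[["sample_type"]]]],
    stringsAsFactors = FALSE
  )
  rep_num <- suppressWarnings(as.integer(rec$replicate))
  if (anyNA(rep_num))
    stop("non-integer replicate at line(s): ",
         paste(utils::head(which(is.na(rep_num)) + 1L, 5), collapse = ", "))
  rec$replicate <- rep_num
  int_chr <- rec$intensity
  int_num <- suppressWarnings(as.numeric(int_chr))
  bad <- is.na(int_num) & !is.na(int_chr) &
    !(trimws(int_chr) %in% c("", "NA", "NaN", "na"))
  if (any(bad))
    stop("non-numeric intensity at line(s): ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
  rec$intensity <- int_num
  keep <- !is.na(int_num) & int_num > 0
  n_skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  validate_intensity_records(rec)
  attr(rec, "n_skipped") <- n_skipped
  rec
}

#' Write a long-format intensity table
#'
#' @param records intensity records as returned by [read_intensity_table()].
#' @param path output path; `.csv` extension writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cols <- c("analyte_id", "protein_id", "group", "replicate", "intensity",
            "sample_type")
  utils::write.table(records[, cols], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_intensity_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("analyte_id", "protein_id", "group", "replicate", "intensity",
              "sample_type")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0)
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (any(records$intensity <= 0, na.rm = TRUE))
    stop("non-positive intensities present; treat as missing before this point")
  bad_type <- setdiff(unique(records$sample_type), c("lip", "tryptic_control"))
  if (length(bad_type) > 0)
    stop("unknown sample_type value(s): ", paste(bad_type, collapse = ", "))
  key <- paste(records$analyte_id, records$group, records$replicate,
               records$sample_type, sep = "|")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicated (analyte, group, replicate, sample_type) key(s): ",
         paste(utils::head(dup, 5), collapse = "; "))
  }
  invisible(records)
}

#' Locate peptides on their proteins and classify tryptic termini
#'
#' Assigns 1-based inclusive start/end coordinates by exact substring search
#' and classifies each peptide as fully tryptic (both termini consistent with
#' trypsin: preceded by K/R or the protein N-terminus, and ending in K/R or at
#' the protein C-terminus) or semi-tryptic otherwise. A configurable
#' refinement suppresses cleavage before proline.
#'
#' @param peptides data frame with columns `peptide_id`, `protein_id`,
#'   `sequence` (the `peptide_id` may equal the sequence).
#' @param proteome data frame with columns `protein_id`, `sequence` (e.g. from
#'   [make_proteome()] or [read_proteome_fasta()]).
#' @param no_cleave_before_proline if `TRUE`, K/R followed by P does not count
#'   as a tryptic terminus.
#' @return A data frame with columns `peptide_id`, `protein_id`, `sequence`,
#'   `start`, `end`, `tryptic_type`, plus attributes `unmapped` (peptide ids
#'   not found in their protein) and `ambiguous` (ids occurring more than
#'   once; the first occurrence is used).
#' @export
annotate_peptides <- function(peptides, proteome,
                              no_cleave_before_proline = FALSE) {
  stopifnot(all(c("peptide_id", "protein_id", "sequence") %in% names(peptides)))
  prot_seq <- stats::setNames(proteome$sequence, proteome$protein_id)
  n <- nrow(peptides)
  start <- integer(n); end <- integer(n)
  ambiguous <- logical(n); unmapped <- logical(n)
  for (i in seq_len(n)) {
    ps <- prot_seq[[peptides$protein_id[i]]]
    if (is.null(ps) || is.na(ps)) { unmapped[i] <- TRUE; next }
    hits <- gregexpr(peptides$sequence[i], ps, fixed = TRUE)[[1]]
    if (hits[1] == -1L) { unmapped[i] <- TRUE; next }
    if (length(hits) > 1L) ambiguous[i] <- TRUE
    start[i] <- hits[1]
    end[i] <- hits[1] + nchar(peptides$sequence[i]) - 1L
  }
  tryptic <- function(i) {
    ps <- prot_seq[[peptides$protein_id[i]]]
    s <- start[i]; e <- end[i]
    prev <- if (s > 1L) substr(ps, s - 1L, s - 1L) else ""
    last <- substr(ps, e, e)
    nxt <- if (e < nchar(ps)) substr(ps, e + 1L, e + 1L) else ""
    n_ok <- s == 1L || (prev %in% c("K", "R") &&
                          !(no_cleave_before_proline && substr(ps, s, s) == "P"))
    c_ok <- e == nchar(ps) || (last %in% c("K", "R") &&
                                 !(no_cleave_before_proline && nxt == "P"))
    if (n_ok && c_ok) "fully_tryptic" else "semi_tryptic"
  }
  out <- peptides[!unmapped, c("peptide_id", "protein_id", "sequence"),
                  drop = FALSE]
  idx <- which(!unmapped)
  out$start <- start[idx]
  out$end <- end[idx]
  out$tryptic_type <- vapply(idx, tryptic, character(1))
  rownames(out) <- NULL
  attr(out, "unmapped") <- peptides$peptide_id[unmapped]
  attr(out, "ambiguous") <- peptides$peptide_id[which(ambiguous & !unmapped)]
  out
}

#' Detection filter: replicate floor in a minimum number of groups
#'
#' An analyte is retained if it is measured in at least `min_reps` replicates
#' in each of at least `min_groups` groups (conditions or size fractions).
#' LiP peptides additionally require their parent protein in the tryptic
#' control to pass the same rule. For retained analytes, records from groups
#' below the replicate floor are also dropped, so downstream tests compare
#' only groups where the analyte passes the floor.
#'
#' @param records intensity records (LiP and/or tryptic control rows).
#' @param min_reps minimum replicates per group (default 3, i.e. biological
#'   triplicates).
#' @param min_groups minimum number of qualifying groups (default 2).
#' @return Filtered records with attribute `filter_counts`, a named integer
#'   vector with retained/dropped analyte counts.
#' @export
detection_filter <- function(records, min_reps = 3L, min_groups = 2L) {
  validate_intensity_records(records)
  cell <- paste(records$sample_type, records$analyte_id, records$group,
                sep = "|")
  cell_n <- table(cell)
  rec_cell_ok <- as.vector(cell_n[cell]) >= min_reps
  # per analyte: number of distinct groups meeting the replicate floor
  akey <- paste(records$sample_type, records$analyte_id, sep = "|")
  grp_of_cell <- !duplicated(cell)
  qual <- tapply(rec_cell_ok[grp_of_cell], akey[grp_of_cell], sum)
  analyte_ok <- stats::setNames(as.vector(qual) >= min_groups, names(qual))

  # proteins that pass in the tryptic control
  is_tc <- records$sample_type == "tryptic_control"
  tc_pass <- unique(records$analyte_id[is_tc][
    analyte_ok[paste("tryptic_control", records$analyte_id[is_tc], sep = "|")]])

  keep <- analyte_ok[akey] & rec_cell_ok
  is_lip <- records$sample_type == "lip"
  keep[is_lip] <- keep[is_lip] & records$protein_id[is_lip] %in% tc_pass

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_analytes <- length(unique(akey))
  n_kept <- length(unique(akey[keep]))
  attr(out, "filter_counts") <- c(analytes = n_analytes, retained = n_kept,
                                  dropped = n_analytes - n_kept)
  out
}

#' Read a proteome FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with columns `protein_id`, `sequence`, `mw_da`.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  data.frame(protein_id = ids, sequence = unname(seqs),
             mw_da = vapply(seqs, protein_mw, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a proteome FASTA
#'
#' @param proteome data frame with `protein_id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$sequence,
                                                proteome$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# average residue masses (Da); water added once per chain
.residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

#' Protein molecular weight from sequence
#'
#' Average-mass molecular weight of the unmodified monomer (sum of average
#' residue masses plus one water).
#'
#' @param sequence amino-acid string.
#' @return Molecular weight in Da.
#' @export
protein_mw <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  m <- .residue_mass[aa]
  if (anyNA(m)) stop("unknown residue(s): ",
                     paste(unique(aa[is.na(m)]), collapse = ", "))
  sum(m) + 18.0153
}
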