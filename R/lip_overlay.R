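#' Fraction of a peptide covered by a marker region
#'
#' Both intervals are 1-based inclusive residue ranges on the same protein;
#' the denominator is the peptide's length (so the value answers "how much of
#' this peptide lies inside the marker").
#'
#' @param pep_start,pep_end peptide interval.
#' @param marker_start,marker_end marker interval.
#' @return Overlap fraction in `[0, 1]` (vectorized).
#' @export
overlap_fraction <- function(pep_start, pep_end, marker_start, marker_end) {
  inter <- pmin(pep_end, marker_end) - pmax(pep_start, marker_start) + 1
  pmax(inter, 0) / (pep_end - pep_start + 1)
}

#' Call marker hits in a perturbation LiP-MS experiment
#'
#' A significant, abundance-corrected peptide from a perturbation experiment
#' is a marker hit if it overlaps a library marker of its protein by at least
#' `min_overlap` of the peptide's length (boundary inclusive). Hits inherit
#' the marker's confidence class.
#'
#' @param results per-peptide results from [propagated_anova()] on the
#'   perturbation experiment.
#' @param annotations peptide coordinates for the perturbation peptides.
#' @param library marker library from [build_library()].
#' @param min_overlap minimum overlap fraction (default 0.5).
#' @param q_threshold peptide significance threshold (default 0.05).
#' @return Data frame of hits (`peptide_id`, `protein_id`, `marker_start`,
#'   `marker_end`, `overlap`, `q`, `log2fc`, `confidence`), with attribute
#'   `protein_summary` counting hits per protein.
#' @export
call_marker_hits <- function(results, annotations, library,
                             min_overlap = 0.5, q_threshold = 0.05) {
  sig <- results[!is.na(results$q) & results$q < q_threshold, , drop = FALSE]
  idx <- match(sig$peptide_id, annotations$peptide_id)
  sig$start <- annotations$start[idx]
  sig$end <- annotations$end[idx]
  rows <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    mk <- library[library$protein_id == sig$protein_id[i], , drop = FALSE]
    if (nrow(mk) == 0) next
    ov <- overlap_fraction(sig$start[i], sig$end[i], mk$start, mk$end)
    j <- which.max(ov)
    if (ov[j] >= min_overlap)
      rows[[i]] <- data.frame(peptide_id = sig$peptide_id[i],
                              protein_id = sig$protein_id[i],
                              marker_start = mk$start[j],
                              marker_end = mk$end[j],
                              overlap = ov[j], q = sig$q[i],
                              log2fc = sig$max_abs_log2fc[i],
                              confidence = mk$confidence[j],
                              stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(peptide_id = character(0), protein_id = character(0),
                       marker_start = integer(0), marker_end = integer(0),
                       overlap = numeric(0), q = numeric(0),
                       log2fc = numeric(0), confidence = character(0))
  rownames(hits) <- NULL
  attr(hits, "protein_summary") <-
    as.data.frame(table(protein_id = hits$protein_id),
                  stringsAsFactors = FALSE)
  hits
}

#' Proteins with changed abundance
#'
#' Flags proteins whose tryptic-control statistics pass both an effect-size
#' and a significance threshold: `|log2 fold change| > lfc_threshold`
#' (strict) and `q < q_threshold`.
#'
#' @param protein_results data frame with `protein_id` (or `peptide_id` when
#'   produced by running the ANOVA machinery at protein level),
#'   `max_abs_log2fc` and `q`.
#' @param lfc_threshold default 0.5.
#' @param q_threshold default 0.05 (relaxed analyses may use 0.1).
#' @return Character vector of changed protein ids.
#' @export
protein_abundance_changes <- function(protein_results, lfc_threshold = 0.5,
                                      q_threshold = 0.05) {
  sel <- !is.na(protein_results$q) &
    abs(protein_results$max_abs_log2fc) > lfc_threshold &
    protein_results$q < q_threshold
  unique(protein_results$protein_id[sel])
}
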