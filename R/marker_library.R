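#' Fractions a protein is expected to elute in
#'
#' Serial ultrafiltration through descending molecular-weight cutoffs is not
#' strict: a protein is classified as eluting in the correct fraction if half
#' of its molecular weight does not exceed the fraction's expected upper
#' bound, i.e. the next-larger cutoff (unbounded for the largest-cutoff
#' fraction). An 80-kDa protein is therefore allowed down to the 30-kDa
#' fraction (40 <= 50) but not in the 10-kDa fraction (40 > 30).
#'
#' @param protein_mw_kda monomer molecular weight in kDa.
#' @param cutoffs strictly descending membrane cutoffs in kDa.
#' @param labels fraction labels matching `cutoffs` (retentate of each).
#' @return Character vector of allowed fraction labels.
#' @export
expected_fractions <- function(protein_mw_kda, cutoffs = c(100, 50, 30, 10),
                               labels = paste0(cutoffs, "K")) {
  if (protein_mw_kda <= 0) stop("protein molecular weight must be positive")
  if (any(diff(cutoffs) >= 0)) stop("cutoffs must be strictly descending")
  upper <- c(Inf, cutoffs[-length(cutoffs)])
  labels[protein_mw_kda / 2 <= upper]
}

#' Confidence class of a marker region
#'
#' A change that is only significant when a fraction the protein should not
#' elute in is involved may be driven by degraded or anomalously eluting
#' protein, and the marker is classed low-confidence. If at least one
#' significant fraction pair lies entirely within the allowed fractions, the
#' marker is high-confidence.
#'
#' @param sig_pairs data frame with `group1`, `group2` giving the significant
#'   fraction pairs of the region.
#' @param allowed_fractions fraction labels from [expected_fractions()].
#' @return `"high"` or `"low"`.
#' @export
classify_confidence <- function(sig_pairs, allowed_fractions) {
  if (is.null(sig_pairs) || nrow(sig_pairs) == 0)
    stop("no significant fraction pair: region is not a marker")
  both_ok <- sig_pairs$group1 %in% allowed_fractions &
    sig_pairs$group2 %in% allowed_fractions
  if (any(both_ok)) "high" else "low"
}

# any-residue interval overlap on the same protein
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

#' Attach interface evidence flags to markers
#'
#' Flags each marker region for overlap (at least one residue) with
#' protein-binding or RNA-binding annotated domains, and for proximity to a
#' known binding interface when a structural distance is available.
#'
#' @param markers marker data frame with `protein_id`, `start`, `end`.
#' @param domains optional data frame `protein_id`, `start`, `end`,
#'   `go_term` (values `"protein binding"` / `"RNA binding"` are used).
#' @param distances optional data frame `protein_id`, `start`, `end`,
#'   `distance` (angstrom, mean distance of the region to an interface).
#' @param distance_cutoff flag threshold, strict (`< cutoff`), default 2.6.
#' @return `markers` with logical columns `protein_binding_domain`,
#'   `rna_binding_domain`, `near_interface`.
#' @export
annotate_marker <- function(markers, domains = NULL, distances = NULL,
                            distance_cutoff = 2.6) {
  n <- nrow(markers)
  markers$protein_binding_domain <- rep(FALSE, n)
  markers$rna_binding_domain <- rep(FALSE, n)
  markers$near_interface <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.null(domains)) {
      d <- domains[domains$protein_id == markers$protein_id[i] &
                     intervals_overlap(domains$start, domains$end,
                                       markers$start[i], markers$end[i]), ,
                   drop = FALSE]
      markers$protein_binding_domain[i] <- any(d$go_term == "protein binding")
      markers$rna_binding_domain[i] <- any(d$go_term == "RNA binding")
    }
    if (!is.null(distances)) {
      dd <- distances[distances$protein_id == markers$protein_id[i] &
                        intervals_overlap(distances$start, distances$end,
                                          markers$start[i], markers$end[i]), ,
                      drop = FALSE]
      if (nrow(dd) > 0)
        markers$near_interface[i] <- any(dd$distance < distance_cutoff)
    }
  }
  markers
}

#' Assemble the marker library
#'
#' Keeps unique regions with median q below the significance threshold,
#' attaches their significant fraction pairs and the molecular-weight based
#' confidence class, and adds any evidence annotations.
#'
#' @param regions region results from [group_to_parent()].
#' @param tukey pairwise results from [pairwise_tukey()].
#' @param proteome proteome data frame (for molecular weights).
#' @param q_threshold region significance threshold on `q_median` (default
#'   0.05) and pair significance threshold on the Tukey `q`.
#' @param cutoffs,fraction_labels see [expected_fractions()].
#' @param domains,distances optional evidence tables, see
#'   [annotate_marker()].
#' @return Marker data frame (one row per region) with columns `protein_id`,
#'   `start`, `end`, `q_median`, `confidence`, evidence flags, `sig_pairs`,
#'   `peptide_ids`; attribute `summary` holds marker/protein counts and the
#'   high-confidence share.
#' @export
build_library <- function(regions, tukey, proteome, q_threshold = 0.05,
                          cutoffs = c(100, 50, 30, 10),
                          fraction_labels = paste0(cutoffs, "K"),
                          domains = NULL, distances = NULL) {
  lib <- regions[regions$q_median < q_threshold, , drop = FALSE]
  if (nrow(lib) == 0) {
    lib <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), q_median = numeric(0),
                      confidence = character(0), sig_pairs = character(0),
                      peptide_ids = character(0))
    attr(lib, "summary") <- list(n_markers = 0L, n_proteins = 0L,
                                 pct_high_confidence = NA_real_)
    return(lib)
  }
  mw <- stats::setNames(proteome$mw_da, proteome$protein_id) / 1000
  conf <- character(nrow(lib))
  pair_txt <- character(nrow(lib))
  sig_tukey <- tukey[tukey$q < q_threshold, , drop = FALSE]
  for (i in seq_len(nrow(lib))) {
    members <- strsplit(lib$peptide_ids[i], ";", fixed = TRUE)[[1]]
    sp <- sig_tukey[sig_tukey$peptide_id %in% members, , drop = FALSE]
    sp <- unique(sp[, c("group1", "group2")])
    pair_txt[i] <- paste(paste(sp$group1, sp$group2, sep = "-"),
                         collapse = ";")
    if (nrow(sp) == 0) {
      # region significant by median q but no single pair passes: keep,
      # classify from the ANOVA alone as low confidence
      conf[i] <- "low"
    } else {
      allowed <- expected_fractions(mw[[lib$protein_id[i]]], cutoffs,
                                    fraction_labels)
      conf[i] <- classify_confidence(sp, allowed)
    }
  }
  lib$confidence <- conf
  lib$sig_pairs <- pair_txt
  lib <- annotate_marker(lib, domains, distances)
  attr(lib, "summary") <- list(
    n_markers = nrow(lib),
    n_proteins = length(unique(lib$protein_id)),
    pct_high_confidence = 100 * mean(lib$confidence == "high"))
  rownames(lib) <- NULL
  lib
}
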