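# peptides assigned to annotation terms by any-residue interval overlap
assign_terms <- function(peptides, table_intervals) {
  hits <- rep(FALSE, nrow(peptides))
  terms <- vector("list", nrow(peptides))
  by_prot <- split(table_intervals, table_intervals$protein_id)
  for (i in seq_len(nrow(peptides))) {
    iv <- by_prot[[peptides$protein_id[i]]]
    if (is.null(iv)) next
    ov <- intervals_overlap(iv$start, iv$end, peptides$start[i],
                            peptides$end[i])
    if (any(ov)) {
      hits[i] <- TRUE
      terms[[i]] <- unique(iv$term[ov])
    }
  }
  list(hit = hits, terms = terms)
}

#' Domain-term enrichment of the marker library (Fisher exact)
#'
#' Peptides are assigned to domain terms by interval overlap; for each term a
#' 2x2 table (in library vs background x in term vs not) is tested one-sided
#' for enrichment with Fisher's exact test, and p-values are BH-adjusted
#' across terms. The background is the set of all detected peptides
#' (including the library peptides).
#'
#' @param marker_peptides,background_peptides data frames with `peptide_id`,
#'   `protein_id`, `start`, `end`; `background_peptides` is all detected
#'   peptides.
#' @param domains data frame `protein_id`, `start`, `end`, `term`.
#' @return One row per term: counts, odds ratio, one-sided `p`, BH `q`.
#' @export
domain_fisher <- function(marker_peptides, background_peptides, domains) {
  stopifnot(all(c("protein_id", "start", "end", "term") %in% names(domains)))
  in_lib <- background_peptides$peptide_id %in% marker_peptides$peptide_id
  asg <- assign_terms(background_peptides, domains)
  all_terms <- sort(unique(domains$term))
  rows <- lapply(all_terms, function(tm) {
    in_term <- vapply(asg$terms, function(tt) tm %in% tt, logical(1))
    a <- sum(in_lib & in_term); b <- sum(in_lib & !in_term)
    c_ <- sum(!in_lib & in_term); d <- sum(!in_lib & !in_term)
    if (a + c_ == 0) return(NULL)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.frame(term = tm, lib_in = a, lib_out = b, bg_in = c_, bg_out = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), lib_in = integer(0),
                      lib_out = integer(0), bg_in = integer(0),
                      bg_out = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Disorder overlap of significant vs non-significant peptides
#'
#' A peptide at least partially overlapping an annotated disordered region is
#' classified disordered. Reports the percentage of disordered peptides among
#' significant and non-significant peptides and a one-sided Fisher test of
#' association between significance and disorder.
#'
#' @param peptides data frame `peptide_id`, `protein_id`, `start`, `end`,
#'   `significant` (logical).
#' @param disorder data frame `protein_id`, `start`, `end` of disordered
#'   regions (proteins without annotation count as ordered).
#' @return List with the flagged peptide table, `pct_disordered` (named:
#'   significant / nonsignificant / all) and `p` (one-sided Fisher).
#' @export
disorder_analysis <- function(peptides, disorder) {
  if (nrow(disorder) > 0) disorder$term <- "disordered"
  flag <- if (nrow(disorder) == 0) rep(FALSE, nrow(peptides))
          else assign_terms(peptides, disorder)$hit
  peptides$disordered <- flag
  pct <- c(significant = 100 * mean(flag[peptides$significant]),
           nonsignificant = 100 * mean(flag[!peptides$significant]),
           all = 100 * mean(flag))
  p <- if (!any(flag) || all(flag) ||
           !any(peptides$significant) || all(peptides$significant)) 1
    else stats::fisher.test(table(factor(peptides$significant,
                                         levels = c(FALSE, TRUE)),
                                  factor(flag, levels = c(FALSE, TRUE))),
                            alternative = "greater")$p.value
  list(peptides = peptides, pct_disordered = pct, p = p)
}

#' Fraction of mutation sites covered by (window-extended) markers
#'
#' A site counts as overlapped if it lies within any marker interval of its
#' protein extended by `window_aa` residues on each side.
#'
#' @param markers marker data frame (`protein_id`, `start`, `end`).
#' @param sites data frame `protein_id`, `position`.
#' @param window_aa extension in residues (0 or 10 in typical use).
#' @param protein_lengths optional named vector for input validation.
#' @return Fraction in `[0, 1]`.
#' @export
mutation_overlap <- function(markers, sites, window_aa = 0L,
                             protein_lengths = NULL) {
  if (!is.null(protein_lengths)) {
    bad <- sites$position > protein_lengths[sites$protein_id]
    if (any(bad, na.rm = TRUE))
      stop("mutation site beyond protein length at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    mk <- markers[markers$protein_id == sites$protein_id[i], , drop = FALSE]
    any(sites$position[i] >= mk$start - window_aa &
          sites$position[i] <= mk$end + window_aa)
  }, logical(1))
  mean(hit)
}

#' Resampling null for the mutation-site overlap
#'
#' Each draw places `n_sites` sites uniformly at random over the pooled
#' residues of the protein set (proteins weighted by length) and records the
#' overlap fraction with the markers. The empirical p is the fraction of
#' draws at or above the observed overlap; a one-sided normal-approximation
#' p is also returned, since few draws bound the empirical p at
#' `1/(n_draws)`.
#'
#' @param markers marker data frame.
#' @param proteins data frame `protein_id`, `length`.
#' @param n_sites sites per draw.
#' @param n_draws number of draws (default 10).
#' @param observed observed overlap fraction (optional).
#' @param window_aa marker extension passed to [mutation_overlap()].
#' @return List `null` (per-draw overlaps), `mean_null`, `p_empirical`,
#'   `p_normal`.
#' @export
mutation_null <- function(markers, proteins, n_sites, n_draws = 10L,
                          observed = NULL, window_aa = 0L) {
  if (n_draws < 1) stop("n_draws must be at least 1")
  pool_prot <- rep(proteins$protein_id, proteins$length)
  pool_pos <- unlist(lapply(proteins$length, seq_len))
  null <- vapply(seq_len(n_draws), function(d) {
    idx <- sample.int(length(pool_prot), n_sites, replace = TRUE)
    mutation_overlap(markers,
                     data.frame(protein_id = pool_prot[idx],
                                position = pool_pos[idx],
                                stringsAsFactors = FALSE),
                     window_aa)
  }, numeric(1))
  out <- list(null = null, mean_null = mean(null))
  if (!is.null(observed)) {
    out$p_empirical <- mean(null >= observed)
    s <- stats::sd(null)
    out$p_normal <- if (is.na(s) || s == 0) as.numeric(mean(null) >= observed)
      else stats::pnorm(observed, mean(null), s, lower.tail = FALSE)
  }
  out
}
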