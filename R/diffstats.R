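#' Median normalization of intensity samples
#'
#' Rescales each sample (one `sample_type` x `group` x `replicate`
#' combination) multiplicatively so that its median intensity equals the
#' median of sample medians over the normalization scope. LiP and tryptic
#' control samples are always normalized separately (they come from separate
#' searches). `scope = "global"` equalizes all samples of a sample type;
#' `scope = "per_group"` equalizes only the replicates within each group
#' (the convention for a fraction-wise marker-library experiment, where every
#' fraction is searched separately).
#'
#' @param records intensity records.
#' @param scope `"global"` or `"per_group"`.
#' @return Records with rescaled intensities.
#' @export
median_normalize <- function(records, scope = c("global", "per_group")) {
  scope <- match.arg(scope)
  validate_intensity_records(records)
  sample_key <- paste(records$sample_type, records$group, records$replicate,
                      sep = "|")
  med <- tapply(records$intensity, sample_key, stats::median)
  scope_key_of_sample <- if (scope == "global") {
    sub("^([^|]+)\\|.*$", "\\1", names(med))
  } else {
    sub("^([^|]+\\|[^|]+)\\|.*$", "\\1", names(med))
  }
  target <- tapply(med, scope_key_of_sample, stats::median)
  factor_per_sample <- target[scope_key_of_sample] / med
  names(factor_per_sample) <- names(med)
  records$intensity <- records$intensity *
    as.vector(factor_per_sample[sample_key])
  records
}

#' Protein-abundance correction of LiP peptide intensities
#'
#' Divides each LiP peptide intensity by the tryptic-control intensity of its
#' parent protein in the same group and replicate, yielding the
#' abundance-corrected ratio that carries the accessibility signal. In
#' library mode (`renormalize_ratios = TRUE`) the ratios of each sample are
#' further rescaled so that sample medians are equal across fractions, since
#' fraction-wise searches leave the raw ratios on different scales.
#'
#' @param lip_records LiP intensity records.
#' @param protein_records tryptic-control intensity records.
#' @param renormalize_ratios equalize per-sample ratio medians after the
#'   division.
#' @return Data frame `peptide_id`, `protein_id`, `group`, `replicate`,
#'   `ratio`, with attribute `n_dropped` counting LiP records lacking a
#'   protein measurement.
#' @export
correct_by_protein <- function(lip_records, protein_records,
                               renormalize_ratios = FALSE) {
  pk <- paste(protein_records$analyte_id, protein_records$group,
              protein_records$replicate, sep = "|")
  lk <- paste(lip_records$protein_id, lip_records$group,
              lip_records$replicate, sep = "|")
  idx <- match(lk, pk)
  dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  out <- data.frame(peptide_id = lip_records$analyte_id[keep],
                    protein_id = lip_records$protein_id[keep],
                    group = lip_records$group[keep],
                    replicate = lip_records$replicate[keep],
                    ratio = lip_records$intensity[keep] /
                      protein_records$intensity[idx[keep]],
                    stringsAsFactors = FALSE)
  if (renormalize_ratios && nrow(out) > 0) {
    sample_key <- paste(out$group, out$replicate, sep = "|")
    med <- tapply(out$ratio, sample_key, stats::median)
    target <- stats::median(med)
    out$ratio <- out$ratio * as.vector(target / med[sample_key])
  }
  attr(out, "n_dropped") <- dropped
  out
}

# per-key n, mean, sd (sample sd, n-1); keys returned sorted
key_stats <- function(x, key) {
  n <- as.vector(rowsum(rep(1, length(x)), key))
  s <- rowsum(x, key)
  ss <- as.vector(rowsum(x^2, key))
  keys <- rownames(s)
  m <- as.vector(s) / n
  v <- (ss - n * m^2) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  data.frame(key = keys, n = n, mean = m, sd = sqrt(pmax(v, 0)),
             stringsAsFactors = FALSE)
}

#' Error-propagated one-way ANOVA across groups
#'
#' Tests, per peptide, whether the abundance-corrected ratio differs between
#' groups. The within-group spread is not taken from the ratios themselves
#' but propagated from the joint uncertainty of the raw peptide and protein
#' intensities: `sd_c = Mean_c * sqrt(cv_pep_c^2 + cv_prot_c^2)`, with CVs
#' computed from the (post-normalization) intensities in group `c`.
#'
#' Two variants of the between-group mean square are available.
#' `"as_printed"` centers group means on `sum_c Mean_c / N` and divides by the
#' number of groups `C`; `"textbook"` uses the replicate-weighted grand mean
#' and divides by `C - 1`, giving the classically calibrated statistic. The
#' F statistic is referred to an F distribution with `(C - 1, N - C)` degrees
#' of freedom in both variants.
#'
#' @param ratios data frame from [correct_by_protein()].
#' @param lip_records,protein_records raw (normalized) intensity records used
#'   for the coefficient-of-variation terms.
#' @param variant `"as_printed"` or `"textbook"`.
#' @return One row per peptide: `peptide_id`, `protein_id`, `C`, `N`,
#'   `ms_between`, `ms_within`, `f`, `p`, `q` (BH), `max_abs_log2fc`,
#'   `degenerate` flag. Peptides observed in fewer than two groups, or with
#'   no residual degrees of freedom, are returned with `NA` statistics and a
#'   `skip_reason`.
#' @export
propagated_anova <- function(ratios, lip_records, protein_records,
                             variant = c("as_printed", "textbook")) {
  variant <- match.arg(variant)
  pg_key <- paste(ratios$peptide_id, ratios$group, sep = "|")
  pg <- key_stats(ratios$ratio, pg_key)
  split_key <- strsplit(pg$key, "|", fixed = TRUE)
  pg$peptide_id <- vapply(split_key, `[`, character(1), 1L)
  pg$group <- vapply(split_key, `[`, character(1), 2L)

  # CV of raw peptide intensities per peptide x group
  lip_stats <- key_stats(lip_records$intensity,
                         paste(lip_records$analyte_id, lip_records$group,
                               sep = "|"))
  cv_pep <- (lip_stats$sd / lip_stats$mean)[match(pg$key, lip_stats$key)]

  # CV of raw protein intensities per protein x group
  prot_stats <- key_stats(protein_records$intensity,
                          paste(protein_records$analyte_id,
                                protein_records$group, sep = "|"))
  prot_of_pep <- ratios$protein_id[match(pg$peptide_id, ratios$peptide_id)]
  cv_prot <- (prot_stats$sd / prot_stats$mean)[
    match(paste(prot_of_pep, pg$group, sep = "|"), prot_stats$key)]

  cv_pep[is.na(cv_pep)] <- 0
  cv_prot[is.na(cv_prot)] <- 0
  # guard against floating-point residue in exact zero-noise data
  cv_pep[cv_pep < 1e-9] <- 0
  cv_prot[cv_prot < 1e-9] <- 0
  pg$sd_prop <- pg$mean * sqrt(cv_pep^2 + cv_prot^2)

  pk <- pg$peptide_id
  N <- as.vector(rowsum(pg$n, pk))
  C <- as.vector(rowsum(rep(1L, nrow(pg)), pk))
  sum_mean <- as.vector(rowsum(pg$mean, pk))
  sum_nmean <- as.vector(rowsum(pg$n * pg$mean, pk))
  sum_nmean2 <- as.vector(rowsum(pg$n * pg$mean^2, pk))
  sum_within <- as.vector(rowsum((pg$n - 1) * pg$sd_prop^2, pk))
  max_mean <- tapply(pg$mean, pk, max)
  min_mean <- tapply(pg$mean, pk, min)
  peptides <- rownames(rowsum(pg$n, pk))

  grand <- if (variant == "as_printed") sum_mean / N else sum_nmean / N
  ssb <- sum_nmean2 - 2 * grand * sum_nmean + grand^2 * N
  # exact-tie guard: identical group means give SSB 0, not rounding residue
  tied <- (as.vector(max_mean[peptides]) - as.vector(min_mean[peptides])) <=
    1e-9 * pmax(abs(as.vector(max_mean[peptides])), 1e-300)
  ssb[tied] <- 0
  ms_between <- ssb / if (variant == "as_printed") C else pmax(C - 1, 1)
  df2 <- N - C
  ms_within <- ifelse(df2 > 0, sum_within / df2, NA_real_)

  f <- p <- rep(NA_real_, length(peptides))
  degenerate <- rep(FALSE, length(peptides))
  skip <- rep(NA_character_, length(peptides))
  ok <- C >= 2 & df2 > 0
  skip[C < 2] <- "single_group"
  skip[C >= 2 & df2 <= 0] <- "no_residual_df"
  reg <- ok & ms_within > 0
  f[reg] <- ms_between[reg] / ms_within[reg]
  p[reg] <- stats::pf(f[reg], C[reg] - 1, df2[reg], lower.tail = FALSE)
  d0 <- ok & ms_within == 0
  degenerate[d0] <- TRUE
  f[d0 & ms_between > 0] <- Inf
  p[d0 & ms_between > 0] <- 0
  f[d0 & ms_between == 0] <- 0
  p[d0 & ms_between == 0] <- 1

  res <- data.frame(
    peptide_id = peptides,
    protein_id = ratios$protein_id[match(peptides, ratios$peptide_id)],
    C = C, N = N, ms_between = ms_between, ms_within = ms_within,
    f = f, p = p,
    max_abs_log2fc = log2(as.vector(max_mean[peptides]) /
                            as.vector(min_mean[peptides])),
    degenerate = degenerate, skip_reason = skip,
    stringsAsFactors = FALSE)
  res$q <- NA_real_
  res$q[!is.na(res$p)] <- adjust_bh(res$p[!is.na(res$p)])
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' @param p raw p-values in `[0, 1]`.
#' @return Step-up adjusted q-values.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Tukey HSD between groups, per peptide
#'
#' Within each peptide, every group pair is compared with the studentized
#' range statistic on the propagated within-group mean square of
#' [propagated_anova()]; the per-pair p-values are then adjusted across all
#' peptide x pair tests with Benjamini-Hochberg (the Tukey distribution
#' already accounts for the within-peptide family).
#'
#' @param ratios data frame from [correct_by_protein()].
#' @param lip_records,protein_records raw intensity records (CV terms).
#' @param variant ANOVA variant, see [propagated_anova()].
#' @param anova optional precomputed result of [propagated_anova()] on the
#'   same inputs.
#' @return Data frame `peptide_id`, `group1`, `group2`, `diff_log2fc`, `p`,
#'   `q`. Pairs with fewer than two replicates on either side are omitted.
#' @export
pairwise_tukey <- function(ratios, lip_records, protein_records,
                           variant = c("as_printed", "textbook"),
                           anova = NULL) {
  variant <- match.arg(variant)
  if (is.null(anova))
    anova <- propagated_anova(ratios, lip_records, protein_records, variant)
  pg_key <- paste(ratios$peptide_id, ratios$group, sep = "|")
  pg <- key_stats(ratios$ratio, pg_key)
  split_key <- strsplit(pg$key, "|", fixed = TRUE)
  pg$peptide_id <- vapply(split_key, `[`, character(1), 1L)
  pg$group <- vapply(split_key, `[`, character(1), 2L)

  pg_split <- split(pg, pg$peptide_id)
  rows <- vector("list", nrow(anova))
  for (i in seq_len(nrow(anova))) {
    if (!is.na(anova$skip_reason[i])) next
    g <- pg_split[[anova$peptide_id[i]]]
    g <- g[g$n >= 2, , drop = FALSE]
    if (nrow(g) < 2) next
    cmb <- utils::combn(seq_len(nrow(g)), 2)
    msw <- anova$ms_within[i]
    df2 <- anova$N[i] - anova$C[i]
    d <- abs(g$mean[cmb[1, ]] - g$mean[cmb[2, ]])
    se <- sqrt(msw / 2 * (1 / g$n[cmb[1, ]] + 1 / g$n[cmb[2, ]]))
    pv <- ifelse(se > 0,
                 stats::ptukey(d / se, nmeans = anova$C[i], df = df2,
                               lower.tail = FALSE),
                 ifelse(d > 0, 0, 1))
    rows[[i]] <- data.frame(peptide_id = anova$peptide_id[i],
                            group1 = g$group[cmb[1, ]],
                            group2 = g$group[cmb[2, ]],
                            diff_log2fc = log2(g$mean[cmb[1, ]] /
                                                 g$mean[cmb[2, ]]),
                            p = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(peptide_id = character(0), group1 = character(0),
                      group2 = character(0), diff_log2fc = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Group overlapping peptides into unique-region markers
#'
#' Peptides generated from the same fully tryptic parent (by stochastic PK
#' cleavage or missed cleavage) map to overlapping positions. Each tested
#' peptide is assigned to the longest observed fully tryptic peptide that
#' contains it; peptides sharing a parent merge into one region whose q-value
#' is the median of the member q-values. A peptide without an identified
#' fully tryptic parent becomes its own region and is flagged as an orphan.
#' Should assigned parents themselves overlap (possible with missed
#' cleavages), those regions are merged into their union so that regions
#' within a protein never overlap.
#'
#' @param results per-peptide results from [propagated_anova()].
#' @param annotations peptide annotations with coordinates and
#'   `tryptic_type`.
#' @return One row per region: `protein_id`, `start`, `end`, `q_median`,
#'   `n_peptides`, `peptide_ids` (semicolon-separated), `orphan`.
#' @export
group_to_parent <- function(results, annotations) {
  res <- results[is.na(results$skip_reason), , drop = FALSE]
  ann_idx <- match(res$peptide_id, annotations$peptide_id)
  if (anyNA(ann_idx))
    stop("annotations missing for peptide(s): ",
         paste(utils::head(res$peptide_id[is.na(ann_idx)], 5), collapse = ", "))
  res$start <- annotations$start[ann_idx]
  res$end <- annotations$end[ann_idx]
  parents <- annotations[annotations$tryptic_type == "fully_tryptic", ,
                         drop = FALSE]

  reg_start <- res$start; reg_end <- res$end
  orphan <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    cand <- parents[parents$protein_id == res$protein_id[i] &
                      parents$start <= res$start[i] &
                      parents$end >= res$end[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    j <- which.max(cand$end - cand$start)
    reg_start[i] <- cand$start[j]
    reg_end[i] <- cand$end[j]
    orphan[i] <- FALSE
  }
  res$reg_start <- reg_start; res$reg_end <- reg_end; res$orphan <- orphan

  out <- lapply(split(res, res$protein_id), function(d) {
    d <- d[order(d$reg_start, d$reg_end), , drop = FALSE]
    region_id <- integer(nrow(d))
    cur <- 1L; cur_end <- d$reg_end[1]
    region_id[1] <- 1L
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (d$reg_start[i] <= cur_end) {
        region_id[i] <- cur
        cur_end <- max(cur_end, d$reg_end[i])
      } else {
        cur <- cur + 1L
        region_id[i] <- cur
        cur_end <- d$reg_end[i]
      }
    }
    do.call(rbind, lapply(split(d, region_id), function(m)
      data.frame(protein_id = m$protein_id[1],
                 start = min(m$reg_start), end = max(m$reg_end),
                 q_median = stats::median(m$q),
                 n_peptides = nrow(m),
                 peptide_ids = paste(m$peptide_id, collapse = ";"),
                 orphan = any(m$orphan), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
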