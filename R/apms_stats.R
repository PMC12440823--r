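#' High-confidence interactor filter for AP-MS
#'
#' A prey is kept if its SAINT probability reaches `prob_min`, it was
#' detected (spectral count > 0) in all `min_reps` pull-down replicates, and
#' its mean spectral count is at least `min_mean_sc` (boundaries inclusive).
#'
#' @param saint data frame with `prey_id`, `saint_prob` and one spectral
#'   count column per replicate named `sc_1`, `sc_2`, ...
#' @param prob_min SAINT probability floor (default 1.0).
#' @param min_reps required detections out of `min_reps` replicates
#'   (default 4).
#' @param min_mean_sc mean spectral-count floor (default 4.5).
#' @return Character vector of kept prey ids.
#' @export
filter_interactors <- function(saint, prob_min = 1.0, min_reps = 4L,
                               min_mean_sc = 4.5) {
  sc_cols <- grep("^sc_", names(saint), value = TRUE)
  if (length(sc_cols) < min_reps)
    stop("need at least ", min_reps, " spectral-count columns (sc_*)")
  sc <- as.matrix(saint[, sc_cols[seq_len(min_reps)], drop = FALSE])
  keep <- saint$saint_prob >= prob_min &
    rowSums(sc > 0) == min_reps &
    rowMeans(sc) >= min_mean_sc
  saint$prey_id[keep]
}

#' Total-area normalization across AP-MS samples
#'
#' Rescales each sample (tag x treatment x replicate) so that its total
#' intensity equals the mean total over all samples.
#'
#' @param records data frame `protein_id`, `tag`, `treatment`, `replicate`,
#'   `intensity`.
#' @return Records with rescaled intensities.
#' @export
normalize_total_area <- function(records) {
  key <- paste(records$tag, records$treatment, records$replicate, sep = "|")
  tot <- tapply(records$intensity, key, sum)
  target <- mean(tot)
  records$intensity <- records$intensity * as.vector(target / tot[key])
  records
}

#' Bait-normalized differential interaction statistic
#'
#' For each prey, the prey/bait double ratio `R` is formed per treatment
#' (prey tagged/untagged over bait tagged/untagged, using mean intensities),
#' its standard deviation is propagated from the four coefficients of
#' variation, and the difference of the two treatments' ratios is referred to
#' a Student's t distribution with `df` degrees of freedom using the pooled
#' denominator `sqrt((sd_HU^2 + sd_untreated^2) / 3)`.
#'
#' @param records intensity data frame `protein_id`, `tag` (`"FLAG"` /
#'   `"non-FLAG"`), `treatment` (`"untreated"` / `"HU"`), `replicate`,
#'   `intensity`; normalized together by total area sums (see
#'   [normalize_total_area()]).
#' @param bait_id bait protein id (must be present in all four sample
#'   classes).
#' @param treatments the two treatment labels, reference second.
#' @param min_reps detection floor per sample class (default 3).
#' @param df t degrees of freedom (default 4).
#' @return One row per prey: `prey_id`, `r_treated`, `r_untreated`,
#'   `sd_treated`, `sd_untreated`, `t`, `df`, `p` (two-sided), `log2fc`;
#'   preys failing the detection floor or with an undefined mean are
#'   reported with `skip_reason`.
#' @export
differential_interaction <- function(records, bait_id,
                                     treatments = c("HU", "untreated"),
                                     min_reps = 3L, df = 4L) {
  if (any(records$intensity < 0)) stop("negative intensities in input")
  tags <- c("FLAG", "non-FLAG")
  tab <- key_stats(records$intensity,
                   paste(records$protein_id, records$tag, records$treatment,
                         sep = "|"))
  lut <- stats::setNames(seq_len(nrow(tab)), tab$key)
  cls_stats <- function(prot, tag, treat) {
    i <- lut[paste(prot, tag, treat, sep = "|")]
    if (is.na(i)) return(list(n = 0L, mu = NA_real_, sigma = NA_real_))
    list(n = tab$n[i], mu = tab$mean[i], sigma = tab$sd[i])
  }
  for (tg in tags) for (tr in treatments)
    if (cls_stats(bait_id, tg, tr)$n == 0)
      stop("bait absent from sample class ", tg, " / ", tr)

  ratio_cv2 <- function(prot, treat) {
    s <- list(pf = cls_stats(prot, "FLAG", treat),
              pn = cls_stats(prot, "non-FLAG", treat),
              bf = cls_stats(bait_id, "FLAG", treat),
              bn = cls_stats(bait_id, "non-FLAG", treat))
    if (any(vapply(s, function(z) z$n == 0 || z$mu == 0, logical(1))))
      return(NULL)
    r <- (s$pf$mu / s$pn$mu) / (s$bf$mu / s$bn$mu)
    cv2 <- sum(vapply(s, function(z)
      (if (z$n > 1) z$sigma / z$mu else 0)^2, numeric(1)))
    list(r = r, sd = r * sqrt(cv2),
         n_min = min(vapply(s[c("pf", "pn")], `[[`, numeric(1), "n")))
  }

  preys <- setdiff(unique(records$protein_id), character(0))
  rows <- lapply(preys, function(pr) {
    out <- data.frame(prey_id = pr, r_treated = NA_real_,
                      r_untreated = NA_real_, sd_treated = NA_real_,
                      sd_untreated = NA_real_, t = NA_real_, df = df,
                      p = NA_real_, log2fc = NA_real_,
                      skip_reason = NA_character_, stringsAsFactors = FALSE)
    a <- ratio_cv2(pr, treatments[1])
    b <- ratio_cv2(pr, treatments[2])
    if (is.null(a) || is.null(b)) {
      out$skip_reason <- "mean_zero_or_absent"
      return(out)
    }
    n_det <- vapply(c(treatments[1], treatments[2]), function(tr)
      min(cls_stats(pr, "FLAG", tr)$n, cls_stats(pr, "non-FLAG", tr)$n),
      numeric(1))
    if (any(n_det < min_reps)) {
      out$skip_reason <- "below_replicate_floor"
      return(out)
    }
    denom <- sqrt((a$sd^2 + b$sd^2) / 3)
    tval <- if (denom == 0) {
      if (a$r == b$r) 0 else sign(a$r - b$r) * Inf
    } else (a$r - b$r) / denom
    out$r_treated <- a$r; out$r_untreated <- b$r
    out$sd_treated <- a$sd; out$sd_untreated <- b$sd
    out$t <- tval
    out$p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    out$log2fc <- log2(a$r / b$r)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
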