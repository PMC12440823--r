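# shared fixture builders and independent oracles

rec_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(analyte_id = r[[1]], protein_id = r[[2]], group = r[[3]],
               replicate = as.integer(r[[4]]), intensity = as.numeric(r[[5]]),
               sample_type = r[[6]], stringsAsFactors = FALSE)))
}

# records for one analyte across groups/replicates with given intensities
block_rec <- function(analyte, protein, groups, reps, intensities, type) {
  g <- expand.grid(replicate = reps, group = groups,
                   stringsAsFactors = FALSE)
  data.frame(analyte_id = analyte, protein_id = protein, group = g$group,
             replicate = as.integer(g$replicate), intensity = intensities,
             sample_type = type, stringsAsFactors = FALSE)
}

# independent, deliberately plain transcription of the propagated one-way
# ANOVA (Eqs. for group mean, propagated sd, between/within mean squares,
# F, and the F-tail p), looped peptide by peptide
anova_oracle <- function(ratios, lip, prot, variant) {
  out <- list()
  for (pep in sort(unique(ratios$peptide_id))) {
    rp <- ratios[ratios$peptide_id == pep, ]
    prot_id <- rp$protein_id[1]
    groups <- sort(unique(rp$group))
    if (length(groups) < 2) next
    n_c <- numeric(0); mean_c <- numeric(0); sd_c <- numeric(0)
    for (g in groups) {
      r_g <- rp$ratio[rp$group == g]
      ip <- lip$intensity[lip$analyte_id == pep & lip$group == g]
      ir <- prot$intensity[prot$analyte_id == prot_id & prot$group == g]
      m <- mean(r_g)
      cvp <- if (length(ip) > 1) sd(ip) / mean(ip) else 0
      cvr <- if (length(ir) > 1) sd(ir) / mean(ir) else 0
      n_c <- c(n_c, length(r_g))
      mean_c <- c(mean_c, m)
      sd_c <- c(sd_c, m * sqrt(cvp^2 + cvr^2))
    }
    N <- sum(n_c); C <- length(groups)
    if (N - C <= 0) next
    grand <- if (variant == "as_printed") sum(mean_c) / N
             else sum(n_c * mean_c) / N
    ms_b <- sum(n_c * (mean_c - grand)^2) /
      (if (variant == "as_printed") C else C - 1)
    ms_w <- sum((n_c - 1) * sd_c^2) / (N - C)
    f <- ms_b / ms_w
    out[[pep]] <- data.frame(
      peptide_id = pep, ms_between = ms_b, ms_within = ms_w, f = f,
      p = pf(f, C - 1, N - C, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# plain transcription of the bait-normalized AP-MS double-ratio statistic
apms_oracle <- function(records, bait, prey,
                        treatments = c("HU", "untreated"), df = 4) {
  cls <- function(prot, tag, treat)
    records$intensity[records$protein_id == prot & records$tag == tag &
                        records$treatment == treat]
  one <- function(treat) {
    pf_ <- cls(prey, "FLAG", treat); pn <- cls(prey, "non-FLAG", treat)
    bf <- cls(bait, "FLAG", treat); bn <- cls(bait, "non-FLAG", treat)
    r <- (mean(pf_) / mean(pn)) / (mean(bf) / mean(bn))
    s <- r * sqrt((sd(pf_) / mean(pf_))^2 + (sd(pn) / mean(pn))^2 +
                    (sd(bf) / mean(bf))^2 + (sd(bn) / mean(bn))^2)
    list(r = r, sd = s)
  }
  a <- one(treatments[1]); b <- one(treatments[2])
  t_val <- (a$r - b$r) / sqrt((a$sd^2 + b$sd^2) / 3)
  list(r_treated = a$r, r_untreated = b$r, t = t_val,
       p = 2 * pt(abs(t_val), df, lower.tail = FALSE),
       log2fc = log2(a$r / b$r))
}

# exact one-sided hypergeometric tail P(X >= a) by direct summation
hyper_tail_oracle <- function(a, b, c_, d) {
  m <- a + b          # library peptides
  n <- c_ + d         # background-only peptides
  k <- a + c_         # peptides in term
  total <- choose(m + n, k)
  sum(vapply(a:min(m, k), function(x)
    choose(m, x) * choose(n, k - x), numeric(1))) / total
}

# small complete pipeline on simulated data; returns pieces for reuse
run_library_pipeline <- function(proteome, peptides, truth,
                                 variant = "textbook",
                                 renormalize = TRUE, normalize = TRUE) {
  sim <- simulate_flip_experiment(truth, proteome, peptides)
  filt <- detection_filter(rbind(sim$lip, sim$tryptic_control))
  norm <- if (normalize) median_normalize(filt, "per_group") else filt
  lip <- norm[norm$sample_type == "lip", ]
  tc <- norm[norm$sample_type == "tryptic_control", ]
  ratios <- correct_by_protein(lip, tc, renormalize_ratios = renormalize)
  anova <- propagated_anova(ratios, lip, tc, variant = variant)
  list(sim = sim, lip = lip, tc = tc, ratios = ratios, anova = anova)
}
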