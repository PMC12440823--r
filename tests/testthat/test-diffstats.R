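test_that("median normalization equalizes sample medians within scope", {
  # two samples with medians 10 and 20 -> factors 1.5 and 0.75
  rec <- rbind(
    block_rec("A", "P", "g1", 1, c(5), "lip"),
    block_rec("B", "P", "g1", 1, c(10), "lip"),
    block_rec("C", "P", "g1", 1, c(15), "lip"),
    block_rec("A", "P", "g1", 2, c(10), "lip"),
    block_rec("B", "P", "g1", 2, c(20), "lip"),
    block_rec("C", "P", "g1", 2, c(30), "lip"))
  out <- median_normalize(rec, "global")
  expect_equal(out$intensity[out$replicate == 1],
               c(5, 10, 15) * 1.5)
  expect_equal(out$intensity[out$replicate == 2],
               c(10, 20, 30) * 0.75)

  # already-equal medians: identity
  expect_equal(median_normalize(out, "global")$intensity, out$intensity)

  # per-group scope never mixes fractions: each group normalized alone
  rec2 <- rbind(
    block_rec("A", "P", "f1", 1:2, c(10, 20), "lip"),
    block_rec("A", "P", "f2", 1:2, c(1000, 2000), "lip"))
  out2 <- median_normalize(rec2, "per_group")
  med <- tapply(out2$intensity, paste(out2$group, out2$replicate), median)
  expect_equal(as.vector(med[c("f1 1", "f1 2")]), c(15, 15))
  expect_equal(as.vector(med[c("f2 1", "f2 2")]), c(1500, 1500))
})

test_that("protein correction forms abundance-invariant ratios", {
  lip <- block_rec("PEP", "P1", c("g1", "g2"), 1, c(100, 200), "lip")
  tc <- block_rec("P1", "P1", c("g1", "g2"), 1, c(50, 100),
                  "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  expect_equal(ra$ratio, c(2, 2))

  # missing protein measurement drops the LiP record, counted
  lip2 <- rbind(lip, block_rec("PEP", "P1", "g3", 1, 100, "lip"))
  ra2 <- correct_by_protein(lip2, tc)
  expect_equal(nrow(ra2), 2)
  expect_equal(attr(ra2, "n_dropped"), 1)
})

test_that("propagated ANOVA matches a step-by-step transcription oracle", {
  set.seed(21)
  groups <- c("100K", "50K", "30K")
  lip <- NULL; tc <- NULL
  for (pep in c("PEPONE", "PEPTWO", "PEPSIX")) {
    lip <- rbind(lip, block_rec(pep, "P1", groups, 1:4,
                                runif(12, 80, 120), "lip"))
  }
  tc <- block_rec("P1", "P1", groups, 1:4, runif(12, 900, 1100),
                  "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  for (variant in c("as_printed", "textbook")) {
    got <- propagated_anova(ra, lip, tc, variant = variant)
    want <- anova_oracle(ra, lip, tc, variant = variant)
    got <- got[match(want$peptide_id, got$peptide_id), ]
    expect_equal(got$ms_between, want$ms_between, tolerance = 1e-10)
    expect_equal(got$ms_within, want$ms_within, tolerance = 1e-10)
    expect_equal(got$f, want$f, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("with constant protein the textbook variant is a classic ANOVA", {
  set.seed(31)
  groups <- c("a", "b", "c", "d")
  lip <- block_rec("PEPCLS", "P1", groups, 1:4, runif(16, 80, 120), "lip")
  tc <- block_rec("P1", "P1", groups, 1:4, 1, "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  got <- propagated_anova(ra, lip, tc, variant = "textbook")
  ref <- summary(aov(ratio ~ group, data = ra))[[1]]
  expect_equal(got$f, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("degenerate inputs resolve to the documented fixed points", {
  lip <- block_rec("PEPAAA", "P1", c("g1", "g2"), 1:3, 100, "lip")
  tc <- block_rec("P1", "P1", c("g1", "g2"), 1:3, 50, "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  got <- propagated_anova(ra, lip, tc)
  expect_equal(got$f, 0)
  expect_equal(got$p, 1)
  expect_true(got$degenerate)

  # zero within-group variance with a real difference: p = 0 and flagged
  lip2 <- rbind(block_rec("PEPBBB", "P1", "g1", 1:3, 100, "lip"),
                block_rec("PEPBBB", "P1", "g2", 1:3, 200, "lip"))
  ra2 <- correct_by_protein(lip2, tc)
  got2 <- propagated_anova(ra2, lip2, tc)
  expect_equal(got2$p, 0)
  expect_true(got2$degenerate)
})

test_that("BH adjustment reproduces hand-derived q-values", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("two-group Tukey equals the pooled t-test", {
  set.seed(41)
  lip <- block_rec("PEPTTT", "P1", c("g1", "g2"), 1:4,
                   c(runif(4, 80, 120), runif(4, 150, 190)), "lip")
  tc <- block_rec("P1", "P1", c("g1", "g2"), 1:4, 1, "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  tk <- pairwise_tukey(ra, lip, tc, variant = "textbook")
  tt <- t.test(ratio ~ group, data = ra, var.equal = TRUE)
  # the studentized-range CDF in R is itself accurate to about 1e-4
  expect_equal(tk$p, tt$p.value, tolerance = 2e-3)
})

test_that("Tukey flags exactly the groups that differ", {
  set.seed(43)
  # group a shifted 8 sd away; b and c identical in expectation
  lip <- rbind(
    block_rec("PEPSEP", "P1", "a", 1:4, rnorm(4, 200, 5), "lip"),
    block_rec("PEPSEP", "P1", "b", 1:4, rnorm(4, 100, 5), "lip"),
    block_rec("PEPSEP", "P1", "c", 1:4, rnorm(4, 100, 5), "lip"))
  tc <- block_rec("P1", "P1", c("a", "b", "c"), 1:4, 1, "tryptic_control")
  ra <- correct_by_protein(lip, tc)
  tk <- pairwise_tukey(ra, lip, tc, variant = "textbook")
  sig <- tk[tk$q < 0.05, c("group1", "group2")]
  pairs <- apply(sig, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(pairs, c("a-b", "a-c"))

  # identical groups: all pairwise p near 1
  lip0 <- block_rec("PEPNUL", "P1", c("a", "b", "c"), 1:4,
                    rep(c(100, 101, 99, 100), 3), "lip")
  ra0 <- correct_by_protein(lip0, tc)
  tk0 <- pairwise_tukey(ra0, lip0, tc, variant = "textbook")
  expect_true(all(tk0$p > 0.5))
})

test_that("overlapping peptides group to their fully tryptic parent", {
  ann <- data.frame(
    peptide_id = c("GGSTKLLK", "GSTKLLK", "SOLOPEP", "OTHERK"),
    protein_id = c("P1", "P1", "P1", "P1"),
    sequence = c("GGSTKLLK", "GSTKLLK", "SOLOPEP", "OTHERK"),
    start = c(10, 11, 40, 60), end = c(17, 17, 46, 65),
    tryptic_type = c("fully_tryptic", "semi_tryptic", "semi_tryptic",
                     "fully_tryptic"),
    stringsAsFactors = FALSE)
  res <- data.frame(
    peptide_id = c("GGSTKLLK", "GSTKLLK", "SOLOPEP", "OTHERK"),
    protein_id = "P1", q = c(0.01, 0.03, 0.2, 0.5),
    skip_reason = NA_character_, stringsAsFactors = FALSE)
  reg <- group_to_parent(res, ann)
  expect_equal(nrow(reg), 3)
  parent <- reg[reg$start == 10, ]
  expect_equal(parent$q_median, 0.02)
  expect_equal(parent$n_peptides, 2)
  solo <- reg[reg$start == 40, ]
  expect_true(solo$orphan)
  expect_equal(solo$n_peptides, 1)
  # regions within a protein never overlap
  reg <- reg[order(reg$start), ]
  expect_true(all(diff(reg$start) > 0 &
                    reg$start[-1] > reg$end[-nrow(reg)]))
})
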