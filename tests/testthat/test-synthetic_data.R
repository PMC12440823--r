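test_that("proteome generation is seeded and mass-correct", {
  p1 <- make_proteome(1, c(10, 10), seed = 1)
  p2 <- make_proteome(1, c(10, 10), seed = 1)
  expect_equal(p1$sequence, p2$sequence)
  expect_equal(nchar(p1$sequence), 10)

  polyg <- paste(rep("G", 100), collapse = "")
  expect_equal(protein_mw(polyg), 100 * 57.0519 + 18.0153, tolerance = 1e-8)

  p <- make_proteome(100, c(50, 500), seed = 7)
  expect_equal(nrow(p), 100)
  expect_true(all(nchar(p$sequence) >= 50 & nchar(p$sequence) <= 500))
  expect_error(make_proteome(3, c(10, 5)), "length_range")
})

test_that("in-silico digest obeys cleavage, nesting and the length floor", {
  prot <- data.frame(protein_id = "T1", sequence = "AAAAAKCCCCCR",
                     stringsAsFactors = FALSE)
  pep <- digest_in_silico(prot, pk_sites_per_protein = 0, seed = 1)
  expect_setequal(pep$sequence, c("AAAAAK", "CCCCCR"))
  expect_true(all(pep$tryptic_type == "fully_tryptic"))

  # with PK sites, every semi-tryptic peptide nests in one tryptic parent
  prot2 <- make_proteome(10, c(100, 200), seed = 2)
  pep2 <- digest_in_silico(prot2, pk_sites_per_protein = 4, seed = 3)
  expect_true(all(nchar(pep2$sequence) >= 6))
  semis <- pep2[pep2$tryptic_type == "semi_tryptic", ]
  fulls <- pep2[pep2$tryptic_type == "fully_tryptic", ]
  for (i in seq_len(nrow(semis))) {
    parents <- fulls[fulls$protein_id == semis$protein_id[i] &
                       fulls$start <= semis$start[i] &
                       fulls$end >= semis$end[i], ]
    expect_lte(nrow(parents), 1)
  }
  # substring invariant
  seqs <- setNames(prot2$sequence, prot2$protein_id)
  expect_true(all(substr(seqs[pep2$protein_id], pep2$start, pep2$end) ==
                    pep2$sequence))
})

test_that("zero-noise simulation gives exact fraction-constant ratios", {
  prot <- make_proteome(5, c(80, 160), seed = 4)
  pep <- digest_in_silico(prot, 2, seed = 5)
  tr <- flip_truth(cv_peptide = 0, cv_protein = 0, seed = 6)
  sim <- simulate_flip_experiment(tr, prot, pep)
  ra <- correct_by_protein(sim$lip, sim$tryptic_control)
  spread <- tapply(ra$ratio, ra$peptide_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("a planted marker changes the ratio by exactly its fold change", {
  prot <- make_proteome(5, c(80, 160), seed = 4)
  pep <- digest_in_silico(prot, 2, seed = 5)
  target <- pep[pep$tryptic_type == "fully_tryptic", ][1, ]
  planted <- data.frame(protein_id = target$protein_id,
                        start = target$start, end = target$end,
                        log2fc = 1, fraction = "100K",
                        stringsAsFactors = FALSE)
  tr <- flip_truth(planted_markers = planted, cv_peptide = 0,
                   cv_protein = 0, seed = 6)
  sim <- simulate_flip_experiment(tr, prot, pep)
  ra <- correct_by_protein(sim$lip, sim$tryptic_control)
  hit <- ra[ra$peptide_id == target$peptide_id, ]
  r100 <- unique(hit$ratio[hit$group == "100K"])
  r10 <- unique(hit$ratio[hit$group == "10K"])
  expect_equal(r100 / r10, 2, tolerance = 1e-12)
  # non-overlapping peptides unchanged
  truth <- sim$peptide_truth
  others <- ra[ra$peptide_id %in% truth$peptide_id[!truth$is_marker], ]
  spread <- tapply(others$ratio, others$peptide_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("simulations are byte-identical under a fixed seed", {
  prot <- make_proteome(4, c(60, 100), seed = 1)
  pep <- digest_in_silico(prot, 2, seed = 2)
  tr <- flip_truth(seed = 3, missingness = 0.1)
  s1 <- simulate_flip_experiment(tr, prot, pep)
  s2 <- simulate_flip_experiment(tr, prot, pep)
  expect_identical(s1, s2)
})

test_that("replicate noise converges to the configured CV", {
  prot <- data.frame(protein_id = "P1",
                     sequence = paste(rep("AAAAAK", 10), collapse = ""),
                     stringsAsFactors = FALSE)
  prot$mw_da <- protein_mw(prot$sequence)
  pep <- digest_in_silico(prot, 0, seed = 1)
  tr <- flip_truth(n_replicates = 1000, cv_peptide = 0.2, cv_protein = 0,
                   seed = 9)
  sim <- simulate_flip_experiment(tr, prot, pep)
  one <- sim$lip[sim$lip$analyte_id == pep$peptide_id[1] &
                   sim$lip$group == "100K", ]
  cv <- sd(one$intensity) / mean(one$intensity)
  expect_lt(abs(cv - 0.2) / 0.2, 0.1)
})

test_that("toy dimers plant a verifiable contact patch", {
  st <- simulate_dimer_structure(30, 8, seed = 2)
  expect_identical(st$atoms, simulate_dimer_structure(30, 8, seed = 2)$atoms)
  expect_equal(nrow(st$truth), 16)

  # every truth residue has a partner-chain atom within 5 A; residues more
  # than one position outside the window do not
  a <- st$atoms
  min_partner_dist <- function(ch, rn) {
    own <- a[a$chain == ch & a$resno == rn, ]
    oth <- a[a$chain != ch, ]
    min(sqrt(outer(own$x, oth$x, "-")^2 + outer(own$y, oth$y, "-")^2 +
               outer(own$z, oth$z, "-")^2))
  }
  for (i in seq_len(nrow(st$truth)))
    expect_lt(min_partner_dist(st$truth$chain[i], st$truth$resno[i]), 5)
  window <- range(st$truth$resno)
  outside <- setdiff(seq_len(30), (window[1] - 1):(window[2] + 1))
  for (rn in outside) {
    expect_gte(min_partner_dist("A", rn), 5)
    expect_gte(min_partner_dist("B", rn), 5)
  }

  # separated chains leave an empty truth set
  far <- simulate_dimer_structure(30, 8, seed = 2, contact_gap = 100)
  expect_equal(nrow(far$truth), 0)
})

test_that("planted-community networks have the designed structure", {
  two <- simulate_complex_network(c(5, 5), 0, seed = 1)
  g <- igraph::graph_from_data_frame(two$edges, directed = FALSE)
  expect_equal(igraph::ecount(g), 20)
  expect_equal(igraph::count_components(g), 2)

  bridged <- simulate_complex_network(c(5, 5), 1, seed = 2)
  gb <- igraph::graph_from_data_frame(bridged$edges, directed = FALSE)
  expect_equal(igraph::ecount(gb), 2 * choose(5, 2) + 1)
  expect_equal(igraph::count_components(gb), 1)

  expect_identical(simulate_complex_network(c(4, 6), 2, seed = 5),
                   simulate_complex_network(c(4, 6), 2, seed = 5))
})
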