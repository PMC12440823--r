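test_that("numeric SASA matches the closed form and the burial limit", {
  lone <- data.frame(x = 0, y = 0, z = 0, radius = 1.9)
  expect_equal(atom_sasa(lone), 4 * pi * (1.9 + 1.4)^2, tolerance = 1e-9)

  # an atom enclosed in a tight shell of neighbours is fully buried
  dirs <- local({
    i <- seq_len(60) - 0.5
    phi <- acos(1 - 2 * i / 60)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  })
  shell <- data.frame(x = 2.2 * dirs[, 1], y = 2.2 * dirs[, 2],
                      z = 2.2 * dirs[, 3], radius = 1.9)
  atoms <- rbind(data.frame(x = 0, y = 0, z = 0, radius = 1.9), shell)
  expect_equal(atom_sasa(atoms)[1], 0)
})

test_that("per-residue SASA agrees with a 10x point-density reference", {
  st <- simulate_dimer_structure(20, 6, seed = 3)
  lo <- relative_sasa(st, n_points = 240)
  hi <- relative_sasa(st, n_points = 2400)
  rel <- abs(lo$sasa - hi$sasa) / pmax(hi$sasa, 1e-9)
  expect_true(all(rel < 0.05))
})

test_that("the 25-point accessibility-change rule is strict", {
  expect_false(flag_interface(50, 25))          # change exactly 25
  expect_true(flag_interface(50.1, 25))
  expect_false(flag_interface(50, 26))
})

test_that("planted interfaces are detected accurately and rigid motions are irrelevant", {
  st <- simulate_dimer_structure(40, 10, seed = 7)
  iface <- detect_interface(st)
  truth_key <- paste(st$truth$chain, st$truth$resno)
  det_key <- paste(iface$chain, iface$resno)[iface$is_interface]
  expect_gte(mean(truth_key %in% det_key), 0.9)   # sensitivity
  expect_gte(mean(det_key %in% truth_key), 0.9)   # precision

  # random rigid-body transform of the whole assembly changes nothing
  set.seed(8)
  ang <- runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% rz
  st2 <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(rot)
  st2$atoms$x <- xyz[, 1] + 11.3
  st2$atoms$y <- xyz[, 2] - 40
  st2$atoms$z <- xyz[, 3] + 5.5
  iface2 <- detect_interface(st2)
  expect_equal(iface2$is_interface, iface$is_interface)

  # chains far apart yield no interface
  far <- simulate_dimer_structure(40, 10, seed = 7, contact_gap = 100)
  expect_false(any(detect_interface(far)$is_interface))

  # a single chain cannot have an interface
  single <- st
  single$atoms <- single$atoms[single$atoms$chain == "A", ]
  expect_warning(i1 <- detect_interface(single), "single-chain")
  expect_false(any(i1$is_interface))
})

test_that("peptides map to chains deterministically under a seed", {
  st <- simulate_dimer_structure(30, 8, seed = 9)
  csA <- paste(
    st$atoms$aa[st$atoms$chain == "A" & st$atoms$atom == "CA"], collapse = "")
  pep <- substr(csA, 5, 12)
  mp <- map_peptide_to_chain(pep, st)
  expect_equal(mp$chain, "A")
  expect_equal(mp$resno, 5:12)
  expect_null(map_peptide_to_chain("WWWWWWWW", st))

  # homodimer: both chains identical; seeded choice is reproducible
  homo <- st
  b <- st$atoms[st$atoms$chain == "A", ]
  b$chain <- "B"; b$y <- b$y + 50
  homo$atoms <- rbind(st$atoms[st$atoms$chain == "A", ], b)
  set.seed(101); m1 <- map_peptide_to_chain(pep, homo)
  set.seed(101); m2 <- map_peptide_to_chain(pep, homo)
  expect_identical(m1, m2)
})

test_that("peptide-to-interface distances equal an exhaustive oracle", {
  st <- simulate_dimer_structure(40, 10, seed = 11)
  iface <- detect_interface(st)
  ifr <- iface[iface$is_interface, ]
  ca <- st$atoms[st$atoms$atom == "CA", ]

  # peptide consisting solely of interface residues has distance zero
  w <- st$truth[st$truth$chain == "A", ]
  mp0 <- list(chain = "A", resno = w$resno)
  expect_equal(peptide_interface_distance(mp0, iface, st), 0)

  # residues at min distances d1 and d2 average to (d1 + d2)/2
  mp <- list(chain = "A", resno = c(min(w$resno) - 3, min(w$resno) - 5))
  oracle <- mean(sapply(mp$resno, function(rn) {
    p <- ca[ca$chain == "A" & ca$resno == rn, c("x", "y", "z")]
    min(sapply(seq_len(nrow(ifr)), function(j) {
      q <- ca[ca$chain == ifr$chain[j] & ca$resno == ifr$resno[j],
              c("x", "y", "z")]
      sqrt(sum((p - q)^2))
    }))
  }))
  expect_equal(peptide_interface_distance(mp, iface, st), oracle,
               tolerance = 1e-12)

  # association at 0.3 A is a subset of association at 2.6 A
  seqs <- paste(ca$aa[ca$chain == "A"], collapse = "")
  peps <- data.frame(peptide_id = sprintf("p%d", 1:8),
                     sequence = sapply(seq(1, 29, 4), function(s)
                       substr(seqs, s, s + 7)), stringsAsFactors = FALSE)
  sc26 <- score_peptides_on_structure(peps, st, cutoff = 2.6,
                                      interface = iface)
  sc03 <- score_peptides_on_structure(peps, st, cutoff = 0.3,
                                      interface = iface)
  expect_true(all(which(sc03$interface_associated) %in%
                    which(sc26$interface_associated)))
})

test_that("structure selection policies behave as documented", {
  s2 <- simulate_dimer_structure(20, 5, seed = 1)
  s6 <- s2
  for (k in 3:6) {
    extra <- s2$atoms[s2$atoms$chain == "A", ]
    extra$chain <- LETTERS[k]
    extra$y <- extra$y + 40 * k
    s6$atoms <- rbind(s6$atoms, extra)
  }
  cands <- list(two = s2, six = s6)
  expect_identical(select_structure(cands, "biggest")$atoms, s6$atoms)

  set.seed(5); pick1 <- select_structure(cands, "random")$id
  set.seed(5); pick2 <- select_structure(cands, "random")$id
  expect_equal(pick1, pick2)

  # "best": structure placing the marker at its interface wins
  st_good <- simulate_dimer_structure(30, 8, seed = 21)
  st_bad <- simulate_dimer_structure(30, 8, seed = 21, contact_gap = 100)
  ca <- st_good$atoms[st_good$atoms$atom == "CA" &
                        st_good$atoms$chain == "A", ]
  sq <- paste(ca$aa[order(ca$resno)], collapse = "")
  w <- range(st_good$truth$resno[st_good$truth$chain == "A"])
  peps <- data.frame(
    peptide_id = c("mk", "bg"),
    sequence = c(substr(sq, w[1], w[2]), substr(sq, 1, 6)),
    is_marker = c(TRUE, FALSE), stringsAsFactors = FALSE)
  best <- select_structure(list(b = st_bad, g = st_good), "best",
                           peptides = peps)
  expect_equal(best$id, st_good$id)
})

test_that("ROC AUC equals brute-force pair counting with half ties", {
  expect_equal(interface_roc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1)
  expect_equal(interface_roc(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                          FALSE))$auc, 0.5)

  score <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  label <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  brute <- 0
  for (i in which(label)) for (j in which(!label))
    brute <- brute + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  brute <- brute / (sum(label) * sum(!label))
  expect_equal(interface_roc(score, label)$auc, brute)

  expect_message(r <- interface_roc(c(1, 2), c(TRUE, TRUE)), "single-class")
  expect_true(is.na(r$auc))

  conf <- interface_roc(score, label, is_marker = c(TRUE, TRUE, FALSE,
                                                    FALSE, TRUE, FALSE))
  expect_equal(unname(conf$confusion["tp"]), 2)
  expect_equal(sum(conf$confusion), 6)
})

test_that("toy structures survive a PDB round-trip", {
  st <- simulate_dimer_structure(15, 4, seed = 31)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  back <- read_structure_pdb(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(sort(unique(back$atoms$chain)), c("A", "B"))
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(read_structure(path)$atoms, back$atoms)
})
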