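#' Generate a random proteome
#'
#' Draws `n_proteins` amino-acid sequences with lengths uniform in
#' `length_range` and residues sampled uniformly from the 20 standard amino
#' acids. Deterministic for a fixed seed.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_range integer vector `c(min, max)` of sequence lengths.
#' @param seed RNG seed.
#' @return Data frame with `protein_id`, `sequence`, `mw_da`.
#' @export
make_proteome <- function(n_proteins, length_range = c(150L, 600L), seed = 1L) {
  stopifnot(n_proteins >= 1)
  if (length_range[1] > length_range[2])
    stop("length_range min exceeds max")
  aas <- names(.residue_mass)
  withr_seed(seed, {
    lens_pool <- seq.int(length_range[1], length_range[2])
    lens <- lens_pool[sample.int(length(lens_pool), n_proteins,
                                 replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(aas, L, replace = TRUE), collapse = ""), character(1))
  })
  data.frame(protein_id = sprintf("P%04d", seq_len(n_proteins)),
             sequence = seqs,
             mw_da = vapply(seqs, protein_mw, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

#' In-silico digest: fully tryptic and PK semi-tryptic peptides
#'
#' Fully tryptic peptides come from cleavage after every K/R (no missed
#' cleavages). Semi-tryptic peptides emulate limited proteolysis: random
#' internal proteinase K cut sites are paired with the flanking tryptic
#' termini of their host peptide, so every semi-tryptic peptide nests within
#' exactly one fully tryptic parent. Peptides shorter than `min_length`
#' residues are discarded; peptide sequences shared by several proteins are
#' dropped (proteotypic-only).
#'
#' @param proteome data frame from [make_proteome()] / [read_proteome_fasta()].
#' @param pk_sites_per_protein random PK cut sites drawn per protein.
#' @param seed RNG seed.
#' @param min_length minimum peptide length (default 6).
#' @return Peptide annotation data frame (`peptide_id`, `protein_id`,
#'   `sequence`, `start`, `end`, `tryptic_type`), coordinates 1-based
#'   inclusive.
#' @export
digest_in_silico <- function(proteome, pk_sites_per_protein = 2L, seed = 1L,
                             min_length = 6L) {
  stopifnot(nrow(proteome) >= 1)
  out <- vector("list", nrow(proteome))
  withr_seed(seed, {
    for (i in seq_len(nrow(proteome))) {
      ps <- proteome$sequence[i]
      L <- nchar(ps)
      res <- strsplit(ps, "")[[1]]
      cut_after <- which(res %in% c("K", "R"))
      bounds <- unique(c(0L, cut_after, L))
      starts <- utils::head(bounds, -1) + 1L
      ends <- bounds[-1]
      tr <- data.frame(start = starts, end = ends, tryptic_type = "fully_tryptic",
                       stringsAsFactors = FALSE)
      semi <- NULL
      if (pk_sites_per_protein > 0 && L > 2) {
        pk <- sample(seq_len(L - 1L), min(pk_sites_per_protein, L - 1L))
        semi_list <- lapply(pk, function(p) {
          host <- which(starts <= p & ends > p)  # cut strictly inside host
          if (length(host) != 1) return(NULL)
          data.frame(start = c(starts[host], p + 1L),
                     end = c(p, ends[host]),
                     tryptic_type = "semi_tryptic", stringsAsFactors = FALSE)
        })
        semi <- do.call(rbind, semi_list)
      }
      pep <- rbind(tr, semi)
      pep <- pep[pep$end - pep$start + 1L >= min_length, , drop = FALSE]
      if (nrow(pep) == 0) next
      pep$protein_id <- proteome$protein_id[i]
      pep$sequence <- substring(ps, pep$start, pep$end)
      out[[i]] <- pep
    }
  })
  pep <- do.call(rbind, out)
  if (is.null(pep)) stop("no peptides above the length floor")
  pep <- pep[!duplicated(paste(pep$protein_id, pep$start, pep$end)), ]
  # proteotypic only: drop sequences seen in more than one protein
  multi <- unique(pep$sequence[duplicated(unique(pep[c("sequence",
                                                       "protein_id")])$sequence)])
  pep <- pep[!pep$sequence %in% multi, , drop = FALSE]
  pep$peptide_id <- pep$sequence
  rownames(pep) <- NULL
  pep[, c("peptide_id", "protein_id", "sequence", "start", "end",
          "tryptic_type")]
}

#' Ground-truth parameters for a simulated fractionation experiment
#'
#' @param planted_markers data frame with `protein_id`, `start`, `end`,
#'   `log2fc`, `fraction`: the peptide/protein ratio of peptides overlapping
#'   the region is multiplied by `2^log2fc` in the named fraction.
#' @param fractions group labels, largest molecular weight cutoff first.
#' @param n_replicates replicates per fraction.
#' @param cv_peptide,cv_protein replicate coefficients of variation of the
#'   log-normal intensity noise.
#' @param missingness independent record drop-out probability.
#' @param seed RNG seed.
#' @return A list of class `flip_truth`.
#' @export
flip_truth <- function(planted_markers = NULL,
                       fractions = c("100K", "50K", "30K", "10K"),
                       n_replicates = 4L, cv_peptide = 0.1, cv_protein = 0.1,
                       missingness = 0, seed = 1L) {
  stopifnot(cv_peptide >= 0, cv_protein >= 0,
            missingness >= 0, missingness < 1, n_replicates >= 1)
  if (!is.null(planted_markers)) {
    stopifnot(all(c("protein_id", "start", "end", "log2fc", "fraction") %in%
                    names(planted_markers)))
    stopifnot(all(is.finite(planted_markers$log2fc)))
    stopifnot(all(planted_markers$fraction %in% fractions))
  }
  structure(list(planted_markers = planted_markers, fractions = fractions,
                 n_replicates = n_replicates, cv_peptide = cv_peptide,
                 cv_protein = cv_protein, missingness = missingness,
                 seed = seed),
            class = "flip_truth")
}

# log-normal multiplier with unit mean and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a fractionated LiP experiment with planted markers
#'
#' Protein intensities follow per-protein, per-fraction mean abundances with
#' multiplicative log-normal replicate noise at `cv_protein`. Each peptide has
#' a fraction-constant expected peptide/protein yield; peptides overlapping a
#' planted marker region have that yield multiplied by `2^log2fc` in the
#' marker's fraction. Peptide intensities get independent log-normal noise at
#' `cv_peptide`. Records are dropped independently at the missingness rate.
#'
#' @param truth a [flip_truth()] object.
#' @param proteome proteome data frame.
#' @param peptides peptide annotations (e.g. from [digest_in_silico()]).
#' @param fraction_abundance optional matrix (proteins x fractions) of mean
#'   protein abundances; defaults to a per-protein log-normal base abundance
#'   constant across fractions.
#' @return List with `lip` and `tryptic_control` intensity records and
#'   `peptide_truth` (per peptide: `is_marker` and the planted `log2fc`).
#' @export
simulate_flip_experiment <- function(truth, proteome, peptides,
                                     fraction_abundance = NULL) {
  stopifnot(inherits(truth, "flip_truth"))
  frs <- truth$fractions
  reps <- seq_len(truth$n_replicates)
  np <- nrow(proteome); nf <- length(frs)

  withr_seed(truth$seed, {
    if (is.null(fraction_abundance)) {
      base <- stats::rlnorm(np, meanlog = log(1e6), sdlog = 0.5)
      fraction_abundance <- matrix(base, np, nf,
                                   dimnames = list(proteome$protein_id, frs))
    }
    yield <- stats::setNames(stats::rlnorm(nrow(peptides), log(0.1), 0.3),
                             peptides$peptide_id)

    # marker multiplier per peptide x fraction
    mult <- matrix(1, nrow(peptides), nf,
                   dimnames = list(peptides$peptide_id, frs))
    is_marker <- rep(FALSE, nrow(peptides))
    planted_fc <- rep(0, nrow(peptides))
    pm <- truth$planted_markers
    if (!is.null(pm) && nrow(pm) > 0) {
      for (k in seq_len(nrow(pm))) {
        if (pm$end[k] < pm$start[k] ||
            pm$start[k] < 1)
          stop("planted region invalid: row ", k)
        hit <- peptides$protein_id == pm$protein_id[k] &
          peptides$start <= pm$end[k] & peptides$end >= pm$start[k]
        if (!any(hit))
          warning("planted region without covering peptide: ",
                  pm$protein_id[k], " [", pm$start[k], ",", pm$end[k], "]")
        mult[hit, pm$fraction[k]] <- mult[hit, pm$fraction[k]] * 2^pm$log2fc[k]
        is_marker <- is_marker | hit
        planted_fc[hit] <- planted_fc[hit] + pm$log2fc[k]
      }
    }

    # tryptic control (protein level)
    tc <- expand.grid(analyte_id = proteome$protein_id, group = frs,
                      replicate = reps, stringsAsFactors = FALSE)
    tc$protein_id <- tc$analyte_id
    tc$intensity <- fraction_abundance[cbind(tc$analyte_id, tc$group)] *
      rlnorm_cv(nrow(tc), truth$cv_protein)
    tc$sample_type <- "tryptic_control"

    # LiP (peptide level)
    lp <- expand.grid(analyte_id = peptides$peptide_id, group = frs,
                      replicate = reps, stringsAsFactors = FALSE)
    lp$protein_id <- peptides$protein_id[match(lp$analyte_id,
                                               peptides$peptide_id)]
    expected <- fraction_abundance[cbind(lp$protein_id, lp$group)] *
      yield[lp$analyte_id] * mult[cbind(lp$analyte_id, lp$group)]
    lp$intensity <- expected * rlnorm_cv(nrow(lp), truth$cv_peptide)
    lp$sample_type <- "lip"

    if (truth$missingness > 0) {
      tc <- tc[stats::runif(nrow(tc)) >= truth$missingness, , drop = FALSE]
      lp <- lp[stats::runif(nrow(lp)) >= truth$missingness, , drop = FALSE]
    }
  })
  cols <- c("analyte_id", "protein_id", "group", "replicate", "intensity",
            "sample_type")
  rownames(tc) <- rownames(lp) <- NULL
  list(lip = lp[, cols], tryptic_control = tc[, cols],
       peptide_truth = data.frame(peptide_id = peptides$peptide_id,
                                  protein_id = peptides$protein_id,
                                  is_marker = is_marker,
                                  planted_log2fc = planted_fc,
                                  stringsAsFactors = FALSE))
}

#' Simulate a toy dimer with a planted binding interface
#'
#' Two straight chains of C-alpha plus pseudo-side-chain spheres (uniform
#' atomic radius 1.9 angstrom) run in parallel. A central window of
#' `interface_width` residues of chain B is brought into contact with chain A
#' (side-chain gap about 1.5 angstrom); all other residues sit `far_gap`
#' angstrom away. The contacting window on both chains is recorded as the
#' ground-truth buried set.
#'
#' @param chain_length residues per chain.
#' @param interface_width residues in the contact window
#'   (< `chain_length`).
#' @param seed RNG seed (sequences and a small coordinate jitter).
#' @param contact_gap,far_gap C-alpha plane separation (angstrom) inside and
#'   outside the contact window.
#' @return A `flip_structure`: list with `id`, `atoms` (chain, resno, aa,
#'   atom, x, y, z, radius), `chains`, and `truth` (chain, resno of planted
#'   interface residues).
#' @export
simulate_dimer_structure <- function(chain_length = 40L, interface_width = 10L,
                                     seed = 1L, contact_gap = 4.0,
                                     far_gap = 30) {
  stopifnot(interface_width < chain_length, interface_width >= 1)
  aas <- names(.residue_mass)
  withr_seed(seed, {
    seq_a <- sample(aas, chain_length, replace = TRUE)
    seq_b <- sample(aas, chain_length, replace = TRUE)
    jitter <- stats::runif(4 * chain_length, -0.05, 0.05)
  })
  i <- seq_len(chain_length)
  w0 <- floor((chain_length - interface_width) / 2) + 1L
  window <- seq(w0, w0 + interface_width - 1L)
  x <- 3.8 * i
  gap_b <- ifelse(i %in% window, contact_gap, far_gap)
  atoms <- rbind(
    data.frame(chain = "A", resno = i, aa = seq_a, atom = "CA",
               x = x, y = 0, z = jitter[i], stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = i, aa = seq_a, atom = "CB",
               x = x, y = 1.5, z = jitter[chain_length + i],
               stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = i, aa = seq_b, atom = "CA",
               x = x, y = gap_b, z = jitter[2 * chain_length + i],
               stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = i, aa = seq_b, atom = "CB",
               x = x, y = gap_b - 1.5, z = jitter[3 * chain_length + i],
               stringsAsFactors = FALSE))
  atoms$radius <- 1.9
  truth <- if (contact_gap <= 8)
    data.frame(chain = rep(c("A", "B"), each = interface_width),
               resno = rep(window, 2), stringsAsFactors = FALSE)
  else
    data.frame(chain = character(0), resno = integer(0))
  # reference maximal accessibility: the mid-residue of an unbound toy
  # chain (analogous to the Gly-X-Gly context used for real residue
  # references); identical for every residue type of the toy geometry
  mini <- expand.grid(resno = 1:5, atom = c("CA", "CB"))
  mini$x <- 3.8 * mini$resno
  mini$y <- ifelse(mini$atom == "CA", 0, 1.5)
  mini$z <- 0
  mini$radius <- 1.9
  ref <- sum(atom_sasa(mini)[mini$resno == 3])
  structure(list(id = sprintf("dimer_seed%d", seed), atoms = atoms,
                 chains = c("A", "B"), truth = truth,
                 ref_table = stats::setNames(rep(ref, length(aas)), aas)),
            class = "flip_structure")
}

#' Simulate a protein-complex network with planted communities
#'
#' One clique per complex plus `n_bridge_edges` random cross-complex edges;
#' no self-loops or duplicate edges.
#'
#' @param complex_sizes integer vector of complex sizes (each >= 2).
#' @param n_bridge_edges number of random bridges between distinct complexes.
#' @param seed RNG seed.
#' @return List with `edges` (data frame `from`, `to`), `complexes`
#'   (data frame `complex_id`, `complex_name`, `protein_id`) and `membership`
#'   (named integer vector: planted community per protein).
#' @export
simulate_complex_network <- function(complex_sizes, n_bridge_edges = 0L,
                                     seed = 1L) {
  stopifnot(all(complex_sizes >= 2))
  n <- sum(complex_sizes)
  proteins <- sprintf("N%03d", seq_len(n))
  membership <- rep(seq_along(complex_sizes), complex_sizes)
  names(membership) <- proteins
  cliques <- lapply(seq_along(complex_sizes), function(k) {
    mem <- proteins[membership == k]
    t(utils::combn(mem, 2))
  })
  edges <- do.call(rbind, cliques)
  withr_seed(seed, {
    added <- 0L
    guard <- 0L
    while (added < n_bridge_edges && guard < 10000L) {
      guard <- guard + 1L
      pair <- sample(proteins, 2)
      if (membership[pair[1]] == membership[pair[2]]) next
      key <- paste(sort(pair), collapse = "|")
      have <- paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]), sep = "|")
      if (key %in% have) next
      edges <- rbind(edges, pair)
      added <- added + 1L
    }
  })
  complexes <- data.frame(
    complex_id = sprintf("CPX-%d", membership),
    complex_name = sprintf("complex_%d", membership),
    protein_id = proteins, stringsAsFactors = FALSE)
  list(edges = data.frame(from = edges[, 1], to = edges[, 2],
                          stringsAsFactors = FALSE),
       complexes = complexes, membership = membership)
}
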