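# Residue-type reference maximal accessibilities (theoretical, A^2),
# Tien et al. style; configurable via the ref_table arguments.
.rsasa_ref <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Numeric solvent-accessible surface area per atom
#'
#' Sphere-sampling (Shrake-Rupley style) accessibility: each atom's surface
#' is sampled at `n_points` deterministic points on the sphere of radius
#' `radius + probe_radius`; points not buried inside any neighbouring atom's
#' probe-expanded sphere count as accessible. Deterministic for a fixed point
#' count.
#'
#' @param atoms data frame with `x`, `y`, `z`, `radius`.
#' @param probe_radius solvent probe radius in angstrom (default 1.4).
#' @param n_points sample points per atom.
#' @return Numeric vector of per-atom SASA (A^2).
#' @export
atom_sasa <- function(atoms, probe_radius = 1.4, n_points = 240L) {
  pts <- sphere_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r_ext <- atoms$radius + probe_radius
  n <- nrow(atoms)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    p <- pts * r_ext[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= r_ext[j]^2
    }
    out[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue relative solvent accessibility
#'
#' Sums atom SASA per residue and divides by the residue type's reference
#' maximal accessibility (percent). Values above 100% are possible with
#' theoretical reference maxima and are not clipped.
#'
#' @param structure a `flip_structure`, or an atom data frame with `chain`,
#'   `resno`, `aa`, `x`, `y`, `z`, `radius`.
#' @param probe_radius,n_points see [atom_sasa()].
#' @param ref_table named vector of reference maximal accessibilities per
#'   one-letter residue type.
#' @param ref_default fallback for unknown residue types (a warning is
#'   emitted).
#' @return Data frame `chain`, `resno`, `aa`, `sasa`, `rsasa` (percent).
#' @export
relative_sasa <- function(structure, probe_radius = 1.4, n_points = 240L,
                          ref_table = NULL, ref_default = 130) {
  if (is.null(ref_table))
    ref_table <- if (inherits(structure, "flip_structure") &&
                       !is.null(structure$ref_table)) structure$ref_table
                 else .rsasa_ref
  atoms <- if (inherits(structure, "flip_structure")) structure$atoms
           else structure
  a_sasa <- atom_sasa(atoms, probe_radius, n_points)
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  res_sasa <- rowsum(a_sasa, key)
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    aa = atoms$aa[first], stringsAsFactors = FALSE)
  res$sasa <- as.vector(res_sasa[match(paste(res$chain, res$resno, sep = "|"),
                                       rownames(res_sasa))])
  ref <- ref_table[res$aa]
  if (anyNA(ref)) {
    warning("unknown residue type(s): ",
            paste(unique(res$aa[is.na(ref)]), collapse = ", "),
            "; using reference ", ref_default)
    ref[is.na(ref)] <- ref_default
  }
  res$rsasa <- 100 * res$sasa / ref
  res
}

#' Interface flag from accessibility change
#'
#' A residue is at an interface if its relative accessibility drops by more
#' than 25 percentage points when the full oligomer is compared to its chain
#' in isolation ("above 25%", strict: a change of exactly 25 does not
#' qualify).
#'
#' @param rsasa_isolated,rsasa_oligomer per-residue rSASA (percent).
#' @param threshold percentage-point threshold (default 25).
#' @return Logical vector.
#' @export
flag_interface <- function(rsasa_isolated, rsasa_oligomer, threshold = 25) {
  (rsasa_isolated - rsasa_oligomer) > threshold
}

#' Detect interface residues on a multimeric structure
#'
#' Computes per-residue rSASA on the full assembly and on every chain in
#' isolation; residues whose rSASA drops by more than `threshold` percentage
#' points upon assembly are flagged as interface.
#'
#' @param structure a `flip_structure` with at least two chains.
#' @param threshold percentage-point cutoff (default 25, strict).
#' @param probe_radius,n_points,ref_table,ref_default see [relative_sasa()].
#' @return Data frame `chain`, `resno`, `aa`, `rsasa_oligomer`,
#'   `rsasa_isolated`, `is_interface`.
#' @export
detect_interface <- function(structure, threshold = 25, probe_radius = 1.4,
                             n_points = 240L, ref_table = NULL,
                             ref_default = 130) {
  if (is.null(ref_table))
    ref_table <- if (!is.null(structure$ref_table)) structure$ref_table
                 else .rsasa_ref
  atoms <- structure$atoms
  chains <- unique(atoms$chain)
  olig <- relative_sasa(atoms, probe_radius, n_points, ref_table, ref_default)
  if (length(chains) < 2) {
    warning("single-chain structure: no interface can be detected")
    olig$rsasa_oligomer <- olig$rsasa
    olig$rsasa_isolated <- olig$rsasa
    olig$is_interface <- FALSE
    return(olig[, c("chain", "resno", "aa", "rsasa_oligomer",
                    "rsasa_isolated", "is_interface")])
  }
  iso <- do.call(rbind, lapply(chains, function(ch)
    relative_sasa(atoms[atoms$chain == ch, , drop = FALSE], probe_radius,
                  n_points, ref_table, ref_default)))
  key_o <- paste(olig$chain, olig$resno, sep = "|")
  key_i <- paste(iso$chain, iso$resno, sep = "|")
  olig$rsasa_oligomer <- olig$rsasa
  olig$rsasa_isolated <- iso$rsasa[match(key_o, key_i)]
  olig$is_interface <- flag_interface(olig$rsasa_isolated,
                                      olig$rsasa_oligomer, threshold)
  olig[, c("chain", "resno", "aa", "rsasa_oligomer", "rsasa_isolated",
           "is_interface")]
}

# one-letter chain sequence and resno index from the CA trace
chain_sequence <- function(atoms, chain) {
  ca <- atoms[atoms$chain == chain & atoms$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  list(seq = paste(ca$aa, collapse = ""), resno = ca$resno)
}

#' Map a peptide sequence onto a structure chain
#'
#' Exact substring match of the peptide against every chain sequence. If the
#' peptide occurs in several chain copies (e.g. a homodimer), one occurrence
#' is selected at random under the session RNG, so a fixed seed gives a
#' reproducible choice. Unmapped peptides are excluded downstream.
#'
#' @param peptide_seq amino-acid string.
#' @param structure a `flip_structure`.
#' @return List with `chain`, `resno` (residue numbers covered) or `NULL`
#'   if the peptide is absent from the structure.
#' @export
map_peptide_to_chain <- function(peptide_seq, structure) {
  atoms <- structure$atoms
  hits <- list()
  for (ch in unique(atoms$chain)) {
    cs <- chain_sequence(atoms, ch)
    m <- gregexpr(peptide_seq, cs$seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (pos in as.vector(m))
      hits[[length(hits) + 1L]] <-
        list(chain = ch,
             resno = cs$resno[seq(pos, pos + nchar(peptide_seq) - 1L)])
  }
  if (length(hits) == 0) return(NULL)
  if (length(hits) == 1) return(hits[[1]])
  hits[[sample.int(length(hits), 1L)]]
}

#' Mean minimum C-alpha distance of a peptide to the interface
#'
#' Each peptide residue is assigned its minimum C-alpha to C-alpha distance
#' to any interface residue; the peptide's distance is the mean over its
#' residues.
#'
#' @param mapping result of [map_peptide_to_chain()].
#' @param interface data frame from [detect_interface()] (rows with
#'   `is_interface` are used).
#' @param structure a `flip_structure`.
#' @return Distance in angstrom, or `NA` if the interface is empty.
#' @export
peptide_interface_distance <- function(mapping, interface, structure) {
  ifres <- interface[interface$is_interface, , drop = FALSE]
  if (nrow(ifres) == 0) return(NA_real_)
  atoms <- structure$atoms
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, sep = "|")
  pep_xyz <- as.matrix(ca[match(paste(mapping$chain, mapping$resno, sep = "|"),
                                ca_key), c("x", "y", "z")])
  if_xyz <- as.matrix(ca[match(paste(ifres$chain, ifres$resno, sep = "|"),
                               ca_key), c("x", "y", "z")])
  mins <- vapply(seq_len(nrow(pep_xyz)), function(i) {
    d2 <- (if_xyz[, 1] - pep_xyz[i, 1])^2 + (if_xyz[, 2] - pep_xyz[i, 2])^2 +
      (if_xyz[, 3] - pep_xyz[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
  mean(mins)
}

#' Distance and interface label for a set of peptides on one structure
#'
#' Maps each peptide, computes its interface distance and labels it
#' interface-associated when the distance is below `cutoff` (strict).
#'
#' @param peptides data frame with `peptide_id`, `sequence`.
#' @param structure a `flip_structure`.
#' @param cutoff association cutoff in angstrom (2.6 or 0.3).
#' @param interface optional precomputed [detect_interface()] table.
#' @param ... passed to [detect_interface()].
#' @return Data frame `peptide_id`, `distance`, `interface_associated`;
#'   unmapped peptides and peptides without a defined distance carry `NA`.
#' @export
score_peptides_on_structure <- function(peptides, structure, cutoff = 2.6,
                                        interface = NULL, ...) {
  if (is.null(interface)) interface <- detect_interface(structure, ...)
  dist <- rep(NA_real_, nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    mp <- map_peptide_to_chain(peptides$sequence[i], structure)
    if (is.null(mp)) next
    dist[i] <- peptide_interface_distance(mp, interface, structure)
  }
  data.frame(peptide_id = peptides$peptide_id, distance = dist,
             interface_associated = !is.na(dist) & dist < cutoff,
             stringsAsFactors = FALSE)
}

#' Choose one structure per protein
#'
#' @param candidates named list of `flip_structure` objects.
#' @param policy `"biggest"` (most chains, ties broken by id order),
#'   `"random"` (uniform under the session RNG), or `"best"` (maximizes an
#'   agreement score: number of marker peptides within `cutoff` of the
#'   interface plus non-marker peptides outside it; ties broken by more
#'   chains).
#' @param peptides for `"best"`: data frame with `peptide_id`, `sequence`,
#'   `is_marker`.
#' @param cutoff distance cutoff for the agreement score.
#' @param ... passed to [detect_interface()] for `"best"`.
#' @return The selected `flip_structure`.
#' @export
select_structure <- function(candidates,
                             policy = c("biggest", "random", "best"),
                             peptides = NULL, cutoff = 2.6, ...) {
  policy <- match.arg(policy)
  stopifnot(length(candidates) >= 1)
  n_chains <- vapply(candidates, function(s) length(unique(s$atoms$chain)),
                     integer(1))
  if (policy == "biggest") return(candidates[[which.max(n_chains)]])
  if (policy == "random")
    return(candidates[[sample.int(length(candidates), 1L)]])
  stopifnot(!is.null(peptides))
  score <- vapply(seq_along(candidates), function(k) {
    sc <- score_peptides_on_structure(peptides, candidates[[k]], cutoff, ...)
    ok <- !is.na(sc$distance)
    sum(peptides$is_marker[ok] & sc$interface_associated[ok]) +
      sum(!peptides$is_marker[ok] & !sc$interface_associated[ok])
  }, numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.max(n_chains[best])]
  candidates[[best]]
}

#' ROC AUC for interface proximity prediction by significance
#'
#' AUC is the probability that a randomly chosen interface-associated peptide
#' outscores a randomly chosen non-associated one, with ties counted half.
#' Confusion counts follow the marker mapping: marker at interface = TP,
#' marker off interface = FP, non-marker at interface = FN, non-marker off
#' interface = TN.
#'
#' @param score numeric prediction score (e.g. `-log10(q)`).
#' @param label logical interface association at the chosen cutoff.
#' @param is_marker optional logical marker call for the confusion counts.
#' @return List with `auc` (`NA` with a message if only one class is
#'   present), `n_pos`, `n_neg` and, when `is_marker` is given, `confusion`.
#' @export
interface_roc <- function(score, label, is_marker = NULL) {
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- as.logical(label[keep])
  n_pos <- sum(label); n_neg <- sum(!label)
  auc <- if (n_pos == 0 || n_neg == 0) {
    message("single-class labels: AUC undefined")
    NA_real_
  } else {
    r <- rank(score)
    (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  out <- list(auc = auc, n_pos = n_pos, n_neg = n_neg)
  if (!is.null(is_marker)) {
    m <- as.logical(is_marker[keep])
    out$confusion <- c(tp = sum(m & label), fp = sum(m & !label),
                       fn = sum(!m & label), tn = sum(!m & !label))
  }
  out
}

# van der Waals radii by element for experimental structures
.element_radius <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2)

#' Read a structure from a PDB file
#'
#' Parses protein atoms (via bio3d), assigns element van der Waals radii and
#' one-letter residue codes.
#'
#' @param path PDB file.
#' @param id structure id (defaults to the file name).
#' @return A `flip_structure`.
#' @export
read_structure_pdb <- function(path, id = basename(path)) {
  from_bio3d(bio3d::read.pdb(path, verbose = FALSE), id)
}

#' Read a structure from a PDB or mmCIF file
#'
#' Dispatches on the file extension (`.cif`/`.mmcif` via bio3d's mmCIF
#' parser, anything else as PDB).
#'
#' @param path structure file.
#' @param id structure id (defaults to the file name).
#' @return A `flip_structure`.
#' @export
read_structure <- function(path, id = basename(path)) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    from_bio3d(bio3d::read.cif(path, verbose = FALSE), id)
  else
    read_structure_pdb(path, id)
}

from_bio3d <- function(pdb, id) {
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  radius <- .element_radius[toupper(elem)]
  radius[is.na(radius)] <- 1.7
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      aa = bio3d::aa321(at$resid), atom = at$elety,
                      x = at$x, y = at$y, z = at$z, radius = unname(radius),
                      stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms, chains = unique(atoms$chain),
                 truth = NULL),
            class = "flip_structure")
}

#' Write a `flip_structure` to a PDB file
#'
#' @param structure a `flip_structure` (e.g. from
#'   [simulate_dimer_structure()]); pseudo-atoms are written as C-alpha/
#'   C-beta carbons.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  aa3 <- stats::setNames(bio3d::aa.table$aa3,
                         bio3d::aa.table$aa1)[a$aa]
  aa3[is.na(aa3)] <- "UNK"
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[, c("x", "y",
                                                                  "z")]))),
                   type = "ATOM", resno = a$resno, resid = aa3,
                   chain = a$chain, elety = a$atom)
  invisible(path)
}
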