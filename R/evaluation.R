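BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA_THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                     GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                     LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                     SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Construct a structure model from an atom table
#'
#' A light container for protein coordinates: one row per heavy atom with
#' chain, residue number, 3-letter residue name, atom name, and x/y/z in
#' Angstrom. Residue numbers are assumed to be mapped to alignment query
#' positions.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("Structure model: %d atoms, chains %s\n", nrow(x$atoms),
              paste(sprintf("%s (%d)", names(ch), ch), collapse = ", ")))
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses with bio3d; keeps ATOM records of the first model, alternate
#' location blank or `A`, hydrogens and HETATM excluded.
#'
#' @param path PDB file path.
#' @return A [structure_model].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    !grepl("^H", trimws(at$elety))
  at <- at[keep, , drop = FALSE]
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = trimws(at$elety),
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE))
}

#' Write a structure model to PDB
#'
#' @param s A [structure_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, chain = at$chain, elety = at$elety)
  invisible(path)
}

chain_atoms <- function(s, chain) {
  s$atoms[s$atoms$chain == chain, , drop = FALSE]
}

is_sidechain <- function(resid, elety) {
  ifelse(resid == "GLY", elety == "CA", !(elety %in% BACKBONE_ATOMS))
}

# distance matrix between two coordinate blocks
cross_dist <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
  sqrt(pmax(d2, 0))
}

#' Residue-pair distance table between two chains
#'
#' For every residue pair across the two chains: the minimal distance
#' between side-chain heavy atoms (Cbeta and beyond; Calpha for glycine),
#' the Cbeta-Cbeta distance (Calpha for glycine), and the Calpha-Calpha
#' distance. Missing atoms yield `NA`, never zero.
#'
#' @param s A [structure_model].
#' @param chain_a,chain_b Chain identifiers.
#' @return Data frame of class `contact_table` with columns `resno_a`,
#'   `resno_b`, `d_sc`, `d_cb`, `d_ca`.
#' @export
pair_distances <- function(s, chain_a, chain_b) {
  at_a <- chain_atoms(s, chain_a)
  at_b <- chain_atoms(s, chain_b)
  if (nrow(at_a) == 0L || nrow(at_b) == 0L)
    stop("both chains must contain at least one residue")
  d <- cross_dist(at_a, at_b)

  res_a <- sort(unique(at_a$resno))
  res_b <- sort(unique(at_b$resno))
  grid <- expand.grid(resno_a = res_a, resno_b = res_b)

  min_over <- function(sel_a, sel_b) {
    vapply(seq_len(nrow(grid)), function(k) {
      ia <- which(at_a$resno == grid$resno_a[k] & sel_a)
      ib <- which(at_b$resno == grid$resno_b[k] & sel_b)
      if (length(ia) == 0L || length(ib) == 0L) return(NA_real_)
      min(d[ia, ib])
    }, numeric(1))
  }
  sc_a <- is_sidechain(at_a$resid, at_a$elety)
  sc_b <- is_sidechain(at_b$resid, at_b$elety)
  cb_a <- ifelse(at_a$resid == "GLY", at_a$elety == "CA", at_a$elety == "CB")
  cb_b <- ifelse(at_b$resid == "GLY", at_b$elety == "CA", at_b$elety == "CB")

  out <- data.frame(grid,
                    d_sc = min_over(sc_a, sc_b),
                    d_cb = min_over(cb_a, cb_b),
                    d_ca = min_over(at_a$elety == "CA", at_b$elety == "CA"))
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Are two chains in contact?
#'
#' Two proteins count as in contact when any Calpha atom of one lies within
#' `d_cut` Angstrom of a Calpha atom of the other (boundary inclusive:
#' a pair at exactly `d_cut` is in contact).
#'
#' @param s A [structure_model].
#' @param chain_a,chain_b Chain identifiers.
#' @param d_cut Calpha-Calpha cutoff in Angstrom.
#' @return Logical.
#' @export
protein_pair_in_contact <- function(s, chain_a, chain_b, d_cut = 12.0) {
  ca_a <- chain_atoms(s, chain_a)
  ca_a <- ca_a[ca_a$elety == "CA", , drop = FALSE]
  ca_b <- chain_atoms(s, chain_b)
  ca_b <- ca_b[ca_b$elety == "CA", , drop = FALSE]
  if (nrow(ca_a) == 0L || nrow(ca_b) == 0L)
    stop("both chains need Calpha atoms")
  any(cross_dist(ca_a, ca_b) <= d_cut)
}

#' Contact precision per score bin
#'
#' Bins scored inter-protein pairs by calibrated score and reports, per
#' bin, the fraction whose minimal side-chain heavy-atom distance in the
#' structure is below `contact_cut`. Pairs are matched to the contact table
#' on query residue numbers. Empty bins report `n = 0` and `NA` precision.
#'
#' @param scores A [coupling_scores] table (inter pairs are used).
#' @param contacts A [pair_distances] table on the same residue numbering.
#' @param breaks Increasing score-bin boundaries.
#' @param contact_cut Distance defining a true contact (Angstrom).
#' @return Data frame with `bin_lo`, `bin_hi`, `n`, `precision`.
#' @export
precision_curve <- function(scores, contacts,
                            breaks = c(0, 0.25, 0.5, 0.75, 1),
                            contact_cut = 12.0) {
  sel <- scores[scores$inter, , drop = FALSE]
  key <- paste(contacts$resno_a, contacts$resno_b)
  idx <- match(paste(sel$resno_i, sel$resno_j), key)
  if (anyNA(idx))
    stop("some scored pairs are absent from the contact table")
  hit <- contacts$d_sc[idx] < contact_cut
  bin <- cut(sel$score, breaks, include.lowest = TRUE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L])
  out$n <- as.integer(table(bin))
  prec <- tapply(hit, bin, function(h) mean(h, na.rm = TRUE))
  out$precision <- as.numeric(prec)
  out$precision[out$n == 0L] <- NA_real_
  out
}

interface_contacts <- function(s, chain_a, chain_b, d_cut) {
  ct <- pair_distances(s, chain_a, chain_b)
  ct[!is.na(ct$d_sc) & ct$d_sc < d_cut, c("resno_a", "resno_b")]
}

#' Fraction of native interface contacts reproduced in a model
#'
#' Native interface contacts are cross-chain residue pairs of the reference
#' whose minimal side-chain heavy-atom distance is below `d_cut`; the
#' returned value is the fraction of them that are also contacts in the
#' model (matched by chain and residue number).
#'
#' @param model,reference [structure_model]s with corresponding chain ids
#'   and residue numbering.
#' @param chain_a,chain_b Chain identifiers.
#' @param d_cut Contact distance in Angstrom.
#' @return Fraction in `[0, 1]`.
#' @export
fnat <- function(model, reference, chain_a = "A", chain_b = "B",
                 d_cut = 5.0) {
  native <- interface_contacts(reference, chain_a, chain_b, d_cut)
  if (nrow(native) == 0L)
    stop("reference structure has no interface contacts")
  modeled <- interface_contacts(model, chain_a, chain_b, d_cut)
  nat_key <- paste(native$resno_a, native$resno_b)
  mod_key <- paste(modeled$resno_a, modeled$resno_b)
  mean(nat_key %in% mod_key)
}

# least-squares superposition (Kabsch, via SVD); returns rotated+translated
# copy of `mobile` (n x 3) onto `fixed` (n x 3)
kabsch_fit <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  sweep(A %*% t(R), 2, cf, "+")
}

#' Interface Calpha RMSD after optimal superposition
#'
#' Interface residues are those of the reference with any cross-chain
#' Calpha within `interface_cut` Angstrom. The model's interface Calpha
#' atoms are superposed onto the reference's by least-squares rotation and
#' the RMSD over them is returned; the value is invariant to rigid motions
#' of the model.
#'
#' @param model,reference [structure_model]s with corresponding chain ids
#'   and residue numbering.
#' @param chain_a,chain_b Chain identifiers.
#' @param interface_cut Calpha-Calpha cutoff defining interface residues.
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, chain_a = "A", chain_b = "B",
                           interface_cut = 12.0) {
  ca <- function(s, chain) {
    at <- chain_atoms(s, chain)
    at[at$elety == "CA", , drop = FALSE]
  }
  ra <- ca(reference, chain_a)
  rb <- ca(reference, chain_b)
  d <- cross_dist(ra, rb)
  ifc_a <- ra$resno[apply(d, 1L, min) <= interface_cut]
  ifc_b <- rb$resno[apply(d, 2L, min) <= interface_cut]
  sel <- rbind(data.frame(chain = chain_a, resno = ifc_a),
               data.frame(chain = chain_b, resno = ifc_b))
  if (nrow(sel) < 3L)
    stop("fewer than 3 interface residues in the reference")

  coords <- function(s) {
    m <- lapply(seq_len(nrow(sel)), function(k) {
      at <- s$atoms[s$atoms$chain == sel$chain[k] &
                      s$atoms$resno == sel$resno[k] &
                      s$atoms$elety == "CA", , drop = FALSE]
      if (nrow(at) != 1L)
        stop(sprintf("missing interface Calpha %s%d in model",
                     sel$chain[k], sel$resno[k]))
      c(at$x, at$y, at$z)
    })
    do.call(rbind, m)
  }
  ref_xyz <- coords(reference)
  mod_xyz <- kabsch_fit(ref_xyz, coords(model))
  sqrt(mean(rowSums((mod_xyz - ref_xyz)^2)))
}
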