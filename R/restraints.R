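# Heavy side-chain atoms per residue (PDB naming); Cbeta counts as
# side chain, glycine falls back to Calpha.
SIDECHAIN_ATOMS <- list(
  A = "CB",
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = "CA",
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  V = c("CB", "CG1", "CG2")
)

centroid_atom <- function(aa) if (aa == "G") "CA" else "CB"

#' Construct a sigmoidal atom-pair distance restraint
#'
#' The restraint evaluates to
#' `weight / (1 + exp(-slope * (d - cutoff))) + intercept` at inter-atomic
#' distance `d`: a smooth step of height `weight` centered at `cutoff`
#' (Angstrom) with steepness `slope` (1/Angstrom). Negative weights reward
#' distances below the cutoff (attractive); positive weights with negative
#' intercepts can encode repulsion.
#'
#' @param chain_i,resno_i,atom_i Selector of the first atom.
#' @param chain_j,resno_j,atom_j Selector of the second atom.
#' @param weight Step height.
#' @param slope Steepness, must be nonzero.
#' @param cutoff Midpoint distance in Angstrom.
#' @param intercept Additive offset.
#' @return An object of class `sigmoid_restraint`.
#' @export
sigmoid_restraint <- function(chain_i, resno_i, atom_i, chain_j, resno_j,
                              atom_j, weight, slope, cutoff,
                              intercept = 0) {
  if (slope == 0) stop("slope must be nonzero")
  structure(list(chain_i = chain_i, resno_i = as.integer(resno_i),
                 atom_i = atom_i, chain_j = chain_j,
                 resno_j = as.integer(resno_j), atom_j = atom_j,
                 weight = weight, slope = slope, cutoff = cutoff,
                 intercept = intercept),
            class = "sigmoid_restraint")
}

#' Construct an ambiguous restraint
#'
#' A non-empty set of alternative atom-pair restraints for one residue
#' pair; the effective score at a set of distances is the minimum over the
#' alternatives (the restraint is satisfied if any alternative is).
#'
#' @param alternatives List of [sigmoid_restraint] objects.
#' @return An object of class `ambiguous_restraint`.
#' @export
ambiguous_restraint <- function(alternatives) {
  if (length(alternatives) == 0L)
    stop("ambiguous restraint needs at least one alternative")
  stopifnot(all(vapply(alternatives, inherits, TRUE, "sigmoid_restraint")))
  structure(list(alternatives = alternatives), class = "ambiguous_restraint")
}

#' Evaluate a restraint at a distance
#'
#' @param r A [sigmoid_restraint] or [ambiguous_restraint].
#' @param d Distance(s) in Angstrom; for an ambiguous restraint either one
#'   distance per alternative or a single distance applied to all, and the
#'   minimum over alternatives is returned.
#' @return Restraint score(s).
#' @export
eval_restraint <- function(r, d) UseMethod("eval_restraint")

#' @export
eval_restraint.sigmoid_restraint <- function(r, d) {
  stopifnot(all(d >= 0))
  r$weight / (1 + exp(-r$slope * (d - r$cutoff))) + r$intercept
}

#' @export
eval_restraint.ambiguous_restraint <- function(r, d) {
  k <- length(r$alternatives)
  if (length(d) == 1L) d <- rep(d, k)
  if (length(d) != k)
    stop("need one distance per alternative (or a single distance)")
  min(mapply(function(alt, dd) eval_restraint(alt, dd), r$alternatives, d))
}

#' Default residue-pair parameters for centroid restraints
#'
#' Editable lookup of Cbeta-Cbeta cutoff (Angstrom) and slope per ordered
#' amino-acid pair. The shipped default is a flat 8 Angstrom cutoff with
#' slope 2 for every pair; supply a data frame with columns `aa_i`, `aa_j`,
#' `cutoff`, `slope` to override specific pairs.
#'
#' @param overrides Optional data frame of per-pair overrides.
#' @return Function `(aa_i, aa_j) -> list(cutoff, slope)`.
#' @export
centroid_params <- function(overrides = NULL) {
  if (!is.null(overrides))
    stopifnot(all(c("aa_i", "aa_j", "cutoff", "slope") %in% names(overrides)))
  function(aa_i, aa_j) {
    if (!is.null(overrides)) {
      hit <- which((overrides$aa_i == aa_i & overrides$aa_j == aa_j) |
                     (overrides$aa_i == aa_j & overrides$aa_j == aa_i))
      if (length(hit))
        return(list(cutoff = overrides$cutoff[hit[1L]],
                    slope = overrides$slope[hit[1L]]))
    }
    list(cutoff = 8, slope = 2)
  }
}

#' Convert top-scoring inter-protein pairs into distance restraints
#'
#' Selects the `top_k` inter-protein pairs by calibrated score and emits
#' one restraint per pair. In `"centroid"` mode a single Cbeta-Cbeta
#' restraint is written (Calpha for glycine) with a residue-pair-specific
#' cutoff and slope from `params`; in `"fullatom"` mode an ambiguous
#' restraint over all side-chain heavy-atom combinations with cutoff 5.5
#' Angstrom and slope 4. The weight of each restraint is
#' `-weight_scale * ncs` (negative: low distances are rewarded), so weight
#' magnitudes preserve the coupling-strength ordering.
#'
#' @param scores A [coupling_scores] table.
#' @param seq_a,seq_b Ungapped query sequences of the two proteins
#'   (single-letter strings); restraint residue numbers index into these.
#' @param mode `"centroid"` or `"fullatom"`.
#' @param top_k Number of inter pairs to restrain; default
#'   `round(3 * L / 2)` capped at the number of inter pairs.
#' @param weight_scale Proportionality constant between `ncs` and the
#'   weight magnitude.
#' @param params Parameter lookup from [centroid_params] (centroid mode).
#' @return List of restraints of class `restraint_set`.
#' @export
build_restraints <- function(scores, seq_a, seq_b,
                             mode = c("centroid", "fullatom"),
                             top_k = NULL, weight_scale = 1,
                             params = centroid_params()) {
  mode <- match.arg(mode)
  L <- attr(scores, "L")
  if (is.null(top_k)) top_k <- round(3 * L / 2)
  sel <- rank_pairs(scores, "inter", top_n = top_k)
  if (nrow(sel) == 0L) stop("no inter-protein pairs to restrain")
  aa_a <- strsplit(seq_a, "")[[1L]]
  aa_b <- strsplit(seq_b, "")[[1L]]

  out <- lapply(seq_len(nrow(sel)), function(k) {
    ri <- sel$resno_i[k]
    rj <- sel$resno_j[k]
    if (ri > length(aa_a) || rj > length(aa_b))
      stop(sprintf("pair (%d, %d) outside the query sequences", ri, rj))
    ai <- aa_a[ri]
    aj <- aa_b[rj]
    wt <- -weight_scale * sel$ncs[k]
    if (mode == "centroid") {
      pp <- params(ai, aj)
      sigmoid_restraint("A", ri, centroid_atom(ai), "B", rj,
                        centroid_atom(aj), weight = wt, slope = pp$slope,
                        cutoff = pp$cutoff)
    } else {
      atoms_i <- SIDECHAIN_ATOMS[[ai]]
      atoms_j <- SIDECHAIN_ATOMS[[aj]]
      combos <- expand.grid(x = atoms_i, y = atoms_j,
                            stringsAsFactors = FALSE)
      ambiguous_restraint(lapply(seq_len(nrow(combos)), function(t)
        sigmoid_restraint("A", ri, combos$x[t], "B", rj, combos$y[t],
                          weight = wt, slope = 4, cutoff = 5.5)))
    }
  })
  structure(out, class = "restraint_set",
            scores = sel[, c("resno_i", "resno_j", "ncs", "score")])
}

#' @export
print.restraint_set <- function(x, ...) {
  amb <- vapply(x, inherits, TRUE, "ambiguous_restraint")
  cat(sprintf("Restraint set: %d restraints (%d ambiguous)\n",
              length(x), sum(amb)))
  invisible(x)
}

flatten_restraints <- function(rs) {
  rows <- list()
  for (k in seq_along(rs)) {
    r <- rs[[k]]
    alts <- if (inherits(r, "ambiguous_restraint")) r$alternatives else list(r)
    for (a in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = k,
        type = if (inherits(r, "ambiguous_restraint")) "ambiguous" else "pair",
        chain_i = a$chain_i, resno_i = a$resno_i, atom_i = a$atom_i,
        chain_j = a$chain_j, resno_j = a$resno_j, atom_j = a$atom_j,
        weight = a$weight, slope = a$slope, cutoff = a$cutoff,
        intercept = a$intercept, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write restraints in the native TSV format
#'
#' One row per atom-pair alternative with a `group` column tying the
#' alternatives of an ambiguous restraint together.
#'
#' @param rs A `restraint_set` from [build_restraints].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints_tsv <- function(rs, path) {
  utils::write.table(flatten_restraints(rs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

rosetta_atompair_line <- function(a) {
  sprintf(paste0("AtomPair %s %d%s %s %d%s SCALARWEIGHTEDFUNC %.3f ",
                 "SUMFUNC 2 SIGMOID %.2f %.2f CONSTANTFUNC %.3f"),
          a$atom_i, a$resno_i, a$chain_i, a$atom_j, a$resno_j, a$chain_j,
          abs(a$weight), a$cutoff, a$slope,
          if (a$weight < 0) -1 else 0)
}

#' Write restraints as Rosetta-style constraint lines
#'
#' Each pair restraint becomes an `AtomPair` line with a scalar-weighted
#' sigmoid function (a `CONSTANTFUNC -1` term shifts attractive restraints
#' so a satisfied restraint scores `-weight` and an unsatisfied one 0);
#' ambiguous restraints are wrapped in
#' `AmbiguousConstraint`/`END_AMBIGUOUS` blocks. Residues are numbered by
#' query position with the chain letter appended.
#'
#' @param rs A `restraint_set` from [build_restraints].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rosetta_constraints <- function(rs, path) {
  lines <- character(0)
  for (r in rs) {
    if (inherits(r, "ambiguous_restraint")) {
      lines <- c(lines, "AmbiguousConstraint",
                 vapply(r$alternatives, rosetta_atompair_line, character(1)),
                 "END_AMBIGUOUS")
    } else {
      lines <- c(lines, rosetta_atompair_line(r))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
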