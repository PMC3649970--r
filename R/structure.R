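# Protein van der Waals radii (Angstrom), NACCESS-style element values
# (Chothia-type set). Used for Shrake-Rupley SASA.
.vdw_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                H = 1.00, SE = 1.90)
.vdw_default <- 1.80

# Chemical element from a PDB atom name ("CA", "1HB", "OXT", "SD", ...).
element_from_atom_name <- function(elety) {
  e <- toupper(gsub("[0-9' ]", "", elety))
  ifelse(substr(e, 1, 2) == "SE", "SE", substr(e, 1, 1))
}

#' Build a structure model from an atom table
#'
#' @param atoms A data.frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `x`, `y`, `z`, and optionally `occ` and
#'   `element`.
#' @param source_id Optional identifier recorded with the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source_id = NA_character_) {
  need <- c("chain", "resno", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$resid)) atoms$resid <- "UNK"
  if (is.null(atoms$element))
    atoms$element <- element_from_atom_name(atoms$elety)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) after altloc filtering")
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, chains %s%s\n",
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ","),
              if (is.na(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

#' Read a protein structure into a structure model
#'
#' Parses PDB or mmCIF coordinate files (via bio3d) or a plain CSV atom
#' table with columns chain, resno, resid, elety, x, y, z. Keeps the
#' highest-occupancy alternate location of each atom; waters, other
#' heteroatoms and hydrogens are excluded by default.
#'
#' @param file Path to a `.pdb`/`.ent`, `.cif` or `.csv` file.
#' @param keep_hetero Keep non-water HETATM records.
#' @param keep_hydrogens Keep hydrogen atoms.
#' @return A [structure_model()].
#' @export
read_structure <- function(file, keep_hetero = FALSE,
                           keep_hydrogens = FALSE) {
  if (!file.exists(file)) stop("no such file: ", file)
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(file)
    at <- pdb$atom
  } else if (ext == "cif") {
    pdb <- bio3d::read.cif(file)
    at <- pdb$atom
  } else if (ext %in% c("csv", "txt")) {
    at <- read.csv(file, stringsAsFactors = FALSE)
    return(structure_model(at, source_id = basename(file)))
  } else stop("unrecognized structure format: .", ext)

  at$resid <- trimws(at$resid)
  if (!keep_hetero) at <- at[at$type == "ATOM" & at$resid != "HOH", ]
  else at <- at[at$resid != "HOH", ]
  at$element <- element_from_atom_name(at$elety)
  if (!keep_hydrogens) at <- at[at$element != "H", ]
  # highest-occupancy altloc per (chain, resno, atom name)
  if (is.null(at$o)) at$o <- 1
  at <- at[order(at$chain, at$resno, at$elety, -at$o), ]
  key <- paste(at$chain, at$resno, at$elety)
  at <- at[!duplicated(key), ]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, element = at$element,
                      x = at$x, y = at$y, z = at$z, occ = at$o,
                      stringsAsFactors = FALSE)
  structure_model(atoms, source_id = basename(file))
}

# Deterministic quasi-uniform unit-sphere sampling (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(model) {
  r <- .vdw_radii[model$atoms$element]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA with a deterministic quasi-uniform sphere sampling
#' (Fibonacci lattice), NACCESS-style protein van der Waals radii and a
#' water-sized probe.
#'
#' @param model A [structure_model()].
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param points_per_atom Sampling points per atom sphere.
#' @return Per-atom accessible areas (Angstrom^2); `sum()` gives the
#'   molecular SASA.
#' @export
sasa <- function(model, probe_radius = 1.4, points_per_atom = 240) {
  stopifnot(inherits(model, "structure_model"), probe_radius > 0,
            points_per_atom >= 12)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  sasa_cpp(xyz, atom_radii(model), probe_radius,
           fibonacci_sphere(points_per_atom))
}

subset_chains <- function(model, chains) {
  structure_model(model$atoms[model$atoms$chain %in% chains, ,
                              drop = FALSE],
                  source_id = model$source_id)
}

#' Buried interface area between two chain groups
#'
#' Computes \[SASA(A alone) + SASA(B alone) - SASA(AB)\] / 2, the buried
#' surface area per monomer of a symmetric dimer interface. The
#' uncorrected total change in accessible area (twice the per-monomer
#' value) is returned alongside, since both conventions are in use.
#'
#' @param model A [structure_model()] containing both chain groups.
#' @param chains_A,chains_B Disjoint, non-empty chain id sets.
#' @param probe_radius,points_per_atom As in [sasa()].
#' @return A list with `per_monomer` and `total_delta` (Angstrom^2) plus
#'   the three component SASA values. Non-contacting chains give 0.
#' @export
buried_interface_area <- function(model, chains_A, chains_B,
                                  probe_radius = 1.4,
                                  points_per_atom = 240) {
  stopifnot(length(chains_A) > 0, length(chains_B) > 0,
            length(intersect(chains_A, chains_B)) == 0)
  mA <- subset_chains(model, chains_A)
  mB <- subset_chains(model, chains_B)
  mAB <- subset_chains(model, c(chains_A, chains_B))
  stopifnot(nrow(mA$atoms) > 0, nrow(mB$atoms) > 0)
  sA <- sum(sasa(mA, probe_radius, points_per_atom))
  sB <- sum(sasa(mB, probe_radius, points_per_atom))
  sAB <- sum(sasa(mAB, probe_radius, points_per_atom))
  delta <- sA + sB - sAB
  if (delta < 1e-6)
    message("chain groups do not contact each other: interface area 0")
  list(per_monomer = max(delta, 0) / 2, total_delta = max(delta, 0),
       sasa_A = sA, sasa_B = sB, sasa_AB = sAB)
}

# Pair atoms of two models by (mapped chain, residue number, atom name).
pair_atoms <- function(model_A, model_B, selection = "CA",
                       chain_map = NULL) {
  a <- model_A$atoms; b <- model_B$atoms
  if (!is.null(selection)) {
    a <- a[a$elety %in% selection, ]
    b <- b[b$elety %in% selection, ]
  }
  map_chain <- function(ch) {
    if (is.null(chain_map)) ch
    else ifelse(ch %in% names(chain_map), unname(chain_map[ch]), NA)
  }
  ka <- paste(map_chain(a$chain), a$resno, a$elety)
  kb <- paste(b$chain, b$resno, b$elety)
  common <- intersect(ka[!grepl("^NA ", ka)], kb)
  ia <- match(common, ka); ib <- match(common, kb)
  list(A = as.matrix(a[ia, c("x", "y", "z")]),
       B = as.matrix(b[ib, c("x", "y", "z")]),
       keys = common)
}

# Kabsch optimal rotation (proper, det = +1) of P onto Q, both centred.
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  svd_h <- svd(H)
  d <- sign(det(svd_h$v %*% t(svd_h$u)))
  if (svd_h$d[2] < 1e-8 * max(svd_h$d))
    stop("degenerate (collinear) selection: rotation is unstable")
  svd_h$v %*% diag(c(1, 1, d)) %*% t(svd_h$u)
}

#' RMSD after optimal rigid superposition
#'
#' Pairs atoms of the two models by chain (optionally remapped), residue
#' number and atom name (C-alpha by default), performs a least-squares
#' rigid superposition (Kabsch algorithm, proper rotation enforced) and
#' returns the post-superposition RMSD.
#'
#' @param model_A,model_B [structure_model()] objects.
#' @param selection Atom name(s) to pair; default `"CA"`. Use `NULL` for
#'   all atoms.
#' @param chain_map Named character vector mapping chains of `model_A` to
#'   chains of `model_B` (e.g. `c(A = "C")`); `NULL` pairs identical
#'   chain ids.
#' @return RMSD in Angstrom, with the number of paired atoms as attribute
#'   `"n_atoms"`.
#' @export
superpose_rmsd <- function(model_A, model_B, selection = "CA",
                           chain_map = NULL) {
  pr <- pair_atoms(model_A, model_B, selection, chain_map)
  n <- nrow(pr$A)
  if (n < 3) stop("need at least 3 paired atoms for superposition")
  cA <- colMeans(pr$A); cB <- colMeans(pr$B)
  P <- sweep(pr$A, 2, cA); Q <- sweep(pr$B, 2, cB)
  U <- kabsch_rotation(P, Q)
  Pr <- P %*% t(U)
  rmsd <- sqrt(mean(rowSums((Pr - Q)^2)))
  attr(rmsd, "n_atoms") <- n
  rmsd
}
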