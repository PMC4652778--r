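# Reaction coordinates from atomic coordinates: the glycosidic chi angle of a
# purine (O4'-C1'-N9-C4) and the CPDb base-flipping pseudodihedral, a dihedral
# of four centres of mass (flanking base pairs, two backbone phosphates, the
# five-membered ring of the target purine).

# Standard atomic weights for frames constructed in code (file input resolves
# masses through bio3d).
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  NA. = 22.990, MG = 24.305, CL = 35.45, K = 39.098, CA = 40.078,
  MN = 54.938, FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904
)

element_from_name <- function(elety) {
  # PDB-style atom names: strip digits and primes, first letters carry the
  # element ("C1'" -> C, "OP1" -> O, "NA" kept as sodium only when exact).
  up <- toupper(elety)
  two <- up %in% c("NA", "MG", "CL", "BR", "FE", "ZN", "MN", "CA2")
  out <- character(length(up))
  stripped <- gsub("[^A-Z]", "", up)
  out[two] <- substr(up[two], 1L, 2L)
  out[!two] <- substr(stripped[!two], 1L, 1L)
  out
}

mass_from_element <- function(elesy) {
  key <- ifelse(toupper(elesy) == "NA", "NA.", toupper(elesy))
  m <- .atomic_weights[key]
  if (any(is.na(m))) {
    stop("unknown element symbol(s): ", paste(unique(elesy[is.na(m)]), collapse = ", "))
  }
  as.numeric(m)
}

#' Build a structure frame from atomic records
#'
#' A structure frame is the minimal atomic container consumed by the
#' reaction-coordinate functions: one row per atom with residue number and
#' name, atom name, element, mass and Cartesian position.
#'
#' @param resno Integer residue numbers.
#' @param resid Character residue names (e.g. "DA", "DT").
#' @param elety Character atom names, unique within a residue (e.g. "C1'").
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param elesy Optional element symbols; derived from `elety` when missing.
#' @param mass Optional masses in amu; resolved from `elesy` when missing.
#' @return A `data.frame` of class `structure_frame`.
#' @export
structure_frame <- function(resno, resid, elety, x, y, z, elesy = NULL, mass = NULL) {
  n <- length(resno)
  stopifnot(length(elety) == n, length(x) == n, length(y) == n, length(z) == n)
  if (any(!is.finite(c(x, y, z)))) stop("structure_frame: non-finite coordinates")
  if (is.null(elesy)) elesy <- element_from_name(elety)
  if (is.null(mass)) mass <- mass_from_element(elesy)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("structure_frame: masses must be > 0")
  key <- paste(resno, elety)
  if (anyDuplicated(key)) {
    stop("structure_frame: duplicated atom name within a residue: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  out <- data.frame(resno = as.integer(resno), resid = as.character(resid),
                    elety = as.character(elety), elesy = as.character(elesy),
                    mass = as.numeric(mass), x = x, y = y, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("structure_frame", "data.frame")
  out
}

#' Read frames from a (multi-model) PDB file
#'
#' ATOM/HETATM records are parsed with bio3d; MODEL/ENDMDL blocks delimit
#' frames and alternate locations other than 'A' or blank are dropped.
#'
#' @param path Path to a PDB file.
#' @return A list of [structure_frame()] objects, one per MODEL.
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  elesy <- tryCatch(suppressWarnings(bio3d::atom2ele(pdb)),
                    error = function(e) element_from_name(at$elety))
  mass <- tryCatch(suppressWarnings(as.numeric(bio3d::atom2mass(pdb))),
                   error = function(e) rep(NA_real_, nrow(at)))
  if (any(is.na(mass))) mass <- mass_from_element(elesy)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    structure_frame(resno = at$resno[keep], resid = at$resid[keep],
                    elety = at$elety[keep], elesy = elesy[keep], mass = mass[keep],
                    x = co[keep, 1L], y = co[keep, 2L], z = co[keep, 3L])
  })
}

#' Pseudoatom selections for the CPDb base-flipping coordinate
#'
#' Each of the four pseudoatoms P1-P4 is a list of selections, one per
#' residue: `list(resno = <int>, atoms = <character or NULL>)`. `atoms =
#' NULL` selects every atom of the residue (heavy atoms only when
#' `heavy_only` is set at evaluation time).
#'
#' @param p1,p2,p3,p4 Lists of selections as described above. P1 is the
#'   centre of mass of the base pairs flanking the target pair, P2 and P3
#'   the two backbone phosphate groups, and P4 the five-membered ring of
#'   the target purine.
#' @return An object of class `pseudoatom_spec`.
#' @export
pseudoatom_spec <- function(p1, p2, p3, p4) {
  groups <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L) stop("pseudoatom_spec: group ", g, " is empty")
    for (sel in groups[[g]]) {
      if (is.null(sel$resno)) stop("pseudoatom_spec: selection without resno in ", g)
    }
  }
  structure(groups, class = "pseudoatom_spec")
}

#' Default pseudoatom selections for a flipping purine in a duplex
#'
#' Encodes the conventional choice for a target purine at residue
#' `target`: P1 is every heavy atom of the base pairs directly above and
#' below the target pair, P2 the phosphate group of the target residue
#' (5' side), P3 the phosphate group of its 3' neighbour, and P4 the
#' five-membered imidazole ring of the purine. The defaults correspond to
#' the A16 target of an A-tract duplex whose flanking pairs are A17-T8 and
#' C15-G10.
#'
#' @param target Residue number of the flipping purine.
#' @param upper,lower Residue numbers of the two flanking base pairs.
#' @return A [pseudoatom_spec()].
#' @export
default_pseudoatom_spec <- function(target = 16L, upper = c(17L, 8L), lower = c(15L, 10L)) {
  phosphate <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'")
  ring <- c("N9", "C8", "N7", "C5", "C4")
  p1 <- lapply(c(upper, lower), function(r) list(resno = as.integer(r), atoms = NULL))
  pseudoatom_spec(
    p1 = p1,
    p2 = list(list(resno = as.integer(target), atoms = phosphate)),
    p3 = list(list(resno = as.integer(target) + 1L, atoms = phosphate)),
    p4 = list(list(resno = as.integer(target), atoms = ring))
  )
}

resolve_selection <- function(frame, sels, heavy_only = TRUE, what = "selection") {
  rows <- integer(0)
  missing <- character(0)
  for (sel in sels) {
    idx <- which(frame$resno == sel$resno)
    if (!is.null(sel$atoms)) {
      idx <- idx[frame$elety[idx] %in% sel$atoms]
    }
    if (heavy_only) idx <- idx[frame$elesy[idx] != "H"]
    if (length(idx) == 0L) {
      missing <- c(missing, paste0("(", sel$resno, ", ",
                                   if (is.null(sel$atoms)) "*" else paste(sel$atoms, collapse = "/"),
                                   ")"))
    }
    rows <- c(rows, idx)
  }
  if (length(rows) == 0L) {
    stop("unresolved ", what, ": no atoms matched ", paste(missing, collapse = ", "))
  }
  rows
}

frame_com <- function(frame, sels, heavy_only = TRUE, what = "selection") {
  rows <- resolve_selection(frame, sels, heavy_only = heavy_only, what = what)
  center_of_mass(frame$mass[rows], as.matrix(frame[rows, c("x", "y", "z")]))
}

#' Glycosidic angle of a purine residue
#'
#' The chi angle is the dihedral of the four consecutive atoms
#' O4'-C1'-N9-C4, resolved by name from the given residue (input row order
#' is irrelevant).
#'
#' @param frame A [structure_frame()].
#' @param resno Residue number of the purine.
#' @return chi in degrees, in `[-180, 180)`.
#' @export
chi_angle <- function(frame, resno) {
  names4 <- c("O4'", "C1'", "N9", "C4")
  rows <- frame[frame$resno == resno, , drop = FALSE]
  pts <- lapply(names4, function(nm) {
    i <- which(rows$elety == nm)
    if (length(i) != 1L) {
      stop("chi_angle: atom ", nm, " is absent from residue ", resno)
    }
    as.numeric(rows[i, c("x", "y", "z")])
  })
  dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}

#' Base-flipping pseudodihedral CPDb
#'
#' The dihedral of the four pseudoatom centres of mass P1-P2-P3-P4.
#' The sign convention is fixed by the P1 -> P2 -> P3 -> P4 ordering of
#' the default spec (5' phosphate of the target as P2, phosphate of the
#' 3' neighbour as P3), chosen so that flipping into the major groove
#' gives CPDb > 0 and into the minor groove CPDb < 0; mirror-imaging the
#' frame negates the angle.
#'
#' @param frame A [structure_frame()].
#' @param spec A [pseudoatom_spec()].
#' @param heavy_only Use heavy atoms only when a selection names a whole
#'   residue (hydrogens are often absent from deposited models).
#' @return CPDb in degrees, in `[-180, 180)`.
#' @export
cpdb_angle <- function(frame, spec, heavy_only = TRUE) {
  stopifnot(inherits(spec, "pseudoatom_spec"))
  coms <- lapply(names(spec), function(g) {
    frame_com(frame, spec[[g]], heavy_only = heavy_only, what = paste0("pseudoatom ", g))
  })
  dihedral(coms[[1L]], coms[[2L]], coms[[3L]], coms[[4L]])
}

#' Classify a glycosidic angle as anti, syn or other
#'
#' anti covers `[-180, -90)`, syn the closed interval `[-90, 90]` (the
#' conventional printed syn range is closed at -90, which that boundary
#' therefore receives), and other the remaining `(90, 180)`.
#'
#' @param chi Numeric vector of glycosidic angles in degrees (wrapped
#'   internally).
#' @return Character vector with values `"anti"`, `"syn"` or `"other"`.
#' @examples
#' classify_chi(c(-120, 0, 135, -90))
#' @export
classify_chi <- function(chi) {
  w <- wrap_angle(chi)
  ifelse(w < -90, "anti", ifelse(w <= 90, "syn", "other"))
}

#' Extract the (time, CPDb, chi) series from a sequence of frames
#'
#' @param frames List of [structure_frame()] objects, in time order.
#' @param chi_resno Residue number of the flipping purine.
#' @param spec A [pseudoatom_spec()] for CPDb.
#' @param times Optional numeric times (ps); defaults to `0, 1, 2, ...`.
#' @param heavy_only Passed to [cpdb_angle()].
#' @return A `data.frame` of class `torsion_series` with columns `time`,
#'   `cpdb`, `chi`, one row per frame in input order.
#' @export
extract_timeseries <- function(frames, chi_resno, spec, times = NULL, heavy_only = TRUE) {
  n <- length(frames)
  if (is.null(times)) times <- seq_len(n) - 1
  stopifnot(length(times) == n)
  cpdb <- chi <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      list(cpdb = cpdb_angle(frames[[i]], spec, heavy_only = heavy_only),
           chi = chi_angle(frames[[i]], chi_resno)),
      error = function(e) stop("extract_timeseries: frame ", i, ": ", conditionMessage(e))
    )
    cpdb[i] <- res$cpdb
    chi[i] <- res$chi
  }
  out <- data.frame(time = as.numeric(times), cpdb = cpdb, chi = chi)
  class(out) <- c("torsion_series", "data.frame")
  out
}
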