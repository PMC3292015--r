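#' Build and validate a molecular topology
#'
#' A topology is the static parameter side of all MM-GBSA energies: per-atom
#' charges, Lennard-Jones and generalized Born parameters, bonded terms
#' (harmonic bonds and angles, periodic dihedrals) and the partition of atoms
#' into ordered residues. Nonbonded exclusions (1-2, 1-3) and scaled 1-4
#' pairs are derived from the bonded terms.
#'
#' @param atoms data.frame with one row per atom and columns `name`,
#'   `element`, `charge` (e), `lj_rmin_half` (A), `lj_epsilon` (kcal/mol),
#'   `gb_radius` (A), `gb_screen`, `mass` (amu), `resno` (1-based residue
#'   number), `resname`. A missing/NA `gb_radius` on a chlorine atom defaults
#'   to 1.75 A.
#' @param bonds data.frame with columns `i`, `j` (atom indices), `k`
#'   (kcal/mol/A^2, energy `k*(r-r0)^2`) and `r0` (A); may be empty.
#' @param angles data.frame with columns `i`, `j`, `k` (vertex `j`), `kf`
#'   (kcal/mol/rad^2, energy `kf*(theta-theta0)^2`) and `theta0` (rad).
#' @param dihedrals data.frame with columns `i`, `j`, `k`, `l`, `v`
#'   (barrier V, kcal/mol, energy `(v/2)*(1+cos(n*phi-gamma))`), `n`
#'   (periodicity) and `gamma` (phase, rad).
#' @param scale14_ele,scale14_vdw divisors applied to 1-4 electrostatic and
#'   Lennard-Jones interactions (force-field convention 1.2 and 2.0).
#'
#' @return An object of class `"mmtopology"`: a list with elements `atoms`,
#'   `bonds`, `angles`, `dihedrals`, `residues` (derived residue table) and
#'   `exclusions` (`excluded` and `scaled14` two-column index matrices).
#' @export
build_topology <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                           scale14_ele = 1.2, scale14_vdw = 2.0) {
  empty_df <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(bonds)) bonds <- empty_df(c("i", "j", "k", "r0"))
  if (is.null(angles)) angles <- empty_df(c("i", "j", "k", "kf", "theta0"))
  if (is.null(dihedrals)) dihedrals <- empty_df(c("i", "j", "k", "l", "v", "n", "gamma"))
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds); angles <- as.data.frame(angles)
  dihedrals <- as.data.frame(dihedrals)
  # atom indices are integral by contract
  for (cc in c("i", "j")) if (!is.null(bonds[[cc]])) bonds[[cc]] <- as.integer(bonds[[cc]])
  for (cc in c("i", "j", "k")) if (!is.null(angles[[cc]])) angles[[cc]] <- as.integer(angles[[cc]])
  for (cc in c("i", "j", "k", "l")) if (!is.null(dihedrals[[cc]])) dihedrals[[cc]] <- as.integer(dihedrals[[cc]])
  if (!is.null(atoms$resno)) atoms$resno <- as.integer(atoms$resno)

  need <- c("name", "element", "charge", "lj_rmin_half", "lj_epsilon",
            "gb_radius", "gb_screen", "mass", "resno", "resname")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("topology schema error: atoms missing field(s): ",
         paste(missing_cols, collapse = ", "))

  # chlorine default intrinsic GB radius
  cl <- atoms$element %in% c("Cl", "CL") & (is.na(atoms$gb_radius))
  atoms$gb_radius[cl] <- 1.75

  top <- structure(list(
    atoms = atoms, bonds = bonds, angles = angles, dihedrals = dihedrals,
    residues = .residue_table(atoms),
    exclusions = .derive_exclusions(nrow(atoms), bonds, angles, dihedrals),
    scale14 = list(ele = scale14_ele, vdw = scale14_vdw)
  ), class = "mmtopology")
  validate_topology(top)
  top
}

.residue_table <- function(atoms) {
  rn <- atoms$resno
  if (any(is.na(rn))) stop("validation error: atom without residue assignment")
  first <- tapply(seq_along(rn), rn, min)
  last <- tapply(seq_along(rn), rn, max)
  ord <- order(as.integer(names(first)))
  data.frame(resno = as.integer(names(first))[ord],
             resname = atoms$resname[first[ord]],
             first = as.integer(first[ord]), last = as.integer(last[ord]),
             row.names = NULL)
}

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

.derive_exclusions <- function(n, bonds, angles, dihedrals) {
  p12 <- if (nrow(bonds)) cbind(bonds$i, bonds$j) else matrix(0L, 0, 2)
  p13 <- if (nrow(angles)) cbind(angles$i, angles$k) else matrix(0L, 0, 2)
  excl <- rbind(p12, p13)
  exkey <- unique(.pair_key(excl[, 1], excl[, 2]))
  p14 <- if (nrow(dihedrals)) cbind(dihedrals$i, dihedrals$l) else matrix(0L, 0, 2)
  if (nrow(p14)) {
    key14 <- .pair_key(p14[, 1], p14[, 2])
    keep <- !(key14 %in% exkey) & p14[, 1] != p14[, 2] & !duplicated(key14)
    p14 <- p14[keep, , drop = FALSE]
  }
  if (length(exkey)) {
    sp <- do.call(rbind, strsplit(exkey, " "))
    excl <- cbind(as.integer(sp[, 1]), as.integer(sp[, 2]))
  } else excl <- matrix(0L, 0, 2)
  list(excluded = excl, scaled14 = p14)
}

#' Validate topology invariants
#'
#' Checks that every atom belongs to exactly one residue, residue spans are
#' contiguous, disjoint and cover all atoms, all bonded indices are in range,
#' 1-4 pairs are a subset of dihedral end pairs, and per-atom parameters are
#' physically admissible (`gb_radius > 0`, `mass > 0`).
#'
#' @param top an `"mmtopology"` object.
#' @return `top`, invisibly; errors describe the failing field.
#' @export
validate_topology <- function(top) {
  atoms <- top$atoms
  n <- nrow(atoms)
  if (n == 0) stop("validation error: topology has no atoms")
  for (f in c("charge", "lj_rmin_half", "lj_epsilon", "gb_radius", "gb_screen", "mass"))
    if (any(is.na(atoms[[f]])))
      stop("topology schema error: atom ", which(is.na(atoms[[f]]))[1],
           " lacks field '", f, "'")
  if (any(atoms$gb_radius <= 0)) stop("validation error: gb_radius must be > 0")
  if (any(atoms$mass <= 0)) stop("validation error: mass must be > 0")

  # residue spans contiguous and exhaustive
  res <- top$residues
  idx <- unlist(lapply(seq_len(nrow(res)), function(r) res$first[r]:res$last[r]))
  if (length(idx) != n || anyDuplicated(idx) || !setequal(idx, seq_len(n)))
    stop("validation error: residue spans must be disjoint and cover all atoms")
  for (r in seq_len(nrow(res)))
    if (!all(atoms$resno[res$first[r]:res$last[r]] == res$resno[r]))
      stop("validation error: residue ", res$resno[r], " is not contiguous")

  chk_idx <- function(ix, what) {
    ix <- unlist(ix)
    if (length(ix) && (any(ix < 1) || any(ix > n)))
      stop("validation error: dangling ", what, " index ",
           ix[which(ix < 1 | ix > n)[1]])
  }
  chk_idx(top$bonds[c("i", "j")], "bond")
  chk_idx(top$angles[c("i", "j", "k")], "angle")
  chk_idx(top$dihedrals[c("i", "j", "k", "l")], "dihedral")

  if (nrow(top$exclusions$scaled14)) {
    dk <- .pair_key(top$dihedrals$i, top$dihedrals$l)
    sk <- .pair_key(top$exclusions$scaled14[, 1], top$exclusions$scaled14[, 2])
    if (!all(sk %in% dk))
      stop("validation error: 1-4 pair not derived from any dihedral")
  }
  invisible(top)
}

#' @export
print.mmtopology <- function(x, ...) {
  cat("mmgbsa topology:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues;",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals\n")
  invisible(x)
}

#' Extract a sub-topology for a set of atoms
#'
#' Keeps the given atoms (indices are remapped to 1..k) together with every
#' bonded term lying entirely inside the selection; exclusions are re-derived.
#' Used by the single-trajectory protocol to evaluate receptor and ligand
#' species from complex coordinates.
#'
#' @param top an `"mmtopology"`.
#' @param idx increasing vector of atom indices to keep.
#' @return an `"mmtopology"` for the selected atoms.
#' @export
subset_topology <- function(top, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1 | idx > nrow(top$atoms))) stop("atom index out of range")
  map <- rep(NA_integer_, nrow(top$atoms))
  map[idx] <- seq_along(idx)
  keep_terms <- function(df, cols) {
    if (!nrow(df)) return(df)
    inside <- rowSums(!is.na(matrix(map[as.matrix(df[cols])], nrow(df)))) == length(cols)
    df <- df[inside, , drop = FALSE]
    for (cc in cols) df[[cc]] <- map[df[[cc]]]
    rownames(df) <- NULL
    df
  }
  build_topology(top$atoms[idx, , drop = FALSE],
                 keep_terms(top$bonds, c("i", "j")),
                 keep_terms(top$angles, c("i", "j", "k")),
                 keep_terms(top$dihedrals, c("i", "j", "k", "l")),
                 scale14_ele = top$scale14$ele, scale14_vdw = top$scale14$vdw)
}

#' Partition a complex into receptor and ligand
#'
#' Splits the solute into two disjoint, exhaustive atom sets along whole-residue
#' boundaries, as required by the single-trajectory MM-GBSA protocol (all three
#' species are evaluated on coordinates taken from the complex trajectory).
#'
#' @param top an `"mmtopology"`.
#' @param ligand residue selector: integer residue numbers or character
#'   residue names; every matched residue goes wholly to the ligand side.
#' @param ligand_atoms alternatively, explicit atom indices; they must cover
#'   whole residues.
#' @return an object of class `"mmpartition"`: list with integer vectors
#'   `receptor` and `ligand`.
#' @export
partition_complex <- function(top, ligand = NULL, ligand_atoms = NULL) {
  n <- nrow(top$atoms)
  if (is.null(ligand_atoms)) {
    if (is.null(ligand)) stop("either 'ligand' or 'ligand_atoms' must be given")
    sel <- if (is.character(ligand)) top$atoms$resname %in% ligand
           else top$atoms$resno %in% ligand
    if (!any(sel)) stop("empty selection: '", paste(ligand, collapse = ","),
                        "' matches no residue")
    ligand_atoms <- which(sel)
  }
  ligand_atoms <- sort(unique(as.integer(ligand_atoms)))
  if (!length(ligand_atoms)) stop("empty selection")
  if (any(ligand_atoms < 1 | ligand_atoms > n)) stop("atom index out of range")
  # whole-residue check
  lr <- unique(top$atoms$resno[ligand_atoms])
  full <- which(top$atoms$resno %in% lr)
  if (!identical(full, ligand_atoms))
    stop("selection splits residue(s) ",
         paste(unique(top$atoms$resno[setdiff(full, ligand_atoms)]), collapse = ","),
         ": ligand must contain whole residues")
  rec <- setdiff(seq_len(n), ligand_atoms)
  if (!length(rec)) stop("selection leaves an empty receptor")
  structure(list(receptor = rec, ligand = ligand_atoms), class = "mmpartition")
}

#' @export
print.mmpartition <- function(x, ...) {
  cat("mmgbsa partition: receptor", length(x$receptor), "atoms; ligand",
      length(x$ligand), "atoms\n")
  invisible(x)
}
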