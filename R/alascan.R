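# Computational alanine scanning: mutant structures are obtained by editing
# the wild-type trajectory (side chain truncated at the first heavy atom
# beyond C-beta, which is replaced by a hydrogen), never by re-simulation.

.backbone_names <- c("N", "H", "CA", "HA", "C", "O")

#' Alanine parameter template
#'
#' Per-atom parameters applied to a residue after truncation to alanine
#' (charges sum to zero over the alanine roster N, H, CA, HA, CB, HB1-3,
#' C, O). Used by [mutate_to_alanine()]; supply a modified template to model
#' other parameter conventions.
#'
#' @return data.frame with columns `name`, `charge`, `lj_rmin_half`,
#'   `lj_epsilon`, `gb_radius`, `gb_screen`, `mass`, `element`.
#' @export
ala_template <- function() {
  data.frame(
    name = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
    charge = c(-0.40, 0.25, 0.01, 0.08, -0.08, 0.03, 0.03, 0.03, 0.55, -0.50),
    lj_rmin_half = c(1.824, 0.6, 1.908, 1.387, 1.908, 1.487, 1.487, 1.487,
                     1.908, 1.661),
    lj_epsilon = c(0.17, 0.0157, 0.1094, 0.0157, 0.1094, 0.0157, 0.0157,
                   0.0157, 0.1094, 0.21),
    gb_radius = c(1.55, 1.30, 1.70, 1.30, 1.70, 1.30, 1.30, 1.30, 1.70, 1.50),
    gb_screen = c(0.79, 0.85, 0.72, 0.85, 0.72, 0.85, 0.85, 0.85, 0.72, 0.85),
    mass = c(14.007, 1.008, 12.011, 1.008, 12.011, 1.008, 1.008, 1.008,
             12.011, 15.999),
    element = c("N", "H", "C", "H", "C", "H", "H", "H", "C", "O"),
    stringsAsFactors = FALSE)
}

#' Mutate one residue to alanine on the existing trajectory
#'
#' Truncates the target residue at the first side-chain heavy atom beyond
#' C-beta: that atom (and everything further out) is removed and replaced by
#' a hydrogen placed `ch_bond` Angstrom from C-beta along the former bond
#' vector, in every frame. Backbone and C-beta coordinates are untouched.
#' Bonded terms involving removed atoms are dropped; the new hydrogen clones
#' the bonded terms of an existing C-beta hydrogen. Atom parameters of the
#' residue are replaced by the alanine template. Proline, glycine and alanine
#' targets are rejected (backbone conformation / no side chain to cut).
#'
#' @param top complex `"mmtopology"`.
#' @param ens `"mmensemble"` of wild-type frames.
#' @param resno 1-based residue number to mutate.
#' @param ala_params alanine parameter template, see [ala_template()];
#'   matched by atom name, atoms without a template row keep their wild-type
#'   parameters.
#' @param ch_bond C-H replacement bond length (A); 1.09 is the standard
#'   aliphatic value.
#' @return list with mutated `topology` and `ensemble`.
#' @export
mutate_to_alanine <- function(top, ens, resno, ala_params = ala_template(),
                              ch_bond = 1.09) {
  res <- top$residues
  r <- match(resno, res$resno)
  if (is.na(r)) stop("residue ", resno, " not present")
  rname <- toupper(res$resname[r])
  if (rname %in% c("PRO", "GLY", "ALA"))
    stop("mutation rule error: ", rname, resno, " cannot be truncated to ",
         "alanine (proline backbone differs; glycine/alanine have no side ",
         "chain beyond C-beta to cut)")
  span <- res$first[r]:res$last[r]
  nm <- top$atoms$name[span]
  cb <- span[match("CB", nm)]
  if (is.na(cb)) stop("structure error: residue ", resno, " lacks CB")
  keep_names <- c(.backbone_names, "CB", "HB1", "HB2", "HB3")
  removed <- span[!(nm %in% keep_names)]
  if (!length(removed)) stop("structure error: residue ", resno,
                             " has no side-chain atoms beyond CB")
  # the truncation site: removed heavy atom bonded to CB
  bmat <- as.matrix(top$bonds[c("i", "j")])
  nb_cb <- c(bmat[bmat[, 1] == cb, 2], bmat[bmat[, 2] == cb, 1])
  cg <- intersect(nb_cb, removed[top$atoms$element[removed] != "H"])
  if (length(cg) != 1)
    stop("structure error: residue ", resno,
         " has no unique side-chain heavy atom bonded to CB (CG)")
  hb1 <- span[match("HB1", nm)]
  if (is.na(hb1)) stop("structure error: residue ", resno, " lacks HB1 to clone")

  # new atom table: drop removed atoms, rename CG -> HB3 in place
  atoms <- top$atoms
  atoms$name[cg] <- "HB3"
  tmpl <- ala_params
  in_res <- seq_len(nrow(atoms)) %in% setdiff(c(span, cg), removed[removed != cg])
  for (k in which(in_res)) {
    t <- match(atoms$name[k], tmpl$name)
    if (!is.na(t)) {
      atoms$charge[k] <- tmpl$charge[t]
      atoms$lj_rmin_half[k] <- tmpl$lj_rmin_half[t]
      atoms$lj_epsilon[k] <- tmpl$lj_epsilon[t]
      atoms$gb_radius[k] <- tmpl$gb_radius[t]
      atoms$gb_screen[k] <- tmpl$gb_screen[t]
      atoms$mass[k] <- tmpl$mass[t]
      atoms$element[k] <- tmpl$element[t]
    }
  }
  atoms$resname[span] <- "ALA"
  drop <- setdiff(removed, cg)
  keep <- setdiff(seq_len(nrow(atoms)), drop)
  map <- rep(NA_integer_, nrow(atoms)); map[keep] <- seq_along(keep)

  remap <- function(df, cols) {
    if (!nrow(df)) return(df)
    m <- matrix(map[as.matrix(df[cols])], nrow(df))
    ok <- rowSums(is.na(m)) == 0
    df <- df[ok, , drop = FALSE]
    for (ci in seq_along(cols)) df[[cols[ci]]] <- m[ok, ci]
    rownames(df) <- NULL
    df
  }
  # every bonded term touching a removed atom (including the old CG) is
  # dropped; HB3 then receives clones of HB1's terms with HB1 -> HB3
  clone <- function(df, cols) {
    if (!nrow(df)) return(df)
    m <- as.matrix(df[cols])
    touches_removed <- rowSums(matrix(m %in% removed, nrow(m))) > 0
    has_hb1 <- rowSums(m == hb1) > 0
    cl <- df[has_hb1 & !touches_removed, , drop = FALSE]
    if (nrow(cl)) for (cc in cols) cl[[cc]][cl[[cc]] == hb1] <- cg
    rbind(df[!touches_removed, , drop = FALSE], cl)
  }
  bonds <- clone(top$bonds, c("i", "j"))
  angles <- clone(top$angles, c("i", "j", "k"))
  dihedrals <- clone(top$dihedrals, c("i", "j", "k", "l"))
  # bond parameters of the new C(B)-H bond: take HB1's bond length/constant
  new_top <- build_topology(atoms[keep, , drop = FALSE],
                            remap(bonds, c("i", "j")),
                            remap(angles, c("i", "j", "k")),
                            remap(dihedrals, c("i", "j", "k", "l")),
                            scale14_ele = top$scale14$ele,
                            scale14_vdw = top$scale14$vdw)
  frames <- lapply(ens$frames, function(f) {
    v <- f[cg, ] - f[cb, ]
    f[cg, ] <- f[cb, ] + ch_bond * v / sqrt(sum(v * v))
    f[keep, , drop = FALSE]
  })
  list(topology = new_top,
       ensemble = new_ensemble(frames, ens$times, topology = new_top))
}

#' Computational alanine scan
#'
#' For each listed residue, truncates it to alanine on the same snapshot set
#' and re-runs the MM-GBSA pipeline (entropy is not recomputed for mutants);
#' reports wild-type versus mutant component means, the binding change
#' `ddG_gb = gb(mutant) - gb(wild)`, and the change in the mutated residue's
#' inhibitor-residue interaction energy. Residues whose interaction weakens
#' by more than `hotspot_cutoff` are flagged as hot spots.
#'
#' @param ens an `"mmensemble"` (already restricted to the snapshot set).
#' @param top complex `"mmtopology"`.
#' @param part an `"mmpartition"`.
#' @param residues integer vector of receptor residue numbers to scan (may be
#'   empty).
#' @param params an [solvation_params()] object.
#' @param mode gas-phase [dielectric()] mode.
#' @param hotspot_cutoff interaction-energy decrease (kcal/mol) flagging a
#'   hot spot.
#' @param ala_params template passed to [mutate_to_alanine()].
#' @return an object of class `"mmalascan"`: data.frame with one row per
#'   mutation (`resno`, `resname`, wild/mutant component means, `ddg_gb`,
#'   `interaction_wt`, `interaction_mut`, `d_interaction`, `hot_spot`);
#'   attribute `"decompositions"` keeps the mutant decompositions.
#' @export
alanine_scan <- function(ens, top, part, residues,
                         params = solvation_params(), mode = dielectric(),
                         hotspot_cutoff = 0.7, ala_params = ala_template()) {
  cols <- c("resno", "resname", "vdw_wt", "vdw_mut", "nopol_wt", "nopol_mut",
            "ele_plus_pol_wt", "ele_plus_pol_mut", "gb_wt", "gb_mut",
            "ddg_gb", "interaction_wt", "interaction_mut", "d_interaction",
            "hot_spot")
  if (!length(residues)) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(structure(out, class = c("mmalascan", "data.frame")))
  }
  wt_tab <- aggregate_energies(ensemble_delta_energies(ens, top, part, params, mode))
  wt_dec <- per_residue_decomposition(ens, top, part, params, mode)
  g <- function(tab, comp) binding_component(tab, comp)
  rows <- lapply(residues, function(rn) {
    mut <- mutate_to_alanine(top, ens, rn, ala_params = ala_params)
    mpart <- partition_complex(mut$topology,
                               ligand = unique(top$atoms$resno[part$ligand]))
    mtab <- aggregate_energies(
      ensemble_delta_energies(mut$ensemble, mut$topology, mpart, params, mode))
    mdec <- per_residue_decomposition(mut$ensemble, mut$topology, mpart,
                                      params, mode)
    iw <- wt_dec$total[wt_dec$resno == rn]
    im <- mdec$total[mdec$resno == rn]
    list(row = data.frame(
      resno = rn, resname = top$residues$resname[top$residues$resno == rn],
      vdw_wt = g(wt_tab, "vdw"), vdw_mut = g(mtab, "vdw"),
      nopol_wt = g(wt_tab, "nopol"), nopol_mut = g(mtab, "nopol"),
      ele_plus_pol_wt = g(wt_tab, "ele_plus_pol"),
      ele_plus_pol_mut = g(mtab, "ele_plus_pol"),
      gb_wt = g(wt_tab, "gb"), gb_mut = g(mtab, "gb"),
      ddg_gb = g(mtab, "gb") - g(wt_tab, "gb"),
      interaction_wt = iw, interaction_mut = im,
      d_interaction = im - iw,
      hot_spot = (im - iw) > hotspot_cutoff),
      dec = mdec)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  rownames(out) <- NULL
  structure(out, class = c("mmalascan", "data.frame"),
            decompositions = stats::setNames(lapply(rows, `[[`, "dec"),
                                             as.character(residues)))
}
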