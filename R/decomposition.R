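#' Per-residue free-energy decomposition
#'
#' Attributes the ensemble-averaged binding components to individual residues:
#' gas-phase pairwise terms (Coulomb, LJ) and generalized Born pair/self terms
#' are split half-and-half between the two partner atoms; per-atom surface
#' terms go to the atom's owning residue. Summed over all residues (receptor
#' and ligand side alike) each column reproduces the corresponding
#' ensemble-mean delta component to numerical precision.
#'
#' The per-residue `total` is the residue's share of
#' `dG_vdw + dG_ele + dG_gb(polar) + dG_surf`, the inhibitor-residue
#' interaction spectrum.
#'
#' @param ens an `"mmensemble"`.
#' @param top complex `"mmtopology"`.
#' @param part an `"mmpartition"`.
#' @param params an [solvation_params()] object.
#' @param mode gas-phase [dielectric()] mode.
#' @param frames frame indices (default all).
#' @return an object of class `"mmdecomposition"`: data.frame with columns
#'   `resno`, `resname`, `region`, `ele`, `vdw`, `pol`, `nopol`, `total`.
#' @export
per_residue_decomposition <- function(ens, top, part,
                                      params = solvation_params(),
                                      mode = dielectric(), frames = NULL) {
  if (is.null(frames)) frames <- seq_along(ens$frames)
  if (!length(frames)) stop("need at least one frame")
  n <- nrow(top$atoms)
  rec <- part$receptor; lig <- part$ligand
  top_r <- subset_topology(top, rec)
  top_l <- subset_topology(top, lig)
  q <- top$atoms$charge
  acc <- matrix(0, n, 4, dimnames = list(NULL, c("ele", "vdw", "pol", "nopol")))
  for (f in frames) {
    xyz <- ens$frames[[f]]
    # gas terms: within-species blocks cancel exactly, only cross-partition
    # halves survive
    Pe <- coulomb_energy(xyz, q, top, mode = mode, detail = TRUE)$pairs
    Pv <- lj_energy(xyz, exclusions = top, detail = TRUE)$pairs
    acc[rec, "ele"] <- acc[rec, "ele"] + rowSums(Pe[rec, lig, drop = FALSE])
    acc[lig, "ele"] <- acc[lig, "ele"] + rowSums(Pe[lig, rec, drop = FALSE])
    acc[rec, "vdw"] <- acc[rec, "vdw"] + rowSums(Pv[rec, lig, drop = FALSE])
    acc[lig, "vdw"] <- acc[lig, "vdw"] + rowSums(Pv[lig, rec, drop = FALSE])
    # polar: GB matrices are nonadditive, subtract species matrices atomwise
    Mc <- gb_polar_energy(xyz, q, effective_born_radii(xyz, top, params),
                          params, detail = TRUE)$pairs
    xr <- xyz[rec, , drop = FALSE]; xl <- xyz[lig, , drop = FALSE]
    Mr <- gb_polar_energy(xr, q[rec], effective_born_radii(xr, top_r, params),
                          params, detail = TRUE)$pairs
    Ml <- gb_polar_energy(xl, q[lig], effective_born_radii(xl, top_l, params),
                          params, detail = TRUE)$pairs
    pol_atom <- rowSums(Mc)
    pol_atom[rec] <- pol_atom[rec] - rowSums(Mr)
    pol_atom[lig] <- pol_atom[lig] - rowSums(Ml)
    acc[, "pol"] <- acc[, "pol"] + pol_atom
    # nonpolar: per-atom buried area
    sa_c <- sasa(xyz, top, params)$per_atom
    sa <- numeric(n)
    sa[rec] <- sasa(xr, top_r, params)$per_atom
    sa[lig] <- sasa(xl, top_l, params)$per_atom
    acc[, "nopol"] <- acc[, "nopol"] + params$gamma * (sa_c - sa)
  }
  acc <- acc / length(frames)
  res <- top$residues
  out <- data.frame(resno = res$resno, resname = res$resname,
                    region = ifelse(res$first %in% rec, "receptor", "ligand"))
  for (cc in colnames(acc))
    out[[cc]] <- as.numeric(rowsum(acc[, cc], top$atoms$resno)[as.character(res$resno), ])
  out$total <- out$ele + out$vdw + out$pol + out$nopol
  structure(out, class = c("mmdecomposition", "data.frame"))
}
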