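#' Select evenly spaced snapshots from the trailing window
#'
#' Mirrors the usual end-state protocol: `window_ps / interval_ps` frames
#' taken from the last `window_ps` of the trajectory at `interval_ps`
#' spacing (e.g. 200 snapshots from the last 2000 ps at 10 ps).
#'
#' @param ens an `"mmensemble"`. Without time stamps an index-based fallback
#'   (1 ps per frame) is used, with a warning.
#' @param window_ps trailing window length (ps).
#' @param interval_ps spacing between selected snapshots (ps).
#' @return integer vector of frame indices.
#' @export
select_snapshots <- function(ens, window_ps, interval_ps) {
  if (interval_ps <= 0) stop("interval_ps must be > 0")
  if (window_ps < interval_ps) stop("window_ps must be >= interval_ps")
  t <- ens$times
  if (is.null(t)) {
    warning("ensemble has no time stamps; using index-based fallback (1 ps/frame)")
    t <- seq_along(ens$frames)
  }
  t_end <- t[length(t)]
  m <- round(window_ps / interval_ps)
  targets <- t_end - window_ps + interval_ps * seq_len(m)
  if (targets[1] < t[1] - 1e-9)
    stop("window of ", window_ps, " ps exceeds trajectory span (",
         t_end - t[1] + (t[2] - t[1]), " ps)")
  idx <- vapply(targets, function(x) which.min(abs(t - x)), 1L)
  if (anyDuplicated(idx))
    warning("snapshot interval finer than frame spacing; duplicated frames dropped")
  unique(idx)
}

#' Per-frame binding energy components (single-trajectory protocol)
#'
#' Evaluates every component on complex, receptor and ligand coordinates
#' extracted from the same frame and returns the differences
#' `complex - receptor - ligand`. Because all three species share one set of
#' internal coordinates, the bonded term `internal` cancels exactly.
#'
#' @param xyz one frame (N x 3, complex coordinates).
#' @param top complex `"mmtopology"`.
#' @param part an `"mmpartition"`.
#' @param params an [solvation_params()] object.
#' @param mode gas-phase [dielectric()] mode.
#' @return an object of class `"mmenergy"`: list with `ele`, `vdw`,
#'   `internal`, `pol`, `nopol` (kcal/mol).
#' @export
frame_delta_energies <- function(xyz, top, part, params = solvation_params(),
                                 mode = dielectric()) {
  xyz <- as.matrix(xyz)
  one <- function(idx, stp = NULL) {
    if (is.null(stp)) stp <- subset_topology(top, idx)
    sxyz <- xyz[idx, , drop = FALSE]
    radii <- effective_born_radii(sxyz, stp, params)
    list(ele = coulomb_energy(sxyz, stp$atoms$charge, stp, mode = mode),
         vdw = lj_energy(sxyz, exclusions = stp),
         pol = gb_polar_energy(sxyz, stp$atoms$charge, radii, params),
         nopol = nonpolar_energy(sasa(sxyz, stp, params)$total, params))
  }
  ec <- one(seq_len(nrow(xyz)), top)
  er <- one(part$receptor)
  el <- one(part$ligand)
  structure(list(ele = ec$ele - er$ele - el$ele,
                 vdw = ec$vdw - er$vdw - el$vdw,
                 internal = .crossing_internal(xyz, top, part),
                 pol = ec$pol - er$pol - el$pol,
                 nopol = ec$nopol - er$nopol - el$nopol),
            class = "mmenergy")
}

# Delta internal energy of the single-trajectory protocol: only bonded terms
# crossing the receptor/ligand partition survive the subtraction (complex,
# receptor and ligand share one set of internal coordinates), so the delta is
# evaluated directly from the crossing terms -- exactly zero for any complex
# whose partition does not cut a bonded term.
.crossing_internal <- function(xyz, top, part) {
  in_lig <- seq_len(nrow(top$atoms)) %in% part$ligand
  cross <- function(df, cols) {
    if (!nrow(df)) return(df[0, , drop = FALSE])
    m <- matrix(in_lig[as.matrix(df[cols])], nrow(df))
    df[rowSums(m) %% length(cols) != 0, , drop = FALSE]
  }
  ctop <- top
  ctop$bonds <- cross(top$bonds, c("i", "j"))
  ctop$angles <- cross(top$angles, c("i", "j", "k"))
  ctop$dihedrals <- cross(top$dihedrals, c("i", "j", "k", "l"))
  if (!nrow(ctop$bonds) && !nrow(ctop$angles) && !nrow(ctop$dihedrals)) return(0)
  bonded_energy(xyz, ctop)$total
}

#' Ensemble binding-energy components
#'
#' Runs [frame_delta_energies()] over selected frames and returns one row per
#' frame.
#'
#' @param ens an `"mmensemble"`.
#' @param frames frame indices (default: all frames).
#' @inheritParams frame_delta_energies
#' @return data.frame with columns `ele`, `vdw`, `internal`, `pol`, `nopol`.
#' @export
ensemble_delta_energies <- function(ens, top, part, params = solvation_params(),
                                    mode = dielectric(), frames = NULL) {
  if (is.null(frames)) frames <- seq_along(ens$frames)
  rows <- lapply(frames, function(f)
    unclass(frame_delta_energies(ens$frames[[f]], top, part, params, mode)))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Aggregate per-frame components into a binding-energy table
#'
#' Means and standard errors (`SE = STD/sqrt(N)`, sample STD) per component,
#' plus the composite rows `ele_plus_pol = ele + pol`,
#' `gb = vdw + nopol + ele_plus_pol` and `bind = gb + minus_TdS`. The entropy
#' term is supplied as a separately computed `-T*dS` mean (its own snapshot
#' protocol) and is stored as printed, with its own SE.
#'
#' @param components data.frame from [ensemble_delta_energies()] (>= 1 row).
#' @param minus_tds mean `-T*dS` (kcal/mol), or `NULL` to omit the entropy
#'   and `bind` rows.
#' @param minus_tds_se standard error of `minus_tds`.
#' @param temperature K.
#' @return an object of class `"mmbinding_table"`: list with `table`
#'   (data.frame `component`, `mean`, `se`), `n_snapshots`, `temperature`.
#' @export
aggregate_energies <- function(components, minus_tds = NULL, minus_tds_se = NA,
                               temperature = 300) {
  components <- as.data.frame(components)
  if (!nrow(components)) stop("empty input: need at least one frame record")
  n <- nrow(components)
  components$ele_plus_pol <- components$ele + components$pol
  components$gb <- components$vdw + components$nopol + components$ele_plus_pol
  comps <- c("ele", "vdw", "pol", "nopol", "ele_plus_pol", "gb")
  mu <- vapply(components[comps], mean, 0)
  se <- vapply(components[comps], function(x)
    if (n > 1) stats::sd(x) / sqrt(n) else 0, 0)
  tab <- data.frame(component = comps, mean = unname(mu), se = unname(se))
  if (!is.null(minus_tds)) {
    bind <- mu[["gb"]] + minus_tds
    bind_se <- if (is.na(minus_tds_se)) NA_real_
               else sqrt(se[["gb"]]^2 + minus_tds_se^2)
    tab <- rbind(tab,
                 data.frame(component = c("minus_TdS", "bind"),
                            mean = c(minus_tds, bind),
                            se = c(minus_tds_se, bind_se)))
  }
  structure(list(table = tab, n_snapshots = n, temperature = temperature),
            class = "mmbinding_table")
}

#' Binding-energy table from component means
#'
#' Applies the composite identities directly to supplied means, as when
#' checking a published table: `ele_plus_pol = ele + pol` (unless an explicit
#' `ele_plus_pol` is given), `gb = vdw + nopol + ele_plus_pol`,
#' `bind = gb + minus_TdS`.
#'
#' @param means named list/vector with `vdw`, `nopol`, and either
#'   `ele_plus_pol` or both `ele` and `pol`; optional `minus_TdS`.
#' @param temperature K.
#' @return an `"mmbinding_table"` (standard errors `NA`).
#' @export
binding_table_from_means <- function(means, temperature = 300) {
  means <- as.list(means)
  epp <- if (!is.null(means$ele_plus_pol)) means$ele_plus_pol
         else means$ele + means$pol
  gb <- means$vdw + means$nopol + epp
  rows <- list(vdw = means$vdw, nopol = means$nopol)
  if (!is.null(means$ele)) rows$ele <- means$ele
  if (!is.null(means$pol)) rows$pol <- means$pol
  rows$ele_plus_pol <- epp
  rows$gb <- gb
  if (!is.null(means$minus_TdS)) {
    rows$minus_TdS <- means$minus_TdS
    rows$bind <- gb + means$minus_TdS
  }
  tab <- data.frame(component = names(rows), mean = unlist(rows, use.names = FALSE),
                    se = NA_real_)
  structure(list(table = tab, n_snapshots = NA_integer_,
                 temperature = temperature),
            class = "mmbinding_table")
}

#' @export
print.mmbinding_table <- function(x, digits = 2, ...) {
  cat("MM-GBSA binding energies (kcal/mol",
      if (!is.na(x$n_snapshots)) paste0(", ", x$n_snapshots, " snapshots"),
      ")\n", sep = "")
  tab <- x$table
  tab$mean <- round(tab$mean, digits)
  tab$se <- round(tab$se, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fetch one component mean from a binding table
#' @param x an `"mmbinding_table"`.
#' @param component component name (e.g. `"gb"`, `"bind"`).
#' @return numeric mean.
#' @export
binding_component <- function(x, component) {
  i <- match(component, x$table$component)
  if (is.na(i)) stop("no component '", component, "' in table")
  x$table$mean[i]
}

#' Convert an IC50 to an approximate binding free energy
#'
#' `dG = R*T*ln(IC50)` with the concentration in mol/L and
#' `R = 0.0019872 kcal/mol/K`: the standard magnitude conversion for ranking
#' affinities, signed so that sub-molar IC50 values give favorable (negative)
#' free energies (1 M maps to 0; halving the IC50 lowers dG by `R*T*ln 2`).
#'
#' @param ic50 concentration in mol/L (> 0).
#' @param temperature K.
#' @return kcal/mol.
#' @export
ic50_to_dg <- function(ic50, temperature = 300) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  mm_constants$R_kcal * temperature * log(ic50)
}
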