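# Conformational entropy by normal-mode analysis: snapshots are minimized in
# the gas phase under a distance-dependent dielectric (4Rij), the
# mass-weighted Hessian is diagonalized, and translational/rotational/
# vibrational entropies are evaluated by standard statistical mechanics.

#' Minimize a structure to a gradient threshold
#'
#' Gas-phase energy (bonded + Coulomb + LJ) under the given dielectric mode,
#' minimized by repeated L-BFGS-B rounds with the analytic gradient until the
#' root-mean-square gradient falls below `tol`.
#'
#' @param xyz N x 3 starting coordinates (A).
#' @param top an `"mmtopology"`.
#' @param mode gas-phase [dielectric()] mode; the entropy protocol uses the
#'   distance-dependent `4Rij` form.
#' @param tol gradient RMS threshold (kcal/mol/A).
#' @param max_rounds maximum optimizer restarts before giving up.
#' @param maxit L-BFGS-B iterations per round.
#' @return list with `xyz` (minimized coordinates), `energy`, `grad_rms`,
#'   `rounds`. Non-convergence raises an error carrying the best-so-far
#'   coordinates in its `data` field.
#' @export
minimize_structure <- function(xyz, top,
                               mode = dielectric("distance_dependent", factor = 4),
                               tol = 1e-4, max_rounds = 60, maxit = 500) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  fn <- function(p) total_energy(matrix(p, n, 3), top, mode)
  gr <- function(p) as.vector(mm_gradient(matrix(p, n, 3), top, mode))
  p <- as.vector(xyz)
  if (!is.finite(fn(p))) stop("non-finite starting energy")
  done <- function(p, rms, round)
    list(xyz = matrix(p, n, 3), energy = fn(p), grad_rms = rms, rounds = round)
  rms <- gradient_rms(matrix(gr(p), n, 3))
  for (round in seq_len(max_rounds)) {
    # quasi-Newton descent into the harmonic basin
    opt <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10, pgtol = 0))
    p <- opt$par
    rms <- gradient_rms(matrix(gr(p), n, 3))
    if (rms <= tol) return(done(p, rms, round))
    # polish with modified-Newton steps: eigenvalue magnitudes make the step
    # a descent direction even along weakly negative (saddle) curvature
    for (it in 1:30) {
      H <- .mw_hessian(matrix(p, n, 3), top, mode, mass_weight = FALSE)$H
      eg <- eigen(H, symmetric = TRUE)
      g <- gr(p)
      lam <- eg$values
      keep <- abs(lam) > 1e-7 * max(abs(lam))
      V <- eg$vectors[, keep, drop = FALSE]
      step <- -as.vector(V %*% ((t(V) %*% g) / abs(lam[keep])))
      alpha <- 1
      rms0 <- rms
      repeat {
        pn <- p + alpha * step
        rmsn <- gradient_rms(matrix(gr(pn), n, 3))
        if (rmsn < rms0 || alpha < 1e-3) break
        alpha <- alpha / 2
      }
      if (rmsn >= rms0) break   # no progress; go back to L-BFGS
      p <- pn; rms <- rmsn
      if (rms <= tol) return(done(p, rms, round))
    }
  }
  cond <- structure(class = c("mm_minimize_error", "error", "condition"),
                    list(message = sprintf(
                      "minimization did not reach gradient RMS %.3g (best %.3g)",
                      tol, rms),
                      call = sys.call(-1),
                      data = list(xyz = matrix(p, n, 3), grad_rms = rms)))
  stop(cond)
}

# (optionally mass-weighted) Hessian by central finite differences of the
# analytic gradient (step in A)
.mw_hessian <- function(xyz, top, mode, step = 1e-5, mass_weight = TRUE) {
  n <- nrow(xyz)
  p <- as.vector(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(3 * n)) {
    pp <- p; pp[k] <- pp[k] + step
    gp <- as.vector(mm_gradient(matrix(pp, n, 3), top, mode))
    pp[k] <- p[k] - step
    gm <- as.vector(mm_gradient(matrix(pp, n, 3), top, mode))
    H[, k] <- (gp - gm) / (2 * step)
  }
  H <- (H + t(H)) / 2
  if (!mass_weight) return(list(H = H))
  # coordinate layout of as.vector(xyz) is column-major: atom i occupies
  # slots i, i+n, i+2n
  m <- rep(top$atoms$mass, 3)
  Hmw <- H / sqrt(outer(m, m))
  list(H = H, Hmw = Hmw)
}

#' Normal modes of a minimized structure
#'
#' Mass-weighted Hessian (central finite differences of the analytic
#' gradient), eigendecomposition and harmonic frequencies. A nonlinear
#' minimized molecule has exactly six near-zero (rigid-body) modes, a linear
#' one five. Imaginary frequencies are reported as negative numbers; a
#' negative frequency beyond `neg_tol` means the input is not a minimum.
#'
#' @param xyz minimized N x 3 coordinates.
#' @param top an `"mmtopology"`.
#' @param mode gas-phase [dielectric()] mode (must match the minimization).
#' @param grad_check error if the gradient RMS exceeds this (kcal/mol/A);
#'   `Inf` disables the check.
#' @param neg_tol tolerance (cm^-1) for imaginary frequencies.
#' @param fd_step finite-difference step (A).
#' @return object of class `"mmnormalmodes"`: list with `frequencies`
#'   (cm^-1, ascending), `xyz`, `masses`.
#' @export
normal_modes <- function(xyz, top,
                         mode = dielectric("distance_dependent", factor = 4),
                         grad_check = 1e-3, neg_tol = 5, fd_step = 1e-5) {
  xyz <- as.matrix(xyz)
  rms <- gradient_rms(mm_gradient(xyz, top, mode))
  if (rms > grad_check)
    stop("not a minimum: gradient RMS ", signif(rms, 3),
         " exceeds ", grad_check)
  hw <- .mw_hessian(xyz, top, mode, step = fd_step)
  ev <- eigen(hw$Hmw, symmetric = TRUE, only.values = TRUE)$values
  fac <- .freq_factor()
  freq <- sort(sign(ev) * sqrt(abs(ev)) * fac)
  if (any(freq < -neg_tol))
    stop("not a minimum: imaginary mode at ", signif(min(freq), 4), " cm^-1")
  structure(list(frequencies = freq, xyz = xyz, masses = top$atoms$mass),
            class = "mmnormalmodes")
}

#' @export
print.mmnormalmodes <- function(x, ...) {
  cat("normal modes:", length(x$frequencies), "modes,",
      sum(abs(x$frequencies) < 1), "rigid-body;",
      sprintf("highest %.1f cm^-1\n", max(x$frequencies)))
  invisible(x)
}

#' Harmonic-oscillator vibrational entropy of one mode
#'
#' `S = R * (x/(exp(x)-1) - log(1-exp(-x)))` with `x = h*nu/(kB*T)`;
#' monotonically decreasing in frequency and vanishing in the stiff-mode
#' limit.
#'
#' @param freq_cm frequency in cm^-1 (> 0).
#' @param temperature K.
#' @return entropy in cal/mol/K.
#' @export
vibrational_entropy <- function(freq_cm, temperature = 300) {
  if (any(freq_cm <= 0)) stop("vibrational entropy needs positive frequencies")
  x <- mm_constants$h * mm_constants$c_cm * freq_cm /
    (mm_constants$kB * temperature)
  s <- ifelse(x > 300, 0,
              mm_constants$R_cal * (x / (exp(x) - 1) - log1p(-exp(-x))))
  s
}

#' Entropy components from a normal-mode result
#'
#' Vibrational entropy from the harmonic-oscillator partition function per
#' mode (the 6 rigid-body modes -- 5 for a linear molecule -- are excluded,
#' as is any residual mode below `rigid_cut`), translational entropy from the
#' Sackur-Tetrode equation at 1 atm, rotational entropy from the classical
#' rigid rotor (symmetry number 1).
#'
#' @param nm an `"mmnormalmodes"` object.
#' @param temperature K.
#' @param pressure Pa.
#' @param sigma rotational symmetry number.
#' @param rigid_cut frequencies below this magnitude (cm^-1) are treated as
#'   rigid-body remnants and excluded from the vibrational sum.
#' @return list with `S_trans`, `S_rot`, `S_vib`, `S_total` (cal/mol/K) and
#'   `minus_TS` (`-T*S_total`, kcal/mol).
#' @export
entropy_from_modes <- function(nm, temperature = 300, pressure = 101325,
                               sigma = 1, rigid_cut = 1.0) {
  kB <- mm_constants$kB; h <- mm_constants$h; Rc <- mm_constants$R_cal
  masses <- nm$masses
  M <- sum(masses) * mm_constants$amu
  qt <- (2 * pi * M * kB * temperature / h^2)^1.5 * kB * temperature / pressure
  S_trans <- Rc * (log(qt) + 2.5)

  xyz_m <- nm$xyz * 1e-10
  com <- colSums(xyz_m * masses) / sum(masses)
  xc <- sweep(xyz_m, 2, com)
  mkg <- masses * mm_constants$amu
  Ixx <- sum(mkg * (xc[, 2]^2 + xc[, 3]^2))
  Iyy <- sum(mkg * (xc[, 1]^2 + xc[, 3]^2))
  Izz <- sum(mkg * (xc[, 1]^2 + xc[, 2]^2))
  Ixy <- -sum(mkg * xc[, 1] * xc[, 2])
  Ixz <- -sum(mkg * xc[, 1] * xc[, 3])
  Iyz <- -sum(mkg * xc[, 2] * xc[, 3])
  Imat <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  mom <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
  linear <- nrow(nm$xyz) < 3 || mom[1] / mom[3] < 1e-8
  if (linear) {
    qr_ <- 8 * pi^2 * mom[3] * kB * temperature / (sigma * h^2)
    S_rot <- Rc * (log(qr_) + 1)
  } else {
    qr_ <- sqrt(pi) / sigma *
      (8 * pi^2 * kB * temperature / h^2)^1.5 * sqrt(prod(mom))
    S_rot <- Rc * (log(qr_) + 1.5)
  }

  freq <- nm$frequencies
  ndrop <- if (linear) 5 else 6
  ndrop <- min(ndrop, length(freq))
  ord <- order(abs(freq))
  vib <- freq[-ord[seq_len(ndrop)]]
  vib <- vib[abs(vib) >= rigid_cut]
  if (any(vib < 0))
    stop("imaginary vibrational mode: frequencies must come from a minimum")
  S_vib <- if (length(vib)) sum(vibrational_entropy(vib, temperature)) else 0

  S_total <- S_trans + S_rot + S_vib
  list(S_trans = S_trans, S_rot = S_rot, S_vib = S_vib, S_total = S_total,
       minus_TS = -temperature * S_total / 1000)
}

#' Binding entropy term by normal-mode analysis
#'
#' For each selected snapshot, minimizes complex, receptor and ligand
#' separately under the distance-dependent dielectric, runs normal-mode
#' analysis on each, and forms `dS = S_complex - S_receptor - S_ligand`;
#' reports `-T*dS` averaged over the snapshot set with `SE = STD/sqrt(N)`.
#'
#' @param ens an `"mmensemble"` of complex frames.
#' @param top complex `"mmtopology"`.
#' @param part an `"mmpartition"`.
#' @param frames snapshot indices used for the entropy average (the entropy
#'   protocol typically uses far fewer snapshots than the energy average).
#' @param temperature K.
#' @param mode dielectric mode for minimization and Hessian.
#' @param tol minimization gradient-RMS threshold (kcal/mol/A).
#' @return list with `minus_tds` (mean, kcal/mol), `se`, `per_frame`
#'   (data.frame of per-snapshot `-T*dS` and species entropies), `n`.
#' @export
binding_entropy <- function(ens, top, part, frames = seq_along(ens$frames),
                            temperature = 300,
                            mode = dielectric("distance_dependent", factor = 4),
                            tol = 1e-4) {
  top_r <- subset_topology(top, part$receptor)
  top_l <- subset_topology(top, part$ligand)
  one_species <- function(xyz, stp) {
    mn <- minimize_structure(xyz, stp, mode = mode, tol = tol)
    entropy_from_modes(normal_modes(mn$xyz, stp, mode = mode),
                       temperature = temperature)$S_total
  }
  per <- lapply(frames, function(f) {
    xyz <- ens$frames[[f]]
    sc <- one_species(xyz, top)
    sr <- one_species(xyz[part$receptor, , drop = FALSE], top_r)
    sl <- one_species(xyz[part$ligand, , drop = FALSE], top_l)
    ds <- sc - sr - sl
    data.frame(frame = f, S_complex = sc, S_receptor = sr, S_ligand = sl,
               dS = ds, minus_tds = -temperature * ds / 1000)
  })
  per <- do.call(rbind, per)
  n <- nrow(per)
  list(minus_tds = mean(per$minus_tds),
       se = if (n > 1) stats::sd(per$minus_tds) / sqrt(n) else 0,
       per_frame = per, n = n)
}
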