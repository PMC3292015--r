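# Synthetic fixtures: small receptor-ligand complexes and designed ensembles
# with known geometric/statistical structure, so every downstream stage is
# testable without MD trajectories.

.atom_row <- function(name, element, charge, rmin_half, eps, gbr, screen, mass,
                      resno, resname) {
  data.frame(name = name, element = element, charge = charge,
             lj_rmin_half = rmin_half, lj_epsilon = eps, gb_radius = gbr,
             gb_screen = screen, mass = mass, resno = resno, resname = resname,
             stringsAsFactors = FALSE)
}

# per-element defaults (AMBER-like magnitudes)
.elem_params <- function(element) {
  tab <- list(
    N  = c(1.824, 0.1700, 1.55, 0.79, 14.007),
    H  = c(1.387, 0.0157, 1.30, 0.85, 1.008),
    C  = c(1.908, 0.1094, 1.70, 0.72, 12.011),
    O  = c(1.661, 0.2100, 1.50, 0.85, 15.999),
    Cl = c(1.948, 0.2650, NA,   0.80, 35.45)   # GB radius defaulted to 1.75
  )
  tab[[element]]
}

# derive angle/dihedral terms from the bond graph; equilibrium values are the
# built geometry, so the base structure is an exact minimum of bonds+angles
# (and of each dihedral: the phase is set so the built torsion sits at the
# cosine minimum)
.derive_terms <- function(bonds_ij, xyz, k_bond = 340, k_angle = 50, v_dih = 0.5) {
  n <- nrow(xyz)
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(bonds_ij))) {
    i <- bonds_ij[r, 1]; j <- bonds_ij[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  d <- xyz[bonds_ij[, 1], , drop = FALSE] - xyz[bonds_ij[, 2], , drop = FALSE]
  bonds <- data.frame(i = bonds_ij[, 1], j = bonds_ij[, 2],
                      k = k_bond, r0 = .rownorm(d))
  ai <- aj <- ak <- integer(0)
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(sort(nbs), 2)
      ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2, ])
    }
  }
  angles <- data.frame(i = ai, j = aj, k = ak, kf = k_angle, theta0 = 0)
  if (nrow(angles)) angles$theta0 <- .angle_geom(xyz, angles)$theta
  di <- dj <- dk <- dl <- integer(0)
  for (r in seq_len(nrow(bonds_ij))) {
    j <- bonds_ij[r, 1]; k <- bonds_ij[r, 2]
    for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], j)) {
      if (i != l) { di <- c(di, i); dj <- c(dj, j); dk <- c(dk, k); dl <- c(dl, l) }
    }
  }
  dihedrals <- data.frame(i = di, j = dj, k = dk, l = dl,
                          v = v_dih, n = 1, gamma = 0)
  if (nrow(dihedrals)) {
    phi0 <- .dihedral_geom(xyz, dihedrals)$phi
    dihedrals$gamma <- (phi0 - pi) %% (2 * pi)
  }
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

# natural-extension reference frame placement: returns d with |d-c| = r,
# angle(b,c,d) = theta and dihedral(a,b,c,d) = phi (radians)
.nerf_place <- function(a, b, c, r, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(matrix(b - a, 1), matrix(bc, 1))[1, ]
  n <- n / sqrt(sum(n^2))
  m <- .cross3(matrix(n, 1), matrix(bc, 1))[1, ]
  c + r * (-cos(theta) * bc + sin(theta) * (cos(phi) * m + sin(phi) * n))
}

# coordinates of the toy complex: a 3-residue leucine-like chain (13 atoms
# per residue: N H CA HA CB HB1 HB2 CG HG1 HG2 HG3 C O, extended backbone
# phi = -120 / psi = 140) and a 9-atom amide-like ligand whose N-H donor is
# built collinear with the residue-2 backbone carbonyl O (N...O = 2.90 A)
.toy_geometry <- function() {
  d <- .deg2rad
  X <- matrix(NA_real_, 48, 3)
  ix <- function(res, k) (res - 1L) * 13L + k
  pl <- function(a, b, c, r, th, ph)
    .nerf_place(X[a, ], X[b, ], X[c, ], r, d(th), d(ph))
  phi_bb <- -120; psi_bb <- 140
  X[1, ] <- c(0, 0, 0)                                   # N1
  X[3, ] <- c(1.458, 0, 0)                               # CA1
  X[12, ] <- X[3, ] + 1.525 * c(cos(d(69)), sin(d(69)), 0)  # C1
  X[2, ] <- pl(12, 3, 1, 1.01, 119, 180)                 # H1 (C-CA-N-H)
  for (res in 1:3) {
    N <- ix(res, 1); H <- ix(res, 2); CA <- ix(res, 3); HA <- ix(res, 4)
    CB <- ix(res, 5); HB1 <- ix(res, 6); HB2 <- ix(res, 7); CG <- ix(res, 8)
    HG1 <- ix(res, 9); HG2 <- ix(res, 10); HG3 <- ix(res, 11)
    C <- ix(res, 12); O <- ix(res, 13)
    if (res > 1) {
      Np <- ix(res - 1, 1); CAp <- ix(res - 1, 3)
      Cp <- ix(res - 1, 12); Op <- ix(res - 1, 13)
      X[N, ] <- pl(Np, CAp, Cp, 1.33, 116, psi_bb)
      X[CA, ] <- pl(CAp, Cp, N, 1.458, 121, 180)         # trans peptide
      X[H, ] <- pl(Op, Cp, N, 1.01, 119, 180)
      X[C, ] <- pl(Cp, N, CA, 1.525, 111, phi_bb)
    }
    # stagger HA/CB around the N-CA axis relative to the H-N-CA-C torsion
    tau <- .rad2deg(.dihedral_geom(X, data.frame(i = H, j = N, k = CA, l = C))$phi)
    X[CB, ] <- pl(H, N, CA, 1.53, 110, tau - 120)
    X[HA, ] <- pl(H, N, CA, 1.09, 109, tau + 120)
    X[CG, ] <- pl(N, CA, CB, 1.53, 112, 180)
    X[HB1, ] <- pl(N, CA, CB, 1.09, 109, 60)
    X[HB2, ] <- pl(N, CA, CB, 1.09, 109, -60)
    X[HG1, ] <- pl(CA, CB, CG, 1.09, 109.5, 60)
    X[HG2, ] <- pl(CA, CB, CG, 1.09, 109.5, 180)
    X[HG3, ] <- pl(CA, CB, CG, 1.09, 109.5, -60)
    X[O, ] <- pl(N, CA, C, 1.229, 121, psi_bb - 180)
  }
  # ligand: N-H donor collinear with the residue-2 carbonyl C=O direction
  o <- X[ix(2, 13), ]; c2 <- X[ix(2, 12), ]
  u <- (o - c2) / sqrt(sum((o - c2)^2))
  L <- 39L
  X[L + 2, ] <- o + 1.90 * u                              # H1 (H...O = 1.90)
  X[L + 1, ] <- o + 2.90 * u                              # N1 (N...O = 2.90)
  h1 <- X[L + 2, ]; n1 <- X[L + 1, ]
  X[L + 3, ] <- .nerf_place(o, h1, n1, 1.01, d(117), d(0))    # H5
  X[L + 4, ] <- .nerf_place(o, h1, n1, 1.36, d(120), d(180))  # C2
  c2l <- X[L + 4, ]
  X[L + 5, ] <- .nerf_place(h1, n1, c2l, 1.23, d(122), d(0))  # O1
  X[L + 6, ] <- .nerf_place(h1, n1, c2l, 1.50, d(115), d(180)) # C3
  c3l <- X[L + 6, ]
  X[L + 7, ] <- .nerf_place(n1, c2l, c3l, 1.09, d(109.5), d(60))   # H2
  X[L + 8, ] <- .nerf_place(n1, c2l, c3l, 1.09, d(109.5), d(-60))  # H3
  X[L + 9, ] <- .nerf_place(n1, c2l, c3l, 1.77, d(109.5), d(180))  # CL
  X
}

# atom tables for the toy complex, matching .toy_geometry atom order
.toy_atoms <- function() {
  res_names <- c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "CG",
                 "HG1", "HG2", "HG3", "C", "O")
  res_el <- c("N", "H", "C", "H", "C", "H", "H", "C", "H", "H", "H", "C", "O")
  res_q <- c(-0.40, 0.25, 0.01, 0.08, -0.05, 0.03, 0.03, -0.09, 0.03, 0.03,
             0.03, 0.55, -0.50)
  lig_names <- c("N1", "H1", "H5", "C2", "O1", "C3", "H2", "H3", "CL")
  lig_el <- c("N", "H", "H", "C", "O", "C", "H", "H", "Cl")
  lig_q <- c(-0.52, 0.31, 0.31, 0.55, -0.55, -0.15, 0.05, 0.05, -0.05)
  out <- NULL
  for (r in 1:3) {
    pars <- t(vapply(res_el, .elem_params, numeric(5)))
    out <- rbind(out, .atom_row(res_names, res_el, res_q, pars[, 1], pars[, 2],
                                pars[, 3], pars[, 4], pars[, 5], r, "LEU"))
  }
  pars <- t(vapply(lig_el, .elem_params, numeric(5)))
  out <- rbind(out, .atom_row(lig_names, lig_el, lig_q, pars[, 1], pars[, 2],
                              pars[, 3], pars[, 4], pars[, 5], 4L, "LIG"))
  # polar (N-bonded) hydrogens carry the small H-bonding LJ radius
  polar_h <- out$name %in% c("H", "H1", "H5")
  out$lj_rmin_half[polar_h] <- 0.60
  rownames(out) <- NULL
  out
}

#' Generate the toy receptor-ligand complex
#'
#' A tripeptide-like receptor (three 13-atom leucine-like residues) plus a
#' 9-atom amide-like ligand carrying one chlorine atom, with full
#' charge/LJ/GB/bonded parameters and a designed ligand-to-backbone hydrogen
#' bond. Frames are the base geometry plus isotropic Gaussian positional
#' noise; deterministic for a given seed (the topology never depends on the
#' seed).
#'
#' @param seed integer RNG seed for the frame noise.
#' @param n_frames number of snapshots.
#' @param noise standard deviation of per-coordinate noise (A).
#' @param dt_ps frame spacing (ps) used for the time stamps.
#' @return list with elements `topology` (`"mmtopology"`) and `ensemble`
#'   (`"mmensemble"`).
#' @export
make_toy_complex <- function(seed = 1, n_frames = 10, noise = 0.03, dt_ps = 10) {
  atoms <- .toy_atoms()
  xyz <- .toy_geometry()
  # intra-residue connectivity (local indices)
  conn <- rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(5, 6), c(5, 7), c(5, 8),
                c(8, 9), c(8, 10), c(8, 11), c(3, 12), c(12, 13))
  bonds <- NULL
  for (rres in 0:2) bonds <- rbind(bonds, conn + rres * 13)
  bonds <- rbind(bonds, c(12, 14), c(25, 27))            # peptide C-N links
  lconn <- rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(4, 6), c(6, 7),
                 c(6, 8), c(6, 9)) + 39
  bonds <- rbind(bonds, lconn)
  trm <- .derive_terms(bonds, xyz)
  top <- build_topology(atoms, trm$bonds, trm$angles, trm$dihedrals)
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(f)
    xyz + matrix(stats::rnorm(length(xyz), sd = noise), nrow(xyz), 3)))
  list(topology = top,
       ensemble = new_ensemble(frames, times = seq_len(n_frames) * dt_ps,
                               topology = top))
}

#' Specification of a designed hydrogen-bond fixture
#'
#' @param seed integer RNG seed.
#' @param n_frames number of frames (> 0).
#' @param hbond_occupancy_target fraction of frames (in `[0, 1]`) that must
#'   satisfy the hydrogen-bond criteria.
#' @param positional_noise_sigma extra isotropic positional noise (A).
#' @param rigid_transform optional `list(R = 3x3 rotation, t = length-3
#'   translation)` applied to every frame.
#' @return list of class `"mmfixture_spec"`.
#' @export
fixture_spec <- function(seed = 1, n_frames = 100, hbond_occupancy_target = 0.7,
                         positional_noise_sigma = 0, rigid_transform = NULL) {
  if (hbond_occupancy_target < 0 || hbond_occupancy_target > 1)
    stop("hbond_occupancy_target must be in [0, 1]")
  if (positional_noise_sigma < 0) stop("positional_noise_sigma must be >= 0")
  structure(list(seed = seed, n_frames = n_frames,
                 hbond_occupancy_target = hbond_occupancy_target,
                 positional_noise_sigma = positional_noise_sigma,
                 rigid_transform = rigid_transform),
            class = "mmfixture_spec")
}

#' Hydrogen-bond ensemble with designed occupancy
#'
#' A three-atom donor/acceptor system (N-H donor residue, carbonyl-O acceptor
#' residue). Exactly `round(n_frames * target)` frames are built safely inside
#' the geometric criteria (heavy-acceptor distance 2.9 +/- 0.1 A, D-H...A
#' angle 155 +/- 5 deg); the remaining frames place the acceptor beyond 4 A.
#'
#' @param spec an [fixture_spec()].
#' @return list with `topology`, `ensemble` and `bound` (logical per-frame
#'   design vector).
#' @export
make_hbond_ensemble <- function(spec = fixture_spec()) {
  if (spec$n_frames < 1) stop("n_frames must be >= 1")
  atoms <- rbind(
    .atom_row("N", "N", -0.40, 1.824, 0.17, 1.55, 0.79, 14.007, 1, "DON"),
    .atom_row("H", "H", 0.40, 0.6, 0.0157, 1.30, 0.85, 1.008, 1, "DON"),
    .atom_row("O", "O", -0.50, 1.661, 0.21, 1.50, 0.85, 15.999, 2, "ACC"))
  bonds <- data.frame(i = 1L, j = 2L, k = 450, r0 = 1.0)
  top <- build_topology(atoms, bonds)
  k <- round(spec$n_frames * spec$hbond_occupancy_target)
  .with_seed(spec$seed, {
    bound <- rep(FALSE, spec$n_frames)
    bound[if (k > 0) sample(spec$n_frames, k) else integer(0)] <- TRUE
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      if (bound[f]) {
        d <- stats::runif(1, 2.8, 3.0)          # N...O distance
        a <- .deg2rad(stats::runif(1, 150, 160)) # N-H...O angle at H
      } else {
        d <- stats::runif(1, 4.5, 6.0)
        a <- .deg2rad(stats::runif(1, 100, 170))
      }
      # N at origin, H at (1,0,0); acceptor in the xy-plane at angle a from
      # the H->N direction, at distance d from N
      th <- pi - a
      L <- -cos(th) + sqrt(cos(th)^2 - 1 + d^2)
      xyz <- rbind(c(0, 0, 0), c(1, 0, 0),
                   c(1 + L * cos(th), L * sin(th), 0))
      if (spec$positional_noise_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(9, sd = spec$positional_noise_sigma), 3, 3)
      if (!is.null(spec$rigid_transform))
        xyz <- xyz %*% t(spec$rigid_transform$R) +
          matrix(spec$rigid_transform$t, 3, 3, byrow = TRUE)
      xyz
    })
    list(topology = top,
         ensemble = new_ensemble(frames, times = seq_len(spec$n_frames) * 10,
                                 topology = top),
         bound = bound)
  })
}

#' Single-ion Born fixture
#'
#' One charged atom at the origin, for closed-form validation of the
#' generalized Born self energy.
#'
#' @param q charge (e).
#' @param radius intrinsic GB radius (A, > 0).
#' @return list with `topology` and `ensemble` (one frame).
#' @export
make_born_fixture <- function(q = 1, radius = 1.5) {
  if (radius <= 0) stop("radius must be > 0")
  atoms <- .atom_row("ION", "X", q, 1.8, 0.1, radius, 0.8, 22.99, 1, "ION")
  top <- build_topology(atoms)
  list(topology = top,
       ensemble = new_ensemble(list(matrix(0, 1, 3)), topology = top))
}
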