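#' Dielectric mode for gas-phase electrostatics
#'
#' Constant dielectric (`epsilon(r) = epsilon_in`) or the distance-dependent
#' form `epsilon(r) = factor * r` used when minimizing snapshots for
#' normal-mode entropy (factor 4, "4Rij").
#'
#' @param kind `"constant"` or `"distance_dependent"`.
#' @param epsilon_in relative dielectric (>= 1), used by the constant mode.
#' @param factor slope of the distance-dependent dielectric (> 0), in 1/A.
#' @return an object of class `"mmdielectric"`.
#' @export
dielectric <- function(kind = c("constant", "distance_dependent"),
                       epsilon_in = 1.0, factor = 4.0) {
  kind <- match.arg(kind)
  if (epsilon_in < 1) stop("epsilon_in must be >= 1")
  if (factor <= 0) stop("factor must be > 0")
  structure(list(kind = kind, epsilon_in = epsilon_in, factor = factor),
            class = "mmdielectric")
}

# nonbonded scale matrix: 0 on the diagonal and on excluded (1-2/1-3) pairs,
# 1/scale on 1-4 pairs, 1 elsewhere
.nb_scale <- function(n, exclusions, scale) {
  S <- matrix(1, n, n)
  diag(S) <- 0
  if (!is.null(exclusions)) {
    ex <- exclusions$excluded
    if (length(ex)) { S[ex] <- 0; S[ex[, 2:1, drop = FALSE]] <- 0 }
    s14 <- exclusions$scaled14
    if (length(s14)) { S[s14] <- 1 / scale; S[s14[, 2:1, drop = FALSE]] <- 1 / scale }
  }
  S
}

.check_singular <- function(r, S, what) {
  bad <- which(S > 0 & r < 1e-6, arr.ind = TRUE)
  if (nrow(bad))
    stop("singularity: interacting ", what, " pair ", bad[1, 1], "-", bad[1, 2],
         " at distance < 1e-6 A")
}

#' Gas-phase Coulomb energy
#'
#' Sum over non-excluded pairs of `ke*qi*qj/(eps(r)*r)`; 1-4 pairs are divided
#' by the 1-4 electrostatic scale factor carried by `exclusions`/topology.
#'
#' @param xyz N x 3 coordinates (A).
#' @param charges length-N charges (e).
#' @param exclusions `NULL` (all pairs interact), an `"mmtopology"`, or a list
#'   with `excluded` and `scaled14` two-column index matrices.
#' @param mode an [dielectric()] mode.
#' @param scale14 1-4 divisor (taken from the topology when one is passed).
#' @param detail if `TRUE` also return the symmetric per-pair matrix whose
#'   total equals the scalar energy (each pair's energy split half/half).
#' @return energy in kcal/mol, or `list(energy, pairs)` when `detail = TRUE`.
#' @export
coulomb_energy <- function(xyz, charges, exclusions = NULL, mode = dielectric(),
                           scale14 = 1.2, detail = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (inherits(exclusions, "mmtopology")) {
    scale14 <- exclusions$scale14$ele
    exclusions <- exclusions$exclusions
  }
  S <- .nb_scale(n, exclusions, scale14)
  r <- as.matrix(stats::dist(xyz))
  .check_singular(r, S, "charge")
  rr <- r; diag(rr) <- 1
  E <- if (mode$kind == "constant") {
    mm_constants$ke * outer(charges, charges) / (mode$epsilon_in * rr)
  } else {
    mm_constants$ke * outer(charges, charges) / (mode$factor * rr^2)
  }
  E <- E * S
  total <- sum(E) / 2
  if (detail) list(energy = total, pairs = E / 2) else total
}

#' Gas-phase Lennard-Jones (12-6) energy
#'
#' Pair parameters follow the Lorentz-Berthelot-style combination used by
#' AMBER-type force fields: `rmin_ij = rmin_half_i + rmin_half_j` and
#' `eps_ij = sqrt(eps_i * eps_j)`; the potential is
#' `eps_ij * ((rmin/r)^12 - 2 (rmin/r)^6)`, minimum `-eps_ij` at `r = rmin`.
#' 1-4 pairs are divided by the 1-4 van der Waals scale factor.
#'
#' @inheritParams coulomb_energy
#' @param rmin_half,epsilon per-atom LJ parameters (A, kcal/mol).
#' @export
lj_energy <- function(xyz, rmin_half, epsilon, exclusions = NULL,
                      scale14 = 2.0, detail = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (inherits(exclusions, "mmtopology")) {
    scale14 <- exclusions$scale14$vdw
    if (missing(rmin_half)) rmin_half <- exclusions$atoms$lj_rmin_half
    if (missing(epsilon)) epsilon <- exclusions$atoms$lj_epsilon
    exclusions <- exclusions$exclusions
  }
  S <- .nb_scale(n, exclusions, scale14)
  r <- as.matrix(stats::dist(xyz))
  .check_singular(r, S, "LJ")
  rr <- r; diag(rr) <- 1
  rmin <- outer(rmin_half, rmin_half, "+")
  epsm <- sqrt(outer(epsilon, epsilon))
  B <- (rmin / rr)^6
  E <- epsm * (B * B - 2 * B) * S
  total <- sum(E) / 2
  if (detail) list(energy = total, pairs = E / 2) else total
}

#' Bonded (internal) energy
#'
#' Harmonic bonds `k*(r-r0)^2`, harmonic angles `kf*(theta-theta0)^2` and
#' periodic dihedrals `(v/2)*(1+cos(n*phi-gamma))`.
#'
#' @param xyz N x 3 coordinates (A).
#' @param top an `"mmtopology"`.
#' @return list with `bonds`, `angles`, `dihedrals` and `total` (kcal/mol).
#' @export
bonded_energy <- function(xyz, top) {
  xyz <- as.matrix(xyz)
  eb <- ea <- ed <- 0
  b <- top$bonds
  if (nrow(b)) {
    d <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- .rownorm(d)
    eb <- sum(b$k * (r - b$r0)^2)
  }
  a <- top$angles
  if (nrow(a)) {
    th <- .angle_geom(xyz, a)$theta
    ea <- sum(a$kf * (th - a$theta0)^2)
  }
  dh <- top$dihedrals
  if (nrow(dh)) {
    phi <- .dihedral_geom(xyz, dh)$phi
    ed <- sum(dh$v / 2 * (1 + cos(dh$n * phi - dh$gamma)))
  }
  list(bonds = eb, angles = ea, dihedrals = ed, total = eb + ea + ed)
}

.angle_geom <- function(xyz, a) {
  u <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
  v <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
  ru <- .rownorm(u); rv <- .rownorm(v)
  if (any(ru < 1e-8) || any(rv < 1e-8))
    stop("geometry error: angle with coincident atoms")
  cth <- pmin(1, pmax(-1, rowSums(u * v) / (ru * rv)))
  list(u = u, v = v, ru = ru, rv = rv, cth = cth, theta = acos(cth))
}

.dihedral_geom <- function(xyz, d) {
  b1 <- xyz[d$j, , drop = FALSE] - xyz[d$i, , drop = FALSE]
  b2 <- xyz[d$k, , drop = FALSE] - xyz[d$j, , drop = FALSE]
  b3 <- xyz[d$l, , drop = FALSE] - xyz[d$k, , drop = FALSE]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  rb2 <- .rownorm(b2)
  phi <- atan2(rowSums(.cross3(n1, n2) * b2) / rb2, rowSums(n1 * n2))
  list(b1 = b1, b2 = b2, b3 = b3, n1 = n1, n2 = n2, rb2 = rb2, phi = phi)
}

#' Total gas-phase potential energy
#'
#' `bonded + Coulomb + Lennard-Jones` under the given dielectric mode; the
#' objective minimized before normal-mode analysis.
#'
#' @inheritParams bonded_energy
#' @param mode an [dielectric()] mode.
#' @return energy in kcal/mol.
#' @export
total_energy <- function(xyz, top, mode = dielectric()) {
  bonded_energy(xyz, top)$total +
    coulomb_energy(xyz, top$atoms$charge, top, mode = mode) +
    lj_energy(xyz, exclusions = top)
}

#' Analytic gradient of the gas-phase energy
#'
#' Exact derivative of `bonded + Coulomb + LJ` with respect to the Cartesian
#' coordinates, under the given dielectric mode.
#'
#' @inheritParams total_energy
#' @return N x 3 gradient matrix (kcal/mol/A).
#' @export
mm_gradient <- function(xyz, top, mode = dielectric()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  G <- matrix(0, n, 3)
  acc <- function(G, idx, contrib) {
    s <- rowsum(contrib, group = idx)
    at <- as.integer(rownames(s))
    G[at, ] <- G[at, , drop = FALSE] + s
    G
  }

  b <- top$bonds
  if (nrow(b)) {
    d <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- .rownorm(d)
    coef <- 2 * b$k * (r - b$r0) / r
    gi <- coef * d
    G <- acc(G, c(b$i, b$j), rbind(gi, -gi))
  }

  a <- top$angles
  if (nrow(a)) {
    g <- .angle_geom(xyz, a)
    sth <- sqrt(pmax(1 - g$cth^2, 1e-12))
    dEdth <- 2 * a$kf * (g$theta - a$theta0)
    uh <- g$u / g$ru; vh <- g$v / g$rv
    dthi <- (g$cth * uh - vh) / (g$ru * sth)
    dthk <- (g$cth * vh - uh) / (g$rv * sth)
    dthj <- -(dthi + dthk)
    G <- acc(G, c(a$i, a$j, a$k), rep(dEdth, 3) * rbind(dthi, dthj, dthk))
  }

  d <- top$dihedrals
  if (nrow(d)) {
    g <- .dihedral_geom(xyz, d)
    dEdphi <- -(d$v * d$n / 2) * sin(d$n * g$phi - d$gamma)
    n1sq <- rowSums(g$n1^2); n2sq <- rowSums(g$n2^2)
    dpi <- -(g$rb2 / n1sq) * g$n1
    dpl <- (g$rb2 / n2sq) * g$n2
    c12 <- rowSums(g$b1 * g$b2) / g$rb2^2
    c32 <- rowSums(g$b3 * g$b2) / g$rb2^2
    dpj <- -(1 + c12) * dpi + c32 * dpl
    dpk <- c12 * dpi - (1 + c32) * dpl
    G <- acc(G, c(d$i, d$j, d$k, d$l), rep(dEdphi, 4) * rbind(dpi, dpj, dpk, dpl))
  }

  # nonbonded: W[i,j] = (dE/dr)/r for each pair
  q <- top$atoms$charge
  Se <- .nb_scale(n, top$exclusions, top$scale14$ele)
  Sv <- .nb_scale(n, top$exclusions, top$scale14$vdw)
  r <- as.matrix(stats::dist(xyz))
  .check_singular(r, pmax(Se, Sv), "nonbonded")
  rr <- r; diag(rr) <- 1
  Ee <- if (mode$kind == "constant") {
    mm_constants$ke * outer(q, q) * Se / (mode$epsilon_in * rr)
  } else {
    mm_constants$ke * outer(q, q) * Se / (mode$factor * rr^2)
  }
  We <- if (mode$kind == "constant") -Ee / rr^2 else -2 * Ee / rr^2
  rmin <- outer(top$atoms$lj_rmin_half, top$atoms$lj_rmin_half, "+")
  epsm <- sqrt(outer(top$atoms$lj_epsilon, top$atoms$lj_epsilon))
  B <- (rmin / rr)^6
  Wv <- 12 * epsm * Sv * (B - B * B) / rr^2
  W <- We + Wv
  diag(W) <- 0
  for (dim in 1:3) {
    D <- outer(xyz[, dim], xyz[, dim], "-")
    G[, dim] <- G[, dim] + rowSums(W * D)
  }
  G
}

#' Root-mean-square of a gradient
#' @param g gradient matrix from [mm_gradient()].
#' @return RMS over all 3N components (kcal/mol/A).
#' @export
gradient_rms <- function(g) sqrt(mean(g^2))
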