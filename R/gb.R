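#' Solvation parameters
#'
#' Parameters of the implicit-solvent model: interior/exterior dielectrics
#' (1/80), the nonpolar surface coefficient `gamma` (0.0072 kcal/mol/A^2) and
#' offset `beta_const` (0), the solvent probe radius (1.4 A), the Born radius
#' offset (0.09 A) and the OBC rescaling coefficients. `obc_variant` selects
#' the published coefficient set: `"OBC2"` (alpha 1.0, beta 0.8, gamma 4.85,
#' default) or `"OBC1"` (0.8, 0, 2.909125); explicit `obc_alpha/beta/gamma`
#' override the variant.
#'
#' @param epsilon_in,epsilon_out solute and solvent dielectric constants.
#' @param gamma surface-tension coefficient, kcal/mol/A^2.
#' @param beta_const additive nonpolar constant, kcal/mol.
#' @param probe_radius solvent probe radius, A.
#' @param born_offset intrinsic-radius offset, A.
#' @param obc_variant `"OBC2"` or `"OBC1"`.
#' @param obc_alpha,obc_beta,obc_gamma optional explicit OBC coefficients.
#' @param sasa_points number of Shrake-Rupley quadrature points per sphere.
#' @return an object of class `"mmsolvation"`.
#' @export
solvation_params <- function(epsilon_in = 1.0, epsilon_out = 80.0,
                             gamma = 0.0072, beta_const = 0.0,
                             probe_radius = 1.4, born_offset = 0.09,
                             obc_variant = c("OBC2", "OBC1"),
                             obc_alpha = NULL, obc_beta = NULL, obc_gamma = NULL,
                             sasa_points = 960) {
  obc_variant <- match.arg(obc_variant)
  if (epsilon_in < 1 || epsilon_out <= epsilon_in)
    stop("need epsilon_out > epsilon_in >= 1")
  if (gamma < 0 || probe_radius < 0) stop("gamma and probe_radius must be >= 0")
  co <- if (obc_variant == "OBC2") c(1.0, 0.8, 4.85) else c(0.8, 0.0, 2.909125)
  structure(list(
    epsilon_in = epsilon_in, epsilon_out = epsilon_out,
    gamma = gamma, beta_const = beta_const,
    probe_radius = probe_radius, born_offset = born_offset,
    obc_variant = obc_variant,
    obc_alpha = if (is.null(obc_alpha)) co[1] else obc_alpha,
    obc_beta = if (is.null(obc_beta)) co[2] else obc_beta,
    obc_gamma = if (is.null(obc_gamma)) co[3] else obc_gamma,
    sasa_points = sasa_points
  ), class = "mmsolvation")
}

#' Effective Born radii (OBC pairwise descreening)
#'
#' Hawkins-Cramer-Truhlar pairwise descreening integrals over offset-reduced,
#' screened atomic spheres, rescaled through the Onufriev-Bashford-Case
#' `tanh(alpha*Psi - beta*Psi^2 + gamma*Psi^3)` correction. An isolated atom's
#' effective radius equals its offset-reduced intrinsic radius.
#'
#' @param xyz N x 3 coordinates (A).
#' @param top an `"mmtopology"` (uses `gb_radius`, `gb_screen`).
#' @param params an [solvation_params()] object.
#' @return numeric vector of per-atom effective Born radii (A).
#' @export
effective_born_radii <- function(xyz, top, params = solvation_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rho <- top$atoms$gb_radius - params$born_offset
  if (any(rho <= 0)) stop("offset-reduced gb_radius must be positive")
  if (n == 1) return(unname(rho))
  r <- as.matrix(stats::dist(xyz))
  off <- r + diag(Inf, n)
  bad <- which(off < 1e-6, arr.ind = TRUE)
  if (nrow(bad))
    stop("overlapping identical centers: atoms ", min(bad[1, ]), " and ",
         max(bad[1, ]))
  RH <- matrix(rho, n, n)                 # rho_i by row
  SK <- matrix(top$atoms$gb_screen * rho, n, n, byrow = TRUE)  # s_j*rho_j by col
  U <- r + SK
  L <- pmax(RH, abs(r - SK))
  rr <- r; diag(rr) <- 1                  # dummy, masked out below
  term <- 0.5 * (1 / L - 1 / U +
                 0.25 * (rr - SK^2 / rr) * (1 / U^2 - 1 / L^2) +
                 0.5 * log(L / U) / rr +
                 ifelse(SK > rr + RH, 2 * (1 / RH - 1 / L), 0))
  term[U <= RH] <- 0                      # neighbor buried inside rho_i
  diag(term) <- 0
  I <- rowSums(term)
  psi <- I * rho
  a <- params$obc_alpha; b <- params$obc_beta; g <- params$obc_gamma
  inv <- 1 / rho - tanh(a * psi - b * psi^2 + g * psi^3) / top$atoms$gb_radius
  if (any(inv <= 0)) stop("numerical error computing Born radii: atom ",
                          which(inv <= 0)[1])
  unname(1 / inv)
}

#' Generalized Born polar solvation energy
#'
#' Still's pairwise energy with the canonical interpolation
#' `fGB = sqrt(r^2 + Ri*Rj*exp(-r^2/(4*Ri*Rj)))`, including the i = j Born
#' self terms; no salt screening:
#' `dGpol = -(ke/2) (1/eps_in - 1/eps_out) * sum_ij qi qj / fGB`.
#'
#' @param xyz N x 3 coordinates (A).
#' @param charges length-N charges (e).
#' @param radii per-atom effective Born radii (A), from
#'   [effective_born_radii()].
#' @param params an [solvation_params()] object.
#' @param detail if `TRUE` also return the symmetric per-pair/self matrix
#'   whose total equals the scalar energy.
#' @return kcal/mol, or `list(energy, pairs)` when `detail = TRUE`.
#' @export
gb_polar_energy <- function(xyz, charges, radii, params = solvation_params(),
                            detail = FALSE) {
  xyz <- as.matrix(xyz)
  if (any(radii <= 0)) stop("effective radii must be positive")
  r2 <- as.matrix(stats::dist(xyz))^2
  RiRj <- outer(radii, radii)
  fgb <- sqrt(r2 + RiRj * exp(-r2 / (4 * RiRj)))
  if (any(!is.finite(fgb))) stop("non-finite fGB term")
  tau <- 1 / params$epsilon_in - 1 / params$epsilon_out
  M <- -0.5 * mm_constants$ke * tau * outer(charges, charges) / fgb
  total <- sum(M)
  if (detail) list(energy = total, pairs = M) else total
}

# deterministic near-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Counts quadrature points on each atom's solvent-expanded sphere
#' (radius `gb_radius + probe`) that fall outside every neighbor's expanded
#' sphere; per-atom areas sum exactly to the total.
#'
#' @param xyz N x 3 coordinates (A).
#' @param top an `"mmtopology"` (atomic radii are its `gb_radius` column).
#' @param params an [solvation_params()] object (`probe_radius`,
#'   `sasa_points`).
#' @return list with `total` (A^2) and `per_atom` (length-N vector).
#' @export
sasa <- function(xyz, top, params = solvation_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  R <- top$atoms$gb_radius + params$probe_radius
  pts <- .sphere_points(params$sasa_points)
  per <- numeric(n)
  if (n > 1) d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    p <- xyz[rep(i, nrow(pts)), , drop = FALSE] + R[i] * pts
    acc <- rep(TRUE, nrow(pts))
    if (n > 1) {
      nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
      for (j in nb) {
        dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
        acc <- acc & (dx * dx + dy * dy + dz * dz > R[j]^2)
        if (!any(acc)) break
      }
    }
    per[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(total = sum(per), per_atom = per)
}

#' Nonpolar solvation energy
#'
#' Linear surface-area model `gamma * SASA + beta`.
#'
#' @param sasa_total total solvent-accessible surface area (A^2).
#' @param params an [solvation_params()] object.
#' @return kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, params = solvation_params()) {
  if (sasa_total < 0) stop("sasa_total must be >= 0")
  params$gamma * sasa_total + params$beta_const
}
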