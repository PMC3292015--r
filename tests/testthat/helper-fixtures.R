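# shared fixtures and independent oracles for the test suite

KE <- mmgbsa::mm_constants$ke

# a bare point-charge topology with no bonded terms
point_topology <- function(q, rmin_half = 1.8, eps = 0.1, gbr = 1.5,
                           screen = 0.8, mass = 12) {
  n <- length(q)
  build_topology(data.frame(
    name = paste0("A", seq_len(n)), element = "C", charge = q,
    lj_rmin_half = rep_len(rmin_half, n), lj_epsilon = rep_len(eps, n),
    gb_radius = rep_len(gbr, n), gb_screen = rep_len(screen, n),
    mass = rep_len(mass, n), resno = seq_len(n), resname = "ION"))
}

random_config <- function(n, seed, spread = 6) {
  set.seed(seed)
  list(xyz = matrix(stats::runif(3 * n, 0, spread), n, 3),
       q = stats::runif(n, -1, 1),
       rmin_half = stats::runif(n, 1.2, 2.1),
       eps = stats::runif(n, 0.01, 0.3),
       radii = stats::runif(n, 1.2, 2.4))
}

# brute-force double-loop oracles, intentionally naive
oracle_coulomb <- function(xyz, q, eps_in = 1) {
  e <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    e <- e + KE * q[i] * q[j] / (eps_in * sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  e
}

oracle_lj <- function(xyz, rmin_half, eps) {
  e <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rm <- rmin_half[i] + rmin_half[j]
    ee <- sqrt(eps[i] * eps[j])
    e <- e + ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

oracle_gb <- function(xyz, q, radii, eps_in = 1, eps_out = 80) {
  tau <- 1 / eps_in - 1 / eps_out
  e <- 0
  n <- nrow(xyz)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    f <- sqrt(r2 + radii[i] * radii[j] * exp(-r2 / (4 * radii[i] * radii[j])))
    e <- e - 0.5 * KE * tau * q[i] * q[j] / f
  }
  e
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[1] * a[2] * C + a[3] * s, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s,
           a[1] * a[3] * C - a[2] * s, a[2] * a[3] * C + a[1] * s, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

# a homonuclear harmonic diatomic at equilibrium
diatomic_topology <- function(k = 300, r0 = 1.5, mass = 12) {
  build_topology(
    data.frame(name = c("A1", "A2"), element = "C", charge = 0,
               lj_rmin_half = 1.0, lj_epsilon = 0, gb_radius = 1.7,
               gb_screen = 0.72, mass = mass, resno = 1, resname = "DIA"),
    bonds = data.frame(i = 1L, j = 2L, k = k, r0 = r0))
}

# lazily computed, cached expensive fixtures (shared across test files)
.cache <- new.env(parent = emptyenv())

minimized_toy <- function() {
  if (is.null(.cache$min_toy)) {
    tc <- make_toy_complex(seed = 11, n_frames = 1, noise = 0.03)
    mn <- minimize_structure(tc$ensemble$frames[[1]], tc$topology)
    .cache$min_toy <- list(top = tc$topology, min = mn,
                           nm = normal_modes(mn$xyz, tc$topology))
  }
  .cache$min_toy
}
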