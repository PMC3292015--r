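test_that("Coulomb energy matches the closed form for a unit-charge pair", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(xyz, c(1, -1)), -332.0637128)
  # distance-dependent dielectric eps(r) = 4r
  expect_equal(coulomb_energy(xyz, c(1, -1),
                              mode = dielectric("distance_dependent", factor = 4)),
               -332.0637128 / 4)
  # and at 2 A the 4r mode divides by 4*2*2
  xyz2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(coulomb_energy(xyz2, c(1, -1),
                              mode = dielectric("distance_dependent", factor = 4)),
               -332.0637128 / 16)
})

test_that("Coulomb and LJ totals equal brute-force double loops", {
  for (seed in 1:5) {
    cf <- random_config(10, seed)
    expect_equal(coulomb_energy(cf$xyz, cf$q), oracle_coulomb(cf$xyz, cf$q),
                 tolerance = 1e-12)
    expect_equal(lj_energy(cf$xyz, cf$rmin_half, cf$eps),
                 oracle_lj(cf$xyz, cf$rmin_half, cf$eps), tolerance = 1e-12)
  }
})

test_that("LJ pair potential has its minimum -eps at r = rmin", {
  xyz <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  expect_equal(lj_energy(xyz, c(1.5, 1.5), c(0.1, 0.1)), -0.1)
  far <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_lt(abs(lj_energy(far, c(1.5, 1.5), c(0.1, 0.1))), 1e-6)
})

test_that("1-4 pairs are scaled and 1-2/1-3 excluded in gas-phase terms", {
  # linear 4-atom chain: only the 1-4 pair interacts, divided by the scales
  q <- c(0.3, 0, 0, -0.4)
  xyz <- cbind(c(0, 1.5, 3.0, 4.5), 0, 0)
  atoms <- data.frame(name = paste0("A", 1:4), element = "C", charge = q,
                      lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = 1.7,
                      gb_screen = 0.72, mass = 12, resno = 1, resname = "XX")
  top <- build_topology(
    atoms,
    bonds = data.frame(i = 1:3, j = 2:4, k = 300, r0 = 1.5),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, kf = 50, theta0 = pi),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, v = 1, n = 3, gamma = 0))
  e14 <- KE * q[1] * q[4] / 4.5 / 1.2
  expect_equal(coulomb_energy(xyz, q, top), e14)
  lj14 <- 0.1 * ((3.8 / 4.5)^12 - 2 * (3.8 / 4.5)^6) / 2.0
  expect_equal(lj_energy(xyz, exclusions = top), lj14)
})

test_that("bonded terms follow their closed forms", {
  top <- diatomic_topology(k = 300, r0 = 1.5)
  at_eq <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  expect_equal(bonded_energy(at_eq, top)$total, 0)
  stretched <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  expect_equal(bonded_energy(stretched, top)$total, 300 * 0.01)
  # dihedral with zero barrier contributes nothing at any torsion
  set.seed(3)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  atoms <- data.frame(name = paste0("A", 1:4), element = "C", charge = 0,
                      lj_rmin_half = 1, lj_epsilon = 0, gb_radius = 1.7,
                      gb_screen = 0.72, mass = 12, resno = 1, resname = "XX")
  topd <- build_topology(atoms, dihedrals = data.frame(i = 1, j = 2, k = 3,
                                                       l = 4, v = 0, n = 2,
                                                       gamma = 1))
  expect_equal(bonded_energy(xyz, topd)$total, 0)
})

test_that("coincident interacting atoms raise a singularity error", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(coulomb_energy(xyz, c(1, 1)), "singularity")
  expect_error(lj_energy(xyz, c(1, 1), c(0.1, 0.1)), "singularity")
})

test_that("per-pair matrices are symmetric and sum to the scalar totals", {
  cf <- random_config(12, 42)
  ce <- coulomb_energy(cf$xyz, cf$q, detail = TRUE)
  expect_equal(ce$pairs, t(ce$pairs))
  expect_equal(sum(ce$pairs), ce$energy, tolerance = 1e-12)
  le <- lj_energy(cf$xyz, cf$rmin_half, cf$eps, detail = TRUE)
  expect_equal(le$pairs, t(le$pairs))
  expect_equal(sum(le$pairs), le$energy, tolerance = 1e-12)
})

test_that("gas-phase energies are invariant under rigid motion", {
  tc <- make_toy_complex(7, 1, noise = 0.02)
  xyz <- tc$ensemble$frames[[1]]
  top <- tc$topology
  e0 <- total_energy(xyz, top)
  set.seed(10)
  for (rep in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    moved <- xyz %*% t(R) + matrix(rnorm(3, sd = 10), nrow(xyz), 3, byrow = TRUE)
    expect_equal(total_energy(moved, top), e0, tolerance = 1e-9)
  }
})

test_that("well-separated fragments are energetically additive", {
  tc <- make_toy_complex(1, 1, noise = 0)
  top <- tc$topology
  xyz <- tc$ensemble$frames[[1]]
  p <- partition_complex(top, "LIG")
  far <- xyz
  far[p$ligand, ] <- far[p$ligand, ] + matrix(c(500, 0, 0), length(p$ligand), 3,
                                              byrow = TRUE)
  er <- total_energy(xyz[p$receptor, , drop = FALSE],
                     subset_topology(top, p$receptor))
  el <- total_energy(xyz[p$ligand, , drop = FALSE],
                     subset_topology(top, p$ligand))
  expect_equal(total_energy(far, top), er + el, tolerance = 1e-6)
})

test_that("analytic gradient matches central finite differences", {
  tc <- make_toy_complex(4, 1, noise = 0.05)
  top <- tc$topology
  xyz <- tc$ensemble$frames[[1]]
  for (mode in list(dielectric(), dielectric("distance_dependent", factor = 4))) {
    g <- mm_gradient(xyz, top, mode)
    h <- 1e-6
    set.seed(8)
    # spot-check 12 random coordinates (full grids are exercised in dev)
    for (rep in 1:12) {
      i <- sample(nrow(xyz), 1); d <- sample(3, 1)
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      fd <- (total_energy(xp, top, mode) - total_energy(xm, top, mode)) / (2 * h)
      expect_equal(g[i, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("gradient vanishes at a diatomic minimum and under translation", {
  top <- diatomic_topology()
  g <- mm_gradient(rbind(c(0, 0, 0), c(1.5, 0, 0)), top)
  expect_lt(max(abs(g)), 1e-10)
  tc <- make_toy_complex(4, 1)
  g1 <- mm_gradient(tc$ensemble$frames[[1]], tc$topology)
  g2 <- mm_gradient(tc$ensemble$frames[[1]] + 7.3, tc$topology)
  expect_equal(g1, g2, tolerance = 1e-7)
})
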