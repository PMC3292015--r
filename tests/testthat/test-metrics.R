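test_that("RMSD is zero against itself and under rigid motion", {
  tc <- make_toy_complex(5, 3, noise = 0.05)
  top <- tc$topology
  r <- backbone_rmsd(tc$ensemble, top)
  expect_lt(r[1], 1e-10)
  f1 <- tc$ensemble$frames[[1]]
  R <- rotation_matrix(c(0.2, 1, -0.5), 37 * pi / 180)
  moved <- f1 %*% t(R) + matrix(c(5, 0, 0), nrow(f1), 3, byrow = TRUE)
  ens2 <- new_ensemble(list(f1, moved))
  expect_lt(backbone_rmsd(ens2, top)[2], 1e-8)
})

test_that("superposed RMSD matches a brute-force rotation-search oracle", {
  # 4-atom toy: reference square, frame with one atom displaced
  ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  frame <- ref
  frame[1, ] <- frame[1, ] + c(0.6, 0.4, 0.3)
  # disguise with a rigid motion
  R <- rotation_matrix(c(1, 2, 3), 1.234)
  frame <- frame %*% t(R) + matrix(c(2, -1, 4), 4, 3, byrow = TRUE)
  atoms <- data.frame(name = c("N", "CA", "C", "O"), element = "C", charge = 0,
                      lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = 1.7,
                      gb_screen = 0.72, mass = 12, resno = 1, resname = "XX")
  top <- build_topology(atoms)
  ens <- new_ensemble(list(ref, frame))
  got <- backbone_rmsd(ens, top, selection = c("N", "CA", "C", "O"))[2]
  # oracle: center both, grid-search Euler angles then refine locally
  ctr <- function(m) sweep(m, 2, colMeans(m))
  A <- ctr(ref); B <- ctr(frame)
  rms_of <- function(ang) {
    Rz1 <- rotation_matrix(c(0, 0, 1), ang[1])
    Ry <- rotation_matrix(c(0, 1, 0), ang[2])
    Rz2 <- rotation_matrix(c(0, 0, 1), ang[3])
    sqrt(mean(rowSums((B %*% t(Rz2 %*% Ry %*% Rz1) - A)^2)))
  }
  grid <- seq(0, 2 * pi, by = 20 * pi / 180)
  best <- c(0, 0, 0); bestv <- Inf
  for (a1 in grid) for (a2 in grid[grid <= pi]) for (a3 in grid) {
    v <- rms_of(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  ref_opt <- stats::optim(best, rms_of, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(got, ref_opt$value, tolerance = 1e-3)
})

test_that("superposed RMSD agrees with an established implementation", {
  tc <- make_toy_complex(5, 4, noise = 0.1)
  top <- tc$topology
  idx <- which(top$atoms$name %in% c("N", "CA", "C"))
  ours <- backbone_rmsd(tc$ensemble, top)
  for (f in 2:4) {
    a <- as.vector(t(tc$ensemble$frames[[1]][idx, ]))
    b <- as.vector(t(tc$ensemble$frames[[f]][idx, ]))
    # reference implementation reports three decimals
    expect_lt(abs(ours[f] - as.numeric(bio3d::rmsd(a, b, fit = TRUE))),
              6e-4)
  }
})

test_that("RMSD selection rules are enforced", {
  tc <- make_toy_complex(5, 2)
  expect_error(backbone_rmsd(tc$ensemble, tc$topology, selection = "ZZ"),
               "matches no atoms")
  r <- backbone_rmsd(tc$ensemble, tc$topology, include_o = TRUE)
  expect_length(r, 2)
})

test_that("hydrogen-bond criteria: boundary geometries are rejected", {
  # distance 3.6 A at a good angle: too far
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0.3, 0))
  dfar <- sqrt(sum(far[3, ]^2))
  far[3, ] <- far[3, ] * 3.6 / dfar
  # angle 119 deg at a good distance: too bent
  th <- pi - 119 * pi / 180
  L <- -cos(th) + sqrt(cos(th)^2 - 1 + 2.9^2)
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1 + L * cos(th), L * sin(th), 0))
  # and one clearly qualifying frame
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  atoms <- data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
                      charge = c(-0.4, 0.4, -0.5), lj_rmin_half = 1,
                      lj_epsilon = 0.1, gb_radius = 1.5, gb_screen = 0.8,
                      mass = c(14, 1, 16), resno = c(1, 1, 2),
                      resname = c("DON", "DON", "ACC"))
  top <- build_topology(atoms, bonds = data.frame(i = 1L, j = 2L, k = 450,
                                                  r0 = 1))
  ens <- new_ensemble(list(far, bent, good))
  occ <- hbond_occupancy(ens, top,
                         data.frame(donor = 1, hydrogen = 2, acceptor = 3))
  expect_equal(occ$occupancy, 100 / 3)
  # qualifying-frame-only means: the single good frame defines them
  expect_equal(occ$mean_distance, 2.9)
  expect_equal(occ$mean_angle, 180)
})

test_that("occupancy is frame-order invariant and subsamples periodically", {
  hb <- make_hbond_ensemble(fixture_spec(seed = 2, n_frames = 100,
                                         hbond_occupancy_target = 0.5))
  pairs <- data.frame(donor = 1, hydrogen = 2, acceptor = 3)
  occ <- hbond_occupancy(hb$ensemble, hb$topology, pairs)$occupancy
  perm <- sample(100)
  shuf <- new_ensemble(hb$ensemble$frames[perm])
  expect_equal(hbond_occupancy(shuf, hb$topology, pairs)$occupancy, occ)
  # a strictly periodic pattern subsamples exactly
  period <- rep(c(TRUE, FALSE), 50)
  frames <- lapply(period, function(b)
    if (b) rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
    else rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0)))
  ens <- new_ensemble(frames)
  occ_all <- hbond_occupancy(ens, hb$topology, pairs)$occupancy
  half <- new_ensemble(frames[seq(1, 100, by = 2)])
  expect_equal(occ_all, 50)
  expect_equal(hbond_occupancy(half, hb$topology, pairs)$occupancy, 100)
})

test_that("a donor hydrogen must be bonded to its heavy atom", {
  hb <- make_hbond_ensemble(fixture_spec(seed = 1, n_frames = 5))
  expect_error(hbond_occupancy(hb$ensemble, hb$topology,
                               data.frame(donor = 3, hydrogen = 2,
                                          acceptor = 1)),
               "not bonded")
})
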