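test_that("per-residue sums conserve every ensemble-mean delta component", {
  tc <- make_toy_complex(1, 3, noise = 0.04)
  p <- partition_complex(tc$topology, "LIG")
  dec <- per_residue_decomposition(tc$ensemble, tc$topology, p)
  comp <- ensemble_delta_energies(tc$ensemble, tc$topology, p)
  expect_equal(sum(dec$ele), mean(comp$ele), tolerance = 1e-9)
  expect_equal(sum(dec$vdw), mean(comp$vdw), tolerance = 1e-9)
  expect_equal(sum(dec$pol), mean(comp$pol), tolerance = 1e-9)
  expect_equal(sum(dec$nopol), mean(comp$nopol), tolerance = 1e-9)
  expect_equal(sum(dec$total),
               mean(comp$ele + comp$vdw + comp$pol + comp$nopol),
               tolerance = 1e-9)
  expect_equal(dec$total, dec$ele + dec$vdw + dec$pol + dec$nopol)
})

test_that("a residue far from the ligand contributes almost nothing", {
  tc <- make_toy_complex(1, 1, noise = 0)
  top <- tc$topology
  xyz <- tc$ensemble$frames[[1]]
  # push residue 3 sixty Angstrom away from everything
  r3 <- which(top$atoms$resno == 3)
  xyz[r3, ] <- xyz[r3, ] + matrix(c(0, 0, 60), length(r3), 3, byrow = TRUE)
  ens <- new_ensemble(list(xyz))
  p <- partition_complex(top, "LIG")
  dec <- per_residue_decomposition(ens, top, p)
  expect_lt(abs(dec$total[dec$resno == 3]), 0.05)
})

test_that("a two-residue receptor matches hand-summed pairwise attribution", {
  # receptor: two single-atom residues; ligand: one single-atom residue,
  # all far enough apart that only Coulomb/LJ/GB cross terms matter
  atoms <- data.frame(
    name = c("A", "B", "L"), element = "C", charge = c(0.4, -0.3, 0.25),
    lj_rmin_half = 1.8, lj_epsilon = 0.12, gb_radius = 1.6, gb_screen = 0.8,
    mass = 12, resno = 1:3, resname = c("R1", "R2", "LIG"))
  top <- build_topology(atoms)
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0))
  ens <- new_ensemble(list(xyz))
  p <- partition_complex(top, "LIG")
  dec <- per_residue_decomposition(ens, top, p, solvation_params(gamma = 0))
  pairE <- function(i, j) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rm <- 3.6; ee <- 0.12
    KE * atoms$charge[i] * atoms$charge[j] / r +
      ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  # gas part: half of each receptor-ligand pair goes to the residue
  expect_equal(dec$ele[1] + dec$vdw[1], pairE(1, 3) / 2, tolerance = 1e-9)
  expect_equal(dec$ele[2] + dec$vdw[2], pairE(2, 3) / 2, tolerance = 1e-9)
  # GB part conserves the polar delta
  comp <- ensemble_delta_energies(ens, top, p, solvation_params(gamma = 0))
  expect_equal(sum(dec$pol), mean(comp$pol), tolerance = 1e-9)
})

test_that("alanine truncation produces the alanine atom roster", {
  tc <- make_toy_complex(1, 3)
  mut <- mutate_to_alanine(tc$topology, tc$ensemble, 2)
  r2 <- mut$topology$atoms[mut$topology$atoms$resno == 2, ]
  expect_setequal(r2$name, c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3",
                             "C", "O"))
  expect_true(all(r2$resname == "ALA"))
  expect_silent(validate_topology(mut$topology))
  # ensemble and topology stay consistent
  expect_equal(mut$ensemble$natoms, nrow(mut$topology$atoms))
})

test_that("truncation replaces CG by a hydrogen on the old bond vector", {
  tc <- make_toy_complex(1, 2)
  top <- tc$topology
  cb <- which(top$atoms$resno == 2 & top$atoms$name == "CB")
  cg <- which(top$atoms$resno == 2 & top$atoms$name == "CG")
  mut <- mutate_to_alanine(top, tc$ensemble, 2)
  hb3 <- which(mut$topology$atoms$resno == 2 & mut$topology$atoms$name == "HB3")
  cb2 <- which(mut$topology$atoms$resno == 2 & mut$topology$atoms$name == "CB")
  for (f in 1:2) {
    old <- tc$ensemble$frames[[f]]
    new <- mut$ensemble$frames[[f]]
    v <- old[cg, ] - old[cb, ]
    expected <- old[cb, ] + 1.09 * v / sqrt(sum(v^2))
    expect_equal(new[hb3, ], expected, tolerance = 1e-12)
    expect_equal(sqrt(sum((new[hb3, ] - new[cb2, ])^2)), 1.09,
                 tolerance = 1e-12)
  }
})

test_that("backbone coordinates are untouched by the mutation", {
  tc <- make_toy_complex(1, 2)
  top <- tc$topology
  mut <- mutate_to_alanine(top, tc$ensemble, 1)
  bb_names <- c("N", "H", "CA", "HA", "CB", "C", "O")
  for (f in 1:2) {
    old_bb <- tc$ensemble$frames[[f]][top$atoms$name %in% bb_names, ]
    new_bb <- mut$ensemble$frames[[f]][mut$topology$atoms$name %in% bb_names, ]
    expect_identical(old_bb, new_bb)
  }
})

test_that("proline, glycine and alanine targets are rejected", {
  tc <- make_toy_complex(1, 1)
  top <- tc$topology
  for (nm in c("PRO", "GLY", "ALA")) {
    t2 <- top
    t2$atoms$resname[t2$atoms$resno == 1] <- nm
    t2$residues$resname[t2$residues$resno == 1] <- nm
    expect_error(mutate_to_alanine(t2, tc$ensemble, 1), nm)
  }
  expect_error(mutate_to_alanine(top, tc$ensemble, 99), "not present")
})

test_that("a null side chain mutates with zero gas-phase binding change", {
  tc <- make_toy_complex(1, 2)
  top <- tc$topology
  # silence residue 1's side chain beyond CB and keep the rest of the
  # residue's parameters on mutation
  sc <- which(top$atoms$resno == 1 &
                top$atoms$name %in% c("CG", "HG1", "HG2", "HG3"))
  top$atoms$charge[sc] <- 0
  top$atoms$lj_epsilon[sc] <- 0
  r1 <- top$atoms[top$atoms$resno == 1, ]
  tmpl <- data.frame(name = c(r1$name[r1$name != "CG" &
                                        !grepl("^HG", r1$name)], "HB3"),
                     stringsAsFactors = FALSE)
  keep <- r1[match(tmpl$name[tmpl$name != "HB3"], r1$name), ]
  tmpl <- rbind(
    data.frame(name = keep$name, charge = keep$charge,
               lj_rmin_half = keep$lj_rmin_half, lj_epsilon = keep$lj_epsilon,
               gb_radius = keep$gb_radius, gb_screen = keep$gb_screen,
               mass = keep$mass, element = keep$element),
    data.frame(name = "HB3", charge = 0, lj_rmin_half = 1.487, lj_epsilon = 0,
               gb_radius = 1.3, gb_screen = 0.85, mass = 1.008, element = "H"))
  p <- partition_complex(top, "LIG")
  mut <- mutate_to_alanine(top, tc$ensemble, 1, ala_params = tmpl)
  mp <- partition_complex(mut$topology, "LIG")
  e_wt <- frame_delta_energies(tc$ensemble$frames[[1]], top, p)
  e_mut <- frame_delta_energies(mut$ensemble$frames[[1]], mut$topology, mp)
  expect_equal(e_mut$ele + e_mut$vdw, e_wt$ele + e_wt$vdw, tolerance = 1e-9)
})

test_that("alanine scan reports consistent wild/mutant bookkeeping", {
  tc <- make_toy_complex(1, 2, noise = 0.03)
  top <- tc$topology
  p <- partition_complex(top, "LIG")
  scan <- alanine_scan(tc$ensemble, top, p, c(1, 3))
  expect_equal(nrow(scan), 2)
  expect_equal(scan$ddg_gb, scan$gb_mut - scan$gb_wt, tolerance = 1e-12)
  expect_equal(scan$d_interaction,
               scan$interaction_mut - scan$interaction_wt, tolerance = 1e-12)
  # the stored mutant decomposition reproduces the reported interaction
  decs <- attr(scan, "decompositions")
  m1 <- decs[["1"]]
  expect_equal(m1$total[m1$resno == 1], scan$interaction_mut[1])
  # decomposition conservation also holds for the mutant
  mut <- mutate_to_alanine(top, tc$ensemble, 1)
  mp <- partition_complex(mut$topology, "LIG")
  comp <- ensemble_delta_energies(mut$ensemble, mut$topology, mp)
  expect_equal(sum(m1$total),
               mean(comp$ele + comp$vdw + comp$pol + comp$nopol),
               tolerance = 1e-9)
})

test_that("an empty scan list yields an empty table", {
  tc <- make_toy_complex(1, 1)
  p <- partition_complex(tc$topology, "LIG")
  scan <- alanine_scan(tc$ensemble, tc$topology, p, integer(0))
  expect_equal(nrow(scan), 0)
  expect_s3_class(scan, "mmalascan")
})

test_that("backbone-mediated hydrogen bonds survive alanine mutation", {
  tc <- make_toy_complex(1, 6, noise = 0.03)
  top <- tc$topology
  # ligand N1-H1 donates to the backbone carbonyl O of residue 2
  d <- which(top$atoms$resno == 4 & top$atoms$name == "N1")
  h <- which(top$atoms$resno == 4 & top$atoms$name == "H1")
  a <- which(top$atoms$resno == 2 & top$atoms$name == "O")
  occ_wt <- hbond_occupancy(tc$ensemble, top,
                            data.frame(donor = d, hydrogen = h, acceptor = a))
  mut <- mutate_to_alanine(top, tc$ensemble, 2)
  d2 <- which(mut$topology$atoms$resno == 4 & mut$topology$atoms$name == "N1")
  h2 <- which(mut$topology$atoms$resno == 4 & mut$topology$atoms$name == "H1")
  a2 <- which(mut$topology$atoms$resno == 2 & mut$topology$atoms$name == "O")
  occ_mut <- hbond_occupancy(mut$ensemble, mut$topology,
                             data.frame(donor = d2, hydrogen = h2,
                                        acceptor = a2))
  expect_gt(occ_wt$occupancy, 0)
  expect_equal(occ_mut$occupancy, occ_wt$occupancy)
  expect_equal(occ_mut$mean_distance, occ_wt$mean_distance)
})
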