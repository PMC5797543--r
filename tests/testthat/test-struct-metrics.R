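# Superposition/RMSD, displacement, SASA/BSA, contacts and dihedrals.

rigid_move <- function(xyz, axis = c(1, 1, 0), angle = 0.7,
                       shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, `+`)
}

test_that("Kabsch recovers rigid transforms exactly", {
  set.seed(4)
  ref <- matrix(rnorm(30), ncol = 3)
  sp0 <- kabsch_superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  moved <- rigid_move(ref)
  sp <- kabsch_superpose(moved, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(ref[1:5, ], ref), "differ in size")
})

test_that("Kabsch rmsd matches the bio3d fit on noisy point sets", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(rnorm(12), ncol = 3)
    b <- rigid_move(a) + matrix(rnorm(12, sd = 0.4), ncol = 3)
    mine <- kabsch_superpose(b, a)$rmsd
    fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b))))
    oracle <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - a)^2)))
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("rmsd is invariant under a common rigid transform", {
  m1 <- micro_groove()
  at2 <- m1$atoms
  xyz <- rigid_move(atom_xyz(at2), angle = 1.2, shift = c(-4, 7, 2))
  at2$x <- xyz[, 1]; at2$y <- xyz[, 2]; at2$z <- xyz[, 3]
  m2 <- structure_model(at2, "moved")
  v <- selection_rmsd(m1, m2, sel(chain = "A", backbone = TRUE),
                      sel(chain = "C"), atom_set = "backbone")
  expect_equal(v, 0, tolerance = 1e-8)
})

test_that("selection rmsd measures without refitting and drops unpairable atoms", {
  m1 <- micro_groove()
  at2 <- m1$atoms
  # displace the peptide rigidly by 2 Angstrom in z while walls stay put
  at2$z[at2$chain == "C"] <- at2$z[at2$chain == "C"] + 2
  m2 <- structure_model(at2, "pep-shift")
  v <- selection_rmsd(m1, m2, sel(chain = "A", backbone = TRUE),
                      sel(chain = "C"), atom_set = "backbone")
  expect_equal(v, 2, tolerance = 1e-6)
  # frame == measure collapses to the plain Kabsch rmsd
  fa <- select_atoms(m1, chain = "A", backbone = TRUE)
  fb <- select_atoms(m2, chain = "A", backbone = TRUE)
  expect_equal(selection_rmsd(m1, m2, sel(chain = "A", backbone = TRUE),
                              sel(chain = "A", backbone = TRUE)),
               kabsch_superpose(atom_xyz(fb), atom_xyz(fa))$rmsd,
               tolerance = 1e-10)
  # an atom present in only one structure is dropped with a warning
  drop_ca <- which(at2$chain == "C" & at2$resseq == 9 & at2$name == "CA")
  m3 <- structure_model(at2[-drop_ca, ], "missing-atom")
  expect_warning(selection_rmsd(m1, m3, sel(chain = "A", backbone = TRUE),
                                sel(chain = "C")), "unpairable")
})

test_that("atom displacement reports the post-superposition distance", {
  m1 <- micro_groove()
  expect_equal(atom_displacement(m1, m1, sel(chain = "A", backbone = TRUE),
                                 "C", 5, "CA"), 0, tolerance = 1e-10)
  at2 <- m1$atoms
  i <- which(at2$chain == "C" & at2$resseq == 5 & at2$name == "CA")
  at2$x[i] <- at2$x[i] + 2
  m2 <- structure_model(at2, "bump")
  expect_equal(atom_displacement(m1, m2, sel(chain = "A", backbone = TRUE),
                                 "C", 5, "CA"), 2, tolerance = 1e-6)
  expect_error(atom_displacement(m1, m2, sel(chain = "A", backbone = TRUE),
                                 "C", 99, "CA"), "not uniquely present")
})

single_atom <- function(x = 0, y = 0, z = 0, el = "C", resseq = 1L,
                        chain = "A") {
  data.frame(serial = 1L, name = "X", altloc = "", resname = "ALA",
             chain = chain, resseq = resseq, icode = "", x = x, y = y,
             z = z, occupancy = 1, bfactor = 0, element = el,
             stringsAsFactors = FALSE)
}

test_that("SASA matches closed forms for one and two spheres", {
  # isolated carbon: 4*pi*(1.7 + 1.4)^2
  s1 <- sasa(single_atom(), probe = 1.4, n_points = 960)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 0.01 * s1$total)
  # far-apart atoms are independent
  two_far <- rbind(single_atom(), single_atom(x = 100, resseq = 2L))
  expect_equal(sasa(two_far)$total, 2 * 4 * pi * 3.1^2, tolerance = 0.5)
  # overlapping spheres: spherical-cap oracle
  d <- 2.5
  R <- 1.7 + 1.4
  x_plane <- d / 2  # equal radii: plane bisects
  cap_area <- 2 * pi * R * (R - x_plane)
  oracle <- 2 * (4 * pi * R^2 - cap_area)
  two_near <- rbind(single_atom(), single_atom(x = d, resseq = 2L))
  expect_equal(sasa(two_near)$total, oracle, tolerance = 0.02 * oracle)
})

test_that("SASA is deterministic and converges with the point count", {
  m <- micro_groove()
  pep <- select_atoms(m, chain = "C")
  a1 <- sasa(pep, n_points = 960)
  a2 <- sasa(pep, n_points = 960)
  expect_identical(a1$area, a2$area)
  a3 <- sasa(pep, n_points = 1920)
  expect_lt(abs(a3$total - a1$total) / a1$total, 0.01)
})

test_that("buried surface area is symmetric, zero for separated parts", {
  m <- micro_groove()
  bsa <- buried_surface_area(m, sel(chain = "A"), sel(chain = "C"))
  bsa_flip <- buried_surface_area(m, sel(chain = "C"), sel(chain = "A"))
  expect_gt(bsa, 0)
  expect_equal(bsa, bsa_flip, tolerance = 1e-9)
  # pulled-apart complex buries nothing
  at <- m$atoms
  at$x[at$chain == "C"] <- at$x[at$chain == "C"] + 200
  m_far <- structure_model(at, "apart")
  expect_equal(buried_surface_area(m_far, sel(chain = "A"),
                                   sel(chain = "C")), 0, tolerance = 0.5)
  expect_error(buried_surface_area(m, sel(chain = "A"), sel(chain = "A")),
               "overlap")
})

test_that("contact typing and cutoffs behave as specified", {
  # planted N-O pair at 2.9 Angstrom: one polar contact
  atoms <- rbind(single_atom(el = "N", chain = "A"),
                 single_atom(x = 2.9, el = "O", chain = "C"))
  atoms$name <- c("N", "O")
  m <- structure_model(atoms, "pair")
  ct <- contacts(m, sel(chain = "A"), sel(chain = "C"))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$type, "polar")
  expect_equal(ct$distance, 2.9)
  # beyond both cutoffs: nothing
  atoms2 <- atoms; atoms2$x[2] <- 6
  expect_equal(nrow(contacts(structure_model(atoms2, "far"),
                             sel(chain = "A"), sel(chain = "C"))), 0)
  # lowering cutoffs never increases counts
  mg <- micro_groove()
  full <- contacts(mg, sel(chain = "A"), sel(chain = "C"))
  tight <- contacts(mg, sel(chain = "A"), sel(chain = "C"),
                    polar_cutoff = 3.0, hydrophobic_cutoff = 4.0)
  expect_lte(nrow(tight), nrow(full))
})

test_that("phi/psi recover the builder's dihedrals; termini are undefined", {
  m <- make_peptide_model(rep(-120, 6), rep(120, 6))
  pp <- phi_psi(m, "C")
  expect_true(is.na(pp$phi[1]))
  expect_true(is.na(pp$psi[6]))
  expect_equal(pp$phi[2:6], rep(-120, 5), tolerance = 1e-6)
  expect_equal(pp$psi[1:5], rep(120, 5), tolerance = 1e-6)
})

test_that("3_10 spans are found where they are built and nowhere else", {
  # extended strand: no helix
  ext <- classify_310(phi_psi(make_peptide_model(rep(-120, 9),
                                                 rep(120, 9)), "C"))
  expect_equal(nrow(ext$spans), 0)
  # residues 4-7 in the 3_10 window
  phi <- rep(-120, 9); psi <- rep(120, 9)
  phi[4:7] <- -60; psi[4:7] <- -25
  cls <- classify_310(phi_psi(make_peptide_model(phi, psi), "C"))
  expect_equal(cls$spans$from, 4)
  expect_equal(cls$spans$to, 7)
  expect_equal(cls$class[4:7], rep("3_10", 4))
  # a run shorter than run_length is not a span
  phi2 <- rep(-120, 9); psi2 <- rep(120, 9)
  phi2[4:5] <- -60; psi2[4:5] <- -25
  cls2 <- classify_310(phi_psi(make_peptide_model(phi2, psi2), "C"))
  expect_equal(nrow(cls2$spans), 0)
})
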