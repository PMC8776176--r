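test_that("torsion angle reproduces planar cis/trans arrangements", {
  a <- c(1, 1, 0); b <- c(1, 0, 0); cc <- c(2, 0, 0)
  expect_equal(torsion_angle(a, b, cc, c(2, 1, 0)), 0)    # cis / eclipsed
  expect_equal(torsion_angle(a, b, cc, c(2, -1, 0)), 180) # trans
  # wrap convention: exactly 180, never -180
  expect_true(torsion_angle(a, b, cc, c(2, -1, 0)) > 0)
})

test_that("dihedrals match an independent torsion implementation", {
  set.seed(3)
  n <- 10
  phi <- c(NA, runif(n - 1, -180, 180))
  psi <- c(runif(n - 1, -180, 180), NA)
  ens <- make_backbone_ensemble(phi, psi)
  d <- compute_dihedrals(ens)
  # oracle: bio3d torsions over consecutive backbone atom quadruples;
  # tor[j] is the torsion of atoms (j-1..j+2), so with N,CA,C repeating,
  # psi_i sits at index 3i-1 and phi_(i+1) at index 3i+1
  tor <- bio3d::torsion.xyz(ens$xyz[1, ], atm.inc = 1)
  psi_oracle <- tor[seq(2, by = 3, length.out = n - 1)]
  phi_oracle <- tor[seq(4, by = 3, length.out = n - 1)]
  expect_lt(max(abs(angular_diff(d$psi[1, 1:(n - 1)], psi_oracle))), 1e-6)
  expect_lt(max(abs(angular_diff(d$phi[1, 2:n], phi_oracle))), 1e-6)
  # prescribed-angle (NeRF) round trip
  expect_lt(max(abs(angular_diff(d$phi[1, -1], phi[-1]))), 1e-4)
  expect_lt(max(abs(angular_diff(d$psi[1, -n], psi[-n]))), 1e-4)
})

test_that("dihedrals are invariant to rigid-body motion and flag termini", {
  set.seed(4)
  ens <- make_backbone_ensemble(phi = c(NA, runif(6, -180, 180)),
                                psi = c(runif(6, -180, 180), NA))
  moved <- transform_ensemble(ens)
  d0 <- compute_dihedrals(ens)
  d1 <- compute_dihedrals(moved)
  expect_lt(max(abs(angular_diff(d0$phi[, -1], d1$phi[, -1]))), 1e-9)
  expect_true(all(is.na(d0$phi[, 1])) && all(is.na(d0$psi[, 7])))
})

test_that("missing backbone atoms are a geometry error naming the residue", {
  ens <- make_backbone_ensemble(phi = c(NA, rep(-65, 4)),
                                psi = c(rep(-40, 4), NA))
  keep <- !(ens$atoms$resno == 3 & ens$atoms$elety == "CA")
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  broken <- ensemble(ens$atoms[keep, ], ens$xyz[, cols, drop = FALSE])
  expect_error(compute_dihedrals(broken), "residue 3.*CA")
})

test_that("kabsch RMSD is a symmetric congruence-invariant metric", {
  set.seed(5)
  a <- matrix(rnorm(30, sd = 4), ncol = 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  moved <- transform_ensemble(ensemble(
    data.frame(chain = "A", resno = 1:10, resid = "ALA", elety = "CA"),
    as.vector(t(a))))
  b <- frame_coords(moved, 1)
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  d <- a + matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(a, d), kabsch_rmsd(d, a), tolerance = 1e-9)
  expect_gt(kabsch_rmsd(a, d), 0)
  expect_error(kabsch_rmsd(a, a[1:5, ]), "differ in size")
})

test_that("single displaced atom: fitted RMSD matches the brute-force optimum", {
  # square of 4 points, one displaced 1 A out of plane; the no-refit value
  # sqrt(1/4) = 0.5 is an upper bound, the optimal superposition is lower
  a <- matrix(c(0, 0, 0, 2, 0, 0, 2, 2, 0, 0, 2, 0), ncol = 3, byrow = TRUE)
  b <- a
  b[4, 3] <- b[4, 3] + 1
  got <- kabsch_rmsd(a, b)
  expect_lte(got, 0.5)
  expect_equal(got, oracle_min_rmsd(a, b), tolerance = 1e-5)
})

test_that("RMSF is zero for static ensembles and d/2 for a two-frame toggle", {
  base <- matrix(rnorm(60, sd = 5), ncol = 3)
  atoms <- data.frame(chain = "A", resno = 1:20, resid = "ALA", elety = "CA")
  static <- ensemble(atoms, matrix(rep(as.vector(t(base)), 4), 4,
                                   byrow = TRUE))
  expect_true(all(rmsf_profile(static)$rmsf < 1e-12))

  two <- base
  xyz2 <- rbind(as.vector(t(base)), as.vector(t(base)))
  xyz2[2, 3 * 7] <- xyz2[2, 3 * 7] + 0.8       # atom 7 moves 0.8 A in z
  toggled <- ensemble(atoms, xyz2)
  r <- rmsf_profile(toggled, fit = FALSE)
  expect_equal(r$rmsf[7], 0.4, tolerance = 1e-12)
  expect_true(all(r$rmsf[-7] < 1e-12))
})

test_that("RMSF is invariant to rigid-body motion applied to all frames", {
  set.seed(6)
  atoms <- data.frame(chain = "A", resno = 1:15, resid = "ALA", elety = "CA")
  xyz <- t(replicate(10, rnorm(45, sd = 3)))
  ens <- ensemble(atoms, xyz)
  moved <- transform_ensemble(ens)
  expect_equal(rmsf_profile(ens)$rmsf, rmsf_profile(moved)$rmsf,
               tolerance = 1e-9)
})

test_that("mean RMSF approaches sigma*sqrt(3) for isotropic Gaussian noise", {
  set.seed(8)
  n_atoms <- 100
  sigma <- 0.3
  base <- matrix(runif(3 * n_atoms, 0, 30), ncol = 3)
  atoms <- data.frame(chain = "A", resno = seq_len(n_atoms), resid = "ALA",
                      elety = "CA")
  xyz <- t(vapply(1:500, function(f) {
    as.vector(t(base + matrix(rnorm(3 * n_atoms, 0, sigma), ncol = 3)))
  }, numeric(3 * n_atoms)))
  r <- rmsf_profile(ensemble(atoms, xyz))
  expect_equal(mean(r$rmsf), sigma * sqrt(3), tolerance = 0.05)
})

test_that("single-frame RMSF warns and returns zeros; burn-in drops frames", {
  atoms <- data.frame(chain = "A", resno = 1:5, resid = "ALA", elety = "CA")
  one <- ensemble(atoms, rnorm(15))
  expect_warning(r <- rmsf_profile(one), "single-frame")
  expect_true(all(r$rmsf == 0))
  xyz <- rbind(rep(0, 15), rep(0, 15) + 5, rep(5, 15), rep(5, 15))
  drift <- ensemble(atoms, xyz)
  expect_true(all(rmsf_profile(drift, fit = FALSE, burnin = 2)$rmsf == 0))
  expect_error(rmsf_profile(drift, burnin = 4), "every frame")
})

test_that("B-factor conversion follows B = 8 pi^2 / 3 * RMSF^2", {
  expect_equal(bfactor_from_rmsf(0), 0)
  expect_equal(bfactor_from_rmsf(1), 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(bfactor_from_rmsf(0.5), 8 * pi^2 / 3 * 0.25, tolerance = 1e-12)
  expect_equal(round(bfactor_from_rmsf(1), 2), 26.32)
  expect_error(bfactor_from_rmsf(-1))
})

test_that("contact persistence counts the fraction of in-contact frames", {
  # site atom at origin; partner toggles between 2 A and 9 A away
  atoms <- data.frame(chain = "A", resno = c(1, 2), resid = c("CA", "ALA"),
                      elety = c("CA", "OD1"))
  near <- c(0, 0, 0, 2, 0, 0)
  far <- c(0, 0, 0, 9, 0, 0)
  frames <- rbind(matrix(rep(near, 42), 42, byrow = TRUE),
                  matrix(rep(far, 58), 58, byrow = TRUE))
  ens <- ensemble(atoms, frames)
  res <- contact_persistence(ens, site = 1, partner = 2, cutoff = 3)
  expect_equal(res$fraction, 0.42)
  expect_equal(res$by_residue$fraction, 0.42)

  always <- ensemble(atoms, matrix(rep(near, 10), 10, byrow = TRUE))
  expect_equal(contact_persistence(always, 1, 2, 3)$fraction, 1.0)
  never <- ensemble(atoms, matrix(rep(far, 10), 10, byrow = TRUE))
  expect_equal(contact_persistence(never, 1, 2, 3)$fraction, 0.0)
  expect_error(contact_persistence(ens, integer(0), 2, 3), "non-empty")
})
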