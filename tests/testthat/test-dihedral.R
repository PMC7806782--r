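test_that("backbone torsions are recovered exactly from built coordinates", {
  g <- gen_trajectory(trajectory_spec(n_residues = 30, n_replicas = 1,
                                      n_frames = 4, torsion_jitter_sd = 0,
                                      jitter_sd = 0, seed = 1))
  dih <- compute_dihedrals(g$ensemble)
  phi <- dih$angles[1, dih$torsions$torsion == "phi"]
  psi <- dih$angles[1, dih$torsions$torsion == "psi"]
  resno <- g$truth$resno
  expect_equal(unname(phi), g$truth$base_phi[match(
    dih$torsions$resno[dih$torsions$torsion == "phi"], resno)],
    tolerance = 1e-6)
  expect_equal(unname(psi), g$truth$base_psi[match(
    dih$torsions$resno[dih$torsions$torsion == "psi"], resno)],
    tolerance = 1e-6)
  # terminal torsions omitted: no phi for first, no psi for last residue
  expect_false(any(dih$torsions$resno == min(resno) &
                     dih$torsions$torsion == "phi"))
  expect_false(any(dih$torsions$resno == max(resno) &
                     dih$torsions$torsion == "psi"))
})

test_that("torsion sign follows the chirality convention", {
  set.seed(3)
  p <- lapply(1:4, function(i) matrix(rnorm(3), 1))
  ang <- rrmtether:::dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  # independent reference implementation
  ref <- bio3d::torsion.xyz(as.vector(t(do.call(rbind, p))))
  expect_equal(as.numeric(ang), as.numeric(ref), tolerance = 1e-6)

  # mirror image negates every torsion
  m <- lapply(p, function(x) x * matrix(c(1, 1, -1), 1))
  expect_equal(as.numeric(rrmtether:::dihedral_angle(m[[1]], m[[2]], m[[3]], m[[4]])),
               -as.numeric(ang), tolerance = 1e-6)

  g <- gen_trajectory(trajectory_spec(n_residues = 15, n_replicas = 1,
                                      n_frames = 3, seed = 2))
  mir <- g$ensemble
  zc <- seq(3, ncol(mir$replicas[[1]]), by = 3)
  mir$replicas[[1]][, zc] <- -mir$replicas[[1]][, zc]
  expect_equal(compute_dihedrals(mir)$angles,
               -compute_dihedrals(g$ensemble)$angles, tolerance = 1e-6)

  # collinear atoms have no defined torsion
  z <- function(x) matrix(c(x, 0, 0), 1)
  expect_error(rrmtether:::dihedral_angle(z(0), z(1), z(2), z(3)), "collinear")
})

test_that("MI estimator matches closed forms and detects independence", {
  a <- gen_correlated_angles(50000, 0.8, seed = 5)
  expect_equal(a$mi_true, 0.5108256, tolerance = 1e-6)
  mi <- mutual_information(a$x, a$y, bias_correction = "shuffle", seed = 2)
  expect_lt(abs(as.numeric(mi) - a$mi_true), 0.1 * a$mi_true)

  # MI(x, x) = H(x) = log(bins) for uniform angles
  u <- gen_correlated_angles(20000, 0, seed = 6)$x
  expect_equal(mutual_information(u, u, bin_count = 24), log(24),
               tolerance = 0.01)

  ind <- gen_correlated_angles(20000, 0, seed = 7)
  mi0 <- mutual_information(ind$x, ind$y, bias_correction = "shuffle", seed = 2)
  expect_lt(abs(as.numeric(mi0)), 3 * attr(mi0, "null_sd"))

  # exact symmetry, and positivity before correction
  expect_identical(mutual_information(ind$x, ind$y, bin_count = 12),
                   mutual_information(ind$y, ind$x, bin_count = 12))
  expect_gte(mutual_information(ind$x, ind$y, bin_count = 12), 0)

  expect_error(mutual_information(1:100, 1:99), "lengths differ")
  expect_error(mutual_information(ind$x, ind$y, bin_count = 1), "bin_count")
  expect_error(mutual_information(ind$x[1:50], ind$y[1:50]), "10 samples")
})

test_that("coarser binning does not inflate the MI estimate", {
  a <- gen_correlated_angles(30000, 0.6, seed = 9)
  mi24 <- mutual_information(a$x, a$y, bin_count = 24)
  mi8 <- mutual_information(a$x, a$y, bin_count = 8)
  expect_lt(mi8, mi24 + 0.02)
})

test_that("residue MI matrix is symmetric, unit-diagonal and finds planted pairs", {
  cp <- cbind(c(10L, 20L), c(60L, 70L))
  g <- gen_trajectory(trajectory_spec(n_residues = 80, n_replicas = 2,
                                      n_frames = 400, coupled_pairs = cp,
                                      copula_rho = 0.9,
                                      domain1 = domain_def("RRM1", 5, 40),
                                      domain2 = domain_def("RRM2", 50, 76),
                                      seed = 10))
  dih <- compute_dihedrals(g$ensemble)
  mi <- residue_mi_matrix(dih, seed = 4)
  expect_true(isSymmetric(mi$raw))
  expect_true(all(diag(mi$normalized) == 1))
  expect_true(all(mi$normalized >= 0 & mi$normalized <= 1))

  rep <- coupling_report(mi, domain_def("RRM1", 5, 40),
                         domain_def("RRM2", 50, 76), threshold = 0.3)
  found <- rep$pairs[, c("res_i", "res_j")]
  expect_equal(nrow(found), 2L)
  expect_setequal(paste(found$res_i, found$res_j), paste(cp[, 1], cp[, 2]))
  expect_true(all(rep$pairs$class == "inter-domain"))

  # identical torsion series give normalized coupling ~ 1
  dih2 <- dih
  j10 <- which(dih2$torsions$resno == 10)
  j60 <- which(dih2$torsions$resno == 60)
  dih2$angles[, j60] <- dih2$angles[, j10]
  mi2 <- residue_mi_matrix(dih2, bias_correction = "none")
  expect_gt(mi2$normalized["10", "60"], 0.95)
})

test_that("coupling report classifies pairs and handles empty sets", {
  d1 <- domain_def("RRM1", 1, 10); d2 <- domain_def("RRM2", 20, 30)
  fake <- structure(list(
    raw = matrix(0, 4, 4, dimnames = list(c(2, 5, 15, 25), c(2, 5, 15, 25))),
    normalized = matrix(0, 4, 4, dimnames = list(c(2, 5, 15, 25),
                                                 c(2, 5, 15, 25))),
    marginal_entropy = rep(3, 4), bin_count = 24L, bias_corrected = TRUE),
    class = "mi_matrix")
  empty <- coupling_report(fake, d1, d2)
  expect_equal(nrow(empty$pairs), 0L)
  expect_false(empty$ratio_defined)

  fake$normalized[1, 2] <- fake$normalized[2, 1] <- 0.5   # intra-RRM1
  fake$normalized[2, 4] <- fake$normalized[4, 2] <- 0.5   # inter
  fake$normalized[3, 4] <- fake$normalized[4, 3] <- 0.6   # linker-involving
  rep <- coupling_report(fake, d1, d2)
  expect_setequal(rep$pairs$class,
                  c("intra-RRM1", "inter-domain", "linker-involving"))
  expect_equal(rep$inter_intra_ratio, 1)   # equal planted strengths
  expect_error(coupling_report(fake, d1, domain_def("X", 5, 25)), "overlap")
})
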