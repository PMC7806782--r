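make_jitter_ens <- function(n_residues = 60, n_replicas = 1, n_frames = 300,
                            sd = 0.5, seed = 5) {
  gen_trajectory(trajectory_spec(n_residues = n_residues,
                                 n_replicas = n_replicas, n_frames = n_frames,
                                 torsion_jitter_sd = 0, jitter_sd = sd,
                                 seed = seed))$ensemble
}

test_that("static and rigidly rotated trajectories give zero RMSD", {
  ens <- make_jitter_ens(n_residues = 20, n_frames = 5, sd = 0)
  rs <- rmsd_series(ens)
  expect_true(all(unlist(rs$per_replica) < 1e-9))
  expect_equal(rs$mean, 0, tolerance = 1e-10)

  # rotate each frame rigidly: superposition removes it all
  rot <- ens
  for (f in 2:nrow(rot$replicas[[1]])) {
    X <- matrix(rot$replicas[[1]][f, ], ncol = 3, byrow = TRUE)
    rot$replicas[[1]][f, ] <- as.vector(t(rigid(X, angle = 0.1 * f)))
  }
  expect_lt(rmsd_series(rot)$mean, 1e-9)
  expect_error(rmsd_series(ens, resno_range = c(900, 999)), "fewer than 3")
})

test_that("isotropic jitter matches the closed-form RMSD expectation", {
  ens <- make_jitter_ens(n_residues = 100, n_frames = 400, sd = 0.5)
  # deviation from the mean structure: sqrt(3) * sd; from a noisy first
  # frame both terms contribute: sqrt(6) * sd
  rs_mean <- rmsd_series(ens, ref = "mean")
  expect_equal(rs_mean$mean, sqrt(3) * 0.5, tolerance = 0.04)
  rs_first <- rmsd_series(ens, ref = "first")
  expect_equal(rs_first$mean, sqrt(6) * 0.5, tolerance = 0.04)
})

test_that("burn-in discards the leading equilibration stretch", {
  ens <- make_jitter_ens(n_residues = 20, n_frames = 50, sd = 0.2)
  rs0 <- rmsd_series(ens)                      # frame_spacing 0.1 ns
  rs1 <- rmsd_series(ens, burn_in_ns = 1)      # drops 10 frames
  expect_length(rs1$per_replica[[1]], 40L)
  expect_length(rs0$per_replica[[1]], 50L)
  expect_length(rmsf_profile(ens, burn_in_ns = 1)$values, 20L)
  expect_error(rmsd_series(ens, burn_in_ns = 5), "fewer than 2 frames")
})

test_that("pooled RMSD mean is the frame-weighted mean of replica means", {
  g <- gen_trajectory(trajectory_spec(n_residues = 30, n_replicas = 3,
                                      n_frames = 50, seed = 2))
  rs <- rmsd_series(g$ensemble)
  per_means <- vapply(rs$per_replica, mean, numeric(1))
  per_n <- vapply(rs$per_replica, length, integer(1))
  expect_equal(rs$mean, sum(per_means * per_n) / sum(per_n), tolerance = 1e-12)
})

test_that("domain overlays hide hinge motion that the full selection sees", {
  g <- gen_trajectory(trajectory_spec(n_residues = 80, n_replicas = 1,
                                      n_frames = 120, torsion_jitter_sd = 0,
                                      jitter_sd = 0.1, hinge_amplitude = 12,
                                      domain1 = domain_def("RRM1", 5, 35),
                                      domain2 = domain_def("RRM2", 45, 76),
                                      seed = 6))
  full <- rmsd_series(g$ensemble)
  d1 <- domain_overlay_rmsd(g$ensemble, domain_def("RRM1", 5, 35))
  d2 <- domain_overlay_rmsd(g$ensemble, domain_def("RRM2", 45, 76))
  expect_gt(full$mean, 3 * d1$mean)
  expect_gt(full$mean, 3 * d2$mean)
  # overlays stay at the jitter level
  expect_lt(d1$mean, 3 * sqrt(6) * 0.1)
  expect_error(domain_overlay_rmsd(g$ensemble, domain_def("none", 500, 600)),
               "fewer than 3")
})

test_that("RMSF matches closed form, averages replicas, is rigid-invariant", {
  ens <- make_jitter_ens(n_residues = 100, n_frames = 400, sd = 0.5)
  rp <- rmsf_profile(ens)
  expect_equal(mean(rp$values), sqrt(3) * 0.5, tolerance = 0.03)

  static <- make_jitter_ens(n_residues = 20, n_frames = 5, sd = 0)
  expect_true(all(rmsf_profile(static)$values < 1e-9))

  # two replicas with different jitter: averaged profile ~ mean of closed forms
  e1 <- make_jitter_ens(n_residues = 80, n_frames = 300, sd = 0.2, seed = 8)
  e2 <- make_jitter_ens(n_residues = 80, n_frames = 300, sd = 0.6, seed = 9)
  both <- trajectory_ensemble(c(e1$replicas, e2$replicas), e1$topology)
  rp2 <- rmsf_profile(both)
  expect_equal(mean(rp2$values), sqrt(3) * (0.2 + 0.6) / 2, tolerance = 0.05)

  # global rigid transform of every frame leaves RMSF unchanged
  rot <- ens
  X <- rot$replicas[[1]]
  for (f in seq_len(nrow(X)))
    X[f, ] <- as.vector(t(rigid(matrix(X[f, ], ncol = 3, byrow = TRUE))))
  rot$replicas[[1]] <- X
  expect_equal(unname(rmsf_profile(rot)$values), unname(rp$values),
               tolerance = 1e-6)
})

test_that("per-replica RMSF equals the covariance-trace oracle", {
  ens <- make_jitter_ens(n_residues = 12, n_frames = 80, sd = 0.3, seed = 12)
  rp <- rmsf_profile(ens)
  # oracle: over the same CA selection, after superposing onto the mean
  # structure, RMSF_i is the root trace of atom i's positional covariance
  # (mle, i.e. /n)
  ca <- which(ens$topology$elety == "CA")
  cols <- rrmtether:::xyz_cols(ca)
  frames <- ens$replicas[[1]][, cols]
  ref <- matrix(frames[1, ], ncol = 3, byrow = TRUE)
  fit_all <- function(mat, ref) t(apply(mat, 1, function(fr) {
    X <- matrix(fr, ncol = 3, byrow = TRUE)
    s <- kabsch_superpose(ref, X)
    as.vector(t(sweep(sweep(X, 2, colMeans(X)) %*% s$rotation, 2,
                      colMeans(ref), `+`)))
  }))
  fitted <- fit_all(frames, ref)
  m1 <- matrix(colMeans(fitted), ncol = 3, byrow = TRUE)
  fitted2 <- fit_all(frames, m1)
  n <- nrow(fitted2)
  oracle <- vapply(seq_along(ca), function(i) {
    Xi <- fitted2[, (3 * i - 2):(3 * i)]
    sqrt(sum(diag(stats::cov(Xi))) * (n - 1) / n)
  }, numeric(1))
  expect_equal(unname(rp$values), oracle, tolerance = 1e-6)
})

test_that("delta-RMSF applies the mean + sd rule per domain and reports linker", {
  d1 <- domain_def("RRM1", 1, 20); d2 <- domain_def("RRM2", 31, 50)
  mk <- function(resno, values) {
    structure(list(values = stats::setNames(values, resno),
                   per_replica = matrix(values), resno = resno),
              class = "rmsf_profile")
  }
  teth <- mk(1:50, rep(1.5, 50))
  iso1 <- mk(1:20, rep(0.5, 20))
  iso2 <- mk(31:50, rep(0.5, 20))

  same <- delta_rmsf(mk(1:50, rep(0.5, 50)), iso1, iso2, d1, d2)
  expect_true(all(same$delta == 0))
  expect_length(same$selected, 0L)
  expect_equal(same$excluded, 21:30)

  vals <- rep(1.5, 50); vals[10] <- 3.5  # +3.0 above isolated at residue 10
  spiked <- delta_rmsf(mk(1:50, vals), iso1, iso2, d1, d2)
  expect_equal(spiked$selected, 10L)
  expect_equal(spiked$threshold, spiked$mean + spiked$sd)

  expect_error(delta_rmsf(teth, mk(2:20, rep(0.5, 19)), iso2, d1, d2),
               "cover")
})
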