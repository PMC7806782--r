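test_that("the CSD index weights nitrogen by half inside the square", {
  a <- list(residue = 1L, w_H = 8.0, w_N = 115.0)
  shift <- function(dh, dn) list(residue = 1L, w_H = 8.0 + dh, w_N = 115.0 + dn)
  expect_equal(compute_csd(a, shift(0, 0)), 0)
  expect_equal(compute_csd(a, shift(0, 0.4)), 0.2)
  expect_equal(compute_csd(a, shift(0.1, 0.2)), sqrt(0.02))
  expect_error(compute_csd(a, list(residue = 2L, w_H = 8, w_N = 115)),
               "different residues")
})

test_that("csd_profile measures displacement norms and flags disappearance", {
  tt <- noiseless_series(n_residues = 8, kd = 5)
  prof <- csd_profile(tt$series, 20)
  pred <- csd_model_by_row(tt$truth, 0.05, 20)
  expect_equal(unname(prof$values), pred, tolerance = 1e-10)

  prof0 <- csd_profile(tt$series, 0)
  expect_true(all(prof0$values == 0))
  expect_error(csd_profile(tt$series, 3.14), "not a concentration")

  # disappearance: drop a residue from the last list
  tt2 <- tt$series
  keep <- tt2$peaklists[[13]]$residue != tt2$peaklists[[13]]$residue[2]
  gone <- tt2$peaklists[[13]]$residue[2]
  tt2$peaklists[[13]] <- peak_list(as.data.frame(tt2$peaklists[[13]])[keep, ],
                                   validate = FALSE)
  p2 <- csd_profile(tt2, 20)
  expect_true(gone %in% p2$disappeared)
  expect_false(as.character(gone) %in% names(p2$values))
})

test_that("significance rule is mean + one sample sd with strict selection", {
  v <- c(a = 0.1, b = 0.1, c = 0.1, d = 0.5)
  names(v) <- c(11, 12, 13, 14)
  s <- select_significant(v)
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, sqrt(0.12 / 3))
  expect_equal(s$threshold, s$mean + s$sd)
  expect_equal(s$selected, 14L)

  flat <- stats::setNames(rep(0.2, 5), 1:5)
  expect_length(select_significant(flat)$selected, 0L)

  outlier <- stats::setNames(c(rep(0, 50), 1), 1:51)
  expect_equal(select_significant(outlier)$selected, 51L)

  # invariant under residue reordering
  perm <- sample(length(outlier))
  expect_equal(sort(select_significant(outlier[perm])$selected),
               sort(select_significant(outlier)$selected))
  expect_error(select_significant(v[1]), "at least 2")
})

test_that("the depletion isotherm has the right limits and monotonicity", {
  expect_equal(csd_model(5, 0.6, 0.05, 0), 0)
  expect_equal(csd_model(5, 0.6, 0.05, 1e7), 0.6, tolerance = 1e-4)
  expect_equal(csd_model(16.7, 1, 0.05, 10), 0.3740934, tolerance = 1e-6)

  L <- seq(0, 40, by = 0.5)
  expect_true(all(diff(csd_model(3, 0.5, 0.05, L)) > 0))
  kds <- c(1, 2, 5, 10, 20)
  at10 <- vapply(kds, function(k) csd_model(k, 0.5, 0.05, 10), numeric(1))
  expect_true(all(diff(at10) < 0))
  expect_error(csd_model(5, 0.5, 0, 1), "positive")
})

test_that("csd_model collapses to the hyperbolic isotherm when depletion is weak", {
  set.seed(42)
  kd <- runif(200, 0.5, 30)
  P <- kd / runif(200, 100, 1e4)
  L <- runif(200, 0.1, 40)
  cmax <- runif(200, 0.1, 2)
  full <- mapply(function(k, c, p, l) csd_model(k, c, p, l), kd, cmax, P, L)
  hyper <- cmax * L / (L + kd)
  # deviation on the saturation scale; analytic bound P / (4 Kd)
  expect_true(all(abs(full - hyper) / cmax < 0.005))
  expect_true(all(abs(full - hyper) / cmax < P / (4 * kd) + 1e-12))
})

test_that("noiseless traces are recovered to high relative accuracy", {
  concs <- c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20)
  tr <- data.frame(ligand_conc = concs, csd = csd_model(5, 0.6, 0.05, concs))
  f <- fit_kd_residue(tr, 0.05)
  expect_true(f$converged)
  expect_lt(abs(coef(f)["kd"] - 5) / 5, 1e-4)
  expect_lt(abs(coef(f)["csd_max"] - 0.6) / 0.6, 1e-4)

  # scale consistency: scaling CSDs scales CSDmax, leaves Kd put
  f2 <- fit_kd_residue(transform(tr, csd = 3 * csd), 0.05)
  expect_equal(unname(coef(f2)["kd"]), unname(coef(f)["kd"]), tolerance = 1e-6)
  expect_equal(unname(coef(f2)["csd_max"]), 3 * unname(coef(f)["csd_max"]),
               tolerance = 1e-6)
})

test_that("degenerate traces are flagged, never silently defaulted", {
  concs <- c(0.5, 1, 2, 4, 6, 8, 10, 12)
  flat <- data.frame(ligand_conc = concs, csd = rep(0, length(concs)))
  f <- fit_kd_residue(flat, 0.05)
  expect_false(f$converged)
  expect_match(f$reason, "flat")
  expect_error(fit_kd_residue(flat[1:3, ], 0.05), "at least 4")
  expect_error(fit_kd_residue(data.frame(ligand_conc = c(1, 1.5, 2, 3),
                                         csd = c(0.1, 0.12, 0.15, 0.2)), 0.05),
               "4-fold")
})

test_that("noisy Kd recovery stays within 10% for most seeded replicates", {
  concs <- c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20)
  truth <- csd_model(5, 0.6, 0.05, concs)
  hits <- 0L
  for (s in 1:60) {
    set.seed(s)
    tr <- data.frame(ligand_conc = concs,
                     csd = truth + rnorm(length(concs), 0, 0.005))
    f <- fit_kd_residue(tr, 0.05)
    if (f$converged && abs(coef(f)["kd"] - 5) / 5 < 0.10) hits <- hits + 1L
  }
  expect_gte(hits, 57L)  # ~ >= 95%
})

test_that("profile fitting aggregates per-residue and shared-Kd modes", {
  tt <- noiseless_series(n_residues = 10, kd = 7.7, seed = 21)
  res <- tt$truth$residue
  fit1 <- fit_kd_profile(tt$series, res, mode = "per_residue_mean")
  expect_equal(fit1$aggregate_kd, 7.7, tolerance = 1e-4)
  expect_lt(fit1$aggregate_kd_sd, 1e-3)
  fit2 <- fit_kd_profile(tt$series, res, mode = "global_shared_kd")
  expect_equal(fit2$aggregate_kd, 7.7, tolerance = 1e-4)

  # heterogeneous truth: mean and sample sd of {5, 15}
  t2 <- gen_titration(titration_spec(n_residues = 2, true_kd = c(5, 15),
                                     noise_sd = 0, seed = 3))
  fh <- fit_kd_profile(t2$series, t2$truth$residue)
  expect_equal(fh$aggregate_kd, 10, tolerance = 1e-3)
  expect_equal(fh$aggregate_kd_sd, sqrt(50), tolerance = 1e-3)

  # single residue: sd reported as 0 with a flag
  f1 <- fit_kd_profile(tt$series, res[1])
  expect_equal(f1$aggregate_kd_sd, 0)
  expect_true(f1$single_residue)

  expect_error(fit_kd_profile(tt$series, integer(0)), "empty")
  expect_error(fit_kd_profile(tt$series, 9999L), "not in the reference")
})
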