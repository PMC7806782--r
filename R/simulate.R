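# Synthetic-data generators. Each generator is a pure function of its spec
# (seed included): identical specs give byte-identical outputs, and the
# returned ground truth is sufficient to score the downstream estimator.

#' Specification for a synthetic HSQC titration
#'
#' Defaults reproduce the titration design used throughout: protein at
#' 0.05 mM (50 uM) and ligand at 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18 and
#' 20 mM on top of the 0 mM reference.
#'
#' @param n_residues Number of residues.
#' @param resno_start First residue number.
#' @param true_kd True dissociation constant(s), mM (scalar or per residue).
#' @param csd_max_range Interval from which per-residue saturating CSDs are
#'   drawn, ppm.
#' @param noise_sd Gaussian chemical-shift noise, ppm, isotropic in the
#'   (dH, dN/2) metric so that the induced CSD noise has a known scale.
#' @param disappear_prob Probability that a residue's peak disappears from a
#'   random titration point onward.
#' @param protein_conc Protein concentration, mM.
#' @param ligand_concs Ligand concentrations, mM, starting at 0.
#' @param seed Integer seed.
#' @return A `titration_spec` list.
#' @export
titration_spec <- function(n_residues = 40L, resno_start = 193L,
                           true_kd = 16.7, csd_max_range = c(0.1, 0.6),
                           noise_sd = 0.005, disappear_prob = 0,
                           protein_conc = 0.05,
                           ligand_concs = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12,
                                            14, 16, 18, 20),
                           seed = 1L) {
  if (disappear_prob < 0 || disappear_prob > 1)
    stop("disappear_prob must be in [0, 1]", call. = FALSE)
  if (ligand_concs[1] != 0 || any(diff(ligand_concs) <= 0))
    stop("ligand_concs must start at 0 and increase strictly", call. = FALSE)
  stop_if_not_scalar_pos(protein_conc, "protein_conc")
  structure(list(n_residues = as.integer(n_residues),
                 resno_start = as.integer(resno_start),
                 true_kd = true_kd, csd_max_range = csd_max_range,
                 noise_sd = noise_sd, disappear_prob = disappear_prob,
                 protein_conc = protein_conc, ligand_concs = ligand_concs,
                 seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate a synthetic titration series with known ground truth
#'
#' Peak positions move from seeded random reference positions along a
#' per-residue unit direction in (dH, dN/2) space by the CSD predicted by
#' [csd_model()] at each ligand concentration, plus Gaussian noise. With
#' `disappear_prob > 0` a residue may vanish from a random titration point
#' onward (exchange broadening).
#'
#' @param spec A `titration_spec`.
#' @return List with `series` (a `titration_series`) and `truth` (data frame
#'   `residue`, `kd`, `csd_max`, `dir_h`, `dir_n2`, `disappear_from` -- the
#'   ligand concentration from which the peak is absent, `NA` if never).
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    resno <- spec$resno_start + seq_len(n) - 1L
    kd <- rep_len(spec$true_kd, n)
    cmax <- stats::runif(n, spec$csd_max_range[1], spec$csd_max_range[2])
    theta <- stats::runif(n, 0, 2 * pi)
    dir_h <- cos(theta); dir_n2 <- sin(theta)
    ref_h <- stats::runif(n, 7.0, 9.5)
    ref_n <- stats::runif(n, 108, 130)
    K <- length(spec$ligand_concs)
    gone <- stats::runif(n) < spec$disappear_prob
    from_idx <- ifelse(gone, sample(2:K, n, replace = TRUE), NA_integer_)
    resname <- sample(c("A", "G", "L", "V", "S", "T", "D", "E", "K", "R",
                        "N", "Q", "F", "Y", "I", "M"), n, replace = TRUE)
    peaklists <- lapply(seq_len(K), function(k) {
      L <- spec$ligand_concs[k]
      csd <- csd_model_v(kd, cmax, spec$protein_conc, L)
      w_h <- ref_h + csd * dir_h + stats::rnorm(n, 0, spec$noise_sd)
      w_n <- ref_n + 2 * (csd * dir_n2 + stats::rnorm(n, 0, spec$noise_sd))
      present <- is.na(from_idx) | k < from_idx
      peak_list(data.frame(residue = resno, resname = resname,
                           w_H = w_h, w_N = w_n)[present, , drop = FALSE],
                label = sprintf("L=%gmM", L), validate = FALSE)
    })
    truth <- data.frame(residue = resno, kd = kd, csd_max = cmax,
                        dir_h = dir_h, dir_n2 = dir_n2,
                        disappear_from = spec$ligand_concs[from_idx])
    list(series = assemble_titration(peaklists, spec$ligand_concs,
                                     spec$protein_conc),
         truth = truth)
  })
}

# csd_model with per-residue kd/cmax vectors at a single ligand conc
csd_model_v <- function(kd, csd_max, P, L) {
  s <- P + L + kd
  csd_max * (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
}

#' Specification for a synthetic replica trajectory ensemble
#'
#' The generator emulates, at desk scale, a replicated MD ensemble of a
#' two-domain protein: a backbone (N, CA, C per residue) rebuilt every frame
#' from base phi/psi torsions plus Gaussian torsion fluctuations, an optional
#' rigid-body hinge rotation of the second domain about a linker axis driven
#' by an autocorrelated angle series, optional Gaussian-copula coupling
#' between the torsions of chosen residue pairs, and optional Cartesian
#' jitter.
#'
#' @param n_residues Number of residues.
#' @param resno_start First residue number.
#' @param domain1,domain2 `domain_def` ranges for the two structured domains.
#' @param n_replicas,n_frames Ensemble dimensions.
#' @param jitter_sd Cartesian per-coordinate jitter sd, Angstrom; scalar or a
#'   per-residue profile.
#' @param torsion_jitter_sd Sd of the per-frame torsion fluctuations,
#'   degrees.
#' @param hinge_amplitude Sd of the hinge angle series, degrees (0 disables
#'   the hinge).
#' @param hinge_correlation_time AR(1) correlation time of the hinge angle,
#'   frames.
#' @param coupled_pairs Two-column matrix/data frame of residue-number pairs
#'   whose phi and psi fluctuations are drawn from a Gaussian copula with
#'   correlation `copula_rho`.
#' @param copula_rho Copula correlation in [0, 1).
#' @param frame_spacing ns between frames.
#' @param seed Integer seed.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(n_residues = 100L, resno_start = 1L,
                            domain1 = domain_def("RRM1", 6L, 45L),
                            domain2 = domain_def("RRM2", 56L, 95L),
                            n_replicas = 3L, n_frames = 500L,
                            jitter_sd = 0, torsion_jitter_sd = 20,
                            hinge_amplitude = 0,
                            hinge_correlation_time = 50L,
                            coupled_pairs = NULL, copula_rho = 0,
                            frame_spacing = 0.1, seed = 1L) {
  if (copula_rho < 0 || copula_rho >= 1)
    stop("copula_rho must be in [0, 1)", call. = FALSE)
  if (hinge_amplitude < 0) stop("hinge_amplitude must be >= 0", call. = FALSE)
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- as.matrix(coupled_pairs)
    if (ncol(coupled_pairs) != 2L)
      stop("coupled_pairs must have two columns", call. = FALSE)
  }
  structure(list(n_residues = as.integer(n_residues),
                 resno_start = as.integer(resno_start),
                 domain1 = domain1, domain2 = domain2,
                 n_replicas = as.integer(n_replicas),
                 n_frames = as.integer(n_frames),
                 jitter_sd = jitter_sd,
                 torsion_jitter_sd = torsion_jitter_sd,
                 hinge_amplitude = hinge_amplitude,
                 hinge_correlation_time = as.integer(hinge_correlation_time),
                 coupled_pairs = coupled_pairs, copula_rho = copula_rho,
                 frame_spacing = frame_spacing, seed = as.integer(seed)),
            class = "trajectory_spec")
}

# ideal backbone geometry (Angstrom / degrees)
.bb <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
            a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

# place atom D from A, B, C with bond length r, bond angle theta (at C) and
# torsion tau (A-B-C-D); A, B, C are n x 3 matrices, angles in degrees
nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- C - B
  bc <- bc / rownorm(bc)
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / rownorm(n)
  m <- cross3(n, bc)
  d2 <- cbind(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  C + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * n
}

# backbone coordinates from torsion matrices (frames x n_res), columns i of
# phi/psi give the torsions of residue i (phi[ ,1] and psi[, n] unused)
build_backbone <- function(phi, psi, omega = 180) {
  n_fr <- nrow(phi); n_res <- ncol(phi)
  g <- .bb
  N <- CA <- C <- vector("list", n_res)
  one <- function(v) matrix(v, n_fr, 3, byrow = TRUE)
  N[[1]] <- one(c(0, 0, 0))
  CA[[1]] <- one(c(g$b_n_ca, 0, 0))
  a <- g$a_n_ca_c * pi / 180
  C[[1]] <- one(c(g$b_n_ca - g$b_ca_c * cos(a), g$b_ca_c * sin(a), 0))
  for (i in 2:n_res) {
    N[[i]] <- nerf_place(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$b_c_n, g$a_ca_c_n, psi[, i - 1])
    CA[[i]] <- nerf_place(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$b_n_ca, g$a_c_n_ca, omega)
    C[[i]] <- nerf_place(C[[i - 1]], N[[i]], CA[[i]],
                         g$b_ca_c, g$a_n_ca_c, phi[, i])
  }
  # interleave per residue: N, CA, C -> frames x (3 * 3 * n_res)
  out <- matrix(NA_real_, n_fr, 9L * n_res)
  for (i in seq_len(n_res)) {
    out[, (9L * i - 8L):(9L * i - 6L)] <- N[[i]]
    out[, (9L * i - 5L):(9L * i - 3L)] <- CA[[i]]
    out[, (9L * i - 2L):(9L * i)] <- C[[i]]
  }
  out
}

# Rodrigues rotation of points (n x 3) about unit axis u through the origin
rotate_about <- function(X, u, angle_deg) {
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  X %*% R
}

#' Generate a synthetic replica trajectory ensemble with known ground truth
#'
#' See [trajectory_spec()] for the construction. Base torsions are
#' beta-strand-like inside the domains and polyproline-II-like elsewhere,
#' giving a compact folded reference; the hinge axis passes through the
#' linker-midpoint C-alpha of the static reference, direction fixed
#' perpendicular to the local chain axis (deterministic and
#' seed-independent).
#'
#' @param spec A `trajectory_spec`.
#' @return List with `ensemble` (a `traj_ensemble`), and `truth`: base
#'   torsions, coupled pairs, per-replica hinge angle series, and the static
#'   reference coordinates.
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_res <- spec$n_residues
  resno <- spec$resno_start + seq_len(n_res) - 1L
  in1 <- in_domain(resno, spec$domain1)
  in2 <- in_domain(resno, spec$domain2)
  phi0 <- ifelse(in1 | in2, -120, -75)
  psi0 <- ifelse(in1 | in2, 130, 145)

  topo <- data.frame(resno = rep(resno, each = 3L),
                     elety = rep(c("N", "CA", "C"), n_res))
  static <- build_backbone(matrix(phi0, 1), matrix(psi0, 1))
  # hinge geometry from the static reference (seed-independent)
  mid <- which.min(abs(resno - floor((spec$domain1$end + spec$domain2$start) / 2)))
  ca_of <- function(xyzrow, i) xyzrow[(9L * i - 5L):(9L * i - 3L)]
  anchor <- ca_of(static[1, ], mid)
  v <- ca_of(static[1, ], min(mid + 1L, n_res)) - ca_of(static[1, ], max(mid - 1L, 1L))
  axis <- c(v[2], -v[1], 0)             # perpendicular to the chain axis
  if (sqrt(sum(axis^2)) < 1e-8) axis <- c(1, 0, 0)
  axis <- axis / sqrt(sum(axis^2))
  moving <- which(topo$resno > resno[mid])          # second-domain side
  mov_cols <- xyz_cols(moving)

  cp <- spec$coupled_pairs
  rho <- spec$copula_rho
  jit <- rep_len(spec$jitter_sd, n_res)

  out <- with_seed(spec$seed, {
    theta_list <- vector("list", spec$n_replicas)
    reps <- vector("list", spec$n_replicas)
    for (r in seq_len(spec$n_replicas)) {
      nf <- spec$n_frames
      dphi <- matrix(stats::rnorm(nf * n_res, 0, spec$torsion_jitter_sd), nf)
      dpsi <- matrix(stats::rnorm(nf * n_res, 0, spec$torsion_jitter_sd), nf)
      if (!is.null(cp) && rho > 0) {
        for (p in seq_len(nrow(cp))) {
          i <- match(cp[p, 1], resno); j <- match(cp[p, 2], resno)
          for (mat in c("dphi", "dpsi")) {
            m <- get(mat)
            z1 <- stats::rnorm(nf); z2 <- stats::rnorm(nf)
            m[, i] <- spec$torsion_jitter_sd * z1
            m[, j] <- spec$torsion_jitter_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
            assign(mat, m)
          }
        }
      }
      phi <- wrap180(sweep(dphi, 2, phi0, `+`))
      psi <- wrap180(sweep(dpsi, 2, psi0, `+`))
      xyz <- build_backbone(phi, psi)
      theta <- numeric(nf)
      if (spec$hinge_amplitude > 0) {
        a_ar <- exp(-1 / spec$hinge_correlation_time)
        theta[1] <- stats::rnorm(1, 0, spec$hinge_amplitude)
        for (f in 2:nf)
          theta[f] <- a_ar * theta[f - 1] +
            sqrt(1 - a_ar^2) * stats::rnorm(1, 0, spec$hinge_amplitude)
        for (f in seq_len(nf)) {
          X <- as_coords(xyz[f, ], mov_cols)
          X <- rotate_about(sweep(X, 2, anchor), axis, theta[f])
          xyz[f, mov_cols] <- as.vector(t(sweep(X, 2, anchor, `+`)))
        }
      }
      if (any(jit > 0)) {
        sd_xyz <- rep(rep(jit, each = 3L), each = 3L)  # residue -> atom -> x/y/z
        noise <- matrix(stats::rnorm(length(xyz), 0, rep(sd_xyz, each = nf)),
                        nrow = nf)
        xyz <- xyz + noise
      }
      theta_list[[r]] <- theta
      reps[[r]] <- xyz
    }
    list(reps = reps, theta = theta_list)
  })
  list(ensemble = trajectory_ensemble(out$reps, topo,
                                      frame_spacing = spec$frame_spacing),
       truth = list(spec = spec, base_phi = phi0, base_psi = psi0,
                    coupled_pairs = cp, copula_rho = rho,
                    hinge_theta = out$theta, static = static[1, ],
                    hinge_axis = axis, hinge_anchor = anchor,
                    resno = resno))
}

#' Correlated circular variables with analytically known mutual information
#'
#' Draws a bivariate normal pair with correlation `rho` and maps each margin
#' through the normal CDF onto uniform angles over (-180, 180]. Mutual
#' information is invariant under the monotone map, so the pair has
#' MI = -0.5 * log(1 - rho^2) nats exactly.
#'
#' @param n Number of samples.
#' @param rho Correlation in [0, 1).
#' @param seed Integer seed.
#' @return List with angle vectors `x` and `y` (degrees) and `mi_true`
#'   (nats).
#' @export
gen_correlated_angles <- function(n, rho, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    list(x = stats::pnorm(z1) * 360 - 180,
         y = stats::pnorm(z2) * 360 - 180,
         mi_true = -0.5 * log(1 - rho^2))
  })
}

#' Specification for a synthetic thermal denaturation curve
#'
#' Two-state model per transition: unfolded fraction
#' f(T) = 1 / (1 + exp((dH / R) (1/T - 1/Tm))) (temperatures in Kelvin),
#' summed over transitions with individual amplitudes, on a linear baseline,
#' with optional high-temperature exponential signal decay mimicking dye
#' dissociation.
#'
#' @param tm_values Transition midpoints, degrees C.
#' @param van_t_hoff_dh Apparent van 't Hoff enthalpy per transition, kJ/mol
#'   (recycled).
#' @param amplitudes Signal amplitude per transition (recycled).
#' @param baseline Intercept and slope of the linear baseline.
#' @param decay Exponential decay rate (per degree C) applied beyond
#'   `decay_onset`; 0 disables.
#' @param decay_onset Temperature at which decay starts, degrees C.
#' @param temp_range Scan range, degrees C.
#' @param sampling_interval Scan step, degrees C.
#' @param noise_sd Gaussian signal noise sd.
#' @param seed Integer seed.
#' @return A `melt_spec` list.
#' @export
melt_spec <- function(tm_values = 59, van_t_hoff_dh = 700, amplitudes = 1,
                      baseline = c(0.05, 0), decay = 0, decay_onset = 85,
                      temp_range = c(30, 90), sampling_interval = 1,
                      noise_sd = 0, seed = 1L) {
  if (any(tm_values < temp_range[1] | tm_values > temp_range[2]))
    stop("every Tm must lie inside the scanned temperature range",
         call. = FALSE)
  structure(list(tm_values = tm_values, van_t_hoff_dh = van_t_hoff_dh,
                 amplitudes = amplitudes, baseline = baseline, decay = decay,
                 decay_onset = decay_onset, temp_range = temp_range,
                 sampling_interval = sampling_interval, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "melt_spec")
}

#' Generate a synthetic melt curve with known ground truth
#'
#' @param spec A `melt_spec`.
#' @return List with `curve` (a `melt_curve`) and `truth` (the spec).
#' @export
gen_meltcurve <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  R_kj <- 8.31446e-3                     # kJ / (mol K)
  temp <- seq(spec$temp_range[1], spec$temp_range[2],
              by = spec$sampling_interval)
  k <- length(spec$tm_values)
  dh <- rep_len(spec$van_t_hoff_dh, k)
  amp <- rep_len(spec$amplitudes, k)
  tk <- temp + 273.15
  sig <- spec$baseline[1] + spec$baseline[2] * temp
  for (i in seq_len(k)) {
    tm_k <- spec$tm_values[i] + 273.15
    f <- 1 / (1 + exp((dh[i] / R_kj) * (1 / tk - 1 / tm_k)))
    sig <- sig + amp[i] * f
  }
  if (spec$decay > 0)
    sig <- sig * exp(-spec$decay * pmax(0, temp - spec$decay_onset))
  sig <- with_seed(spec$seed, sig + stats::rnorm(length(sig), 0, spec$noise_sd))
  list(curve = melt_curve(temp, sig, label = "synthetic"), truth = spec)
}
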