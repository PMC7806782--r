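# Small fixtures built in code at test time.

# write a Sparky-style peak list file and return its path
write_sparky <- function(residues, w_n, w_h, resname = "G",
                         header = TRUE, path = tempfile(fileext = ".list")) {
  lines <- sprintf("%s%dN-H %9.3f %8.3f", rep_len(resname, length(residues)),
                   residues, w_n, w_h)
  if (header) lines <- c("Assignment w1 w2", lines)
  writeLines(lines, path)
  path
}

# peak_list straight from vectors
pl <- function(residues, w_h, w_n, label = "", resname = "G") {
  peak_list(data.frame(residue = residues,
                       resname = rep_len(resname, length(residues)),
                       w_H = w_h, w_N = w_n),
            label = label, validate = FALSE)
}

# noiseless titration series with a shared Kd over the standard design
noiseless_series <- function(n_residues = 6, kd = 5, seed = 11) {
  gen_titration(titration_spec(n_residues = n_residues, true_kd = kd,
                               noise_sd = 0, seed = seed))
}

# model-predicted CSD per ground-truth row at one ligand concentration
csd_model_by_row <- function(truth, protein_conc, L) {
  vapply(seq_len(nrow(truth)), function(i)
    csd_model(truth$kd[i], truth$csd_max[i], protein_conc, L), numeric(1))
}

# helix-like C-alpha trace with stable curvature (non-collinear)
ca_trace <- function(resno, rise = 1.5, radius = 2.3, turn = 100) {
  t <- seq_along(resno) * turn * pi / 180
  df <- data.frame(resno = resno, resid = "ALA",
                   x = radius * cos(t), y = radius * sin(t),
                   z = rise * seq_along(resno))
  structure(df, model_index = 1L, chain_id = "A",
            class = c("structure_model", "data.frame"))
}

# apply a rigid transform to a structure_model or n x 3 matrix
rigid <- function(x, axis = c(0, 0, 1), angle = 0.8, shift = c(3, -2, 5)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  if (is.matrix(x)) return(sweep(x %*% R, 2, shift, `+`))
  xyz <- as.matrix(x[, c("x", "y", "z")]) %*% R
  x$x <- xyz[, 1] + shift[1]
  x$y <- xyz[, 2] + shift[2]
  x$z <- xyz[, 3] + shift[3]
  x
}
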