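# End-to-end pipelines chaining the analysis stages, with a config (R list
# or JSON file), CSV outputs and a run record. All randomness flows from the
# seeds recorded in the config, so a rerun under a fixed config reproduces
# byte-identical CSVs.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path",
                             call. = FALSE)
  config
}

run_stage <- function(record, name, expr) {
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  record$stages <- rbind(record$stages,
                         data.frame(stage = name, status = "ok"))
  list(record = record, value = res)
}

new_run_record <- function(config) {
  list(timestamp = format(Sys.time(), tz = "UTC"),
       config = config,
       package_version = as.character(utils::packageVersion("rrmtether")),
       stages = data.frame(stage = character(), status = character()),
       manifest = character())
}

emit <- function(record, df, path) {
  write_table(df, path)
  record$manifest <- c(record$manifest, path)
  record
}

write_manifest <- function(record, out_dir) {
  # deliberately excludes the timestamp and output location so that reruns
  # of one config are byte-identical wherever they land
  cfg <- record$config
  cfg$out_dir <- NULL
  jsonlite::write_json(list(config = cfg,
                            package_version = record$package_version,
                            files = basename(record$manifest)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  record
}

#' Run the titration analysis pipeline
#'
#' Chains CSD computation, mean-plus-sd significance selection and
#' residue-specific Kd fitting, writing `csd_table.csv`, `fit_table.csv`,
#' `summary.csv` and `manifest.json` into the output directory.
#'
#' Config fields: `out_dir`; either `synthetic` (fields of
#' [titration_spec()]) or `peaklist_paths` + `ligand_concs` +
#' `protein_conc`; optional `at_conc` (CSD/selection concentration, default
#' the highest), `mode` (see [fit_kd_profile()]), `residues` (override the
#' significance selection).
#'
#' @param config List or path to a JSON file.
#' @return A run record: timestamp, config, package version, per-stage
#'   status, output manifest, and the fitted objects.
#' @export
run_titration_pipeline <- function(config) {
  config <- read_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- new_run_record(config)

  st <- run_stage(record, "assemble", {
    if (!is.null(config$synthetic)) {
      spec <- do.call(titration_spec, config$synthetic)
      gen_titration(spec)$series
    } else {
      if (is.null(config$protein_conc))
        stop("config must give protein_conc (mM)")
      if (is.null(config$peaklist_paths) || is.null(config$ligand_concs))
        stop("config must give peaklist_paths and ligand_concs")
      pls <- lapply(config$peaklist_paths, read_peaklist)
      assemble_titration(pls, config$ligand_concs, config$protein_conc)
    }
  })
  record <- st$record; series <- st$value
  at_conc <- config$at_conc %||% max(series$ligand_concs)

  st <- run_stage(record, "csd", csd_profile(series, at_conc))
  record <- st$record; prof <- st$value

  st <- run_stage(record, "significance", select_significant(prof))
  record <- st$record; sig <- st$value

  residues <- config$residues %||% sig$selected
  st <- run_stage(record, "fit_kd", {
    if (length(residues) == 0L)
      stop("no residues selected for fitting")
    fit_kd_profile(series, residues, mode = config$mode %||% "per_residue_mean")
  })
  record <- st$record; fit <- st$value

  csd_tab <- data.frame(residue = as.integer(names(prof$values)),
                        csd = round(prof$values, 6),
                        significant = as.integer(names(prof$values)) %in%
                          sig$selected)
  if (length(prof$disappeared))
    csd_tab <- rbind(csd_tab, data.frame(residue = prof$disappeared,
                                         csd = NA_real_, significant = NA))
  record <- emit(record, csd_tab, file.path(config$out_dir, "csd_table.csv"))
  fit_tab <- fit$per_residue
  fit_tab[, sapply(fit_tab, is.numeric)] <-
    round(fit_tab[, sapply(fit_tab, is.numeric)], 6)
  record <- emit(record, fit_tab, file.path(config$out_dir, "fit_table.csv"))
  record <- emit(record,
                 data.frame(mode = fit$mode,
                            aggregate_kd = round(fit$aggregate_kd, 6),
                            aggregate_kd_sd = round(fit$aggregate_kd_sd, 6),
                            n_converged = fit$n_converged,
                            csd_threshold = round(sig$threshold, 6)),
                 file.path(config$out_dir, "summary.csv"))
  record <- write_manifest(record, config$out_dir)
  record$csd_profile <- prof
  record$significance <- sig
  record$fit <- fit
  invisible(record)
}

get_ensemble <- function(entry, what) {
  if (!is.null(entry$paths)) read_trajectory(unlist(entry$paths))
  else if (!is.null(entry$spec)) {
    sp <- entry$spec
    for (d in c("domain1", "domain2"))
      if (!is.null(sp[[d]]) && !inherits(sp[[d]], "domain_def"))
        sp[[d]] <- domain_def(sp[[d]]$name %||% d, sp[[d]]$start, sp[[d]]$end)
    gen_trajectory(do.call(trajectory_spec, sp))$ensemble
  } else stop(sprintf("'%s' must give trajectory paths or a synthetic spec",
                      what))
}

#' Run the conformational-dynamics comparison pipeline
#'
#' For tethered and isolated ensembles: full-selection and domain-overlay
#' RMSD series, replica-averaged RMSF, tethered-minus-isolated RMSF
#' significance, and the normalized dihedral mutual-information coupling
#' report for the tethered form. Writes `rmsd_summary.csv`, `rmsd_series.csv`,
#' `rmsf.csv`, `delta_rmsf.csv`, `mi_matrix.csv`, `coupling_pairs.csv` and
#' `manifest.json`.
#'
#' Config fields: `out_dir`; `tethered`, `isolated_rrm1`, `isolated_rrm2`
#' (each `paths` to multi-model PDB replicas or `spec` fields of
#' [trajectory_spec()]); `domain1`, `domain2` (`name`, `start`, `end`);
#' optional `mi_threshold` (0.3), `mi_bins` (24), `seed` (1).
#'
#' @param config List or path to a JSON file.
#' @return A run record (see [run_titration_pipeline()]) with the analysis
#'   objects attached.
#' @export
run_coupling_pipeline <- function(config) {
  config <- read_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- new_run_record(config)
  d1 <- if (inherits(config$domain1, "domain_def")) config$domain1 else
    domain_def(config$domain1$name %||% "RRM1", config$domain1$start,
               config$domain1$end)
  d2 <- if (inherits(config$domain2, "domain_def")) config$domain2 else
    domain_def(config$domain2$name %||% "RRM2", config$domain2$start,
               config$domain2$end)

  st <- run_stage(record, "load_tethered", get_ensemble(config$tethered,
                                                        "tethered"))
  record <- st$record; teth <- st$value
  st <- run_stage(record, "load_isolated_rrm1",
                  get_ensemble(config$isolated_rrm1, "isolated_rrm1"))
  record <- st$record; iso1 <- st$value
  st <- run_stage(record, "load_isolated_rrm2",
                  get_ensemble(config$isolated_rrm2, "isolated_rrm2"))
  record <- st$record; iso2 <- st$value

  st <- run_stage(record, "rmsd", {
    list(teth_full = rmsd_series(teth),
         teth_d1 = domain_overlay_rmsd(teth, d1),
         teth_d2 = domain_overlay_rmsd(teth, d2),
         iso1_full = rmsd_series(iso1),
         iso1_d = domain_overlay_rmsd(iso1, d1),
         iso2_full = rmsd_series(iso2),
         iso2_d = domain_overlay_rmsd(iso2, d2))
  })
  record <- st$record; rmsds <- st$value

  st <- run_stage(record, "rmsf", {
    list(teth = rmsf_profile(teth), iso1 = rmsf_profile(iso1),
         iso2 = rmsf_profile(iso2))
  })
  record <- st$record; rmsfs <- st$value

  st <- run_stage(record, "delta_rmsf",
                  delta_rmsf(rmsfs$teth, rmsfs$iso1, rmsfs$iso2, d1, d2))
  record <- st$record; drmsf <- st$value

  st <- run_stage(record, "mutual_information", {
    dih <- compute_dihedrals(teth)
    mi <- residue_mi_matrix(dih, bin_count = config$mi_bins %||% 24L,
                            seed = config$seed %||% 1L)
    list(mi = mi, report = coupling_report(mi, d1, d2,
                                           threshold = config$mi_threshold %||% 0.3))
  })
  record <- st$record; coup <- st$value

  constructs <- c("tethered", paste0("tethered_", d1$name),
                  paste0("tethered_", d2$name),
                  "isolated_RRM1", paste0("isolated_", d1$name),
                  "isolated_RRM2", paste0("isolated_", d2$name))
  record <- emit(record, data.frame(
    construct = constructs,
    selection = vapply(rmsds, function(x) x$selection, character(1)),
    mean_rmsd = round(vapply(rmsds, function(x) x$mean, numeric(1)), 6),
    sd_rmsd = round(vapply(rmsds, function(x) x$sd, numeric(1)), 6)),
    file.path(config$out_dir, "rmsd_summary.csv"))
  series_tab <- do.call(rbind, lapply(seq_along(rmsds), function(i) {
    per <- rmsds[[i]]$per_replica
    do.call(rbind, lapply(seq_along(per), function(r)
      data.frame(construct = constructs[i], replica = r,
                 frame = seq_along(per[[r]]), rmsd = round(per[[r]], 6))))
  }))
  record <- emit(record, series_tab,
                 file.path(config$out_dir, "rmsd_series.csv"))
  rmsf_tab <- do.call(rbind, lapply(names(rmsfs), function(nm)
    data.frame(construct = nm, residue = rmsfs[[nm]]$resno,
               rmsf = round(unname(rmsfs[[nm]]$values), 6))))
  record <- emit(record, rmsf_tab, file.path(config$out_dir, "rmsf.csv"))
  record <- emit(record, data.frame(
    residue = as.integer(names(drmsf$delta)),
    delta_rmsf = round(unname(drmsf$delta), 6),
    selected = as.integer(names(drmsf$delta)) %in% drmsf$selected),
    file.path(config$out_dir, "delta_rmsf.csv"))
  mi_tab <- as.data.frame(round(coup$mi$normalized, 6))
  mi_tab <- cbind(residue = rownames(coup$mi$normalized), mi_tab)
  record <- emit(record, mi_tab, file.path(config$out_dir, "mi_matrix.csv"))
  pair_tab <- coup$report$pairs
  if (nrow(pair_tab) == 0L)
    pair_tab <- data.frame(res_i = NA_integer_, res_j = NA_integer_,
                           mi = NA_real_, class = "none")
  pair_tab$mi <- round(pair_tab$mi, 6)
  record <- emit(record, pair_tab,
                 file.path(config$out_dir, "coupling_pairs.csv"))
  record <- write_manifest(record, config$out_dir)
  record$rmsd <- rmsds
  record$rmsf <- rmsfs
  record$delta_rmsf <- drmsf
  record$coupling <- coup$report
  record$mi <- coup$mi
  invisible(record)
}
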