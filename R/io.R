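# Readers/writers for the pipeline's plain-text formats, configuration,
# and the wild-type-vs-mutant comparison driver. Residue numbering is
# 1-based biological numbering carried verbatim; nothing is renumbered.

#' Read an intensity table into decay series and NOE pairs
#'
#' TSV with header `residue_number`, `residue_name`, `experiment`
#' (`R1`/`R2`/`NOE_sat`/`NOE_ref`), `delay_s` (empty for NOE rows),
#' `intensity`, `noise_rms`. Rows are grouped per residue per experiment;
#' malformed rows are reported with their line numbers; a residue with a
#' saturated but no reference NOE intensity (or vice versa) loses its NOE
#' with a warning, never silently.
#'
#' @param path TSV file path.
#' @return List with `decays` (list of [decay_series()]) and `noe` (list of
#'   [noe_pair()]).
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_number", "residue_name", "experiment", "delay_s",
            "intensity", "noise_rms")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("intensity table lacks columns: ", paste(miss, collapse = ", "))
  bad <- is.na(tab$residue_number) | is.na(tab$intensity) |
    !(tab$experiment %in% c("R1", "R2", "NOE_sat", "NOE_ref"))
  if (any(bad)) {
    warning("skipping malformed rows at lines: ",
            paste(which(bad) + 1, collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  decays <- list()
  is_decay <- tab$experiment %in% c("R1", "R2")
  if (any(is_decay)) {
    for (g in split(tab[is_decay, ],
                    interaction(tab$residue_number[is_decay],
                                tab$experiment[is_decay], drop = TRUE))) {
      if (any(diff(g$delay_s) <= 0))
        stop(sprintf("non-monotone delays for residue %d %s",
                     g$residue_number[1], g$experiment[1]))
      decays[[length(decays) + 1]] <-
        decay_series(g$residue_number[1], g$experiment[1], g$delay_s,
                     g$intensity, noise_rms = g$noise_rms[1])
    }
  }
  noes <- list()
  nt <- tab[!is_decay, , drop = FALSE]
  for (res in unique(nt$residue_number)) {
    sat <- nt$intensity[nt$residue_number == res & nt$experiment == "NOE_sat"]
    ref <- nt$intensity[nt$residue_number == res & nt$experiment == "NOE_ref"]
    if (length(sat) != 1 || length(ref) != 1) {
      warning(sprintf("residue %d: incomplete NOE pair; NOE absent", res))
      next
    }
    nr <- nt$noise_rms[nt$residue_number == res][1]
    noes[[length(noes) + 1]] <- noe_pair(res, sat, ref, noise_rms = nr)
  }
  list(decays = decays, noe = noes)
}

#' Write decay series and NOE pairs as an intensity table
#'
#' Inverse of [read_intensity_table()]; the written TSV is indistinguishable
#' from a real input file.
#'
#' @param sim List with `decays` and `noe` (as from [make_decay_series()]).
#' @param path Output TSV path.
#' @param residue_names Optional named map from residue number to
#'   one-letter code; defaults to `"X"`.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(sim, path, residue_names = NULL) {
  name_of <- function(res)
    if (is.null(residue_names)) "X"
  else as.character(residue_names[as.character(res)])
  rows <- list()
  for (d in sim$decays)
    rows[[length(rows) + 1]] <- data.frame(
      residue_number = d$residue, residue_name = name_of(d$residue),
      experiment = d$experiment, delay_s = d$delays,
      intensity = d$intensities, noise_rms = d$noise_rms)
  for (p in sim$noe)
    rows[[length(rows) + 1]] <- data.frame(
      residue_number = p$residue, residue_name = name_of(p$residue),
      experiment = c("NOE_sat", "NOE_ref"), delay_s = NA_real_,
      intensity = c(p$intensity_sat, p$intensity_ref),
      noise_rms = p$noise_rms)
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chemical-shift table
#'
#' TSV with columns `residue_number`, `residue_name`, `dHN_ppm`, `dN_ppm`,
#' `dCA_ppm` (empty cells become NA, i.e. unassigned).
#'
#' @param path TSV file path.
#' @return Shift table data frame.
#' @export
read_shift_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_shift_table(tab, path)
}

#' @rdname read_shift_table
#' @param tab Shift table data frame.
#' @export
write_shift_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read amide shifts from a Sparky-style peak list
#'
#' Lines of the form `F451N-H 118.23 8.56` (assignment label, 15N ppm,
#' 1H ppm). Only amide pairs are recovered; Calpha columns are NA.
#'
#' @param path .list file path.
#' @return Shift table data frame (`dCA_ppm` all NA).
#' @export
read_sparky_list <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !grepl("^Assignment", ln)]
  m <- regmatches(ln, regexec(
    "^([A-Za-z]?)(\\d+)N-H?N?\\s+([-0-9.]+)\\s+([-0-9.]+)", ln))
  ok <- lengths(m) == 5
  if (!any(ok)) stop("no parseable amide assignments in ", path)
  if (any(!ok))
    warning("unparseable lines skipped: ", paste(which(!ok), collapse = ", "))
  m <- m[ok]
  tab <- data.frame(
    residue_number = as.integer(vapply(m, `[`, "", 3)),
    residue_name = toupper(vapply(m, `[`, "", 2)),
    dN_ppm = as.numeric(vapply(m, `[`, "", 4)),
    dHN_ppm = as.numeric(vapply(m, `[`, "", 5)),
    dCA_ppm = NA_real_)
  tab$residue_name[tab$residue_name == ""] <- "X"
  tab[order(tab$residue_number), c("residue_number", "residue_name",
                                   "dHN_ppm", "dN_ppm", "dCA_ppm")]
}

#' Read a structure or multi-model ensemble from PDB
#'
#' Angstrom coordinates are converted to nm; residue numbers are preserved;
#' alternate locations other than blank or 'A' are dropped with a warning.
#' Multi-model files become multi-frame ensembles.
#'
#' @param path PDB file path.
#' @return A [coord_ensemble()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  if (!any(keep)) stop("no ATOM records in ", path)
  alt_ok <- is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A")
  if (any(keep & !alt_ok))
    warning("dropping alternate locations other than 'A'")
  keep <- keep & alt_ok
  xyz_idx <- bio3d::atom2xyz(which(keep))
  xyz <- pdb$xyz[, xyz_idx, drop = FALSE] / 10
  nf <- nrow(xyz); na <- sum(keep)
  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  coord_ensemble(coords, atoms = data.frame(
    resno = pdb$atom$resno[keep], elety = pdb$atom$elety[keep],
    resid = pdb$atom$resid[keep]))
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' @param ensemble A [coord_ensemble()] (nm; written in Angstrom).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  xyz <- t(vapply(seq_len(n_frames(ensemble)),
                  function(f) as.numeric(t(.frame(ensemble, f))) * 10,
                  numeric(3 * n_atoms(ensemble))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resid,
                   elety = ensemble$atoms$elety)
  invisible(path)
}

#' Read / write a DSC thermogram
#'
#' TSV with columns `temperature_C`, `cp_kcal_per_mol_K`.
#'
#' @param path TSV file path.
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("temperature_C", "cp_kcal_per_mol_K") %in% names(tab)))
  thermogram(tab$temperature_C, tab$cp_kcal_per_mol_K)
}

#' @rdname read_thermogram
#' @param tg A [thermogram()].
#' @export
write_thermogram <- function(tg, path) {
  utils::write.table(
    data.frame(temperature_C = tg$temperature_c, cp_kcal_per_mol_K = tg$cp),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_defaults <- function() list(
  field_mhz = 600.13, r_nh_angstrom = 1.02, csa_ppm = -160,
  csp_threshold = 0.15, exclusion_sd_multiplier = 1, mc_draws = 500,
  seed = 1, tauc_bracket_ns = c(0.1, 100), dsc_baseline_fraction = 0.15,
  pca_selection = "calpha", output_dir = ".")

#' Run configuration for the comparison workflow
#'
#' Defaults cover every stage; unknown keys are rejected (they are almost
#' always typos) and numeric fields are validated.
#'
#' @param x Named list of overrides, or path to a YAML file of them.
#' @return Object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- .config_defaults()
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(x)] <- x
  stopifnot(cfg$field_mhz > 0, cfg$csp_threshold > 0,
            cfg$exclusion_sd_multiplier > 0, cfg$mc_draws >= 0,
            cfg$dsc_baseline_fraction > 0, cfg$dsc_baseline_fraction < 0.5)
  structure(cfg, class = "run_config")
}

.fmt <- function(x, digits = 4, signif_mode = TRUE) {
  if (is.na(x)) return("")
  if (signif_mode) as.character(signif(x, digits)) else
    formatC(x, digits = digits, format = "f")
}

# one arm (wild type or mutant) of the comparison; returns the per-arm
# summary quantities and writes per-stage CSVs
.run_arm <- function(label, inputs, cfg, outdir) {
  out <- list()
  sp <- spin_params(cfg$field_mhz, cfg$r_nh_angstrom, cfg$csa_ppm)
  if (!is.null(inputs$relaxation)) {
    rel <- if (is.character(inputs$relaxation))
      read_intensity_table(inputs$relaxation) else inputs$relaxation
    rec <- fit_relaxation(rel$decays, rel$noe, mc_draws = cfg$mc_draws,
                          seed = cfg$seed)
    utils::write.csv(rec, file.path(outdir, paste0(label, "_relaxation.csv")),
                     row.names = FALSE)
    out$records <- rec
    out$summary <- summarize_records(rec)
    dif <- tauc_from_records(rec, params = sp,
                             sd_mult = cfg$exclusion_sd_multiplier,
                             bracket_ns = cfg$tauc_bracket_ns)
    flags <- data.frame(residue = dif$used$residue, ratio = dif$used$ratio,
                        used = TRUE, reason = "")
    if (nrow(dif$excluded) > 0)
      flags <- rbind(flags, data.frame(residue = dif$excluded$residue,
                                       ratio = NA_real_, used = FALSE,
                                       reason = dif$excluded$reason))
    utils::write.csv(flags[order(flags$residue), ],
                     file.path(outdir, paste0(label, "_diffusion.csv")),
                     row.names = FALSE)
    out$tauc_ns <- dif$tauc_ns
  }
  if (!is.null(inputs$dsc)) {
    tg <- if (is.character(inputs$dsc)) read_thermogram(inputs$dsc)
    else inputs$dsc
    fit <- fit_twostate(tg)
    utils::write.csv(data.frame(
      Tm_C = fit$model$tm_k - 273.15, dHcal_kcal_mol = fit$model$dh_cal,
      dHvH_kcal_mol = fit$model$dh_vh,
      baseline_intercept = fit$model$baseline[1],
      baseline_slope = fit$model$baseline[2],
      rms_residual = fit$rms_residual, converged = fit$converged),
      file.path(outdir, paste0(label, "_dsc.csv")), row.names = FALSE)
    out$dsc <- fit
  }
  if (!is.null(inputs$ensemble)) {
    ens <- if (is.character(inputs$ensemble)) read_structure(inputs$ensemble)
    else inputs$ensemble
    rg <- radius_of_gyration(ens)
    pc <- pca_ensemble(ens, selection = cfg$pca_selection)
    flu <- rmsf(ens)
    utils::write.csv(data.frame(atom = seq_along(flu),
                                resno = ens$atoms$resno, rmsf_nm = flu),
                     file.path(outdir, paste0(label, "_rmsf.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(pc$fractions),
                                eigenvalue_nm2 = pc$values,
                                fraction = pc$fractions),
                     file.path(outdir, paste0(label, "_pca.csv")),
                     row.names = FALSE)
    out$rg_mean <- attr(rg, "mean")
    out$pc1_fraction <- pc$fractions[1]
  }
  out
}

#' Run the wild-type-versus-mutant comparison workflow
#'
#' Runs every stage for which inputs are present (relaxation rates +
#' rotational diffusion; chemical-shift perturbation; DSC two-state fit;
#' ensemble statistics), writes per-stage CSVs and a comparative summary
#' table, and logs seeds and configuration. Stages with absent inputs are
#' skipped with a notice — nothing is ever imputed.
#'
#' @param config A [run_config()].
#' @param wildtype,mutant Per-arm input lists with optional elements
#'   `relaxation` (path or list of decays/noe), `shifts` (path or shift
#'   table), `dsc` (path or [thermogram()]), `ensemble` (path or
#'   [coord_ensemble()]).
#' @param output_dir Output directory (created if needed); default from
#'   config.
#' @return List of class `compare_result`: `summary` data frame,
#'   `stages_run`, `stages_skipped`, `status` (`"complete"` when every
#'   stage with any input ran for both arms, else `"partial"`), plus
#'   per-arm results.
#' @export
run_compare <- function(config = run_config(), wildtype = list(),
                        mutant = list(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(output_dir)) output_dir <- config$output_dir
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("relaxation", "shifts", "dsc", "ensemble")
  present <- unique(c(names(wildtype), names(mutant)))
  present <- intersect(all_stages, present)
  if (length(present) == 0) stop("no inputs supplied for either arm")
  wt <- .run_arm("wildtype", wildtype, config, output_dir)
  mu <- .run_arm("mutant", mutant, config, output_dir)
  skipped <- setdiff(all_stages, present)
  # CSP needs both arms
  csp_res <- NULL
  if (!is.null(wildtype$shifts) && !is.null(mutant$shifts)) {
    ta <- if (is.character(wildtype$shifts)) read_shift_table(wildtype$shifts)
    else wildtype$shifts
    tb <- if (is.character(mutant$shifts)) read_shift_table(mutant$shifts)
    else mutant$shifts
    pr <- classify_csp(csp(ta, tb), threshold = config$csp_threshold)
    ca <- ca_diff(ta, tb)
    pr$d_ca <- ca$diff$d_ca[match(pr$residue, ca$diff$residue)]
    pr$d_amide <- round(pr$d_amide, 3)
    pr$d_ca <- round(pr$d_ca, 3)
    utils::write.csv(pr, file.path(output_dir, "csp.csv"), row.names = FALSE)
    csp_res <- list(records = pr, ca_r2 = ca$r2,
                    n_above = sum(pr$above_threshold))
  } else if ("shifts" %in% present) {
    message("shift tables present for one arm only; CSP stage skipped")
    skipped <- c(skipped, "shifts")
    present <- setdiff(present, "shifts")
  }
  get_stat <- function(arm, what) {
    switch(what,
           noe = if (!is.null(arm$summary))
             sprintf("%s +/- %s", .fmt(arm$summary["NOE", "mean"]),
                     .fmt(arm$summary["NOE", "sd"])) else "",
           ratio = if (!is.null(arm$summary))
             sprintf("%s +/- %s", .fmt(arm$summary["R2_R1", "mean"]),
                     .fmt(arm$summary["R2_R1", "sd"])) else "",
           tauc = if (!is.null(arm$tauc_ns))
             formatC(arm$tauc_ns, digits = 2, format = "f") else "",
           tm = if (!is.null(arm$dsc))
             .fmt(arm$dsc$model$tm_k - 273.15) else "",
           dh = if (!is.null(arm$dsc)) .fmt(arm$dsc$model$dh_cal) else "",
           rg = if (!is.null(arm$rg_mean)) .fmt(arm$rg_mean, 3) else "",
           pc1 = if (!is.null(arm$pc1_fraction))
             sprintf("%.1f%%", 100 * arm$pc1_fraction) else "")
  }
  quantities <- c(noe = "NOE (avg)", ratio = "R2/R1 (avg)",
                  tauc = "tau_c (ns)", tm = "Transition Temp (C)",
                  dh = "dH_cal (kcal/mol)", rg = "Avg Rg (nm)",
                  pc1 = "PC1 variance fraction")
  summary_tab <- data.frame(
    quantity = unname(quantities),
    wildtype = vapply(names(quantities), get_stat, "", arm = wt),
    mutant = vapply(names(quantities), get_stat, "", arm = mu))
  utils::write.csv(summary_tab, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  writeLines(c(
    sprintf("igdyn %s | R %s", as.character(utils::packageVersion("igdyn")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("stages run: %s", paste(present, collapse = ", ")),
    sprintf("stages skipped: %s",
            if (length(skipped)) paste(skipped, collapse = ", ") else "none")),
    file.path(output_dir, "run.log"))
  structure(list(summary = summary_tab, wildtype = wt, mutant = mu,
                 csp = csp_res, stages_run = present,
                 stages_skipped = skipped,
                 status = if (length(skipped) == 0) "complete" else "partial"),
            class = "compare_result")
}

#' @export
print.compare_result <- function(x, ...) {
  cat(sprintf("comparison run (%s); stages: %s\n", x$status,
              paste(x$stages_run, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
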