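#' Default configuration for a simulated longitudinal TSC study
#'
#' Assembles the configuration consumed by [run_study()]. The defaults
#' emulate the clinical study design at simulation-friendly problem
#' sizes: a cohort of lesions with geometry and prescriptions drawn from
#' the published cohort table, three sodium scans per lesion (baseline
#' two days before SRS, five and forty days after), head repositioning
#' between scans recovered by rigid registration, and the full
#' quantification and ROI chain.
#'
#' @param n_lesions lesions (= simulated patients) in the cohort.
#' @param grid_shape,voxel_size_mm phantom ground-truth (reference) grid;
#'   1 mm isotropic so isodose shells and ROIs are well resolved.
#' @param acq_voxel_mm grid spacing the signal is averaged to before the
#'   radial acquisition is simulated (the forward model integrates over
#'   the object; 2 mm keeps it faithful at a fraction of the cost).
#' @param n_spokes,n_samples radial acquisition size.
#' @param noise_sd complex k-space noise SD (a.u.); the default 0.25
#'   yields white-matter SNR near 25, typical of a 15-minute sodium
#'   protocol. Use 0 for noise-free analyses.
#' @param registration `"estimate"` (register reconstructions to the
#'   scan-I anatomy) or `"true"` (use the known simulated motion; isolates
#'   downstream stages from registration error).
#' @param motion_amp_mm,motion_amp_deg repositioning amplitude between
#'   scans (uniform in +/- amplitude; scan I defines the reference).
#' @param scans character vector of scans to simulate per lesion, or a
#'   list (per lesion) for incomplete follow-up.
#' @param tsc_params a [tsc_evolution_params()].
#' @param between_tissue_sd,between_gtv_sd between-lesion (inter-patient)
#'   SD of the healthy-tissue and lesion baseline concentrations (mM);
#'   the defaults reproduce the across-lesion spread reported for healthy
#'   regions (about 5 mM) and tumours (about 9 mM).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_lesions = 6, grid_shape = c(128, 128, 128),
                         voxel_size_mm = 1, acq_voxel_mm = 2,
                         n_spokes = 2000,
                         n_samples = 384, noise_sd = 0.25,
                         registration = c("estimate", "true"),
                         motion_amp_mm = 2, motion_amp_deg = 1.5,
                         scans = c("I", "II", "III"),
                         tsc_params = tsc_evolution_params(),
                         between_tissue_sd = 4, between_gtv_sd = 8,
                         seed = 1L) {
  registration <- match.arg(registration)
  structure(list(n_lesions = as.integer(n_lesions),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 acq_voxel_mm = acq_voxel_mm,
                 n_spokes = as.integer(n_spokes),
                 n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, registration = registration,
                 motion_amp_mm = motion_amp_mm,
                 motion_amp_deg = motion_amp_deg,
                 scans = scans, tsc_params = tsc_params,
                 between_tissue_sd = between_tissue_sd,
                 between_gtv_sd = between_gtv_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Keys mirror the arguments of [study_config()]; unknown keys error,
#' missing keys keep their defaults. `tsc_params` may be a nested map of
#' [tsc_evolution_params()] arguments.
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown study config keys: ",
                        paste(bad, collapse = ", "))
  if (!is.null(y$tsc_params))
    y$tsc_params <- do.call(tsc_evolution_params, y$tsc_params)
  do.call(study_config, y)
}

# deterministic per-stage seed derivation (kept within 32-bit range)
derive_seed <- function(seed, lesion, stage) {
  (as.integer(seed) * 97L + lesion * 131L + stage * 7919L) %% 2147483000L
}

#' Simulate and analyse one lesion through the full pipeline
#'
#' Generates a single-lesion phantom, composes its dose field and TSC
#' evolution, simulates the requested sodium scans (with inter-scan
#' repositioning), reconstructs, registers back to the scan-I anatomy,
#' quantifies TSC by vitreous-humor normalization, and returns per-ROI
#' statistics on the reference grid.
#'
#' @param config a [study_config()].
#' @param lesion_id index of the lesion within the cohort (drives the
#'   lesion geometry/prescription draw from the published cohort table).
#' @param scans scans to simulate (default from config).
#' @param keep_volumes keep the full ground truth, shells and tissue maps
#'   in the result? [run_study()] passes `FALSE` to bound cohort memory.
#' @return list with `stats` (data.frame of ROI statistics), `dose_by_shell`,
#'   `registration_errors`, and (with `keep_volumes = TRUE`) `phantom`
#'   (ground truth), `shells`, masks and tissue maps.
#' @export
simulate_lesion_study <- function(config, lesion_id = 1L, scans = NULL,
                                  keep_volumes = TRUE) {
  scans <- scans %||% (if (is.list(config$scans)) config$scans[[lesion_id]]
                       else config$scans)
  cohort <- cohort_table1()
  set.seed(derive_seed(config$seed, lesion_id, 0L))
  row <- cohort[sample(nrow(cohort), 1L), ]
  radius_mm <- (3 * row$gtv_cm3 * 1000 / (4 * pi))^(1 / 3)

  meta0 <- grid_meta(config$grid_shape, config$voxel_size_mm)
  geo <- head_geometry(meta0)
  jit <- stats::runif(3, -4, 4) * c(1, 1, 0.5)
  center <- geo$default_lesion_center + jit

  # between-lesion biology: each simulated patient carries their own
  # baseline concentrations around the population values
  tp <- config$tsc_params
  off_tissue <- stats::rnorm(1, 0, config$between_tissue_sd %||% 0)
  off_gtv <- stats::rnorm(1, 0, config$between_gtv_sd %||% 0)
  tp$tsc_wm <- max(10, tp$tsc_wm + off_tissue)
  tp$tsc_gm <- max(10, tp$tsc_gm + off_tissue)
  tp$tsc_gtv_baseline <- max(tp$tsc_wm + 5, tp$tsc_gtv_baseline + off_gtv)

  spec <- phantom_spec(grid_shape = config$grid_shape,
                       voxel_size_mm = config$voxel_size_mm,
                       lesion_centers = list(center),
                       lesion_radii_mm = radius_mm,
                       tsc_params = tp,
                       seed = derive_seed(config$seed, lesion_id, 1L))
  gt <- generate_phantom(spec)
  rx <- prescription_spec(row$dose_gy)
  dg <- compute_dose(gt$labels, list(rx))
  gt <- compose_evolution(gt, dg$dose)

  ref_meta <- gt$labels$meta
  tissue <- segment_tissues(gt$anatomy, gt$brain_mask,
                            seed = derive_seed(config$seed, lesion_id, 2L))
  shells <- build_isodose_shells(dg)
  hrs <- tryCatch(
    place_healthy_rois(tissue, shells, dg$gtv_masks,
                       seed = derive_seed(config$seed, lesion_id, 3L)),
    error = function(e) NULL)
  gtv_mask <- Reduce(`|`, dg$gtv_masks)
  vh_l <- gt$labels$data == phantom_labels[["vh_left"]]

  params <- sequence_params(n_spokes = config$n_spokes,
                            n_samples = config$n_samples,
                            noise_sd = config$noise_sd)
  traj <- make_trajectory(params)

  rows <- list()
  reg_err <- NULL
  dose_ref <- dg$dose
  for (s in scans) {
    sseed <- derive_seed(config$seed, lesion_id, 10L + match(s, c("I", "II", "III")))
    set.seed(sseed)
    motion <- if (s == "I") rigid_transform() else
      rigid_transform(stats::runif(3, -1, 1) * config$motion_amp_deg,
                      stats::runif(3, -1, 1) * config$motion_amp_mm)
    # motion maps scan space -> reference space; the acquired object is the
    # reference-frame signal expressed in scan coordinates, block-averaged
    # to the acquisition grid before the forward model
    signal <- steady_state_signal(gt$tsc[[s]], gt$t1, gt$t2star, params)
    moved <- resample_volume(signal, invert_transform(motion), ref_meta)
    fac <- max(1L, as.integer(round(config$acq_voxel_mm /
                                      config$voxel_size_mm)))
    acq_sig <- if (fac > 1L) downsample_volume(moved, fac) else moved
    ksp <- simulate_acquisition(acq_sig, traj, noise_sd = config$noise_sd,
                                seed = sseed)
    recon <- reconstruct(ksp)
    tf <- if (config$registration == "true" || s == "I") motion else
      register_rigid(recon, gt$anatomy, init = rigid_transform())
    reg_err <- rbind(reg_err, data.frame(
      lesion = lesion_id, scan = s,
      err_mm = sqrt(sum((tf$translation - motion$translation)^2)),
      err_deg = max(abs(tf$angles_deg - motion$angles_deg))))
    vh_scan <- resample_mask(vh_l, invert_transform(tf), recon$meta,
                             meta = ref_meta)
    cal <- calibrate_vh(recon, vh_scan, params)
    tsc <- quantify_tsc(recon, cal)
    tsc_ref <- resample_volume(tsc$values, tf, ref_meta)

    add_stat <- function(mask, name) {
      cs <- subtract_csf(mask, tissue)
      as.data.frame(roi_statistics(tsc_ref, cs$mask, roi_name = name,
                                   scan_id = s,
                                   n_csf_removed = cs$n_removed))
    }
    rows[[length(rows) + 1]] <- add_stat(gtv_mask, "GTV")
    if (!is.null(hrs))
      rows[[length(rows) + 1]] <- add_stat(hrs[[1]]$mask | hrs[[2]]$mask, "HR")
    for (lv in names(shells$masks))
      rows[[length(rows) + 1]] <- add_stat(shells$masks[[lv]], lv)
  }
  stats <- do.call(rbind, rows)
  stats$lesion <- lesion_id
  stats$dose_gy <- row$dose_gy
  stats$histology <- row$histology

  dose_by_shell <- vapply(shells$masks, function(m)
    if (any(m)) mean(dose_ref$data[m]) else NA_real_, numeric(1))

  out <- list(stats = stats, dose_by_shell = dose_by_shell,
              registration_errors = reg_err, prescription = rx,
              cohort_row = row,
              lesion_radius_mm = spec$lesion_radii_mm)
  if (keep_volumes)
    out <- c(out, list(phantom = gt, shells = shells, gtv_mask = gtv_mask,
                       healthy_rois = hrs, tissue = tissue))
  out
}

#' Longitudinal analysis of per-lesion ROI statistics
#'
#' Aggregates a long table of per-lesion, per-scan ROI means into the
#' study report: per-region group means with SD, normality-gated paired
#' t-tests for the three scan pairs (pairwise-available: lesions missing
#' a scan drop out of only the comparisons that need it), and the
#' per-scan Pearson correlation between shell dose level and the
#' lesion-averaged shell mean TSC.
#'
#' @param roi_stats data.frame with columns `lesion`, `roi`, `scan`,
#'   `mean_tsc`, `flag_missing` (as produced by [simulate_lesion_study()]).
#' @return list with `table2`, `comparisons`, `correlations`.
#' @export
analyze_roi_stats <- function(roi_stats) {
  scans <- c("I", "II", "III")
  pairs <- list(c("I", "II"), c("I", "III"), c("II", "III"))
  regions <- unique(roi_stats$roi)
  wide <- function(region) {
    sub <- roi_stats[roi_stats$roi == region & !roi_stats$flag_missing, ]
    sapply(scans, function(s) {
      m <- sub$mean_tsc[sub$scan == s]
      if (length(m)) c(mean = mean(m), sd = stats::sd(m), n = length(m))
      else c(mean = NA, sd = NA, n = 0)
    })
  }
  comparisons <- list()
  table2 <- NULL
  for (rg in regions) {
    sub <- roi_stats[roi_stats$roi == rg & !roi_stats$flag_missing, ]
    per_lesion <- function(s)
      sapply(sort(unique(roi_stats$lesion)), function(l) {
        v <- sub$mean_tsc[sub$lesion == l & sub$scan == s]
        if (length(v)) v[1] else NA_real_
      })
    vals <- lapply(scans, per_lesion)
    names(vals) <- scans
    w <- wide(rg)
    row <- data.frame(region = rg,
                      scan1_mean = w["mean", "I"], scan1_sd = w["sd", "I"],
                      scan2_mean = w["mean", "II"], scan2_sd = w["sd", "II"],
                      scan3_mean = w["mean", "III"], scan3_sd = w["sd", "III"])
    for (pr in pairs) {
      x <- vals[[pr[1]]]; y <- vals[[pr[2]]]
      ok <- sum(is.finite(x) & is.finite(y))
      nm <- paste0(pr[1], "_", pr[2])
      if (ok >= 2) {
        ks <- tryCatch(ks_normality(stats::na.omit(y - x)),
                       error = function(e) list(normal = NA))
        cmp <- paired_t_test(x, y, region = rg, pair = paste(pr, collapse = "-"))
        cmp$ks_normal <- ks$normal
        comparisons[[paste(rg, nm)]] <- cmp
        row[[paste0("p_", nm)]] <- cmp$p
        row[[paste0("dir_", nm)]] <- cmp$direction
      } else {
        row[[paste0("p_", nm)]] <- NA_real_
        row[[paste0("dir_", nm)]] <- NA_character_
      }
    }
    table2 <- rbind(table2, row)
  }

  # per-scan dose-TSC correlation over the shell means (lesion-averaged)
  shell_names <- grep("Gy$", regions, value = TRUE)
  lv <- as.numeric(sub("Gy$", "", shell_names))
  correlations <- do.call(rbind, lapply(scans, function(s) {
    mns <- vapply(shell_names, function(rg) {
      v <- roi_stats$mean_tsc[roi_stats$roi == rg & roi_stats$scan == s &
                                !roi_stats$flag_missing]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    if (sum(is.finite(mns)) < 3)
      return(data.frame(scan = s, r = NA_real_, p = NA_real_,
                        n = sum(is.finite(mns))))
    ct <- dose_tsc_correlation(lv[is.finite(mns)], mns[is.finite(mns)],
                               scan_id = s)
    data.frame(scan = s, r = ct$r, p = ct$p, n = ct$n)
  }))


  list(table2 = table2, comparisons = comparisons,
       correlations = correlations)
}

#' Run the full simulated longitudinal study
#'
#' Executes the end-to-end pipeline (phantom, dose, three-scan radial
#' acquisition and reconstruction, registration, segmentation,
#' vitreous-humor quantification, isodose-shell and healthy-ROI
#' statistics) over a cohort of simulated lesions, then reproduces the
#' longitudinal analysis: normality-checked paired t-tests between scans
#' per region, integer percent changes of the GTV mean, and the per-scan
#' Pearson correlation between dose level and shell mean TSC.
#'
#' @param config a [study_config()] (or a YAML path understood by
#'   [read_study_config()]).
#' @param out_dir optional directory; when given, the report files
#'   (`table1_cohort.csv`, `table2_summary.csv`, `roi_statistics.csv`,
#'   `correlations.csv`, `report.json`) are written there.
#' @return a `study_report` list: `roi_stats`, `table2`, `comparisons`,
#'   `correlations`, `gtv_percent_change`, `registration_errors`,
#'   `dose_by_shell`, `cohort`, `provenance`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  lesions <- lapply(seq_len(config$n_lesions), function(i)
    simulate_lesion_study(config, i, keep_volumes = FALSE))
  roi_stats <- do.call(rbind, lapply(lesions, `[[`, "stats"))
  reg_err <- do.call(rbind, lapply(lesions, `[[`, "registration_errors"))
  dose_by_shell <- colMeans(do.call(rbind,
                                    lapply(lesions, `[[`, "dose_by_shell")),
                            na.rm = TRUE)

  analysis <- analyze_roi_stats(roi_stats)
  table2 <- analysis$table2
  comparisons <- analysis$comparisons
  correlations <- analysis$correlations

  g <- table2[table2$region == "GTV", ]
  gtv_pc <- c(scan2_vs_scan1 = percent_change(g$scan1_mean, g$scan2_mean),
              scan3_vs_scan1 = percent_change(g$scan1_mean, g$scan3_mean))

  cohort <- do.call(rbind, lapply(seq_along(lesions), function(i) {
    r <- lesions[[i]]$cohort_row
    data.frame(lesion = i, template_bm = r$bm, dose_gy = r$dose_gy,
               gtv_cm3 = round(4 / 3 * pi *
                                 lesions[[i]]$lesion_radius_mm^3 / 1000, 3),
               histology = r$histology)
  }))

  report <- structure(list(
    roi_stats = roi_stats, table2 = table2, comparisons = comparisons,
    correlations = correlations, gtv_percent_change = gtv_pc,
    registration_errors = reg_err, dose_by_shell = dose_by_shell,
    cohort = cohort,
    provenance = c(list(seed = config$seed,
                        config_hash = config_hash(unclass(config)),
                        n_lesions = config$n_lesions,
                        registration = config$registration,
                        date = NULL), tool_info())),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", length(unique(x$roi_stats$lesion)), "lesions\n")
  print(x$table2[, 1:7], digits = 3)
  cat("dose-TSC correlations:\n")
  print(x$correlations, digits = 3)
}

#' Write a study report to CSV/JSON files
#'
#' Emits `table1_cohort.csv`, `table2_summary.csv`, `roi_statistics.csv`,
#' `correlations.csv` and a `report.json` with percent changes,
#' registration errors and provenance (seed, config hash, version).
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$cohort, file.path(dir, "table1_cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table2, file.path(dir, "table2_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roi_stats, file.path(dir, "roi_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(gtv_percent_change = as.list(report$gtv_percent_change),
         dose_by_shell = as.list(report$dose_by_shell),
         registration_errors = report$registration_errors,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
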