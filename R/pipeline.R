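#' Default pipeline configuration
#'
#' The template every configuration is validated against. Defaults mirror the
#' dual-subject study conditions this package emulates: 4 runs of 400 volumes
#' at TR 1.5 s (resting/synchrony) or 172-volume runs for the 17-block
#' 18 s/12 s task; 0.01-0.1 Hz temporal band; 1.5 mm (resting) / 2.0 mm
#' (task) FWHM smoothing; fifth-order detrending in the GLM; synchrony
#' threshold z >= 3.1; motion bounds 140 um / 0.6 degrees.
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    convention = list(orientation = "LAS"),
    simulation = list(
      grid = list(dim = c(12, 12, 8), voxel_size_mm = c(1, 1, 1), tr_s = 1.5),
      mask_margin = 1,
      roi_size = c(4, 4, 3),
      rho = 0.3,
      band_hz = c(0.01, 0.1),
      noise = list(baseline = 100, sigma = 2.2, ar1_phi = 0.1,
                   drift_coeffs = c(0.01, -0.005), background_sigma = 1),
      n_runs = 4,
      n_volumes = 400,
      task = list(enabled = FALSE, beta = 2, condition = "transparent"),
      motion_bounds = list(translation_um = 140, rotation_deg = 0.6),
      noise_channels = list(n_samples = 50000)
    ),
    preprocess = list(detrend_order = 5, band_hz = c(0.01, 0.1),
                      fwhm_mm = 1.5, fwhm_mm_task = 2.0),
    qc = list(tsnr_detrend_order = 2, translation_bound_um = 140,
              rotation_bound_deg = 0.6),
    synchrony = list(threshold = 3.1, two_sided = FALSE),
    glm = list(detrend_order = 5, drift_high_hz = 0.01,
               t_threshold = NA, z_threshold = 1.96)
  )
}

check_known_keys <- function(user, template, path = "") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s)%s: %s",
                 if (nzchar(path)) paste0(" in ", path) else "",
                 paste(unknown, collapse = ", ")))
  for (k in names(user))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(user[[k]]))
      check_known_keys(user[[k]], template[[k]],
                       paste0(path, if (nzchar(path)) "/" else "", k))
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys are rejected
#' before any stage runs, and missing keys filled from [default_config()].
#'
#' @param config Path to a YAML file, a list, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  template <- default_config()
  check_known_keys(config, template)
  utils::modifyList(template, config)
}

# brain mask: everything but a margin border; ROI: centred box
box_mask <- function(dims, margin) {
  a <- array(FALSE, dims)
  a[(1 + margin):(dims[1] - margin), (1 + margin):(dims[2] - margin),
    (1 + margin):(dims[3] - margin)] <- TRUE
  a
}

centered_box <- function(dims, size) {
  a <- array(FALSE, dims)
  lo <- pmax(1, floor((dims - size) / 2) + 1)
  a[lo[1]:(lo[1] + size[1] - 1), lo[2]:(lo[2] + size[2] - 1),
    lo[3]:(lo[3] + size[3] - 1)] <- TRUE
  a
}

sim_objects <- function(config) {
  sim <- config$simulation
  dims <- as.integer(sim$grid$dim)
  vox <- as.numeric(sim$grid$voxel_size_mm)
  mask <- mask3d(box_mask(dims, sim$mask_margin), vox)
  roi <- mask3d(centered_box(dims, as.integer(sim$roi_size)), vox)
  coupling <- if (sim$rho > 0)
    coupling_spec(roi, sim$rho, as.numeric(sim$band_hz)) else NULL
  task <- if (isTRUE(sim$task$enabled))
    list(design = social_block_design(sim$grid$tr_s), beta = sim$task$beta,
         roi = roi, condition = sim$task$condition) else NULL
  noise <- noise_spec(sim$noise$baseline, sim$noise$sigma, sim$noise$ar1_phi,
                      as.numeric(sim$noise$drift_coeffs),
                      sim$noise$background_sigma)
  list(mask = mask, roi = roi, coupling = coupling, task = task,
       noise = noise)
}

#' Simulate a complete dual-subject dataset to disk
#'
#' Runs the paired-BOLD generator under the configuration and writes, per
#' subject: NIfTI runs, ground-truth coupling/beta maps, motion traces
#' (6-column text); plus the brain mask and ROI, multi-channel noise samples
#' (TSV, with the channel-to-coil assignment in a JSON sidecar), and a
#' manifest listing every file with its MD5 digest. With one seed the whole
#' tree is byte-identical across invocations.
#'
#' @param config A configuration accepted by [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
simulate_dataset <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  obj <- sim_objects(config)
  pair <- simulate_pair(
    grid = sim$grid, masks = list(obj$mask, obj$mask),
    coupling = obj$coupling, task = obj$task, noise = obj$noise,
    n_runs = sim$n_runs, n_volumes = sim$n_volumes, seed = config$seed,
    motion_bounds = c(translation_um = sim$motion_bounds$translation_um,
                      rotation_deg = sim$motion_bounds$rotation_deg))
  files <- character(0)
  put <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }
  write_volume(obj$mask, put("mask.nii.gz"))
  write_volume(obj$roi, put("roi.nii.gz"))
  vox <- as.numeric(sim$grid$voxel_size_mm)
  wrap_map <- function(a) volume_series(array(a, c(dim(a), 1)),
                                        voxel_size_mm = vox, tr_s = 1)
  runs <- list(A = pair$runs_a, B = pair$runs_b)
  for (s in c("A", "B")) {
    for (r in seq_len(sim$n_runs)) {
      write_volume(runs[[s]][[r]],
                   put(sprintf("sub-%s_run-%02d_bold.nii.gz", s, r)))
      write_motion_trace(pair$truth$motion[[s]][[r]],
                         put(sprintf("motion_sub-%s_run-%02d.txt", s, r)))
    }
    write_volume(wrap_map(pair$truth$coupling_map[[s]]),
                 put(sprintf("truth_coupling_%s.nii.gz", s)))
    write_volume(wrap_map(pair$truth$beta_map[[s]]),
                 put(sprintf("truth_beta_%s.nii.gz", s)))
  }
  shared <- as.data.frame(do.call(cbind, pair$truth$shared_signal))
  names(shared) <- sprintf("run%02d", seq_len(sim$n_runs))
  write_tsv(shared, put("truth_shared_signal.tsv"))
  nc <- example_noise_covariance()
  samp <- simulate_noise_channels(nc$sigma, sim$noise_channels$n_samples,
                                  seed = derive_seed(config$seed, "noisechan"))
  write_tsv(as.data.frame(samp), put("noise_samples.tsv"))
  jsonlite::write_json(list(coil_of = nc$coil_of),
                       put("noise_channels.json"), digits = NA)
  if (!is.null(obj$task)) {
    des <- obj$task$design
    jsonlite::write_json(list(blocks = des$blocks, tr_s = des$tr_s,
                              condition = obj$task$condition,
                              beta = obj$task$beta),
                         put("design.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    seed = config$seed,
    n_runs = sim$n_runs, n_volumes = sim$n_volumes,
    tr_s = sim$grid$tr_s, rho = sim$rho,
    task = isTRUE(sim$task$enabled),
    files = data.frame(name = sort(files),
                       md5 = unname(tools::md5sum(file.path(out_dir,
                                                            sort(files))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "manifest.json"), "simulate",
                   params = list(n_runs = sim$n_runs,
                                 n_volumes = sim$n_volumes, rho = sim$rho),
                   seed = config$seed)
  invisible(manifest)
}

read_dataset_runs <- function(dir, subject, n_runs) {
  lapply(seq_len(n_runs), function(r)
    read_volume(file.path(dir, sprintf("sub-%s_run-%02d_bold.nii.gz",
                                       subject, r)),
                subject_id = subject, run_id = sprintf("run-%02d", r)))
}

dataset_manifest <- function(dir)
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)

#' Temporal-SNR stage
#'
#' Concatenates each subject's runs, computes tSNR maps and the two-subject
#' summary, and writes maps (NIfTI), summary (TSV + JSON) and histograms
#' (TSV).
#'
#' @param dataset_dir Directory written by [simulate_dataset()].
#' @param out_dir Output directory.
#' @param config Pipeline configuration.
#' @return The summary list, invisibly.
#' @export
stage_tsnr <- function(dataset_dir, out_dir, config = NULL) {
  config <- pipeline_config(config)
  man <- dataset_manifest(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- read_mask(file.path(dataset_dir, "mask.nii.gz"))
  maps <- lapply(c("A", "B"), function(s) {
    cc <- concatenate_runs(read_dataset_runs(dataset_dir, s, man$n_runs))
    tsnr_map(cc, config$qc$tsnr_detrend_order)
  })
  for (i in 1:2) {
    v <- volume_series(array(maps[[i]]$data, c(dim(maps[[i]]$data), 1)),
                       voxel_size_mm = mask$voxel_size_mm, tr_s = 1)
    write_volume(v, file.path(out_dir,
                              sprintf("tsnr_sub-%s.nii.gz", c("A", "B")[i])))
  }
  smry <- tsnr_summary(maps[[1]], maps[[2]], list(mask, mask))
  write_tsv(smry$table, file.path(out_dir, "tsnr_summary.tsv"))
  for (i in 1:2)
    write_tsv(smry$histograms[[i]],
              file.path(out_dir, sprintf("tsnr_hist_sub-%s.tsv",
                                         c("A", "B")[i])))
  jsonlite::write_json(
    list(mean_tsnr = stats::setNames(as.list(smry$table$mean_tsnr),
                                     c("A", "B")),
         relative_difference_pct = smry$relative_difference_pct,
         convention = smry$convention),
    file.path(out_dir, "tsnr_summary.json"), auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "tsnr_summary.json"), "tsnr",
                   params = list(detrend_order = config$qc$tsnr_detrend_order),
                   seed = config$seed)
  invisible(smry)
}

#' Receiver noise-correlation stage
#' @inheritParams stage_tsnr
#' @return The `noise_correlation` object, invisibly.
#' @export
stage_noisecorr <- function(dataset_dir, out_dir, config = NULL) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samp <- as.matrix(read_tsv(file.path(dataset_dir, "noise_samples.tsv")))
  coil_of <- unlist(jsonlite::read_json(file.path(dataset_dir,
                                                  "noise_channels.json"),
                                        simplifyVector = TRUE))
  nc <- noise_correlation(samp, coil_of)
  write_tsv(as.data.frame(nc$matrix), file.path(out_dir,
                                                "noise_correlation.tsv"))
  jsonlite::write_json(
    list(intra_coil = nc$summary$intra,
         inter_coil_max_pct = nc$summary$inter_coil_max,
         noise_level_difference_pct = nc$summary$noise_level_difference_pct),
    file.path(out_dir, "noise_correlation.json"), auto_unbox = TRUE,
    digits = NA)
  write_provenance(file.path(out_dir, "noise_correlation.json"), "noisecorr",
                   seed = config$seed)
  invisible(nc)
}

#' Motion QC stage
#' @inheritParams stage_tsnr
#' @return Data frame of per-run summaries, invisibly.
#' @export
stage_motion <- function(dataset_dir, out_dir, config = NULL) {
  config <- pipeline_config(config)
  man <- dataset_manifest(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in c("A", "B")) for (r in seq_len(man$n_runs)) {
    tr <- read_motion_trace(file.path(dataset_dir,
                                      sprintf("motion_sub-%s_run-%02d.txt",
                                              s, r)))
    ms <- motion_summary(tr, config$qc$translation_bound_um,
                         config$qc$rotation_bound_deg)
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, run = r,
      max_translation_um = ms$max_translation_um[["overall"]],
      max_rotation_deg = ms$max_rotation_deg[["overall"]],
      pass = ms$pass)
  }
  tab <- do.call(rbind, rows)
  write_tsv(tab, file.path(out_dir, "motion_summary.tsv"))
  jsonlite::write_json(list(all_pass = all(tab$pass),
                            max_translation_um = max(tab$max_translation_um),
                            max_rotation_deg = max(tab$max_rotation_deg)),
                       file.path(out_dir, "motion_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "motion_summary.json"), "motion",
                   params = config$qc, seed = config$seed)
  invisible(tab)
}

#' Inter-brain synchrony stage
#'
#' The resting pipeline as applied before the synchrony statistic: per run
#' and subject, mask-renormalized Gaussian smoothing, polynomial detrending
#' (slow scanner drift is aperiodic, so it must be removed by regression
#' before a frequency-domain filter, whose circular transform would leak it
#' across the pass band), then temporal band-pass; then the synchrony
#' pipeline (per-run normalization, concatenation, voxel-wise correlation,
#' variance-stabilized Fisher-Z, thresholding). Band-limiting reduces the
#' effective temporal degrees of freedom below the raw time-point count used
#' by the Fisher-Z scaling, so supra-threshold extent is anticonservative
#' after filtering; see the vignette.
#'
#' @inheritParams stage_tsnr
#' @return The `synchrony_result`, invisibly.
#' @export
stage_synchrony <- function(dataset_dir, out_dir, config = NULL) {
  config <- pipeline_config(config)
  man <- dataset_manifest(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- read_mask(file.path(dataset_dir, "mask.nii.gz"))
  pre <- function(run) {
    run <- smooth_gaussian(run, config$preprocess$fwhm_mm, mask)
    run <- detrend_poly(run, config$preprocess$detrend_order)
    bandpass(run, config$preprocess$band_hz[1], config$preprocess$band_hz[2])
  }
  runs_a <- lapply(read_dataset_runs(dataset_dir, "A", man$n_runs), pre)
  runs_b <- lapply(read_dataset_runs(dataset_dir, "B", man$n_runs), pre)
  res <- synchrony_pipeline(runs_a, runs_b, mask,
                            threshold = config$synchrony$threshold,
                            two_sided = config$synchrony$two_sided)
  write_synchrony_result(res, file.path(out_dir, "synchrony"),
                         voxel_size_mm = mask$voxel_size_mm)
  roi <- read_mask(file.path(dataset_dir, "roi.nii.gz"))
  jsonlite::write_json(
    list(n_timepoints = res$n_timepoints, threshold = res$threshold,
         supra_voxels = sum(res$supra_mask),
         roi_median_r = stats::median(res$r_map[roi$data], na.rm = TRUE),
         roi_supra_fraction = mean(res$supra_mask[roi$data])),
    file.path(out_dir, "synchrony_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_provenance(file.path(out_dir, "synchrony_summary.json"), "synchrony",
                   params = c(config$synchrony,
                              list(fwhm_mm = config$preprocess$fwhm_mm,
                                   band_hz = config$preprocess$band_hz)),
                   seed = config$seed)
  invisible(res)
}

#' Task-GLM stage
#'
#' Per run of subject A: 2.0 mm smoothing, design assembly (HRF-convolved
#' condition regressors, fifth-order polynomials, low-frequency cosine drift,
#' motion parameters), voxel-wise OLS; then the paired
#' stimulus-versus-baseline contrast across runs and, if a second paradigm's
#' dataset is given, the unpaired between-paradigm contrast on the stimulus
#' coefficients.
#'
#' @param dataset_dir Task dataset directory (paradigm 1).
#' @param out_dir Output directory.
#' @param config Pipeline configuration.
#' @param dataset_dir_p2 Optional paradigm-2 dataset directory.
#' @return List with `paired` and (optionally) `unpaired` contrast results,
#'   invisibly.
#' @export
stage_glm <- function(dataset_dir, out_dir, config = NULL,
                      dataset_dir_p2 = NULL) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit_paradigm <- function(dir) {
    man <- dataset_manifest(dir)
    des_meta <- jsonlite::read_json(file.path(dir, "design.json"),
                                    simplifyVector = TRUE)
    des <- block_design(des_meta$blocks, des_meta$tr_s)
    mask <- read_mask(file.path(dir, "mask.nii.gz"))
    stim_lab <- paste0("cond_", des_meta$condition)
    base_lab <- setdiff(paste0("cond_", unique(des$blocks$condition)),
                        stim_lab)[1]
    runs <- read_dataset_runs(dir, "A", man$n_runs)
    stim <- list(); base <- list()
    for (r in seq_len(man$n_runs)) {
      run <- smooth_gaussian(runs[[r]], config$preprocess$fwhm_mm_task, mask)
      mot <- read_motion_trace(file.path(dir,
                                         sprintf("motion_sub-A_run-%02d.txt",
                                                 r)))
      X <- build_design(des, motion = mot,
                        detrend_order = config$glm$detrend_order,
                        drift_high_hz = config$glm$drift_high_hz,
                        n_volumes = man$n_volumes)
      fit <- fit_glm(run, X)
      dims <- dim(mask$data)
      stim[[r]] <- array(fit$beta[stim_lab, ], dims)
      base[[r]] <- array(fit$beta[base_lab, ], dims)
    }
    list(stim = stim, base = base, mask = mask)
  }
  p1 <- fit_paradigm(dataset_dir)
  thr <- config$glm$t_threshold
  if (is.na(thr)) thr <- critical_t(0.05, length(p1$stim) - 1)
  paired <- paired_contrast(p1$stim, p1$base, threshold = thr)
  out <- list(paired = paired)
  vox <- p1$mask$voxel_size_mm
  wrap <- function(a) volume_series(array(a, c(dim(a), 1)),
                                    voxel_size_mm = vox, tr_s = 1)
  write_volume(wrap(paired$t_map), file.path(out_dir, "paired_t.nii.gz"))
  write_volume(wrap(paired$effect_map),
               file.path(out_dir, "paired_effect.nii.gz"))
  smry <- list(paired = list(df = paired$df, threshold = paired$threshold,
                             supra_voxels = sum(paired$supra_mask &
                                                  p1$mask$data)))
  if (!is.null(dataset_dir_p2)) {
    p2 <- fit_paradigm(dataset_dir_p2)
    unpaired <- unpaired_contrast(p1$stim, p2$stim,
                                  threshold = config$glm$z_threshold)
    write_volume(wrap(unpaired$z_map),
                 file.path(out_dir, "unpaired_z.nii.gz"))
    smry$unpaired <- list(df = unpaired$df, threshold = unpaired$threshold,
                          supra_voxels = sum(unpaired$supra_mask &
                                               p1$mask$data))
    out$unpaired <- unpaired
  }
  jsonlite::write_json(smry, file.path(out_dir, "glm_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(out_dir, "glm_summary.json"), "glm",
                   params = config$glm, seed = config$seed)
  invisible(out)
}

#' Aggregate stage summaries into one report
#'
#' Collects whatever stage summary JSONs exist under `out_dir` (tSNR means,
#' noise-correlation extrema, motion pass/fail, synchrony and GLM
#' supra-threshold counts) into a single `report.json`.
#'
#' @param out_dir Directory containing stage outputs.
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  pick <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  report <- list(tsnr = pick("tsnr_summary.json"),
                 noise_correlation = pick("noise_correlation.json"),
                 motion = pick("motion_summary.json"),
                 synchrony = pick("synchrony_summary.json"),
                 glm = pick("glm_summary.json"))
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
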