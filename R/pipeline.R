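# Configuration and staged pipeline orchestration: simulate -> preprocess
# -> fit -> gainfield -> metrics -> report, with per-stage TSV/JSON
# artifacts and manifests.

#' Default pipeline configuration
#'
#' Nested list of all tunable parameters: stimulus geometry/timing,
#' simulation (voxel population, generative gain fields, noise, seed),
#' fitting (grids, ridge penalty, selection thresholds), gain-field model
#' search grid, and statistics settings. Serializes losslessly to YAML via
#' [write_config()] / [read_config()].
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    stimulus = list(n_passes = 24, n_positions = 24, step_dva = 0.34,
                    dwell_s = 1.6, pause_s = 4.8, blank_s = 38.4,
                    n_blanks = 4, bar_width_dva = 0.9,
                    aperture_radius_dva = 3.6, extent_dva = 7.2,
                    order_seed = 1),
    simulation = list(n_voxels = 100, ecc_range = c(0, 3.3),
                      size_intercept = 0.25, size_slope = 0.2,
                      size_jitter_sd = 0.05, amplitude = 1, baseline = 100,
                      polar_angle_kappa = 0,
                      sigma_fix = 2.5, sigma_stim_color = 0.65,
                      sigma_stim_tf = 0.75, noise_frac = 0.2, n_runs = 2),
    preprocess = list(window_s = 120, sg_order = 3),
    fitting = list(grid_coarse = 31, grid_fine = 101, lambda = 1e6,
                   xy_bound = 5, sigma_bounds = c(0.05, 10),
                   ecc_max = 3.3, size_max = 7.2, r2_min = 0.1),
    model = list(fix_range = c(1.5, 2.5), stim_range = c(0.6, 1.6),
                 grid_n = 50, n_bins = 8),
    stats = list(n_boot = 2000, k_mad = 5),
    seed = 1),
    class = "pipeline_config")
}

#' @rdname default_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(d, path)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

.write_manifest <- function(dir, stage, config, seed, info) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = .config_hash(config), seed = seed),
      info),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_designs <- function(config) {
  st <- config$stimulus
  seq <- build_bar_sequence(
    n_passes = st$n_passes, n_positions = st$n_positions,
    step_dva = st$step_dva, dwell_s = st$dwell_s, pause_s = st$pause_s,
    blank_s = st$blank_s, n_blanks = st$n_blanks,
    bar_width_dva = st$bar_width_dva,
    aperture_radius_dva = st$aperture_radius_dva,
    extent_dva = st$extent_dva, seed = st$order_seed)
  hrf <- hrf_double_gamma(dt_s = st$dwell_s)
  list(seq = seq, hrf = hrf,
       dm_coarse = render_design_matrix(seq, config$fitting$grid_coarse),
       dm_fine = render_design_matrix(seq, config$fitting$grid_fine))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing versioned TSV/JSON
#' artifacts and a manifest per stage into `out_dir`. A stage whose inputs
#' were not produced in the same call reloads them from `out_dir`; if they
#' are missing, an error names the stage. Reruns with the same
#' configuration produce identical TSV outputs.
#'
#' @param config A `pipeline_config` (default [default_config()]).
#' @param stages Subset of `c("simulate", "preprocess", "fit", "gainfield",
#'   "metrics", "report")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, `out_dir`; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "preprocess", "fit",
                                    "gainfield", "metrics", "report"),
                         out_dir, seed = NULL) {
  all_stages <- c("simulate", "preprocess", "fit", "gainfield", "metrics",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) config$seed <- seed
  des <- .stage_designs(config)
  sim <- config$simulation
  state <- new.env(parent = emptyenv())

  need <- function(what, stage, loader) {
    if (!is.null(state[[what]])) return(state[[what]])
    v <- loader()
    .stop_if(is.null(v), "stage '", stage, "' requires missing upstream ",
             "artifact '", what, "' (run the earlier stage or point out_dir ",
             "at its outputs)")
    state[[what]] <- v
    v
  }
  load_ts <- function() {
    files <- file.path(out_dir, paste0("bold_", .conditions, ".tsv"))
    if (!all(file.exists(files))) return(NULL)
    mats <- lapply(files, function(f) as.matrix(read.delim(f)))
    array(unlist(mats), c(nrow(mats[[1]]), ncol(mats[[1]]), 3),
          dimnames = list(NULL, NULL, .conditions))
  }
  load_fits <- function() {
    f <- file.path(out_dir, "prf_fits.tsv")
    if (!file.exists(f)) return(NULL)
    structure(read.delim(f), class = c("prf_fits", "data.frame"))
  }

  if ("simulate" %in% stages) {
    af <- af_spec(sim$sigma_fix, sim$sigma_stim_color, sim$sigma_stim_tf)
    ds <- simulate_prf_dataset(
      sim$n_voxels, des$dm_fine, des$hrf, af,
      noise_frac = sim$noise_frac, n_runs = sim$n_runs, seed = config$seed,
      ecc_range = sim$ecc_range, size_intercept = sim$size_intercept,
      size_slope = sim$size_slope, size_jitter_sd = sim$size_jitter_sd,
      amplitude = sim$amplitude, baseline = sim$baseline,
      polar_angle_kappa = sim$polar_angle_kappa)
    state$ts <- ds$ts
    state$voxels <- ds$voxels
    write_frame_table(des$seq, file.path(out_dir, "frames.tsv"))
    .write_tsv(ds$voxels, file.path(out_dir, "ground_truth_voxels.tsv"))
    for (cond in .conditions)
      .write_tsv(as.data.frame(ds$ts[, , cond]),
                 file.path(out_dir, paste0("bold_", cond, ".tsv")))
    .write_manifest(out_dir, "simulate", config, config$seed,
                    list(n_voxels = sim$n_voxels,
                         n_frames = nrow(des$seq$frames),
                         noise_frac = sim$noise_frac))
  }

  if ("preprocess" %in% stages) {
    ts <- need("ts", "preprocess", load_ts)
    pp <- ts
    for (cond in .conditions) for (v in seq_len(dim(ts)[2]))
      pp[, v, cond] <- percent_signal_change(
        savgol_detrend(ts[, v, cond], tr_s = config$stimulus$dwell_s,
                       window_s = config$preprocess$window_s,
                       order = config$preprocess$sg_order))
    state$ts_pp <- pp
    for (cond in .conditions)
      .write_tsv(as.data.frame(pp[, , cond]),
                 file.path(out_dir, paste0("psc_", cond, ".tsv")))
    .write_manifest(out_dir, "preprocess", config, config$seed,
                    list(window_s = config$preprocess$window_s))
  }

  if ("fit" %in% stages) {
    ts <- if (!is.null(state$ts_pp)) state$ts_pp else {
      files <- file.path(out_dir, paste0("psc_", .conditions, ".tsv"))
      if (all(file.exists(files))) {
        mats <- lapply(files, function(f) as.matrix(read.delim(f)))
        array(unlist(mats), c(nrow(mats[[1]]), ncol(mats[[1]]), 3),
              dimnames = list(NULL, NULL, .conditions))
      } else need("ts", "fit", load_ts)
    }
    fitc <- config$fitting
    reg_c <- convolve_design(des$dm_coarse, des$hrf)
    reg_f <- convolve_design(des$dm_fine, des$hrf)
    fits <- fit_prf_dataset(ts, reg_c, reg_f, lambda = fitc$lambda,
                            xy_bound = fitc$xy_bound,
                            sigma_bounds = fitc$sigma_bounds)
    state$fits <- fits
    write_prf_fits(fits, file.path(out_dir, "prf_fits.tsv"))
    .write_manifest(out_dir, "fit", config, config$seed,
                    list(n_voxels = length(unique(fits$voxel_id)),
                         median_r2 = median(fits$r2)))
  }

  sel_and_records <- function() {
    fits <- need("fits", "gainfield/metrics", load_fits)
    sel <- select_voxels(fits, ecc_max = config$fitting$ecc_max,
                         size_max = config$fitting$size_max,
                         r2_min = config$fitting$r2_min)
    list(sel = sel, records = shift_records(sel$fits, "AttendStimulus"))
  }

  if ("gainfield" %in% stages) {
    sr <- sel_and_records()
    vecs <- bin_shift_vectors_quadrant(sr$records,
                                       n_bins = config$model$n_bins,
                                       ecc_max = config$fitting$ecc_max)
    gf <- fit_af_sizes(vecs, des$dm_fine,
                       fix_range = config$model$fix_range,
                       stim_range = config$model$stim_range,
                       grid_n = config$model$grid_n)
    state$gf <- gf
    surf <- expand.grid(sigma_fix = gf$sigma_fix_values,
                        sigma_stim = gf$sigma_stim_values)
    surf$objective <- as.vector(gf$surface)
    .write_tsv(surf, file.path(out_dir, "af_surface.tsv"))
    jsonlite::write_json(
      list(sigma_fix = gf$sigma_fix,
           sigma_stim_kernel = gf$sigma_stim_kernel,
           effective_stim_size = gf$effective_stim_size,
           objective = gf$objective, n_vectors = gf$n_vectors,
           n_empty_bins = attr(vecs, "n_empty")),
      file.path(out_dir, "af_fit.json"), auto_unbox = TRUE, digits = NA)
    .write_manifest(out_dir, "gainfield", config, config$seed,
                    list(n_vectors = gf$n_vectors,
                         rejection = as.list(setNames(
                           sr$sel$log$n_excluded, sr$sel$log$criterion))))
  }

  if ("metrics" %in% stages) {
    sr <- sel_and_records()
    dec <- decompose_shift_directions(sr$records,
                                      n_boot = config$stats$n_boot)
    ami <- compute_feature_ami(sr$sel$fits)
    esc <- ecc_size_change_analysis(sr$sel$fits,
                                    n_boot = config$stats$n_boot,
                                    outlier_k = config$stats$k_mad)
    .write_tsv(dec$ratios, file.path(out_dir, "shift_ratios.tsv"))
    .write_tsv(ami, file.path(out_dir, "feature_ami.tsv"))
    .write_tsv(esc$profile, file.path(out_dir, "ecc_size_profile.tsv"))
    state$metrics <- list(dec = dec, ami = ami, esc = esc)
    .write_manifest(out_dir, "metrics", config, config$seed,
                    list(n_records = nrow(sr$records)))
  }

  if ("report" %in% stages) {
    sr <- sel_and_records()
    mt <- state$metrics
    af_json <- file.path(out_dir, "af_fit.json")
    rep <- list(
      n_frames = nrow(des$seq$frames),
      run_duration_s = run_duration(des$seq),
      n_voxels_fit = sr$sel$n_total, n_voxels_selected = sr$sel$n_kept,
      af_fit = if (!is.null(state$gf))
        list(sigma_fix = state$gf$sigma_fix,
             sigma_stim_kernel = state$gf$sigma_stim_kernel,
             effective_stim_size = state$gf$effective_stim_size)
      else if (file.exists(af_json)) jsonlite::read_json(af_json) else NULL,
      shift_ratios = if (!is.null(mt)) as.list(setNames(
        mt$dec$ratios$estimate, mt$dec$ratios$component)) else NULL,
      mean_feature_ami = if (!is.null(mt))
        mean(mt$ami$feature_ami, na.rm = TRUE) else NULL)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(out_dir, "report", config, config$seed, list())
  }
  invisible(out_dir)
}

#' Read a 4-D NIfTI volume as a voxel time-series table
#'
#' Maps voxels (optionally restricted to a mask) to rows of a time-series
#' matrix, dropping voxels containing non-finite values.
#'
#' @param path Path to a 4-D NIfTI file.
#' @param mask Optional 3-D logical/numeric array (or NIfTI path); nonzero
#'   entries select voxels.
#' @return List with `ts` (frames x voxels matrix), `index` (voxel_id and
#'   i/j/k volume indices) and `n_dropped`.
#' @export
read_external_volume <- function(path, mask = NULL) {
  vol <- RNifti::readNifti(path)
  .stop_if(length(dim(vol)) != 4, "expected a 4-D volume")
  d <- dim(vol)
  if (is.null(mask)) {
    keep <- array(TRUE, d[1:3])
  } else {
    if (is.character(mask)) mask <- RNifti::readNifti(mask)
    .stop_if(!all(dim(mask)[1:3] == d[1:3]),
             "mask shape does not match the volume")
    keep <- array(as.logical(mask != 0), d[1:3])
  }
  idx <- which(keep, arr.ind = TRUE)
  .stop_if(nrow(idx) == 0, "mask selects no voxels")
  ts <- t(apply(idx, 1, function(r) vol[r[1], r[2], r[3], ]))
  ok <- apply(ts, 1, function(v) all(is.finite(v)))
  if (any(!ok)) message(sum(!ok), " voxel(s) with non-finite values dropped")
  list(ts = t(ts[ok, , drop = FALSE]),
       index = data.frame(voxel_id = seq_len(sum(ok)),
                          i = idx[ok, 1], j = idx[ok, 2], k = idx[ok, 3]),
       n_dropped = sum(!ok))
}
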