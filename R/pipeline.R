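#' Extract the full feature stack from a baseline/contrast pair
#'
#' Runs the registration and feature-extraction stages: VOI segmentation,
#' baseline registration (per the configured mode), per-echo intensity and
#' intensity-change maps, R2* fitting, phase unwrapping of both scans,
#' unreliable-phase detection, s-map and p-map, and assembles the
#' standardized feature stack.
#'
#' @param contrast,baseline `multi_echo_dataset`s.
#' @param config `spiolocate_config`.
#' @return List: `stack`, `voi`, `r2star`, `noise_floor`,
#'   `registration` (transform or `NULL`), `baseline_registered`.
#' @export
extract_feature_stack <- function(contrast, baseline, config = default_run_config()) {
  fcfg <- config$features
  voi <- compute_voi(contrast$magnitude[[1]],
                     membership_threshold = fcfg$voi_membership_threshold)
  reg <- NULL
  baseline_reg <- baseline
  if (config$registration$mode == "rigid") {
    reg <- register_rigid(baseline$magnitude[[1]], contrast$magnitude[[1]],
                          bins = config$registration$bins,
                          levels = config$registration$levels)
    baseline_reg <- resample(baseline, reg)
  } else if (config$registration$mode == "nonrigid") {
    rig <- register_rigid(baseline$magnitude[[1]], contrast$magnitude[[1]],
                          bins = config$registration$bins,
                          levels = config$registration$levels)
    reg <- register_nonrigid(baseline$magnitude[[1]], contrast$magnitude[[1]],
                             init = rig)
    baseline_reg <- resample(baseline, reg)
  }
  rho <- signal_intensity(contrast)
  drho <- delta_rho(contrast, baseline_reg)
  noise_floor <- estimate_noise_floor(contrast, voi, fcfg$noise_floor_factor)
  r2s <- fit_r2star(contrast, noise_floor)
  phi <- unwrap_dataset_phases(contrast, voi)
  baseline_phi <- unwrap_dataset_phases(baseline_reg, voi)
  unrel <- unreliable_phase_mask(phi, contrast$protocol,
                                 residual_tol = fcfg$unreliable_residual_tol,
                                 intercept_tol = fcfg$unreliable_intercept_tol,
                                 voi = voi)
  e_s <- min(fcfg$s_echo, n_echoes(contrast))
  sdiff <- vol_like(phi$phase[[e_s]],
                    ifelse(is.na(phi$phase[[e_s]]$data - baseline_phi$phase[[e_s]]$data), 0,
                           phi$phase[[e_s]]$data - baseline_phi$phase[[e_s]]$data))
  s_map <- short_range_perturbations(sdiff, voi, band = fcfg$band_pass_periods,
                                     echo_used = contrast$protocol$echo_times[e_s])
  p_map <- perturbation_propagation(phi, baseline_phi, voi,
                                    band = fcfg$band_pass_periods)
  stack <- assemble_features(rho, drho, r2s, phi, baseline_phi, unrel,
                             s_map, p_map, voi)
  list(stack = stack, voi = voi, r2star = r2s, noise_floor = noise_floor,
       registration = reg, baseline_registered = baseline_reg)
}

#' Run the complete localization pipeline on one simulated phantom
#'
#' Simulate (or accept) a baseline/contrast pair, extract features, train
#' the SVM on a labeled subsample (or apply a pre-trained model), classify
#' all VOI voxels, convert R2* of positive voxels to concentration, and
#' evaluate against ground truth.
#'
#' @param config `spiolocate_config`.
#' @param study optional pre-simulated study (as from
#'   [simulate_phantom_study()]); simulated from the config when `NULL`.
#' @param model optional pre-trained `svm_model` (skips training).
#' @param calibration optional pre-fit `calibration_model` (otherwise fit on
#'   this phantom's truth).
#' @param out_dir optional directory; when given, intermediate volumes and
#'   the run manifest are written there.
#' @return List: `result` (`localization_result`), `report`
#'   (`evaluation_report`), `model`, `calibration`, `stack`, `study`,
#'   `manifest`.
#' @export
run_full_pipeline <- function(config = default_run_config(), study = NULL,
                              model = NULL, calibration = NULL, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- t1 - t0
    t0 <<- t1
  }
  if (is.null(study)) study <- simulate_phantom_study(config)
  tick("simulate")
  fx <- withCallingHandlers(
    extract_feature_stack(study$contrast, study$baseline, config),
    error = function(e) stop("pipeline stage 'extract' failed: ", conditionMessage(e)))
  tick("extract")
  if (is.null(model)) {
    training <- sample_training_set(fx$stack, study$truth$positive_mask,
                                    fraction = config$svm$fraction,
                                    seed = config$seed,
                                    stratified = config$svm$stratified)
    model <- train_svm(training, cost_grid = config$svm$cost_grid,
                       gamma_grid = config$svm$gamma_grid,
                       cv_folds = config$svm$cv_folds,
                       cv_max_samples = config$svm$cv_max_samples,
                       seed = config$seed)
  }
  tick("train")
  positives <- predict_voxels(fx$stack, model)
  tick("predict")
  if (is.null(calibration))
    calibration <- fit_calibration(fx$r2star, study$truth, voi = fx$voi)
  conc <- concentration_from_r2star(fx$r2star, calibration)
  result <- build_localization_result(positives, conc$concentration)
  tick("concentration")
  report <- evaluate_result(result, study$truth, fx$voi,
                            shell_width = config$evaluation$shell_width,
                            attribution_distance = config$evaluation$attribution_distance)
  tick("evaluate")
  manifest <- list(config = config, seed = config$seed,
                   stage_seconds = as.list(stage_times),
                   n_voi_voxels = sum(fx$voi$data),
                   svm = list(cost = model$cost, gamma = model$gamma,
                              n_support = model$n_support),
                   calibration = list(intercept = calibration$intercept_r2star,
                                      slope = calibration$slope_relaxivity))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(study$contrast, file.path(out_dir, "contrast"))
    write_dataset(study$baseline, file.path(out_dir, "baseline"))
    write_volume_file(study$truth$concentration, file.path(out_dir, "truth_concentration.nii.gz"))
    write_volume_file(fx$voi, file.path(out_dir, "voi.nii.gz"))
    write_volume_file(fx$r2star$r2star, file.path(out_dir, "r2star.nii.gz"))
    write_volume_file(result$positives, file.path(out_dir, "positives.nii.gz"))
    write_volume_file(result$concentration, file.path(out_dir, "concentration.nii.gz"))
    utils::write.csv(report$per_inlay, file.path(out_dir, "report.csv"), row.names = FALSE)
    yaml::write_yaml(manifest_serializable(manifest), file.path(out_dir, "run.yaml"))
  }
  list(result = result, report = report, model = model, calibration = calibration,
       stack = fx$stack, voi = fx$voi, r2star = fx$r2star, study = study,
       manifest = manifest)
}

manifest_serializable <- function(m) {
  m$config <- unclass(m$config)
  rapply(m, function(x) if (is.numeric(x)) as.numeric(x) else x, how = "replace")
}

#' Train-on-A / evaluate-on-B transfer experiment
#'
#' Trains the SVM (and the R2*-to-concentration calibration) on one
#' simulated phantom and applies the pre-trained model, without retraining,
#' to an independently seeded second phantom — returning the training
#' phantom's self-consistency report and the evaluation phantom's report.
#'
#' @param train_config,eval_config `spiolocate_config`s; they should differ
#'   at least in `seed`.
#' @return List: `training` (full pipeline output on phantom A),
#'   `evaluation` (output on phantom B using A's model and calibration).
#' @export
run_transfer_experiment <- function(train_config = default_run_config(),
                                    eval_config = NULL) {
  if (is.null(eval_config)) {
    eval_config <- train_config
    eval_config$seed <- train_config$seed + 1L
  }
  if (identical(train_config$seed, eval_config$seed))
    stop("run_transfer_experiment: training and evaluation seeds must differ")
  training <- run_full_pipeline(train_config)
  evaluation <- run_full_pipeline(eval_config, model = training$model,
                                  calibration = training$calibration)
  list(training = training, evaluation = evaluation)
}
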