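#' Default pipeline configuration
#'
#' All tunable parameters of the localization pipeline with their defaults:
#' acquisition protocol, phantom/noise settings, contrast (relaxivity /
#' susceptibility) model, feature-extraction thresholds, registration and SVM
#' settings, and evaluation conventions.
#'
#' @return Nested named list (class `spiolocate_config`).
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    protocol = list(
      echo_times = c(2.54, 3.78, 11.34),  # ms
      repetition_time = 200,              # ms
      flip_angle = 25,                    # degrees
      field_strength = 4.7,               # tesla
      voxel_size = c(0.4, 0.4, 0.4),      # mm
      matrix_size = c(64L, 128L, 32L)
    ),
    phantom = list(
      spec = "paper-block",      # "paper-block", "invivo-like", or a YAML path
      noise_sigma = 0.05         # complex noise sd, fraction of background magnitude
    ),
    contrast = list(
      r2star_relaxivity = 0.6,               # 1/s per uM Fe2O3
      susceptibility_per_concentration = 0.006,  # ppm per uM
      per_cell_iron_load = 90                # pg per cell
    ),
    features = list(
      noise_floor_factor = 2,        # x background-air magnitude median
      voi_membership_threshold = 0.5,
      band_pass_periods = c(2, 10),  # spatial periods (voxels) passed
      s_echo = 2L,                   # echo used for the s-map
      unreliable_residual_tol = 0.15, # rad RMS of the phase-vs-TE fit
      unreliable_intercept_tol = 0.25,# rad deviation from smoothed intercept
      source_threshold = 0.3         # rad, |s| threshold for source localization
    ),
    registration = list(
      mode = "rigid",   # "none", "rigid", "nonrigid"
      bins = 32L,
      levels = 3L
    ),
    svm = list(
      fraction = 0.15,
      cost_grid = 2^seq(-3, 9, by = 2),
      gamma_grid = 2^seq(-9, 3, by = 2),
      cv_folds = 5L,
      cv_max_samples = 4000L,
      stratified = FALSE
    ),
    evaluation = list(
      shell_width = 3L,          # background shell around each inlay (voxels)
      attribution_distance = 3L  # positives within this of an inlay attribute to it
    )
  ), class = "spiolocate_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, overlays it on [default_run_config()],
#' and validates it: unknown keys and out-of-range values are errors.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged on top (same structure), mostly for
#'   programmatic use.
#' @return Validated `spiolocate_config`.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::yaml.load_file(path)
    cfg <- merge_config(cfg, user, "config")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, where) {
  if (is.null(user)) return(base)
  if (!is.list(user)) stop(sprintf("load_run_config: %s must be a mapping", where))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("load_run_config: unknown key(s) %s under '%s'; valid keys: %s",
                 paste(unknown, collapse = ", "), where,
                 paste(names(base), collapse = ", ")))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], k)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # constructing the protocol enforces echo-time / voxel-size invariants
  do.call(acquisition_protocol, cfg$protocol)
  with(cfg, {
    if (phantom$noise_sigma < 0) stop("config: phantom.noise_sigma must be >= 0")
    if (contrast$r2star_relaxivity <= 0) stop("config: contrast.r2star_relaxivity must be > 0")
    if (features$noise_floor_factor < 0) stop("config: features.noise_floor_factor must be >= 0")
    bp <- features$band_pass_periods
    if (length(bp) != 2 || bp[1] <= 0 || bp[2] <= bp[1])
      stop("config: features.band_pass_periods must be an increasing positive pair")
    if (!registration$mode %in% c("none", "rigid", "nonrigid"))
      stop("config: registration.mode must be none/rigid/nonrigid")
    if (registration$bins < 2) stop("config: registration.bins must be >= 2")
    if (svm$fraction <= 0 || svm$fraction > 1) stop("config: svm.fraction must be in (0, 1]")
    if (!length(svm$cost_grid) || !length(svm$gamma_grid) ||
        any(svm$cost_grid <= 0) || any(svm$gamma_grid <= 0))
      stop("config: svm grids must be nonempty and positive")
    if (svm$cv_folds < 2) stop("config: svm.cv_folds must be >= 2")
    if (evaluation$shell_width < 1) stop("config: evaluation.shell_width must be >= 1")
  })
  invisible(cfg)
}

# Protocol object from a config.
config_protocol <- function(cfg) do.call(acquisition_protocol, cfg$protocol)
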