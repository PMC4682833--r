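GYROMAGNETIC_RATIO <- 2.67513e8  # rad/s/T for protons

#' Noise specification
#' @param complex_noise_sigma sd of the complex Gaussian noise added to each
#'   of the real and imaginary channels, as a fraction of the background
#'   proton density (signal scale).
#' @param seed integer seed; the baseline draw uses a derived independent seed.
#' @return `noise_spec` object.
#' @export
noise_spec <- function(complex_noise_sigma = 0.05, seed = 1L) {
  if (complex_noise_sigma < 0) stop("noise_spec: sigma must be >= 0")
  structure(list(complex_noise_sigma = complex_noise_sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# FFT frequencies (cycles per mm) for one axis.
fft_freqs <- function(n, spacing) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / (n * spacing)
}

#' Susceptibility-induced dipole phase field
#'
#' Converts the ground-truth concentration map into a susceptibility map,
#' convolves it with the unit dipole kernel in the Fourier domain
#' (`1/3 - kz^2/|k|^2` with the k = 0 term set to zero, kz along B0) and
#' scales by gyromagnetic ratio, B0 and echo time. Linear in both
#' concentration and TE; has zero spatial mean.
#'
#' @param truth `phantom_truth`.
#' @param model `contrast_model`.
#' @param protocol `acquisition_protocol`.
#' @param te echo time, ms.
#' @return `scalar_volume` of phase in radians (not wrapped).
#' @export
dipole_phase_field <- function(truth, model, protocol, te) {
  if (te <= 0) stop("dipole_phase_field: te must be > 0")
  conc <- truth$concentration
  chi <- conc$data * model$susceptibility_per_concentration * 1e-6  # dimensionless
  d <- dim(chi)
  kx <- fft_freqs(d[1], protocol$voxel_size[1])
  ky <- fft_freqs(d[2], protocol$voxel_size[2])
  kz <- fft_freqs(d[3], protocol$voxel_size[3])
  KX <- array(rep(kx, times = d[2] * d[3]), d)
  KY <- array(rep(rep(ky, each = d[1]), times = d[3]), d)
  KZ <- array(rep(kz, each = d[1] * d[2]), d)
  b0 <- protocol$b0_direction
  kpar <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
  k2 <- KX^2 + KY^2 + KZ^2
  D <- 1 / 3 - kpar^2 / ifelse(k2 > 0, k2, 1)
  D[1, 1, 1] <- 0
  field <- Re(stats::fft(stats::fft(chi) * D, inverse = TRUE)) / prod(d)
  phase <- GYROMAGNETIC_RATIO * protocol$field_strength * field * (te * 1e-3)
  vol_like(conc, phase)
}

# Proton density and R2* arrays for a spec (+ truth concentration) on a grid.
phantom_tissue_maps <- function(spec, truth, protocol) {
  block <- block_mask_array(spec, protocol)
  d <- dim(block)
  pd <- ifelse(block, spec$background_proton_density, 0)
  r2s <- ifelse(block, spec$background_r2star, 0)
  if (length(spec$low_density_regions)) {
    vs <- protocol$voxel_size
    origin <- -d * vs / 2 + vs / 2
    xs <- origin[1] + (seq_len(d[1]) - 1) * vs[1]
    ys <- origin[2] + (seq_len(d[2]) - 1) * vs[2]
    zs <- origin[3] + (seq_len(d[3]) - 1) * vs[3]
    X <- array(rep(xs, times = d[2] * d[3]), d)
    Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
    Z <- array(rep(zs, each = d[1] * d[2]), d)
    for (rg in spec$low_density_regions) {
      inside <- (X - rg$center[1])^2 + (Y - rg$center[2])^2 + (Z - rg$center[3])^2 <=
        rg$radius^2
      pd[inside & block] <- pd[inside & block] * rg$pd_multiplier
      extra <- if (!is.null(rg$extra_r2star)) rg$extra_r2star else 0
      r2s[inside & block] <- r2s[inside & block] + extra
    }
  }
  r2s <- r2s + 0  # background concentration contribution added by caller
  list(pd = pd, r2star = r2s)
}

# Slow spatially varying background phase at a given TE (ms): a constant
# receiver phase plus a low-order off-resonance ramp (a few Hz across the FOV).
background_phase <- function(dims, te_ms, receiver_phase = 0.3, f0_span_hz = 8) {
  gx <- (seq_len(dims[1]) - 1) / max(dims[1] - 1, 1) - 0.5
  gy <- (seq_len(dims[2]) - 1) / max(dims[2] - 1, 1) - 0.5
  f0 <- outer(outer(gx * 0.6, gy, "+"), rep(0, dims[3]), "+") * f0_span_hz
  receiver_phase + 2 * pi * f0 * te_ms * 1e-3
}

#' Synthesize a baseline/contrast pair of multi-echo datasets
#'
#' Standard spoiled gradient-echo forward model: per voxel and echo the
#' complex signal is
#' `pd * exp(-(R2*_bg + relaxivity * c) * TE) * exp(i (phi_bg + phi_dipole))`
#' plus seeded complex Gaussian noise; magnitude is the modulus (Rician) and
#' phase is wrapped into `[-pi, pi)`. The baseline is generated identically
#' with zero concentration and an independently seeded noise draw.
#'
#' @param truth `phantom_truth`.
#' @param spec `phantom_spec` (tissue background; usually `truth$spec`).
#' @param model `contrast_model`.
#' @param protocol `acquisition_protocol`.
#' @param noise `noise_spec`.
#' @param return_truth_phase if `TRUE`, attach the noiseless pre-wrap phase
#'   (per echo) as `truth_phase` for diagnostic use.
#' @return List with elements `baseline` and `contrast`
#'   (`multi_echo_dataset`s), and optionally `truth_phase`.
#' @export
synthesize_dataset <- function(truth, spec = truth$spec, model = contrast_model(),
                               protocol = NULL, noise = noise_spec(),
                               return_truth_phase = FALSE) {
  if (is.null(protocol))
    protocol <- acquisition_protocol(matrix_size = dim(truth$concentration$data),
                                     voxel_size = truth$concentration$voxel_size)
  tissue <- phantom_tissue_maps(spec, truth, protocol)
  vs <- protocol$voxel_size
  origin <- truth$concentration$origin
  dims <- protocol$matrix_size
  make_one <- function(conc_arr, seed, role) {
    rs <- local_rng(seed)
    r2s <- tissue$r2star + model$r2star_relaxivity * conc_arr
    mags <- phs <- vector("list", length(protocol$echo_times))
    tp <- vector("list", length(protocol$echo_times))
    use_dipole <- any(conc_arr != 0)
    for (e in seq_along(protocol$echo_times)) {
      te <- protocol$echo_times[e]
      amp <- tissue$pd * exp(-r2s * te * 1e-3)
      ph <- background_phase(dims, te)
      if (use_dipole) {
        tr2 <- truth
        tr2$concentration$data <- conc_arr
        ph <- ph + dipole_phase_field(tr2, model, protocol, te)$data
      }
      sigma <- noise$complex_noise_sigma * spec$background_proton_density
      re <- amp * cos(ph); im <- amp * sin(ph)
      if (sigma > 0) {
        re <- re + array(rs$rnorm(prod(dims), 0, sigma), dims)
        im <- im + array(rs$rnorm(prod(dims), 0, sigma), dims)
      }
      mags[[e]] <- scalar_volume(sqrt(re^2 + im^2), vs, origin)
      phs[[e]] <- scalar_volume(wrap_angle(atan2(im, re)), vs, origin)
      tp[[e]] <- ph
    }
    list(ds = multi_echo_dataset(protocol, mags, phs, role = role), truth_phase = tp)
  }
  contrast <- make_one(truth$concentration$data, noise$seed, "contrast")
  baseline <- make_one(array(0, dims), noise$seed + 1000003L, "baseline")
  out <- list(baseline = baseline$ds, contrast = contrast$ds)
  if (return_truth_phase) out$truth_phase <- contrast$truth_phase
  out
}

#' Apply a rigid misalignment to a dataset
#'
#' Resamples every echo of a dataset under a rigid transform, acting on the
#' complex representation so wrapped-phase discontinuities are not
#' interpolated across. Intended for constructing registration test cases.
#'
#' @param dataset `multi_echo_dataset`.
#' @param transform `rigid_transform`.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return Misaligned `multi_echo_dataset`.
#' @export
apply_rigid_misalignment <- function(dataset, transform,
                                     mode = c("trilinear", "nearest")) {
  resample(dataset, transform, mode = match.arg(mode), fill = 0)
}

#' Simulate a complete phantom study
#'
#' Convenience wrapper: build the phantom truth for a named or explicit spec
#' and synthesize the baseline/contrast datasets.
#'
#' @param config `spiolocate_config` (see [load_run_config()]).
#' @param seed overrides `config$seed` when given.
#' @return List: `truth`, `baseline`, `contrast`, `protocol`, `model`.
#' @export
simulate_phantom_study <- function(config = default_run_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  protocol <- config_protocol(config)
  model <- do.call(contrast_model, config$contrast)
  spec <- config$phantom$spec
  if (is.character(spec)) {
    spec <- switch(spec,
      "paper-block" = paper_block_spec(model),
      "invivo-like" = build_invivo_like_spec(config$seed, model),
      {
        if (!file.exists(spec)) stop("simulate_phantom_study: unknown phantom spec: ", spec)
        phantom_spec_from_yaml(spec, model)
      })
  }
  truth <- build_phantom_truth(spec, protocol)
  sim <- synthesize_dataset(truth, spec, model, protocol,
                            noise_spec(config$phantom$noise_sigma, config$seed))
  list(truth = truth, baseline = sim$baseline, contrast = sim$contrast,
       protocol = protocol, model = model)
}

# Read a phantom spec from YAML (block_size, background, inlays with
# center/radius/height/cell_density).
phantom_spec_from_yaml <- function(path, model = contrast_model()) {
  y <- yaml::yaml.load_file(path)
  inlays <- lapply(y$inlays, function(il)
    inlay_spec(center = as.numeric(il$center), radius = il$radius,
               height = il$height, cell_density = il$cell_density,
               iron_concentration = il$iron_concentration, model = model))
  phantom_spec(block_size = as.numeric(y$block_size), inlays = inlays,
               background_r2star = y$background_r2star %||% 20,
               background_proton_density = y$background_proton_density %||% 1,
               low_density_regions = y$low_density_regions %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
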