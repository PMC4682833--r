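#' Wrapped phase of complex data
#'
#' Quadrant-aware arctangent of (Im, Re), in `[-pi, pi)`, per echo.
#'
#' @param re,im 3D arrays (or `scalar_volume`s) of real and imaginary parts.
#' @return `scalar_volume` (or array if inputs are arrays) of phase.
#' @export
wrapped_phase <- function(re, im) {
  if (inherits(re, "scalar_volume")) {
    return(vol_like(re, wrap_angle(atan2(im$data, re$data))))
  }
  wrap_angle(atan2(im, re))
}

#' 3D phase unwrapping by best-pair-first region merging
#'
#' Every in-mask voxel starts as its own region; adjacent region pairs are
#' merged best-first by boundary quality (mean of the two voxels' quality,
#' typically magnitude), adding the integer multiple of 2 pi that minimizes
#' the phase step across the merged boundary. The result is congruent to the
#' input modulo 2 pi and is defined only inside the mask (NA outside).
#'
#' @param wrapped `scalar_volume`, radians in `[-pi, pi)`.
#' @param quality `scalar_volume` on the same grid (higher = merged earlier).
#' @param mask `mask_volume`; must be nonempty.
#' @return `scalar_volume` of unwrapped phase.
#' @export
unwrap_phase_3d <- function(wrapped, quality, mask) {
  stop_if_grid_mismatch(wrapped, quality, "unwrap inputs")
  stop_if_grid_mismatch(wrapped, mask, "unwrap inputs")
  if (!any(mask$data)) stop("unwrap_phase_3d: empty mask")
  out <- cpp_unwrap_region_merge(as.vector(wrapped$data), as.vector(quality$data),
                                 as.vector(mask$data), dim(wrapped$data))
  vol_like(wrapped, out)
}

#' Unwrapped phase set for a dataset
#'
#' Unwraps every echo of a dataset inside the VOI using the per-echo
#' magnitude as quality, and records the per-echo reference offset (the
#' VOI-median unwrapped phase, for reporting only).
#'
#' @param dataset `multi_echo_dataset`.
#' @param voi `mask_volume`.
#' @return `unwrapped_phase_set`: `phase` (list of `scalar_volume`),
#'   `reference_offset`, `echo_times`.
#' @export
unwrap_dataset_phases <- function(dataset, voi) {
  ne <- n_echoes(dataset)
  phase <- vector("list", ne)
  offs <- numeric(ne)
  for (e in seq_len(ne)) {
    u <- unwrap_phase_3d(dataset$phase_wrapped[[e]], dataset$magnitude[[e]], voi)
    # anchor the arbitrary global 2 pi multiple of each echo to the wrapped
    # branch: otherwise the per-echo offsets corrupt the phase-vs-TE fits
    # (and the baseline subtraction) by echo-dependent constants
    k <- round(stats::median((u$data - dataset$phase_wrapped[[e]]$data)[voi$data]) /
                 (2 * pi))
    u$data <- u$data - 2 * pi * k
    offs[e] <- 2 * pi * k
    phase[[e]] <- u
  }
  structure(list(phase = phase, reference_offset = offs,
                 echo_times = dataset$protocol$echo_times),
            class = "unwrapped_phase_set")
}

# Per-voxel linear fit of unwrapped phase vs TE: returns slope (rad/ms),
# intercept (rad, at TE = 0) and RMS residual arrays.
phase_te_fit <- function(unwrapped, echo_times) {
  ne <- length(echo_times)
  dims <- dim(unwrapped$phase[[1]]$data)
  nv <- prod(dims)
  P <- vapply(unwrapped$phase, function(v) as.vector(v$data), numeric(nv))
  te <- echo_times
  tbar <- mean(te)
  stt <- sum((te - tbar)^2)
  pbar <- rowMeans(P)
  slope <- as.vector(P %*% (te - tbar)) / stt
  intercept <- pbar - slope * tbar
  pred <- intercept + outer(slope, te)
  rms <- sqrt(rowMeans((P - pred)^2))
  list(slope = array(slope, dims), intercept = array(intercept, dims),
       rms = array(rms, dims))
}

#' Unreliable-phase mask
#'
#' Fits each voxel's unwrapped phase against echo time by a line and
#' extrapolates to the excitation pulse (TE = 0). A voxel is unreliable when
#' the fit residual exceeds `residual_tol` or its TE = 0 intercept deviates
#' from the locally smoothed intercept field by more than `intercept_tol`.
#'
#' @param unwrapped `unwrapped_phase_set` with >= 3 echoes.
#' @param protocol `acquisition_protocol` (echo times).
#' @param residual_tol rad RMS.
#' @param intercept_tol rad.
#' @param smooth_hw half-width (voxels) of the intercept smoothing box.
#' @param voi optional `mask_volume`; voxels outside are marked reliable.
#' @return `mask_volume` of unreliable voxels.
#' @export
unreliable_phase_mask <- function(unwrapped, protocol, residual_tol = 0.15,
                                  intercept_tol = 0.25, smooth_hw = 2L,
                                  voi = NULL) {
  if (length(protocol$echo_times) < 3L)
    stop("unreliable_phase_mask: at least 3 echoes required")
  fit <- phase_te_fit(unwrapped, protocol$echo_times)
  dims <- dim(fit$intercept)
  inter <- fit$intercept
  if (!is.null(voi)) {
    smooth_ref <- array(fill_outside_mask(ifelse(voi$data, inter, NA), voi$data), dims)
  } else smooth_ref <- inter
  smooth_int <- box_smooth(smooth_ref, smooth_hw)
  unrel <- (fit$rms > residual_tol) | (abs(inter - smooth_int) > intercept_tol)
  unrel[is.na(unrel)] <- TRUE
  if (!is.null(voi)) unrel <- unrel & voi$data
  v1 <- unwrapped$phase[[1]]
  mask_volume(array(unrel, dims), v1$voxel_size, v1$origin)
}

# Radial raised-cosine band-pass transfer function over spatial periods
# [band[1], band[2]] voxels, shoulders one octave wide on each side.
band_pass_filter_3d <- function(dims, band) {
  if (band[1] <= 0 || band[2] <= band[1])
    stop("band_pass_filter_3d: band must be an increasing positive pair of periods")
  f_hi <- 1 / band[1]  # cycles/voxel
  f_lo <- 1 / band[2]
  fx <- fft_freqs(dims[1], 1)
  fy <- fft_freqs(dims[2], 1)
  fz <- fft_freqs(dims[3], 1)
  FX <- array(rep(fx, times = dims[2] * dims[3]), dims)
  FY <- array(rep(rep(fy, each = dims[1]), times = dims[3]), dims)
  FZ <- array(rep(fz, each = dims[1] * dims[2]), dims)
  f <- sqrt(FX^2 + FY^2 + FZ^2)
  H <- array(0, dims)
  lo0 <- f_lo / 2
  up <- f > lo0 & f < f_lo
  H[up] <- 0.5 * (1 - cos(pi * (f[up] - lo0) / (f_lo - lo0)))
  H[f >= f_lo & f <= f_hi] <- 1
  dn <- f > f_hi & f < 2 * f_hi
  H[dn] <- 0.5 * (1 + cos(pi * (f[dn] - f_hi) / f_hi))
  H
}

#' Short-range phase perturbation map (s-map)
#'
#' Frequency-domain raised-cosine band-pass of the unwrapped phase at one
#' echo, isolating the short-range perturbations the nanoparticle dipole
#' fields imprint. Values outside the VOI are filled by inward extrapolation
#' before the transform and the result is restricted to the VOI.
#'
#' @param unwrapped_phase `scalar_volume` of unwrapped phase at one echo.
#' @param voi `mask_volume`.
#' @param band spatial-period pass band in voxels, default `c(2, 10)`.
#' @param echo_used echo time (ms) of the input, carried in the result.
#' @return `perturbation_map`: `s` (`scalar_volume`, radians, 0 outside
#'   VOI), `echo_used`.
#' @export
short_range_perturbations <- function(unwrapped_phase, voi, band = c(2, 10),
                                      echo_used = NA_real_) {
  H <- band_pass_filter_3d(dim(unwrapped_phase$data), band)
  filled <- fill_outside_mask(unwrapped_phase$data, voi$data)
  s <- Re(stats::fft(stats::fft(filled) * H, inverse = TRUE)) / prod(dim(H))
  s[!voi$data] <- 0
  structure(list(s = vol_like(unwrapped_phase, s), echo_used = echo_used),
            class = "perturbation_map")
}

#' Localize perturbation sources
#'
#' Thresholds `|s|`, labels 26-connected components, merges components whose
#' 2-voxel dilations overlap (the positive and negative lobes of one dipole
#' source) and returns the strength-weighted centroid of each merged source.
#'
#' @param s_map `perturbation_map`.
#' @param threshold radians, > 0.
#' @return Data frame: centroid (`x`, `y`, `z`, mm), `strength`
#'   (sum of `|s|`), `voxels`.
#' @export
localize_sources <- function(s_map, threshold) {
  if (threshold <= 0) stop("localize_sources: threshold must be > 0")
  svol <- s_map$s
  mask <- abs(svol$data) >= threshold
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      strength = numeric(0), voxels = integer(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask, 26L)
  merged <- label_components(dilate_mask(mask, 2L, 26L), 26L)
  comp_ids <- sort(unique(lab[lab > 0L]))
  group_of <- vapply(comp_ids, function(id) merged[which(lab == id)[1]], 0L)
  d <- dim(mask)
  xs <- axis_coords(svol, 1); ys <- axis_coords(svol, 2); zs <- axis_coords(svol, 3)
  rows <- lapply(unique(group_of), function(gid) {
    vox <- which(lab > 0L & merged == gid)
    wts <- abs(svol$data[vox])
    ijk <- arrayInd(vox, d)
    data.frame(x = sum(xs[ijk[, 1]] * wts) / sum(wts),
               y = sum(ys[ijk[, 2]] * wts) / sum(wts),
               z = sum(zs[ijk[, 3]] * wts) / sum(wts),
               strength = sum(wts), voxels = length(vox))
  })
  do.call(rbind, rows)
}

#' Perturbation-propagation map (p-map)
#'
#' Per echo, band-passes the baseline-subtracted unwrapped phase; per voxel,
#' fits `|s(TE)|` against TE by a line through the origin. The slope (rad/ms)
#' measures how fast the short-range perturbation grows with echo time —
#' faster growth marks higher-susceptibility sources.
#'
#' @param unwrapped `unwrapped_phase_set` of the contrast scan.
#' @param baseline_unwrapped `unwrapped_phase_set` of the registered baseline.
#' @param voi `mask_volume`.
#' @param band spatial-period pass band, voxels.
#' @return `propagation_map`: `p` (`scalar_volume`, rad/ms).
#' @export
perturbation_propagation <- function(unwrapped, baseline_unwrapped, voi,
                                     band = c(2, 10)) {
  te <- unwrapped$echo_times
  if (!isTRUE(all.equal(te, baseline_unwrapped$echo_times)))
    stop("perturbation_propagation: echo times differ")
  dims <- dim(unwrapped$phase[[1]]$data)
  num <- array(0, dims)
  for (e in seq_along(te)) {
    diffph <- vol_like(unwrapped$phase[[e]],
                       unwrapped$phase[[e]]$data - baseline_unwrapped$phase[[e]]$data)
    diffph$data[is.na(diffph$data)] <- 0
    s_e <- short_range_perturbations(diffph, voi, band = band, echo_used = te[e])
    num <- num + te[e] * abs(s_e$s$data)
  }
  p <- num / sum(te^2)
  structure(list(p = vol_like(unwrapped$phase[[1]], p)), class = "propagation_map")
}
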