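#' Per-echo signal intensity
#'
#' The magnitude volumes of a dataset (modulus of the complex signal),
#' validated to be non-negative.
#'
#' @param dataset `multi_echo_dataset`.
#' @return List of `scalar_volume`, one per echo.
#' @export
signal_intensity <- function(dataset) {
  for (m in dataset$magnitude)
    if (any(m$data < 0)) stop("signal_intensity: magnitude must be >= 0")
  dataset$magnitude
}

#' Volume of interest by spatial fuzzy clustering
#'
#' Two-class fuzzy c-means on (intensity, neighborhood-mean intensity)
#' channels of the first-echo magnitude, thresholded on the object-class
#' membership, followed by largest-connected-component selection and hole
#' filling — so signal voids inside the object (e.g. strong SPIO inlays)
#' remain part of the VOI while air background is excluded.
#'
#' @param magnitude_first_echo `scalar_volume`.
#' @param membership_threshold object-class membership cutoff (default 0.5).
#' @param fuzziness FCM fuzziness exponent m.
#' @param max_iter,tol FCM iteration controls.
#' @return `mask_volume`.
#' @export
compute_voi <- function(magnitude_first_echo, membership_threshold = 0.5,
                        fuzziness = 2, max_iter = 100L, tol = 1e-5) {
  arr <- magnitude_first_echo$data
  if (max(arr) == min(arr)) stop("compute_voi: constant volume is degenerate")
  sc <- max(arr)
  f1 <- as.vector(arr) / sc
  f2 <- as.vector(box_smooth(arr, 1L)) / sc
  X <- cbind(f1, f2)
  # init centers from intensity quantiles (robust to class imbalance)
  c_lo <- stats::quantile(f1, 0.05); c_hi <- stats::quantile(f1, 0.95)
  centers <- rbind(c(c_lo, c_lo), c(c_hi, c_hi))
  p <- 2 / (fuzziness - 1)
  u_hi <- NULL
  for (it in seq_len(max_iter)) {
    d1 <- (X[, 1] - centers[1, 1])^2 + (X[, 2] - centers[1, 2])^2
    d2 <- (X[, 1] - centers[2, 1])^2 + (X[, 2] - centers[2, 2])^2
    d1 <- pmax(d1, 1e-12); d2 <- pmax(d2, 1e-12)
    r <- (d2 / d1)^(p / 2)
    u2 <- 1 / (1 + 1 / r)  # membership of class 2 (high)
    u1 <- 1 - u2
    w1 <- u1^fuzziness; w2 <- u2^fuzziness
    newc <- rbind(colSums(w1 * X) / sum(w1), colSums(w2 * X) / sum(w2))
    moved <- max(abs(newc - centers))
    centers <- newc
    u_hi <- u2
    if (moved < tol) break
  }
  obj <- if (centers[2, 1] >= centers[1, 1]) u_hi else 1 - u_hi
  mask <- array(obj >= membership_threshold, dim(arr))
  mask <- largest_component(mask, 26L)
  mask <- fill_holes(mask)
  out <- mask_volume(mask, magnitude_first_echo$voxel_size, magnitude_first_echo$origin)
  out
}

#' Hyper-/hypo-intensity change maps
#'
#' Per-echo voxelwise absolute magnitude difference between the contrast scan
#' and the registered baseline.
#'
#' @param contrast `multi_echo_dataset`.
#' @param baseline_registered `multi_echo_dataset` on the same grid and echo
#'   times.
#' @return List of `scalar_volume`, one per echo.
#' @export
delta_rho <- function(contrast, baseline_registered) {
  if (!isTRUE(all.equal(contrast$protocol$echo_times,
                        baseline_registered$protocol$echo_times)))
    stop("delta_rho: echo times differ between contrast and baseline")
  lapply(seq_len(n_echoes(contrast)), function(e) {
    stop_if_grid_mismatch(contrast$magnitude[[e]], baseline_registered$magnitude[[e]],
                          "delta_rho inputs")
    vol_like(contrast$magnitude[[e]],
             abs(contrast$magnitude[[e]]$data - baseline_registered$magnitude[[e]]$data))
  })
}

#' R2* map from multi-echo magnitude decay
#'
#' Voxelwise mono-exponential fit `S(TE) = S0 exp(-R2* TE)` by least squares
#' on the log-magnitude weighted by squared magnitude. Echoes at or below the
#' noise floor are excluded; voxels with fewer than two usable echoes fall
#' back to the two-echo estimate from the first two echoes and are flagged,
#' as are voxels where any excluded echo forced a reduced fit. Negative
#' fitted rates are clamped to zero and flagged.
#'
#' @param dataset `multi_echo_dataset` (>= 2 echoes).
#' @param noise_floor magnitude threshold; echoes with `S <= noise_floor`
#'   are excluded from the fit.
#' @return `r2star_map` object: `r2star` (1/s), `fit_quality` (RMS residual
#'   of log-magnitude), `low_confidence_mask`.
#' @export
fit_r2star <- function(dataset, noise_floor = 0) {
  ne <- n_echoes(dataset)
  if (ne < 2L) stop("fit_r2star: at least 2 echoes required")
  dims <- dim(dataset$magnitude[[1]]$data)
  nv <- prod(dims)
  S <- vapply(dataset$magnitude, function(m) as.vector(m$data), numeric(nv))
  te <- dataset$protocol$echo_times * 1e-3  # seconds
  use <- S > noise_floor
  nuse <- rowSums(use)
  low_conf <- rowSums(!use) > 0
  # voxels with < 2 usable echoes: fall back to the first two echoes
  fallback <- nuse < 2L
  use[fallback, ] <- FALSE
  use[fallback, 1:2] <- TRUE
  logS <- log(pmax(S, .Machine$double.xmin))
  w <- S^2 * use
  sw <- rowSums(w)
  swt <- as.vector(w %*% te)
  swt2 <- as.vector(w %*% te^2)
  swy <- rowSums(w * logS)
  swty <- as.vector(rowSums(w * logS * rep(te, each = nv)))
  denom <- sw * swt2 - swt^2
  slope <- ifelse(denom > 0, (sw * swty - swt * swy) / denom, 0)
  intercept <- ifelse(sw > 0, (swy - slope * swt) / sw, 0)
  r2 <- -slope
  negative <- r2 < 0
  r2[negative] <- 0
  low_conf <- low_conf | negative | (denom <= 0)
  pred <- intercept + outer(slope, te)
  res2 <- rowSums(use * (logS - pred)^2)
  rms <- sqrt(res2 / pmax(nuse, 2))
  vs <- dataset$magnitude[[1]]$voxel_size
  org <- dataset$magnitude[[1]]$origin
  structure(list(
    r2star = scalar_volume(array(r2, dims), vs, org),
    fit_quality = scalar_volume(array(rms, dims), vs, org),
    low_confidence_mask = mask_volume(array(low_conf, dims), vs, org)),
    class = "r2star_map")
}

#' Noise floor estimate from air background
#'
#' `factor` times the median first-echo magnitude outside the VOI.
#'
#' @param dataset `multi_echo_dataset`.
#' @param voi `mask_volume`.
#' @param factor multiplier (default 2).
#' @return Scalar magnitude threshold.
#' @export
estimate_noise_floor <- function(dataset, voi, factor = 2) {
  air <- dataset$magnitude[[1]]$data[!voi$data]
  if (!length(air)) return(0)
  factor * stats::median(air)
}

#' R2*-to-concentration calibration
#'
#' Least-squares line through (inlay concentration, median inlay R2*) pairs
#' including the background point (0, median background R2* away from the
#' inlays). Inlays whose voxels are mostly flagged low-confidence — the
#' signal at the longest echo fell below the noise floor, so their R2* is
#' biased low — are excluded from the fit when enough reliable inlays
#' remain; such concentrations are then read off the extrapolated line and
#' come out underestimated, as expected in the floor-limited regime.
#' Requires at least two distinct nonzero concentrations.
#'
#' @param r2star_map `r2star_map`.
#' @param truth `phantom_truth`.
#' @param voi optional `mask_volume` restricting the background sample.
#' @return `calibration_model`: `intercept_r2star` (1/s),
#'   `slope_relaxivity` (1/s per uM), `fit_points` data frame (with an
#'   `included` flag).
#' @export
fit_calibration <- function(r2star_map, truth, voi = NULL) {
  labels <- truth$inlay_labels
  concs <- vapply(truth$spec$inlays, function(i) i$iron_concentration, 0)
  nz <- which(concs > 0)
  if (length(unique(concs[nz])) < 2L)
    stop("fit_calibration: need >= 2 distinct nonzero inlay concentrations")
  r2 <- r2star_map$r2star$data
  lowconf <- r2star_map$low_confidence_mask$data
  pts_c <- pts_r <- flagged <- numeric(0)
  for (i in nz) {
    vox <- labels == i
    if (!any(vox)) next
    pts_c <- c(pts_c, concs[i])
    pts_r <- c(pts_r, stats::median(r2[vox]))
    flagged <- c(flagged, mean(lowconf[vox]))
  }
  keep <- flagged <= 0.5
  if (length(unique(pts_c[keep])) >= 2L) {
    pts_c_fit <- pts_c[keep]; pts_r_fit <- pts_r[keep]; included <- keep
  } else {
    pts_c_fit <- pts_c; pts_r_fit <- pts_r; included <- rep(TRUE, length(pts_c))
  }
  all_pts <- data.frame(concentration = pts_c, r2star = pts_r, included = included)
  pts_c <- pts_c_fit; pts_r <- pts_r_fit
  if (length(unique(pts_c)) < 2L)
    stop("fit_calibration: need >= 2 distinct nonzero inlay concentrations with voxels")
  bg <- !dilate_mask(truth$positive_mask$data, 2L, 26L)
  if (!is.null(voi)) bg <- bg & voi$data
  if (any(bg)) {
    pts_c <- c(pts_c, 0); pts_r <- c(pts_r, stats::median(r2[bg]))
    all_pts <- rbind(all_pts, data.frame(concentration = 0,
                                         r2star = stats::median(r2[bg]),
                                         included = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, pts_c), pts_r)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope <= 0)
    stop("fit_calibration: non-positive fitted relaxivity")
  structure(list(intercept_r2star = unname(fit$coefficients[1]),
                 slope_relaxivity = unname(slope),
                 fit_points = all_pts),
            class = "calibration_model")
}

#' Convert an R2* map to iron oxide concentration
#'
#' `c = max(0, (R2* - intercept) / slope)` per voxel; the low-confidence flag
#' of the R2* fit travels with the result.
#'
#' @param r2star_map `r2star_map`.
#' @param calibration `calibration_model`.
#' @return List: `concentration` (`scalar_volume`, uM),
#'   `low_confidence_mask`.
#' @export
concentration_from_r2star <- function(r2star_map, calibration) {
  conc <- pmax(0, (r2star_map$r2star$data - calibration$intercept_r2star) /
                 calibration$slope_relaxivity)
  list(concentration = vol_like(r2star_map$r2star, conc),
       low_confidence_mask = r2star_map$low_confidence_mask)
}
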