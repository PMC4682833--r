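#' Rigid transform
#'
#' Rotation (Euler angles, degrees, applied as Rz * Ry * Rx about `center`)
#' followed by translation, in world millimeters: `y = R (x - c) + c + t`.
#' The identity has all-zero parameters.
#'
#' @param rotation length-3 Euler angles (x, y, z), degrees.
#' @param translation length-3, mm.
#' @param center rotation center, mm.
#' @return `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Map world points (n x 3) through the transform / its inverse.
apply_rigid <- function(transform, pts, inverse = FALSE) {
  R <- rotation_matrix(transform$rotation)
  c0 <- transform$center; t0 <- transform$translation
  if (!inverse) t(R %*% (t(pts) - c0) + c0 + t0)
  else t(t(R) %*% (t(pts) - c0 - t0) + c0)
}

#' Invert a rigid transform
#' @param transform `rigid_transform`.
#' @return `rigid_transform` performing the inverse map.
#' @export
invert_rigid <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  # inverse of y = R(x - c) + c + t is x = R^T (y - c) + c - R^T t
  rigid_transform(rotation = euler_from_matrix(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

# Euler angles (degrees, Rz Ry Rx convention) of a rotation matrix.
euler_from_matrix <- function(R) {
  b <- asin(max(min(-R[3, 1], 1), -1))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g) * 180 / pi
}

# Trilinear interpolation at continuous 0-based voxel positions. Positions
# within a rounding epsilon of the boundary are clamped inside rather than
# falling to the fill value.
interp_trilinear <- function(arr, px, py, pz, fill = 0) {
  d <- dim(arr)
  eps <- 1e-9
  out <- rep(fill, length(px))
  inside <- px >= -eps & px <= d[1] - 1 + eps &
            py >= -eps & py <= d[2] - 1 + eps &
            pz >= -eps & pz <= d[3] - 1 + eps
  if (!any(inside)) return(out)
  px <- pmin(pmax(px[inside], 0), d[1] - 1)
  py <- pmin(pmax(py[inside], 0), d[2] - 1)
  pz <- pmin(pmax(pz[inside], 0), d[3] - 1)
  x0 <- pmin(floor(px), d[1] - 2); y0 <- pmin(floor(py), d[2] - 2); z0 <- pmin(floor(pz), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- (arr[idx(x0, y0, z0)] * (1 - fx) + arr[idx(x0 + 1, y0, z0)] * fx) * (1 - fy) * (1 - fz) +
       (arr[idx(x0, y0 + 1, z0)] * (1 - fx) + arr[idx(x0 + 1, y0 + 1, z0)] * fx) * fy * (1 - fz) +
       (arr[idx(x0, y0, z0 + 1)] * (1 - fx) + arr[idx(x0 + 1, y0, z0 + 1)] * fx) * (1 - fy) * fz +
       (arr[idx(x0, y0 + 1, z0 + 1)] * (1 - fx) + arr[idx(x0 + 1, y0 + 1, z0 + 1)] * fx) * fy * fz
  out[inside] <- v
  out
}

interp_nearest <- function(arr, px, py, pz, fill = 0) {
  d <- dim(arr)
  x <- round(px); y <- round(py); z <- round(pz)
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  # round() already absorbs boundary rounding noise for the nearest mode
  out <- rep(fill, length(px))
  out[inside] <- arr[1 + x[inside] + d[1] * (y[inside] + d[2] * z[inside])]
  out
}

# World coordinates (n x 3) of every voxel center of a volume.
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  as.matrix(expand.grid(x = axis_coords(vol, 1), y = axis_coords(vol, 2),
                        z = axis_coords(vol, 3)))
}

# Source 0-based voxel positions for resampling `vol` under `transform`
# (output voxel y samples the input at T^{-1} y).
source_positions <- function(vol, transform) {
  pts <- voxel_centers(vol)
  if (inherits(transform, "rigid_transform")) {
    src <- apply_rigid(transform, pts, inverse = TRUE)
  } else if (inherits(transform, "deformation_field")) {
    src <- pts + cbind(as.vector(transform$displacement[[1]]$data),
                       as.vector(transform$displacement[[2]]$data),
                       as.vector(transform$displacement[[3]]$data))
  } else stop("resample: unsupported transform type")
  sweep(sweep(src, 2, vol$origin), 2, vol$voxel_size, "/")
}

#' Resample a volume or dataset under a transform
#'
#' Volumes are resampled with trilinear (default) or nearest-neighbor
#' interpolation; out-of-field voxels take `fill`. Datasets are resampled in
#' the complex representation (re/im rebuilt from magnitude and phase) and
#' magnitude/phase are re-extracted, so wrapped-phase discontinuities are
#' never interpolated across.
#'
#' @param x `scalar_volume`, `mask_volume`, or `multi_echo_dataset`.
#' @param transform `rigid_transform` or `deformation_field`.
#' @param mode `"trilinear"` or `"nearest"`.
#' @param fill fill value for out-of-field voxels.
#' @return Object of the same type as `x`.
#' @export
resample <- function(x, transform, mode = c("trilinear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  if (inherits(x, "multi_echo_dataset")) {
    pos <- source_positions(x$magnitude[[1]], transform)
    ds <- x
    for (e in seq_len(n_echoes(x))) {
      mag <- x$magnitude[[e]]$data; ph <- x$phase_wrapped[[e]]$data
      if (mode == "nearest") {
        newmag <- interp_nearest(mag, pos[, 1], pos[, 2], pos[, 3], fill = fill)
        newph <- interp_nearest(ph, pos[, 1], pos[, 2], pos[, 3], fill = 0)
      } else {
        re <- mag * cos(ph); im <- mag * sin(ph)
        nre <- interp_trilinear(re, pos[, 1], pos[, 2], pos[, 3], fill = fill)
        nim <- interp_trilinear(im, pos[, 1], pos[, 2], pos[, 3], fill = 0)
        newmag <- sqrt(nre^2 + nim^2)
        newph <- wrap_angle(atan2(nim, nre))
      }
      ds$magnitude[[e]] <- vol_like(x$magnitude[[e]], newmag)
      ds$phase_wrapped[[e]] <- vol_like(x$phase_wrapped[[e]], newph)
    }
    return(ds)
  }
  if (!inherits(x, "scalar_volume")) stop("resample: unsupported input type")
  pos <- source_positions(x, transform)
  arr <- x$data
  is_mask <- inherits(x, "mask_volume")
  if (is_mask) storage.mode(arr) <- "double"
  vals <- if (mode == "nearest") interp_nearest(arr, pos[, 1], pos[, 2], pos[, 3], fill = fill)
          else interp_trilinear(arr, pos[, 1], pos[, 2], pos[, 3], fill = fill)
  if (is_mask) vol_like(x, vals >= 0.5) else vol_like(x, vals)
}

#' Normalized mutual information of two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from the joint intensity histogram
#' (equal-width bins over each image's range); lies in `[1, 2]` and equals 2
#' for identical (or monotonically remapped, up to discretization) images.
#' When used as a registration objective the smoothness in the transform
#' parameters comes from trilinear resampling of the moving image.
#'
#' @param a,b `scalar_volume`s on one grid.
#' @param bins histogram bins per axis (>= 2).
#' @return Scalar NMI.
#' @export
normalized_mutual_information <- function(a, b, bins = 32L) {
  stop_if_grid_mismatch(a, b, "NMI inputs")
  if (bins < 2) stop("normalized_mutual_information: bins must be >= 2")
  av <- as.vector(a$data); bv <- as.vector(b$data)
  keep <- is.finite(av) & is.finite(bv)
  av <- av[keep]; bv <- bv[keep]
  if (max(av) == min(av) || max(bv) == min(bv))
    stop("normalized_mutual_information: constant image has degenerate entropy")
  nmi_from_vectors(av, bv, bins)
}

nmi_from_vectors <- function(av, bv, bins) {
  ia <- pmin(floor((av - min(av)) / (max(av) - min(av)) * bins), bins - 1)
  ib <- pmin(floor((bv - min(bv)) / (max(bv) - min(bv)) * bins), bins - 1)
  h <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  h <- h / sum(h)
  hj <- matrix(h, bins, bins)  # rows = b-bins (fastest), cols = a-bins
  pa_m <- colSums(hj); pb_m <- rowSums(hj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(pa_m) + ent(pb_m)) / ent(h)
}

# Block-average downsampling by integer factor (dims cropped to multiples).
downsample_volume <- function(vol, f) {
  if (f <= 1) return(vol)
  d <- dim(vol$data)
  nd <- pmax(d %/% f, 1L)
  arr <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  m <- array(arr, c(f, nd[1], f, nd[2], f, nd[3]))
  out <- apply(m, c(2, 4, 6), mean)
  scalar_volume(out, vol$voxel_size * f,
                vol$origin + (f - 1) / 2 * vol$voxel_size)
}

#' Rigid registration by normalized mutual information
#'
#' Estimates the rigid transform mapping `moving` into the space of `fixed`
#' by maximizing NMI with a three-level multi-resolution derivative-free
#' (Nelder-Mead direction-set) search over the 6 rigid parameters.
#'
#' @param moving,fixed `scalar_volume`s (typically first-echo magnitudes).
#' @param bins NMI histogram bins.
#' @param levels number of resolution levels (downsampling by 2 per level).
#' @param maxit optimizer iterations per level.
#' @return `rigid_transform` mapping moving into fixed space.
#' @export
register_rigid <- function(moving, fixed, bins = 32L, levels = 3L, maxit = 300L,
                           capture_mm = 2.4) {
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$voxel_size
  par <- rep(0, 6)
  nmi_id <- NULL
  # half resolution carries the search; full resolution polishes. Both are
  # pre-smoothed: noise puts micro-maxima on the NMI landscape otherwise.
  # Small volumes skip the pyramid: a half-resolution histogram over a few
  # thousand voxels is too noisy to steer the search.
  factors <- if (prod(dim(fixed$data)) < 150000 || levels < 2) 1 else c(2, 1)
  for (li in seq_along(factors)) {
    f <- factors[li]
    presmooth <- function(v) { v$data <- box_smooth(v$data, 2L); v }
    mv <- presmooth(downsample_volume(moving, f))
    fx <- presmooth(downsample_volume(fixed, f))
    # evaluate both images on a half-voxel-offset grid so every candidate
    # transform (identity and integer shifts included) incurs the same
    # interpolation blur; otherwise interpolation-free grid-aligned shifts
    # create spurious NMI maxima
    pts_h <- sweep(voxel_centers(fx), 2, fx$voxel_size / 2, "+")
    to_vox <- function(pts, vol) sweep(sweep(pts, 2, vol$origin), 2, vol$voxel_size, "/")
    ph_f <- to_vox(pts_h, fx)
    fx_h <- interp_trilinear(fx$data, ph_f[, 1], ph_f[, 2], ph_f[, 3], fill = 0)
    obj <- function(p) {
      tr <- rigid_transform(rotation = p[1:3], translation = p[4:6], center = center)
      src <- to_vox(apply_rigid(tr, pts_h, inverse = TRUE), mv)
      warped <- interp_trilinear(mv$data, src[, 1], src[, 2], src[, 3], fill = 0)
      -nmi_from_vectors(warped, fx_h, bins)
    }
    first <- li == 1
    finest <- li == length(factors)
    if (first) {
      nmi_id <- -obj(rep(0, 6))
      # direction-set capture: cyclic line searches over translations (and
      # in-plane rotation), two sweeps, before the simplex refinement
      line_step <- max(fx$voxel_size) / 4
      bestv <- obj(par)
      for (sweep_i in 1:2) {
        for (ax in 4:6) {
          cand <- par[ax] + seq(-capture_mm, capture_mm, by = line_step)
          for (cv in cand) {
            p2 <- par; p2[ax] <- cv
            v <- obj(p2)
            if (v < bestv) { bestv <- v; par <- p2 }
          }
        }
        for (cv in par[3] + seq(-4, 4, by = 1)) {
          p2 <- par; p2[3] <- cv
          v <- obj(p2)
          if (v < bestv) { bestv <- v; par <- p2 }
        }
      }
    }
    scale <- c(rep(2, 3), rep(max(fx$voxel_size), 3))
    if (first) {
      res <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(parscale = scale, maxit = maxit,
                                         reltol = 1e-10))
      res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                          control = list(parscale = scale / 5, maxit = maxit,
                                         reltol = 1e-11))
    } else {
      # polish the sub-voxel estimate from the cheaper level
      res <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(parscale = scale / 5, maxit = maxit %/% 2,
                                         reltol = 1e-11))
    }
    par <- res$par
    if (first && -res$value < nmi_id - 1e-6)
      stop("register_rigid: optimization failed to improve NMI over identity at the coarsest level")
  }
  rigid_transform(rotation = par[1:3], translation = par[4:6], center = center)
}

#' Deformation field
#'
#' Dense displacement field in mm: the warped image samples the moving image
#' at `y + d(y)` for output location `y`.
#'
#' @param displacement list of three `scalar_volume`s (x, y, z components).
#' @return `deformation_field` object.
#' @export
deformation_field <- function(displacement) {
  stopifnot(length(displacement) == 3L)
  structure(list(displacement = displacement), class = "deformation_field")
}

# Central-difference gradient of a 3D array, per-axis spacing in mm.
array_gradient <- function(arr, voxel_size) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    plus <- shift_array(arr, -(ax == 1:3))   # value at i+1 (zero-padded)
    minus <- shift_array(arr, (ax == 1:3))   # value at i-1
    g[[ax]] <- (plus - minus) / (2 * voxel_size[ax])
  }
  g
}

#' Non-rigid (demons-style) registration refinement
#'
#' Diffusion-regularized demons refinement after rigid pre-alignment.
#' Returns the total deformation field (including the rigid part) mapping
#' output locations into the original moving image.
#'
#' @param moving,fixed `scalar_volume`s.
#' @param init `rigid_transform` pre-alignment.
#' @param iterations demons iterations per level.
#' @param smooth_hw half-width (voxels) of the field smoothing kernel.
#' @param step_cap maximum update per iteration, voxels.
#' @return `deformation_field`.
#' @export
register_nonrigid <- function(moving, fixed, init = rigid_transform(),
                              iterations = 60L, smooth_hw = 2L, step_cap = 0.4) {
  mv <- resample(moving, init, mode = "trilinear", fill = 0)
  d <- dim(fixed$data)
  vs <- fixed$voxel_size
  u <- lapply(1:3, function(i) array(0, d))  # mm, demons part only
  fgrad <- array_gradient(fixed$data, vs)
  scale2 <- mean(vs)^2
  pts <- voxel_centers(fixed)
  for (it in seq_len(iterations)) {
    src <- pts + cbind(as.vector(u[[1]]), as.vector(u[[2]]), as.vector(u[[3]]))
    posv <- sweep(sweep(src, 2, mv$origin), 2, mv$voxel_size, "/")
    warped <- interp_trilinear(mv$data, posv[, 1], posv[, 2], posv[, 3], fill = 0)
    diffv <- as.vector(fixed$data) - warped
    gsq <- as.vector(fgrad[[1]])^2 + as.vector(fgrad[[2]])^2 + as.vector(fgrad[[3]])^2
    denom <- gsq + diffv^2 / scale2
    fac <- ifelse(denom > 1e-12, diffv / denom, 0)
    for (ax in 1:3) {
      du <- fac * as.vector(fgrad[[ax]])
      cap <- step_cap * vs[ax]
      du <- pmax(pmin(du, cap), -cap)
      u[[ax]] <- box_smooth(array(as.vector(u[[ax]]) + du, d), smooth_hw)
    }
  }
  # compose with the rigid part: total source point = T^{-1}(y + u(y))
  src <- pts + cbind(as.vector(u[[1]]), as.vector(u[[2]]), as.vector(u[[3]]))
  total_src <- apply_rigid(init, src, inverse = TRUE)
  disp <- total_src - pts
  deformation_field(lapply(1:3, function(i)
    scalar_volume(array(disp[, i], d), vs, fixed$origin)))
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of `d(y + d(y))/dy` by central differences; positive
#' everywhere for a diffeomorphic field.
#'
#' @param field `deformation_field`.
#' @return 3D numeric array.
#' @export
jacobian_determinant <- function(field) {
  vs <- field$displacement[[1]]$voxel_size
  d <- dim(field$displacement[[1]]$data)
  J <- array(0, c(d, 3, 3))
  for (i in 1:3) {
    g <- array_gradient(field$displacement[[i]]$data, vs)
    for (j in 1:3) J[, , , i, j] <- g[[j]] + (i == j)
  }
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}
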