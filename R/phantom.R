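#' Cylindrical inlay specification
#'
#' One agarose compartment with iron-oxide-labeled cells: a cylinder with its
#' axis along z, described in world coordinates (mm).
#'
#' @param center length-3 center, mm.
#' @param radius cylinder radius, mm.
#' @param height cylinder height, mm.
#' @param cell_density labeled cells per mm^3.
#' @param iron_concentration uM Fe2O3; if `NULL`, derived from `cell_density`
#'   via [cells_to_concentration()].
#' @param model `contrast_model` used for the derivation.
#' @return `inlay_spec` object.
#' @export
inlay_spec <- function(center, radius, height, cell_density,
                       iron_concentration = NULL, model = contrast_model()) {
  if (radius <= 0 || height <= 0) stop("inlay_spec: radius and height must be > 0")
  if (cell_density < 0) stop("inlay_spec: cell_density must be >= 0")
  if (is.null(iron_concentration))
    iron_concentration <- cells_to_concentration(cell_density, model)
  structure(list(center = as.numeric(center), radius = radius, height = height,
                 cell_density = cell_density,
                 iron_concentration = iron_concentration),
            class = "inlay_spec")
}

#' Phantom specification
#'
#' An agarose block (axis-aligned cuboid centered in the field of view)
#' containing cylindrical labeled-cell inlays, and optionally spherical
#' low-proton-density confounder regions (air/bone analogs) for the
#' in-vivo-like variant.
#'
#' @param block_size length-3, mm.
#' @param inlays list of [inlay_spec()] objects, pairwise disjoint and inside
#'   the block.
#' @param background_r2star background R2* of the agarose, 1/s.
#' @param background_proton_density arbitrary units (sets the signal scale).
#' @param low_density_regions optional list of
#'   `list(center =, radius =, pd_multiplier =, extra_r2star =)` spheres.
#' @return `phantom_spec` object.
#' @export
phantom_spec <- function(block_size, inlays, background_r2star = 20,
                         background_proton_density = 1,
                         low_density_regions = list()) {
  block_size <- as.numeric(block_size)
  if (length(block_size) != 3L || any(block_size <= 0))
    stop("phantom_spec: block_size must be 3 positive numbers")
  for (il in inlays) {
    if (!inherits(il, "inlay_spec")) stop("phantom_spec: inlays must be inlay_spec objects")
    lo <- il$center - c(il$radius, il$radius, il$height / 2)
    hi <- il$center + c(il$radius, il$radius, il$height / 2)
    if (any(lo < -block_size / 2) || any(hi > block_size / 2))
      stop("phantom_spec: inlay extends outside the block")
  }
  if (length(inlays) > 1) {
    for (i in seq_along(inlays)) for (j in seq_along(inlays)) {
      if (j <= i) next
      a <- inlays[[i]]; b <- inlays[[j]]
      rxy <- sqrt(sum((a$center[1:2] - b$center[1:2])^2))
      dz <- abs(a$center[3] - b$center[3])
      if (rxy < a$radius + b$radius && dz < (a$height + b$height) / 2)
        stop("phantom_spec: inlays overlap")
    }
  }
  structure(list(block_size = block_size, inlays = inlays,
                 background_r2star = background_r2star,
                 background_proton_density = background_proton_density,
                 low_density_regions = low_density_regions),
            class = "phantom_spec")
}

#' Contrast model constants
#'
#' Maps iron oxide concentration to its MR effects: R2* relaxivity
#' (1/s per uM), volume susceptibility per concentration (ppm per uM), and
#' the average intracellular iron load used by the analytic cell-to-iron
#' conversion.
#'
#' @param r2star_relaxivity 1/s per uM.
#' @param susceptibility_per_concentration ppm per uM.
#' @param per_cell_iron_load pg Fe2O3 per cell.
#' @return `contrast_model` object.
#' @export
contrast_model <- function(r2star_relaxivity = 0.6,
                           susceptibility_per_concentration = 0.006,
                           per_cell_iron_load = 90) {
  if (r2star_relaxivity <= 0) stop("contrast_model: relaxivity must be > 0")
  structure(list(r2star_relaxivity = r2star_relaxivity,
                 susceptibility_per_concentration = susceptibility_per_concentration,
                 per_cell_iron_load = per_cell_iron_load),
            class = "contrast_model")
}

# Dilution-series lookup: cells/mm^3 -> uM Fe2O3 as used for the phantoms.
CELLS_UM_TABLE <- cbind(cells = c(0, 30, 60, 120, 240, 480),
                        um = c(0, 19, 38, 78, 156, 313))

#' Convert labeled-cell density to iron oxide concentration
#'
#' Default mode interpolates the phantom dilution-series pairs
#' (30, 60, 120, 240, 480 cells/mm^3 <-> 19, 38, 78, 156, 313 uM Fe2O3,
#' plus the origin), extrapolating linearly beyond 480. The `"analytic"` mode
#' computes iron mass per mm^3 from the per-cell load and divides by the
#' Fe2O3 molar mass; it is approximate and does not exactly reproduce the
#' dilution-series pairs.
#'
#' @param cell_density cells per mm^3 (vectorized, >= 0).
#' @param model `contrast_model`.
#' @param mode `"lookup"` (default) or `"analytic"`.
#' @return Concentration in uM Fe2O3.
#' @export
cells_to_concentration <- function(cell_density, model = contrast_model(),
                                   mode = c("lookup", "analytic")) {
  mode <- match.arg(mode)
  if (any(cell_density < 0)) stop("cells_to_concentration: cell_density must be >= 0")
  if (mode == "analytic") {
    molar_mass_fe2o3 <- 159.69  # g/mol
    # cells/mm^3 x pg/cell = pg/mm^3 = ug/L; / (g/mol) = umol/L = uM
    return(cell_density * model$per_cell_iron_load / molar_mass_fe2o3)
  }
  stats::approx(CELLS_UM_TABLE[, "cells"], CELLS_UM_TABLE[, "um"],
                xout = cell_density, rule = 2)$y +
    pmax(cell_density - 480, 0) * (313 - 156) / (480 - 240)
}

#' Detection-limit arithmetic
#'
#' Converts a cell density and voxel size into cells per voxel and iron mass
#' per voxel: e.g. 30 cells/mm^3 in a (0.4 mm)^3 voxel is 1.92, i.e. about
#' 2 cells, carrying 2 x 90 = 180 pg Fe2O3.
#'
#' @param cell_density cells per mm^3.
#' @param voxel_size length-3 voxel size, mm.
#' @param model `contrast_model` (supplies pg per cell).
#' @return List with `cells_per_voxel`, `cells_per_voxel_rounded`,
#'   `iron_pg_per_voxel` (rounded cells x per-cell load).
#' @export
detection_limit <- function(cell_density, voxel_size = c(0.4, 0.4, 0.4),
                            model = contrast_model()) {
  vvol <- prod(voxel_size)
  cpv <- cell_density * vvol
  rounded <- round(cpv)
  list(cells_per_voxel = cpv,
       cells_per_voxel_rounded = rounded,
       iron_pg_per_voxel = rounded * model$per_cell_iron_load)
}

#' Default agarose block phantom specification
#'
#' Five cylindrical inlays in a 2:1 dilution series from 480 down to
#' 30 labeled cells per mm^3 (313 down to 19 uM Fe2O3), evenly spaced along
#' the long axis of an agarose block. The geometry is a scaled version of a
#' physical training block, sized so the default 64 x 128 x 32 grid at
#' 0.4 mm isotropic voxels holds the block with an air margin.
#'
#' @param model `contrast_model` used to attach concentrations.
#' @return `phantom_spec`.
#' @export
paper_block_spec <- function(model = contrast_model()) {
  cells <- c(480, 240, 120, 60, 30)
  centers_y <- seq(-19.2, 19.2, length.out = 5)
  inlays <- lapply(seq_along(cells), function(i)
    inlay_spec(center = c(0, centers_y[i], 0), radius = 4, height = 6.4,
               cell_density = cells[i], model = model))
  phantom_spec(block_size = c(22.4, 48, 10.4), inlays = inlays)
}

#' In-vivo-like phantom specification
#'
#' A heterogeneous-background variant emulating an animal dataset: two
#' labeled-cell inlays (the two injection sites) in opposite halves of the
#' volume, at least two low-proton-density confounder regions (air/bone
#' analogs) with no iron, and a mildly heterogeneous soft-tissue background.
#' Deterministic given `seed`.
#'
#' @param seed integer seed controlling the randomized positions.
#' @param model `contrast_model`.
#' @return `phantom_spec`.
#' @export
build_invivo_like_spec <- function(seed = 1L, model = contrast_model()) {
  rs <- local_rng(seed)
  jitter3 <- function(scale) rs$runif(3, -scale, scale)
  inlays <- list(
    inlay_spec(center = c(0, -12, 0) + jitter3(1.5), radius = 3, height = 5,
               cell_density = 240, model = model),
    inlay_spec(center = c(0, 12, 0) + jitter3(1.5), radius = 3, height = 5,
               cell_density = 480, model = model))
  low <- list(
    list(center = c(-6, -2, 0) + jitter3(1.0), radius = 2.5,
         pd_multiplier = 0.05, extra_r2star = 0),   # air analog
    list(center = c(6, 2, 0) + jitter3(1.0), radius = 2.0,
         pd_multiplier = 0.08, extra_r2star = 10),  # bone analog
    list(center = c(-4, 16, 1) + jitter3(1.0), radius = 3.0,
         pd_multiplier = 0.7, extra_r2star = 8))    # denser soft tissue
  phantom_spec(block_size = c(22.4, 48, 10.4), inlays = inlays,
               background_r2star = 25, low_density_regions = low)
}

# Self-contained RNG stream (does not disturb the global .Random.seed).
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    fn(...)
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n, k) sample.int(n, k)))
}

#' Rasterize a phantom specification into ground truth
#'
#' Builds the ground-truth concentration volume, integer inlay labels
#' (in spec order) and the positive mask on the protocol grid. Voxels are
#' assigned to an inlay when their center-sampled occupancy is at least 50%
#' (estimated on a 3x3x3 subgrid per voxel).
#'
#' @param spec `phantom_spec`.
#' @param protocol `acquisition_protocol`; the grid must cover the block.
#' @return `phantom_truth` object with fields `concentration`
#'   (`scalar_volume`, uM), `inlay_labels` (integer array), `positive_mask`
#'   (`mask_volume`), `spec`.
#' @export
build_phantom_truth <- function(spec, protocol) {
  dims <- protocol$matrix_size
  vs <- protocol$voxel_size
  fov <- dims * vs
  if (any(spec$block_size > fov + 1e-9))
    stop("build_phantom_truth: protocol grid does not cover the block")
  origin <- -fov / 2 + vs / 2  # voxel centers, block centered at 0
  conc <- array(0, dims)
  labels <- array(0L, dims)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vs[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * vs[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vs[3]
  sub <- c(-1, 0, 1) / 3  # 3^3 occupancy subsamples per voxel
  for (i in seq_along(spec$inlays)) {
    il <- spec$inlays[[i]]
    # bounding box in voxel indices (one-voxel pad)
    ix <- which(abs(xs - il$center[1]) <= il$radius + vs[1])
    iy <- which(abs(ys - il$center[2]) <= il$radius + vs[2])
    iz <- which(abs(zs - il$center[3]) <= il$height / 2 + vs[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = ix, y = iy, z = iz)
    occ <- numeric(nrow(g))
    for (sx in sub) for (sy in sub) for (sz in sub) {
      px <- xs[g$x] + sx * vs[1]; py <- ys[g$y] + sy * vs[2]; pz <- zs[g$z] + sz * vs[3]
      inside <- ((px - il$center[1])^2 + (py - il$center[2])^2 <= il$radius^2) &
        (abs(pz - il$center[3]) <= il$height / 2)
      occ <- occ + inside
    }
    occ <- occ / 27
    sel <- occ >= 0.5
    idx <- cbind(g$x[sel], g$y[sel], g$z[sel])
    conc[idx] <- il$iron_concentration
    labels[idx] <- i
  }
  structure(list(
    concentration = scalar_volume(conc, vs, origin),
    inlay_labels = labels,
    positive_mask = mask_volume(conc > 0, vs, origin),
    spec = spec), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d inlays, %d positive voxels, grid %s\n",
              length(x$spec$inlays), sum(x$positive_mask$data),
              paste(dim(x$concentration$data), collapse = "x")))
  invisible(x)
}

# Logical array of block (agarose) voxels for a spec on a protocol grid.
block_mask_array <- function(spec, protocol) {
  dims <- protocol$matrix_size
  vs <- protocol$voxel_size
  fov <- dims * vs
  origin <- -fov / 2 + vs / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vs[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * vs[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vs[3]
  bx <- abs(xs) <= spec$block_size[1] / 2
  by <- abs(ys) <= spec$block_size[2] / 2
  bz <- abs(zs) <= spec$block_size[3] / 2
  outer(outer(bx, by, "&"), bz, "&")
}
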