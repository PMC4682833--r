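#' Scalar and mask volumes
#'
#' Lightweight containers for 3D image grids. A `scalar_volume` holds a 3D
#' numeric array together with its voxel size (mm) and world-space origin
#' (mm, coordinate of the center of voxel index 0 on each axis; voxel indices
#' are 0-based, axes ordered x, y, z, B0 along +z by convention).
#'
#' @param data 3D numeric (or logical for masks) array.
#' @param voxel_size length-3 positive numeric, mm.
#' @param origin length-3 numeric, mm.
#' @return An object of class `scalar_volume` or `mask_volume`.
#' @export
scalar_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("scalar_volume: data must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("scalar_volume: voxel_size must be 3 positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("scalar_volume: origin must be length 3")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "scalar_volume")
}

#' @rdname scalar_volume
#' @export
mask_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask_volume: data must be a 3D array")
  storage.mode(data) <- "logical"
  v <- scalar_volume(array(0, dim(data)), voxel_size, origin)
  v$data <- data
  class(v) <- c("mask_volume", "scalar_volume")
  v
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, voxel %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              class(x)[1], d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

# Construct a like-shaped volume with new data.
vol_like <- function(template, data) {
  v <- template
  v$data <- array(data, dim(template$data))
  if (inherits(template, "mask_volume")) storage.mode(v$data) <- "logical"
  else storage.mode(v$data) <- "double"
  v
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s are on different grids (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x")))
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-9)
    stop(sprintf("%s have different voxel sizes", what))
  invisible(TRUE)
}

# World coordinates (mm) of all voxel centers along one axis.
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$voxel_size[axis]
}

# Mean filter over an axis-aligned box of half-width `hw` voxels (edge-truncated),
# applied separably. Used for spatial fuzzy clustering and intercept smoothing.
box_smooth <- function(arr, hw = 1L) {
  if (hw < 1L) return(arr)
  d <- dim(arr)
  run1 <- function(m, n) {
    # running mean along rows of an (n x k) matrix via cumulative sums
    cs <- rbind(0, apply(m, 2, cumsum))
    i <- seq_len(n)
    lo <- pmax(i - hw, 1L); hi <- pmin(i + hw, n)
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  a <- array(run1(matrix(arr, d[1], d[2] * d[3]), d[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(run1(matrix(a, d[2], d[1] * d[3]), d[2]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(run1(matrix(a, d[3], d[2] * d[1]), d[3]), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

# Shift an array by integer voxels, zero-padded.
shift_array <- function(arr, by, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    b <- by[ax]
    if (abs(b) >= d[ax]) return(out)
    if (b >= 0) { dst[[ax]] <- (1 + b):d[ax]; src[[ax]] <- 1:(d[ax] - b) }
    else        { dst[[ax]] <- 1:(d[ax] + b); src[[ax]] <- (1 - b):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation of a 3D mask
#'
#' Iterated 26-connected (or 6-connected) dilation.
#'
#' @param mask `mask_volume` or logical array.
#' @param iterations number of one-voxel dilation steps.
#' @param connectivity 26 or 6.
#' @return Same type as `mask`.
#' @export
dilate_mask <- function(mask, iterations = 1L, connectivity = 26L) {
  arr <- if (inherits(mask, "scalar_volume")) mask$data else mask
  out <- cpp_binary_dilate(arr, as.integer(iterations), as.integer(connectivity))
  if (inherits(mask, "scalar_volume")) vol_like(mask, out) else out
}

#' Label connected components of a 3D mask
#'
#' @param mask `mask_volume` or logical array.
#' @param connectivity 26 or 6.
#' @return Integer array of component labels (0 = background), labels ordered
#'   by first (column-major) voxel encountered.
#' @export
label_components <- function(mask, connectivity = 26L) {
  arr <- if (inherits(mask, "scalar_volume")) mask$data else mask
  cpp_label_components(arr, as.integer(connectivity))
}

# Largest connected component of a logical array.
largest_component <- function(arr, connectivity = 26L) {
  lab <- cpp_label_components(arr, as.integer(connectivity))
  if (max(lab) == 0L) return(arr & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Fill interior holes: background 6-components not touching the array border.
fill_holes <- function(arr) {
  bg <- cpp_label_components(!arr, 6L)
  d <- dim(arr)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  arr | (bg > 0L & !(bg %in% border_labels))
}

# Fill values outside `mask` by nearest-available-neighbour diffusion so that
# frequency-domain filters see a smoothly extended field.
fill_outside_mask <- function(arr, mask, max_iter = 1000L) {
  known <- mask & is.finite(arr)
  if (!any(known)) stop("fill_outside_mask: no defined voxels")
  vals <- arr
  vals[!known] <- 0
  w <- known * 1
  shifts <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  iter <- 0L
  while (any(w == 0) && iter < max_iter) {
    acc <- array(0, dim(arr)); accw <- array(0, dim(arr))
    for (s in seq_len(nrow(shifts))) {
      acc  <- acc  + shift_array(vals * w, shifts[s, ])
      accw <- accw + shift_array(w, shifts[s, ])
    }
    new <- w == 0 & accw > 0
    vals[new] <- acc[new] / accw[new]
    w[new] <- 1
    iter <- iter + 1L
  }
  vals[w == 0] <- mean(arr[known])
  vals[known] <- arr[known]
  vals
}
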