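#' Acquisition protocol for a multi-echo gradient-echo scan
#'
#' Describes the FLASH-type 3D gradient-echo acquisition: echo times, TR,
#' flip angle, static field strength, grid geometry and B0 direction.
#'
#' @param echo_times strictly increasing echo times, ms (at least 2).
#' @param repetition_time TR in ms.
#' @param flip_angle degrees.
#' @param field_strength tesla.
#' @param voxel_size length-3, mm.
#' @param matrix_size length-3 voxel counts.
#' @param b0_direction unit 3-vector; defaults to +z.
#' @return `acquisition_protocol` object.
#' @export
acquisition_protocol <- function(echo_times = c(2.54, 3.78, 11.34),
                                 repetition_time = 200,
                                 flip_angle = 25,
                                 field_strength = 4.7,
                                 voxel_size = c(0.4, 0.4, 0.4),
                                 matrix_size = c(64L, 128L, 32L),
                                 b0_direction = c(0, 0, 1)) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 2L) stop("acquisition_protocol: at least 2 echoes required")
  if (any(echo_times <= 0)) stop("acquisition_protocol: echo times must be positive")
  if (any(diff(echo_times) <= 0)) stop("acquisition_protocol: echo times must be strictly increasing")
  if (repetition_time <= 0) stop("acquisition_protocol: repetition_time must be positive")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("acquisition_protocol: voxel_size must be 3 positive numbers")
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3L || any(matrix_size < 1L))
    stop("acquisition_protocol: matrix_size must be 3 positive integers")
  b0_direction <- as.numeric(b0_direction)
  nb <- sqrt(sum(b0_direction^2))
  if (length(b0_direction) != 3L || nb == 0) stop("acquisition_protocol: invalid b0_direction")
  structure(list(echo_times = echo_times, repetition_time = repetition_time,
                 flip_angle = flip_angle, field_strength = field_strength,
                 voxel_size = voxel_size, matrix_size = matrix_size,
                 b0_direction = b0_direction / nb),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> TE = {%s} ms, TR = %g ms, flip %g deg, %g T\n",
              paste(x$echo_times, collapse = ", "), x$repetition_time,
              x$flip_angle, x$field_strength))
  cat(sprintf("  grid %s @ %s mm\n", paste(x$matrix_size, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Multi-echo magnitude + phase dataset
#'
#' One magnitude and one wrapped-phase volume per echo, plus the acquisition
#' protocol. Echoes are stored in ascending echo-time order; constructing a
#' dataset with unsorted echo times reorders the volumes accordingly.
#'
#' @param protocol `acquisition_protocol`.
#' @param magnitude list of `scalar_volume`, one per echo; values >= 0.
#' @param phase_wrapped list of `scalar_volume`, radians in `[-pi, pi)`.
#' @param role `"baseline"` or `"contrast"`.
#' @return `multi_echo_dataset` object.
#' @export
multi_echo_dataset <- function(protocol, magnitude, phase_wrapped,
                               role = c("contrast", "baseline")) {
  role <- match.arg(role)
  ne <- length(protocol$echo_times)
  if (length(magnitude) != ne || length(phase_wrapped) != ne)
    stop("multi_echo_dataset: need one magnitude and one phase volume per echo")
  ord <- order(protocol$echo_times)
  if (any(ord != seq_len(ne))) {
    protocol$echo_times <- protocol$echo_times[ord]
    magnitude <- magnitude[ord]
    phase_wrapped <- phase_wrapped[ord]
  }
  d0 <- dim(magnitude[[1]]$data)
  for (e in seq_len(ne)) {
    stop_if_grid_mismatch(magnitude[[e]], magnitude[[1]], "magnitude volumes")
    stop_if_grid_mismatch(phase_wrapped[[e]], magnitude[[1]], "magnitude/phase volumes")
    if (any(magnitude[[e]]$data < 0)) stop("multi_echo_dataset: magnitude must be >= 0")
    ph <- phase_wrapped[[e]]$data
    if (any(ph < -pi - 1e-9) || any(ph >= pi + 1e-9))
      stop("multi_echo_dataset: phase must lie in [-pi, pi)")
  }
  if (!identical(as.integer(d0), protocol$matrix_size))
    protocol$matrix_size <- as.integer(d0)
  structure(list(protocol = protocol, magnitude = magnitude,
                 phase_wrapped = phase_wrapped, role = role),
            class = "multi_echo_dataset")
}

#' @export
print.multi_echo_dataset <- function(x, ...) {
  cat(sprintf("<multi_echo_dataset> role = %s, %d echoes, grid %s\n", x$role,
              length(x$protocol$echo_times),
              paste(dim(x$magnitude[[1]]$data), collapse = "x")))
  invisible(x)
}

#' Number of echoes in a dataset
#' @param dataset `multi_echo_dataset`.
#' @return integer.
#' @export
n_echoes <- function(dataset) length(dataset$protocol$echo_times)

# Wrap angles into [-pi, pi).
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y >= pi] <- -pi  # guard against fp rounding at the boundary
  y
}
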