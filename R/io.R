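#' Read a multi-echo dataset from a manifest
#'
#' The manifest is a YAML file listing, per echo, one magnitude and one phase
#' file (NIfTI-1 `.nii`/`.nii.gz`, or ANALYZE 7.5 `.hdr` read-only) together
#' with the acquisition parameters. Echoes are reordered by ascending echo
#' time. Phase volumes are normalized to radians in `[-pi, pi)`: floating
#' point radians pass through, integer-scaled phase (e.g. signed 12-bit
#' spanning -2048..2047) is rescaled affinely by its inferred integer
#' half-range, and anything else is rejected.
#'
#' @param directory directory containing the image files.
#' @param manifest path to the manifest YAML; defaults to
#'   `manifest.yaml` inside `directory`.
#' @return `multi_echo_dataset`.
#' @export
read_dataset <- function(directory, manifest = file.path(directory, "manifest.yaml")) {
  if (!file.exists(manifest)) stop("read_dataset: manifest not found: ", manifest)
  m <- yaml::yaml.load_file(manifest)
  required <- c("echoes", "repetition_time", "flip_angle", "voxel_size")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("read_dataset: manifest missing fields: ",
                            paste(missing, collapse = ", "))
  tes <- vapply(m$echoes, function(e) as.numeric(e$echo_time), 0)
  ord <- order(tes)
  tes <- tes[ord]
  m$echoes <- m$echoes[ord]
  if (any(diff(tes) <= 0)) stop("read_dataset: duplicate echo times in manifest")
  voxel_size <- as.numeric(m$voxel_size)
  origin <- if (!is.null(m$origin)) as.numeric(m$origin) else c(0, 0, 0)
  mags <- phs <- vector("list", length(tes))
  for (e in seq_along(tes)) {
    entry <- m$echoes[[e]]
    for (what in c("magnitude", "phase")) {
      f <- file.path(directory, entry[[what]])
      if (!file.exists(f))
        stop(sprintf("read_dataset: missing %s file for echo TE=%g ms: %s",
                     what, tes[e], f))
      arr <- read_volume_file(f)
      vol <- scalar_volume(arr, voxel_size, origin)
      if (what == "magnitude") mags[[e]] <- vol
      else { vol$data <- normalize_phase_range(vol$data); phs[[e]] <- vol }
    }
    if (!identical(dim(mags[[e]]$data), dim(phs[[e]]$data)))
      stop(sprintf("read_dataset: magnitude/phase dimension mismatch at TE=%g ms", tes[e]))
  }
  for (e in seq_along(tes))
    if (!identical(dim(mags[[e]]$data), dim(mags[[1]]$data)))
      stop("read_dataset: echoes have inconsistent dimensions")
  protocol <- acquisition_protocol(
    echo_times = tes,
    repetition_time = as.numeric(m$repetition_time),
    flip_angle = as.numeric(m$flip_angle),
    field_strength = if (!is.null(m$field_strength)) as.numeric(m$field_strength) else 4.7,
    voxel_size = voxel_size,
    matrix_size = dim(mags[[1]]$data))
  multi_echo_dataset(protocol, mags, phs,
                     role = if (!is.null(m$role)) m$role else "contrast")
}

read_volume_file <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.hdr$", lower)) {
    if (!requireNamespace("oro.nifti", quietly = TRUE))
      stop("read_dataset: ANALYZE support requires the oro.nifti package")
    arr <- oro.nifti::img_data(oro.nifti::readANALYZE(sub("\\.hdr$", "", path)))
    arr <- drop(arr)
    if (length(dim(arr)) != 3L) stop("read_dataset: expected a 3D volume in ", path)
    return(unclass(arr))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- RNifti::readNifti(path)
    a <- as.array(arr)
    if (length(dim(a)) != 3L) stop("read_dataset: expected a 3D volume in ", path)
    return(a)
  }
  stop("read_dataset: unsupported volume format: ", path)
}

# Bring stored phase into [-pi, pi) radians. Accepts radians directly or
# integer-scaled phase with a power-of-two half-range (signed or offset
# unsigned). Anything else is a validation error.
normalize_phase_range <- function(x) {
  mx <- max(x); mn <- min(x)
  if (mn >= -pi - 1e-6 && mx < pi + 1e-6) return(wrap_angle(x))
  integer_valued <- max(abs(x - round(x))) < 1e-6
  if (!integer_valued)
    stop("read_dataset: phase range not inferable (values outside [-pi, pi) and not integer-scaled)")
  if (mn < 0) {
    half <- 2^ceiling(log2(max(-mn, mx + 1)))
    return(wrap_angle(x * pi / half))
  }
  half <- 2^ceiling(log2(mx + 1)) / 2
  wrap_angle((x - half) * pi / half)
}

#' Write a multi-echo dataset to a directory
#'
#' Writes one magnitude and one phase NIfTI-1 file per echo (float32, phase in
#' radians) plus a `manifest.yaml`; `read_dataset()` on the result reproduces
#' the dataset to storage precision.
#'
#' @param dataset `multi_echo_dataset`.
#' @param directory output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("write_dataset: cannot create directory ", directory)
  ne <- n_echoes(dataset)
  echoes <- vector("list", ne)
  for (e in seq_len(ne)) {
    magf <- sprintf("mag_echo%d.nii.gz", e)
    phf <- sprintf("phase_echo%d.nii.gz", e)
    write_volume_file(dataset$magnitude[[e]], file.path(directory, magf))
    write_volume_file(dataset$phase_wrapped[[e]], file.path(directory, phf))
    echoes[[e]] <- list(echo_time = dataset$protocol$echo_times[e],
                        magnitude = magf, phase = phf)
  }
  p <- dataset$protocol
  manifest <- list(role = dataset$role,
                   repetition_time = p$repetition_time,
                   flip_angle = p$flip_angle,
                   field_strength = p$field_strength,
                   voxel_size = as.numeric(p$voxel_size),
                   origin = as.numeric(dataset$magnitude[[1]]$origin),
                   echoes = echoes)
  path <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Write one scalar volume as NIfTI-1
#' @param volume `scalar_volume` or `mask_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_file <- function(volume, path) {
  arr <- volume$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
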