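wrapa <- function(x) { y <- (x + pi) %% (2 * pi) - pi; y[y >= pi] <- -pi; y }

test_that("wrapped phase uses the quadrant-aware arctangent", {
  expect_equal(wrapped_phase(1, 0), 0)
  expect_equal(wrapped_phase(0, -1), -pi / 2)
  # branch cut: just above vs just below the negative real axis
  expect_gt(wrapped_phase(-1, 1e-12), pi - 1e-6)
  expect_lt(wrapped_phase(-1, -1e-12), -pi + 1e-6)
  v <- scalar_volume(array(-1, c(2, 2, 2)))
  w <- wrapped_phase(v, scalar_volume(array(0, c(2, 2, 2))))
  expect_true(all(w$data >= -pi & w$data < pi))
})

test_that("region-merging unwrap recovers a multi-wrap ramp and stays congruent", {
  d <- c(40L, 8L, 8L)
  ramp <- array(rep(0.5 * (0:39), times = 64), d)  # ~3 wraps
  w <- scalar_volume(wrapa(ramp)); q <- scalar_volume(array(1, d))
  m <- mask_volume(array(TRUE, d))
  u <- unwrap_phase_3d(w, q, m)
  # 1D Itoh path-integration oracle along x
  itoh <- apply(w$data, c(2, 3), function(col) cumsum(c(col[1], wrapa(diff(col)))))
  off_i <- itoh[1, 1, 1] - u$data[1, 1, 1]
  expect_lt(max(abs(u$data + off_i - itoh)), 1e-9)
  off <- u$data[1, 1, 1] - ramp[1, 1, 1]
  expect_equal(off %% (2 * pi), 0)
  expect_lt(max(abs(u$data - ramp - off)), 1e-9)
  expect_lt(max(abs(wrapa(u$data) - w$data)), 1e-6)
})

test_that("wrap-free fields unwrap to the identity up to one global 2pi multiple", {
  set.seed(5)
  d <- c(16L, 16L, 8L)
  smooth <- spiolocate:::box_smooth(array(rnorm(prod(d)), d), 3L) * 4
  smooth <- smooth - mean(smooth)
  expect_lt(max(abs(smooth)), pi)  # no true wraps by construction
  u <- unwrap_phase_3d(scalar_volume(smooth), scalar_volume(array(1, d)),
                       mask_volume(array(TRUE, d)))
  delta <- u$data - smooth
  expect_lt(max(abs(delta - delta[1])), 1e-9)
  expect_equal(delta[1] %% (2 * pi), 0)
  expect_error(unwrap_phase_3d(scalar_volume(smooth), scalar_volume(array(1, d)),
                               mask_volume(array(FALSE, d))), "empty mask")
})

test_that("a smooth dipole field with a multi-radian peak unwraps to the pre-wrap truth", {
  # Gaussian-blob susceptibility source: the peak exceeds 2 pi but the field
  # stays spatially smooth (adjacent-voxel steps below pi), so the unwrap
  # must reproduce the simulator's pre-wrap field exactly
  prot <- small_protocol()
  model <- contrast_model()
  d <- c(32L, 48L, 16L)
  org <- -d * 0.4 / 2 + 0.2
  conc <- scalar_volume(array(0, d), c(0.4, 0.4, 0.4), org)
  ctrs <- spiolocate:::voxel_centers(conc)
  conc$data <- array(330 * exp(-rowSums(ctrs^2) / 4), d)
  truth <- structure(list(concentration = conc), class = "phantom_truth")
  field <- dipole_phase_field(truth, model, prot, te = 11.34)
  expect_gt(diff(range(field$data)), 2 * pi)
  steps <- max(abs(field$data[-1, , ] - field$data[-d[1], , ]),
               abs(field$data[, -1, ] - field$data[, -d[2], ]),
               abs(field$data[, , -1] - field$data[, , -d[3]]))
  expect_lt(steps, pi)
  u <- unwrap_phase_3d(scalar_volume(wrapa(field$data), c(0.4, 0.4, 0.4), org),
                       scalar_volume(array(1, d), c(0.4, 0.4, 0.4), org),
                       mask_volume(array(TRUE, d), c(0.4, 0.4, 0.4), org))
  dg <- u$data - field$data
  dg <- dg - round(stats::median(dg) / (2 * pi)) * 2 * pi
  expect_lt(max(abs(dg)), 1e-6)
})

test_that("noise-dominated voxels are flagged unreliable, coherent voxels are not", {
  prot <- small_protocol(c(24L, 24L, 12L))
  d <- c(24L, 24L, 12L)
  set.seed(77)
  n_mc <- 10000L
  base_slope <- 0.05  # rad/ms; clean voxels are exactly linear in TE
  flagged <- 0L; total <- 0L
  false_flags <- 0L; clean_total <- 0L
  voi <- mask_volume(array(TRUE, d), prot$voxel_size)
  noise_idx <- sample(prod(d), 100)
  for (b in seq_len(ceiling(n_mc / 100))) {
    phases <- lapply(prot$echo_times, function(te) array(base_slope * te, d))
    bad <- matrix(runif(100 * 3, -pi, pi), 100, 3)
    for (e in 1:3) phases[[e]][noise_idx] <- bad[, e]
    upp <- structure(list(
      phase = lapply(phases, scalar_volume, voxel_size = prot$voxel_size),
      reference_offset = rep(0, 3), echo_times = prot$echo_times),
      class = "unwrapped_phase_set")
    um <- unreliable_phase_mask(upp, prot, voi = voi)
    flagged <- flagged + sum(um$data[noise_idx])
    total <- total + 100L
    clean <- um$data; clean[noise_idx] <- FALSE
    false_flags <- false_flags + sum(clean)
    clean_total <- clean_total + prod(d) - 100L
  }
  expect_gt(flagged / total, 0.99)
  expect_lt(false_flags / clean_total, 0.02)
  # an intercept offset of 1 rad from a flat neighborhood is unreliable
  phases <- lapply(prot$echo_times, function(te) array(base_slope * te, d))
  for (e in 1:3) phases[[e]][6, 6, 3] <- phases[[e]][6, 6, 3] + 1
  upp <- structure(list(
    phase = lapply(phases, scalar_volume, voxel_size = prot$voxel_size),
    reference_offset = rep(0, 3), echo_times = prot$echo_times),
    class = "unwrapped_phase_set")
  um <- unreliable_phase_mask(upp, prot, voi = voi)
  expect_true(um$data[6, 6, 3])
  # fewer than 3 echoes is a validation error
  prot2 <- acquisition_protocol(echo_times = c(2.54, 3.78),
                                matrix_size = d, voxel_size = prot$voxel_size)
  expect_error(unreliable_phase_mask(upp, prot2), "3 echoes")
})

test_that("band-pass passes in-band content unchanged and rejects the stop band", {
  d <- c(32L, 32L, 16L)
  voi <- mask_volume(array(TRUE, d), c(0.4, 0.4, 0.4))
  # constant phase -> s identically ~0
  s0 <- short_range_perturbations(scalar_volume(array(1.3, d)), voi)
  expect_lt(max(abs(s0$s$data)), 1e-10)
  # long-wave content (period 32 voxels >> 10-voxel cutoff) is stopped
  wave <- array(rep(sin(2 * pi * (0:31) / 32), times = d[2] * d[3]), d) * 2
  sw <- short_range_perturbations(scalar_volume(wave), voi)
  expect_lt(max(abs(sw$s$data)), 0.02 * 2)
  # in-band content is passed with unit gain: reapplication changes < 1% RMS
  set.seed(8)
  H <- spiolocate:::band_pass_filter_3d(d, c(2, 10))
  spec_noise <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d) *
    (H >= 0.999)
  x <- Re(stats::fft(spec_noise, inverse = TRUE)) / prod(d)
  s1 <- short_range_perturbations(scalar_volume(x), voi)
  s2 <- short_range_perturbations(s1$s, voi)
  rms <- function(z) sqrt(mean(z^2))
  expect_lt(rms(s2$s$data - s1$s$data) / rms(s1$s$data), 0.01)
  expect_lt(rms(s1$s$data - x) / rms(x), 0.01)
  expect_error(short_range_perturbations(scalar_volume(x), voi, band = c(10, 2)),
               "band")
  # VOI mean of s is ~0 (DC removed)
  expect_lt(abs(mean(s1$s$data)), 1e-8)
})

test_that("s-map equals the band-pass filter oracle applied to the true phase", {
  prot <- small_protocol()
  model <- contrast_model()
  spec <- phantom_spec(c(10.4, 17.6, 5.6),
                       list(inlay_spec(c(0, 0, 0), 2, 3.2, 120, model = model)))
  truth <- build_phantom_truth(spec, prot)
  sim <- synthesize_dataset(truth, spec, model, prot, noise_spec(0, 1),
                            return_truth_phase = TRUE)
  block <- spiolocate:::block_mask_array(spec, prot)
  voi <- mask_volume(block, prot$voxel_size)
  u <- unwrap_phase_3d(sim$contrast$phase_wrapped[[2]], sim$contrast$magnitude[[2]], voi)
  filled <- scalar_volume(
    array(spiolocate:::fill_outside_mask(u$data, block), dim(block)), prot$voxel_size)
  s <- short_range_perturbations(filled, voi, echo_used = prot$echo_times[2])
  oracle <- short_range_perturbations(
    scalar_volume(sim$truth_phase[[2]], prot$voxel_size), voi)
  shell <- dilate_mask(truth$inlay_labels == 1, 10) & !(truth$inlay_labels > 0) & block
  expect_gt(stats::cor(s$s$data[shell], oracle$s$data[shell]), 0.9)
})

test_that("perturbation sources localize to the inlays", {
  prot <- small_protocol()
  model <- contrast_model()
  block <- spiolocate:::block_mask_array(phantom_spec(c(10.4, 17.6, 5.6), list()), prot)
  voi <- mask_volume(block, prot$voxel_size)
  s_of <- function(spec) {
    truth <- build_phantom_truth(spec, prot)
    sim <- synthesize_dataset(truth, spec, model, prot, noise_spec(0, 1))
    u <- unwrap_phase_3d(sim$contrast$phase_wrapped[[3]], sim$contrast$magnitude[[3]], voi)
    filled <- scalar_volume(
      array(spiolocate:::fill_outside_mask(u$data, block), dim(block)),
      prot$voxel_size, truth$concentration$origin)
    short_range_perturbations(filled, voi, echo_used = prot$echo_times[3])
  }
  empty <- structure(list(s = scalar_volume(array(0, dim(block)), prot$voxel_size),
                          echo_used = 11.34), class = "perturbation_map")
  expect_equal(nrow(localize_sources(empty, 0.1)), 0L)
  expect_error(localize_sources(empty, -1), "threshold")
  # single point-like inlay -> one source within a voxel of the center
  sA <- s_of(phantom_spec(c(10.4, 17.6, 5.6),
                          list(inlay_spec(c(0, 0, 0), 1.2, 1.6, 480, model = model))))
  srcA <- localize_sources(sA, 0.4)
  expect_equal(nrow(srcA), 1L)
  expect_lt(sqrt(sum((unlist(srcA[1, 1:3]))^2)), 0.4)
  # two inlays well apart -> exactly two sources at the two centers
  sB <- s_of(phantom_spec(c(10.4, 17.6, 5.6), list(
    inlay_spec(c(0, -4.8, 0), 1.2, 1.6, 120, model = model),
    inlay_spec(c(0, 4.8, 0), 1.2, 1.6, 120, model = model))))
  srcB <- localize_sources(sB, 0.4)
  expect_equal(nrow(srcB), 2L)
  ys <- sort(srcB$y)
  expect_lt(abs(ys[1] - (-4.8)), 0.4)
  expect_lt(abs(ys[2] - 4.8), 0.4)
})

test_that("propagation map is zero without contrast and scales with susceptibility", {
  prot <- small_protocol()
  model <- contrast_model()
  # two weak inlays at concentrations c and 2c (no phase aliasing)
  spec <- phantom_spec(c(10.4, 17.6, 5.6), list(
    inlay_spec(c(0, -4.8, 0), 2, 3.2, 60, model = model),
    inlay_spec(c(0, 4.8, 0), 2, 3.2, 30, model = model)))
  truth <- build_phantom_truth(spec, prot)
  sim <- synthesize_dataset(truth, spec, model, prot, noise_spec(0, 1))
  block <- spiolocate:::block_mask_array(spec, prot)
  voi <- mask_volume(block, prot$voxel_size)
  u_c <- unwrap_dataset_phases(sim$contrast, voi)
  u_b <- unwrap_dataset_phases(sim$baseline, voi)
  p0 <- perturbation_propagation(u_b, u_b, voi)
  expect_true(all(p0$p$data == 0))
  p <- perturbation_propagation(u_c, u_b, voi)
  shell_of <- function(i) dilate_mask(truth$inlay_labels == i, 3) &
    !dilate_mask(truth$inlay_labels == i, 1) & block
  m1 <- mean(p$p$data[shell_of(1)])  # 38 uM
  m2 <- mean(p$p$data[shell_of(2)])  # 19 uM
  expect_lt(abs(m1 / m2 - 2), 0.1 * 2)
  u_bad <- u_b; u_bad$echo_times <- u_b$echo_times + 1
  expect_error(perturbation_propagation(u_c, u_bad, voi), "echo")
})
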