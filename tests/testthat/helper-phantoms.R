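# Shared fixtures, built in code and memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Compact acquisition grid for module tests.
small_protocol <- function(dims = c(32L, 48L, 16L)) {
  acquisition_protocol(matrix_size = dims, voxel_size = c(0.4, 0.4, 0.4))
}

# Three-inlay miniature block phantom (same physics, smaller grid).
small_spec <- function(model = contrast_model()) {
  inlays <- list(
    inlay_spec(c(0, -5.2, 0), radius = 2, height = 3.2, cell_density = 480, model = model),
    inlay_spec(c(0, 0, 0), radius = 2, height = 3.2, cell_density = 120, model = model),
    inlay_spec(c(0, 5.2, 0), radius = 2, height = 3.2, cell_density = 30, model = model))
  phantom_spec(block_size = c(10.4, 17.6, 5.6), inlays = inlays)
}

# The miniature spec serialized to YAML, so configs can reference it by path.
small_spec_path <- function() {
  memo("small_spec_yaml", {
    path <- tempfile("small-spec-", fileext = ".yaml")
    yaml::write_yaml(list(
      block_size = c(10.4, 17.6, 5.6),
      inlays = list(
        list(center = c(0, -5.2, 0), radius = 2, height = 3.2, cell_density = 480),
        list(center = c(0, 0, 0), radius = 2, height = 3.2, cell_density = 120),
        list(center = c(0, 5.2, 0), radius = 2, height = 3.2, cell_density = 30))),
      path)
    path
  })
}

small_config <- function(seed = 1L) {
  cfg <- default_run_config()
  cfg$seed <- as.integer(seed)
  cfg$protocol$matrix_size <- c(32L, 48L, 16L)
  cfg$phantom$spec <- small_spec_path()
  # a coarser hyperparameter grid keeps the miniature pipelines fast; the
  # full default grid is exercised by the acceptance runs
  cfg$svm$cost_grid <- 2^c(-1, 3, 7)
  cfg$svm$gamma_grid <- 2^c(-7, -3, 1)
  cfg$svm$cv_max_samples <- 1500L
  cfg
}

small_study <- function(seed = 1L, noise = 0.05) {
  memo(sprintf("study_%d_%g", seed, noise), {
    prot <- small_protocol()
    spec <- small_spec()
    truth <- build_phantom_truth(spec, prot)
    sim <- synthesize_dataset(truth, spec, contrast_model(), prot,
                              noise_spec(noise, seed), return_truth_phase = TRUE)
    list(truth = truth, baseline = sim$baseline, contrast = sim$contrast,
         truth_phase = sim$truth_phase, protocol = prot, model = contrast_model(),
         spec = spec)
  })
}

# Small-phantom pipeline run, with registration disabled (data are aligned);
# used by classifier and pipeline tests.
small_pipeline <- function(seed = 1L, registration = "none") {
  memo(sprintf("pipe_%d_%s", seed, registration), {
    cfg <- small_config(seed)
    cfg$registration$mode <- registration
    st <- small_study(seed)
    study <- list(truth = st$truth, baseline = st$baseline, contrast = st$contrast,
                  protocol = st$protocol, model = st$model)
    run_full_pipeline(cfg, study = study)
  })
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
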