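#' Assemble the per-voxel feature stack
#'
#' Stacks the channels fed to the classifier — per-echo signal intensity,
#' per-echo baseline-subtracted intensity change, R2*, per-echo unwrapped
#' baseline-subtracted phase, the unreliable-phase indicator, the s-map and
#' the p-map — and standardizes each channel over the VOI by robust
#' location/scale (median / MAD; scale 1 where the MAD vanishes, e.g. for
#' the binary indicator). Voxels flagged unreliable get their phase-derived
#' channels imputed to the standardized center (0) and the indicator set.
#'
#' @param rho list of per-echo magnitude `scalar_volume`s.
#' @param drho list of per-echo intensity-change `scalar_volume`s.
#' @param r2star_map `r2star_map`.
#' @param phi `unwrapped_phase_set` of the contrast scan.
#' @param baseline_phi `unwrapped_phase_set` of the registered baseline.
#' @param unreliable `mask_volume`.
#' @param s_map `perturbation_map`.
#' @param p_map `propagation_map`.
#' @param voi `mask_volume`.
#' @return `feature_stack`: `channels` (named list of arrays, standardized),
#'   `voi`, `channel_scalers` (data frame of center/scale).
#' @export
assemble_features <- function(rho, drho, r2star_map, phi, baseline_phi,
                              unreliable, s_map, p_map, voi) {
  ne <- length(rho)
  raw <- list()
  for (e in seq_len(ne)) raw[[sprintf("rho_te%d", e)]] <- rho[[e]]$data
  for (e in seq_len(ne)) raw[[sprintf("drho_te%d", e)]] <- drho[[e]]$data
  raw[["r2star"]] <- r2star_map$r2star$data
  for (e in seq_len(ne)) {
    dphi <- phi$phase[[e]]$data - baseline_phi$phase[[e]]$data
    dphi[is.na(dphi)] <- 0
    raw[[sprintf("phi_te%d", e)]] <- dphi
  }
  raw[["unreliable_phi"]] <- unreliable$data * 1
  raw[["s"]] <- s_map$s$data
  raw[["p"]] <- p_map$p$data
  dims <- dim(voi$data)
  for (nm in names(raw))
    if (!identical(dim(raw[[nm]]), dims))
      stop("assemble_features: channel '", nm, "' is on a different grid")
  phase_channels <- c(sprintf("phi_te%d", seq_len(ne)), "s", "p")
  inside <- voi$data
  unrel <- unreliable$data & inside
  scalers <- data.frame(channel = names(raw), center = NA_real_, scale = NA_real_)
  channels <- raw
  for (i in seq_along(raw)) {
    nm <- names(raw)[i]
    arr <- raw[[nm]]
    if (nm %in% phase_channels) arr[unrel] <- NA
    vals <- arr[inside]
    ctr <- stats::median(vals, na.rm = TRUE)
    scl <- stats::mad(vals, na.rm = TRUE)
    if (!is.finite(scl) || scl < 1e-12) scl <- 1
    std <- (arr - ctr) / scl
    if (nm %in% phase_channels) std[unrel] <- 0  # impute to standardized center
    std[is.na(std)] <- 0
    scalers$center[i] <- ctr; scalers$scale[i] <- scl
    channels[[nm]] <- std
  }
  structure(list(channels = channels, voi = voi, channel_scalers = scalers),
            class = "feature_stack")
}

# Feature matrix (n_voi x channels) of the VOI voxels plus their linear indices.
stack_matrix <- function(stack) {
  idx <- which(stack$voi$data)
  X <- vapply(stack$channels, function(ch) ch[idx], numeric(length(idx)))
  colnames(X) <- names(stack$channels)
  list(X = X, idx = idx)
}

#' Sample a labeled training set from a feature stack
#'
#' Uniform (or stratified) seeded random sample of VOI voxels at the given
#' fraction; labels come from the ground-truth positive mask.
#'
#' @param stack `feature_stack`.
#' @param truth_labels `mask_volume` of true positive voxels.
#' @param fraction fraction of VOI voxels to sample (default 0.15).
#' @param seed integer seed.
#' @param stratified keep the VOI class ratio in the sample.
#' @return `training_set`: `features` matrix, `labels` factor
#'   (`containing` / `not_containing`), `indices`, `fraction`, `seed`.
#' @export
sample_training_set <- function(stack, truth_labels, fraction = 0.15, seed = 1L,
                                stratified = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("sample_training_set: fraction must be in (0, 1]")
  sm <- stack_matrix(stack)
  scalers <- stack$channel_scalers
  lab_all <- factor(ifelse(truth_labels$data[sm$idx], "containing", "not_containing"),
                    levels = c("containing", "not_containing"))
  n <- nrow(sm$X)
  k <- round(fraction * n)
  rs <- local_rng(seed)
  pick_once <- function() {
    if (stratified) {
      pos <- which(lab_all == "containing"); neg <- which(lab_all == "not_containing")
      kp <- round(fraction * length(pos)); kn <- k - kp
      c(pos[rs$sample_int(length(pos), min(kp, length(pos)))],
        neg[rs$sample_int(length(neg), min(kn, length(neg)))])
    } else rs$sample_int(n, k)
  }
  sel <- pick_once()
  if (nlevels(droplevels(lab_all[sel])) < 2L) sel <- pick_once()
  if (nlevels(droplevels(lab_all[sel])) < 2L)
    stop("sample_training_set: a class is absent from the sample (after one resample)")
  structure(list(features = sm$X[sel, , drop = FALSE], labels = lab_all[sel],
                 indices = sm$idx[sel], fraction = fraction, seed = as.integer(seed),
                 stratified = stratified, channel_scalers = scalers),
            class = "training_set")
}

#' Radial basis function kernel
#'
#' `k(x_i, x_j) = exp(-gamma ||x_i - x_j||^2)`, in (0, 1].
#'
#' @param x_i,x_j numeric vectors of equal length.
#' @param gamma positive sharpness parameter.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  if (length(x_i) != length(x_j)) stop("rbf_kernel: dimension mismatch")
  if (gamma <= 0) stop("rbf_kernel: gamma must be > 0")
  exp(-gamma * sum((x_i - x_j)^2))
}

#' RBF Gram matrix of a sample
#' @param X numeric matrix (rows = samples).
#' @param gamma positive sharpness parameter.
#' @return Symmetric positive semidefinite matrix.
#' @export
rbf_gram <- function(X, gamma) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2 <- pmax(d2, 0)
  diag(d2) <- 0  # exact zero distance on the diagonal despite fp cancellation
  exp(-gamma * d2)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  rs <- local_rng(seed)
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    perm <- idx[rs$sample_int(length(idx), length(idx))]
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

#' Train the C-SVC with five-fold cross-validated hyperparameters
#'
#' For every (C, gamma) grid point, computes stratified k-fold
#' cross-validated balanced accuracy — the mean of the per-class accuracies,
#' the consistent selection metric for a classifier trained with
#' inverse-class-frequency weights on the heavily imbalanced voxel labels —
#' on a seeded subsample of at most `cv_max_samples` training rows, selects
#' the maximizer (ties broken toward smaller gamma, then smaller C), and
#' refits on the full training set at the selected point.
#'
#' @param training `training_set`.
#' @param cost_grid,gamma_grid positive grids (defaults: powers of 4,
#'   C in 2^-3..2^9, gamma in 2^-9..2^3).
#' @param cv_folds folds (default 5).
#' @param cv_max_samples cap on rows used during the grid search.
#' @param seed fold/subsample seed.
#' @return `svm_model`: fitted e1071 svm `fit`, selected `cost`/`gamma`,
#'   `cv_table`, `channel_names`.
#' @export
train_svm <- function(training, cost_grid = 2^seq(-3, 9, by = 2),
                      gamma_grid = 2^seq(-9, 3, by = 2), cv_folds = 5L,
                      cv_max_samples = 4000L, seed = 1L) {
  if (nlevels(droplevels(training$labels)) < 2L)
    stop("train_svm: both classes must be present")
  if (!length(cost_grid) || !length(gamma_grid)) stop("train_svm: empty grid")
  X <- training$features
  y <- training$labels
  n <- nrow(X)
  rs <- local_rng(seed)
  if (n > cv_max_samples) {
    # stratified subsample for the grid search
    keep <- integer(0)
    for (lv in levels(y)) {
      idx <- which(y == lv)
      k <- max(2L, round(cv_max_samples * length(idx) / n))
      keep <- c(keep, idx[rs$sample_int(length(idx), min(k, length(idx)))])
    }
    Xcv <- X[keep, , drop = FALSE]; ycv <- y[keep]
  } else { Xcv <- X; ycv <- y }
  folds <- stratified_folds(ycv, cv_folds, seed + 17L)
  wts <- class_weights(ycv)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    confusion <- matrix(0, 2, 2)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f; te <- !tr
      if (nlevels(droplevels(ycv[tr])) < 2L) next
      fit <- e1071::svm(Xcv[tr, , drop = FALSE], ycv[tr], type = "C-classification",
                        kernel = "radial", cost = grid$cost[g], gamma = grid$gamma[g],
                        class.weights = class_weights(ycv[tr]), scale = FALSE)
      pred <- stats::predict(fit, Xcv[te, , drop = FALSE])
      confusion <- confusion + table(factor(pred, levels(ycv)), ycv[te])
    }
    acc[g] <- mean(diag(confusion) / pmax(colSums(confusion), 1))  # balanced
  }
  # maximal accuracy; ties toward smaller gamma then smaller cost (grid scans
  # cost fastest within sorted gamma, so the first maximum is the winner)
  best <- which(acc >= max(acc) - 1e-12)[1]
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    class.weights = class_weights(y), scale = FALSE)
  structure(list(fit = fit, cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_table = cbind(grid, accuracy = acc),
                 n_support = nrow(fit$SV),
                 channel_names = colnames(X),
                 channel_scalers = training$channel_scalers),
            class = "svm_model")
}

class_weights <- function(y) {
  tab <- table(droplevels(y))
  w <- as.numeric(length(y) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF C-SVC: C = %g, gamma = %g, %d support vectors, best CV accuracy %.4f\n",
              x$cost, x$gamma, x$n_support, max(x$cv_table$accuracy)))
  invisible(x)
}

#' Classify every VOI voxel
#'
#' Applies a trained model to a feature stack; voxels outside the VOI are
#' always negative. When the model carries the training stack's channel
#' scalers, the stack is re-standardized into the training frame, so a
#' pre-trained model transfers across scans without scaler drift.
#'
#' @param stack `feature_stack` with the channels the model was trained on.
#' @param model `svm_model`.
#' @param chunk_size voxels per prediction chunk.
#' @return `mask_volume` of voxels classified as containing labeled cells.
#' @export
predict_voxels <- function(stack, model, chunk_size = 50000L) {
  sm <- stack_matrix(stack)
  if (!identical(colnames(sm$X), model$channel_names))
    stop("predict_voxels: feature channels do not match the trained model")
  if (!is.null(model$channel_scalers) && !is.null(stack$channel_scalers)) {
    ms <- model$channel_scalers; ss <- stack$channel_scalers
    for (i in seq_along(ms$channel)) {
      raw <- sm$X[, i] * ss$scale[i] + ss$center[i]
      sm$X[, i] <- (raw - ms$center[i]) / ms$scale[i]
    }
  }
  out <- array(FALSE, dim(stack$voi$data))
  n <- nrow(sm$X)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    pred <- stats::predict(model$fit, sm$X[s:e, , drop = FALSE])
    out[sm$idx[s:e]] <- pred == "containing"
  }
  mask_volume(out, stack$voi$voxel_size, stack$voi$origin)
}

#' Localization result
#'
#' Combines the binary classification with the R2*-derived concentration:
#' the map equals the concentration estimate on positive voxels and 0
#' elsewhere.
#'
#' @param positives `mask_volume` of positive voxels.
#' @param concentration `scalar_volume` of R2*-derived concentration, uM.
#' @return `localization_result`: `positives`, `concentration`.
#' @export
build_localization_result <- function(positives, concentration) {
  stop_if_grid_mismatch(positives, concentration, "localization inputs")
  conc <- ifelse(positives$data, concentration$data, 0)
  structure(list(positives = positives,
                 concentration = vol_like(concentration, conc)),
            class = "localization_result")
}
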