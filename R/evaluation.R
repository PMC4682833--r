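#' Confusion counts within an evaluation region
#'
#' Standard 2x2 voxel counts of predicted vs true positive masks restricted
#' to an evaluation region.
#'
#' @param predicted,truth `mask_volume`s.
#' @param evaluation_region `mask_volume`, nonempty.
#' @param region_id optional identifier carried in the result.
#' @return `confusion_counts`: `tp`, `fp`, `tn`, `fn`, `region_id`,
#'   `region_size`.
#' @export
confusion_counts <- function(predicted, truth, evaluation_region, region_id = NA) {
  stop_if_grid_mismatch(predicted, truth, "confusion inputs")
  stop_if_grid_mismatch(predicted, evaluation_region, "confusion inputs")
  r <- evaluation_region$data
  if (!any(r)) stop("confusion_counts: empty evaluation region")
  p <- predicted$data[r]; t <- truth$data[r]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 region_id = region_id, region_size = sum(r)),
            class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. A side
#' with an empty denominator is reported as `NA` with a flag.
#'
#' @param counts `confusion_counts`.
#' @return List: `sensitivity`, `specificity`, `sensitivity_defined`,
#'   `specificity_defined`.
#' @export
sensitivity_specificity <- function(counts) {
  rp <- counts$tp + counts$fn
  rn <- counts$tn + counts$fp
  if (rp == 0 && rn == 0)
    stop("sensitivity_specificity: no real positives nor real negatives")
  list(sensitivity = if (rp > 0) counts$tp / rp else NA_real_,
       specificity = if (rn > 0) counts$tn / rn else NA_real_,
       sensitivity_defined = rp > 0,
       specificity_defined = rn > 0)
}

# Attribute predicted-positive voxels to truth regions: a positive belongs to
# region i when it lies within `distance` voxels (26-connectivity dilation)
# of region i and i is the nearest such region in dilation order.
attribute_positives <- function(predicted, inlay_labels, distance = 3L) {
  attribution <- array(0L, dim(predicted))
  remaining <- predicted
  regions <- sort(unique(inlay_labels[inlay_labels > 0L]))
  grown <- lapply(regions, function(i) inlay_labels == i)
  for (d in 0:distance) {
    for (ri in seq_along(regions)) {
      hit <- remaining & grown[[ri]]
      attribution[hit] <- regions[ri]
      remaining[hit] <- FALSE
      if (d < distance) grown[[ri]] <- cpp_binary_dilate(grown[[ri]], 1L, 26L)
    }
  }
  attribution
}

#' Detected-to-real volume ratio for one truth region
#'
#' Predicted-positive voxels are attributed to their nearest truth region
#' within `distance` voxels; the ratio is attributed count over region count.
#'
#' @param predicted `mask_volume`.
#' @param truth_region `mask_volume` of the region, nonempty.
#' @param all_labels optional integer array of all truth regions for nearest-
#'   region attribution; when `NULL` the single region is used alone.
#' @param region_id the label of `truth_region` within `all_labels`.
#' @param distance attribution distance, voxels.
#' @return Scalar ratio (>= 0).
#' @export
volume_ratio <- function(predicted, truth_region, all_labels = NULL,
                         region_id = 1L, distance = 3L) {
  nreal <- sum(truth_region$data)
  if (nreal == 0) stop("volume_ratio: empty truth region")
  if (is.null(all_labels)) all_labels <- ifelse(truth_region$data, region_id, 0L)
  attr_lab <- attribute_positives(predicted$data, all_labels, distance)
  sum(attr_lab == region_id) / nreal
}

#' Per-inlay detected concentration statistics
#'
#' Mean and standard deviation of the detected concentration map over the
#' predicted-positive voxels attributed to each inlay; inlays with no
#' attributed positives are reported as missing (`NA`).
#'
#' @param result `localization_result`.
#' @param truth `phantom_truth`.
#' @param distance attribution distance, voxels.
#' @return Data frame: `inlay`, `true_concentration`, `detected_mean`,
#'   `detected_sd`, `n_voxels`.
#' @export
concentration_report <- function(result, truth, distance = 3L) {
  stop_if_grid_mismatch(result$concentration, truth$concentration,
                        "concentration report inputs")
  labels <- truth$inlay_labels
  attr_lab <- attribute_positives(result$positives$data, labels, distance)
  concs <- vapply(truth$spec$inlays, function(i) i$iron_concentration, 0)
  rows <- lapply(seq_along(concs), function(i) {
    vox <- attr_lab == i & result$positives$data
    if (!any(vox))
      return(data.frame(inlay = i, true_concentration = concs[i],
                        detected_mean = NA_real_, detected_sd = NA_real_,
                        n_voxels = 0L))
    v <- result$concentration$data[vox]
    data.frame(inlay = i, true_concentration = concs[i],
               detected_mean = mean(v), detected_sd = stats::sd(v),
               n_voxels = sum(vox))
  })
  do.call(rbind, rows)
}

#' Halo fraction of the false positives
#'
#' Fraction of false-positive voxels lying within `shell_width` voxels
#' (26-connectivity dilation) of the true positive set. Returns 1 with a
#' flag when there are no false positives.
#'
#' @param predicted,truth `mask_volume`s.
#' @param shell_width >= 1 voxels.
#' @return List: `fraction`, `n_false_positives`, `no_false_positives`.
#' @export
halo_fraction <- function(predicted, truth, shell_width = 2L) {
  if (shell_width < 1) stop("halo_fraction: shell_width must be >= 1")
  fp <- predicted$data & !truth$data
  nfp <- sum(fp)
  if (nfp == 0) return(list(fraction = 1, n_false_positives = 0L,
                            no_false_positives = TRUE))
  halo <- cpp_binary_dilate(truth$data, as.integer(shell_width), 26L) & !truth$data
  list(fraction = sum(fp & halo) / nfp, n_false_positives = nfp,
       no_false_positives = FALSE)
}

#' Evaluate a localization result against phantom ground truth
#'
#' Builds the per-inlay report: sensitivity and specificity within each
#' inlay's evaluation region (the inlay plus a background shell), detected/
#' real volume ratios with nearest-region attribution, detected
#' concentration statistics, plus global specificity over the VOI and the
#' halo fraction of all false positives.
#'
#' @param result `localization_result`.
#' @param truth `phantom_truth`.
#' @param voi `mask_volume`.
#' @param shell_width background shell width, voxels.
#' @param attribution_distance voxels.
#' @return `evaluation_report`: `per_inlay` data frame, `mean_sensitivity`,
#'   `mean_specificity`, `mean_volume_ratio`, `global_specificity`,
#'   `halo_fraction`.
#' @export
evaluate_result <- function(result, truth, voi, shell_width = 3L,
                            attribution_distance = 3L) {
  labels <- truth$inlay_labels
  concs <- vapply(truth$spec$inlays, function(i) i$iron_concentration, 0)
  vs <- truth$concentration$voxel_size
  org <- truth$concentration$origin
  conc_rep <- concentration_report(result, truth, attribution_distance)
  rows <- lapply(seq_along(concs), function(i) {
    region_arr <- cpp_binary_dilate(labels == i, as.integer(shell_width), 26L)
    region_arr <- region_arr & (voi$data | labels == i)
    cc <- confusion_counts(result$positives, truth$positive_mask,
                           mask_volume(region_arr, vs, org), region_id = i)
    ss <- sensitivity_specificity(cc)
    vr <- volume_ratio(result$positives,
                       mask_volume(labels == i, vs, org),
                       all_labels = labels, region_id = i,
                       distance = attribution_distance)
    data.frame(inlay = i, concentration = concs[i],
               sensitivity = ss$sensitivity, specificity = ss$specificity,
               volume_ratio = vr,
               detected_mean = conc_rep$detected_mean[i],
               detected_sd = conc_rep$detected_sd[i],
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn)
  })
  per_inlay <- do.call(rbind, rows)
  global_cc <- confusion_counts(result$positives, truth$positive_mask, voi)
  global_spec <- sensitivity_specificity(global_cc)$specificity
  hf <- halo_fraction(result$positives, truth$positive_mask, shell_width = 2L)
  structure(list(per_inlay = per_inlay,
                 mean_sensitivity = mean(per_inlay$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(per_inlay$specificity, na.rm = TRUE),
                 mean_volume_ratio = mean(per_inlay$volume_ratio),
                 global_specificity = global_spec,
                 halo_fraction = hf$fraction),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$per_inlay, row.names = FALSE, digits = 4)
  cat(sprintf("mean sensitivity %.3f, mean specificity %.3f, mean volume ratio %.3f\n",
              x$mean_sensitivity, x$mean_specificity, x$mean_volume_ratio))
  cat(sprintf("global specificity %.4f, halo fraction %.3f\n",
              x$global_specificity, x$halo_fraction))
  invisible(x)
}
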