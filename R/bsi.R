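# Boundary shift integral (BSI) family: k-means tissue intensity estimation,
# affine intensity normalisation, boundary-shell extraction, the clipped
# intensity integral, and the composed KN-BSI / fixed-window / double-window
# variants, plus differential bias correction.
#
# Sign convention: the integral is
#   voxel_volume / (I2 - I1) * sum(clip(baseline) - clip(followup))
# so positive values mean intensity decrease across the window, i.e. tissue
# loss for brain/hippocampus (bright structure receding into dark CSF) and
# equally expansion for ventricles (dark CSF advancing into bright tissue).

#' Build an image pair on a common grid
#'
#' @param baseline,followup 3D numeric arrays of identical shape, already
#'   co-registered (a grid mismatch is an error; no resampling is attempted).
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(baseline, followup, voxel_volume_ml) {
  if (!identical(dim(baseline), dim(followup))) {
    stop(sprintf("grid mismatch: baseline %s vs followup %s",
                 paste(dim(baseline), collapse = "x"),
                 paste(dim(followup), collapse = "x")))
  }
  if (!is.numeric(voxel_volume_ml) || voxel_volume_ml <= 0) {
    stop("voxel_volume_ml must be > 0")
  }
  if (!all(is.finite(baseline)) || !all(is.finite(followup))) {
    stop("image intensities must be finite")
  }
  structure(list(baseline = baseline, followup = followup,
                 voxel_volume_ml = voxel_volume_ml),
            class = "image_pair")
}

#' Deterministic k-means tissue intensity centroids
#'
#' Lloyd's algorithm on the masked intensities with a fixed, seed-free
#' initialisation: centroids start at evenly spaced fractions of the masked
#' intensity range (10%/50%/90% of the range for k = 3). Ties on cluster
#' boundaries are assigned to the lower cluster. Centroids are returned in
#' ascending order.
#'
#' @param image 3D numeric array.
#' @param mask Logical/binary array of the same shape; only masked voxels are
#'   clustered.
#' @param k Number of clusters (>= 1).
#' @param tol Relative centroid-change convergence tolerance.
#' @param max_iter Maximum Lloyd iterations.
#' @return Numeric vector of k ascending centroids.
#' @export
tissue_means_kmeans <- function(image, mask, k = 3, tol = 1e-6,
                                max_iter = 300) {
  vals <- image[mask > 0]
  if (length(vals) == 0) stop("empty mask")
  if (k < 1) stop("k must be >= 1")
  if (k == 1) return(mean(vals))
  if (length(unique(vals)) < k) {
    stop(sprintf("fewer distinct intensities (%d) than clusters (%d)",
                 length(unique(vals)), k))
  }
  # deterministic, seed-free init: centroids at evenly spaced fractions of
  # the masked intensity range (10%/50%/90% for k = 3); quantile-based inits
  # collapse when one tissue dominates the mask (e.g. WM inside a brain mask)
  rng <- range(vals)
  centroids <- rng[1] + seq(0.1, 0.9, length.out = k) * diff(rng)
  for (it in seq_len(max_iter)) {
    mids <- (centroids[-1] + centroids[-k]) / 2
    # val > mid goes to the upper cluster; ties stay in the lower one
    assign_idx <- rowSums(outer(vals, mids, ">")) + 1L
    new <- vapply(seq_len(k), function(j) {
      v <- vals[assign_idx == j]
      if (length(v) == 0) centroids[j] else mean(v)
    }, numeric(1))
    delta <- max(abs(new - centroids) / pmax(abs(centroids), 1e-12))
    centroids <- sort(new)
    if (delta < tol) break
  }
  centroids
}

#' Affine intensity normalisation of an image pair
#'
#' Rescales each volume with the order-preserving affine map that sends its
#' CSF centroid (lowest) and WM centroid (highest) onto `target_means`.
#'
#' @param pair An [image_pair()].
#' @param centroids_baseline,centroids_followup Ascending centroid vectors
#'   (same length) for the two timepoints.
#' @param target_means Length-2 target for the (CSF, WM) centroids.
#' @return A list with the normalised `pair` and the mapped centroid vectors
#'   `centroids_baseline`, `centroids_followup`.
#' @export
normalise_pair <- function(pair, centroids_baseline, centroids_followup,
                           target_means = c(0.2, 0.8)) {
  stopifnot(inherits(pair, "image_pair"))
  if (length(centroids_baseline) != length(centroids_followup)) {
    stop("centroid vectors must have the same length for both timepoints")
  }
  if (any(diff(centroids_baseline) <= 0) || any(diff(centroids_followup) <= 0)) {
    stop("centroids must be strictly ascending (coincident centroids)")
  }
  if (diff(range(target_means)) <= 0) stop("target_means must be distinct")
  affine <- function(img, cts) {
    lo <- cts[1]; hi <- cts[length(cts)]
    a <- (target_means[2] - target_means[1]) / (hi - lo)
    target_means[1] + a * (img - lo)
  }
  base_n <- affine(pair$baseline, centroids_baseline)
  foll_n <- affine(pair$followup, centroids_followup)
  map_c <- function(cts) {
    lo <- cts[1]; hi <- cts[length(cts)]
    target_means[1] + (target_means[2] - target_means[1]) *
      (cts - lo) / (hi - lo)
  }
  list(
    pair = image_pair(base_n, foll_n, pair$voxel_volume_ml),
    centroids_baseline = map_c(centroids_baseline),
    centroids_followup = map_c(centroids_followup)
  )
}

#' Boundary shell between two masks
#'
#' The region within which the structure boundary can have moved: the union
#' of the two masks dilated by `dilate` voxels, minus the intersection eroded
#' by `erode` voxels (6-connected morphology).
#'
#' @param mask_base,mask_follow Logical arrays on the same grid.
#' @param dilate,erode Non-negative integer morphology rounds.
#' @return Logical array marking the boundary shell.
#' @export
boundary_region <- function(mask_base, mask_follow, dilate = 1, erode = 1) {
  if (!identical(dim(mask_base), dim(mask_follow))) {
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(mask_base), collapse = "x"),
                 paste(dim(mask_follow), collapse = "x")))
  }
  if (dilate < 0 || erode < 0) stop("dilate and erode must be >= 0")
  mb <- mask_base > 0
  mf <- mask_follow > 0
  dilate_n(mb | mf, dilate) & !erode_n(mb & mf, erode)
}

#' Intensity window for the clipped boundary shift integral
#'
#' @param I1,I2 Lower and upper window intensities (normalised units),
#'   `I2 > I1`.
#' @return An object of class `intensity_window`.
#' @export
intensity_window <- function(I1, I2) {
  if (!is.finite(I1) || !is.finite(I2) || I2 <= I1) {
    stop("intensity window requires I2 > I1")
  }
  structure(list(I1 = I1, I2 = I2), class = "intensity_window")
}

#' Clipped boundary shift integral over a region
#'
#' Computes `voxel_volume / (I2 - I1) * sum(clip(baseline, I1, I2) -
#' clip(followup, I1, I2))` over the boundary region. The result is
#' antisymmetric in the two timepoints and bounded by
#' `voxel_volume * n_boundary_voxels` in magnitude.
#'
#' @param pair A normalised [image_pair()].
#' @param region Logical boundary-shell array (see [boundary_region()]).
#' @param window An [intensity_window()].
#' @return An object of class `bsi_result`: `value_ml`, `windows` (list of
#'   windows used), `n_boundary_voxels`.
#' @export
clipped_bsi <- function(pair, region, window) {
  stopifnot(inherits(pair, "image_pair"), inherits(window, "intensity_window"))
  if (!identical(dim(region), dim(pair$baseline))) {
    stop(sprintf("grid mismatch: region %s vs images %s",
                 paste(dim(region), collapse = "x"),
                 paste(dim(pair$baseline), collapse = "x")))
  }
  idx <- which(region > 0)
  if (length(idx) == 0) {
    warning("empty boundary region; BSI is 0")
    return(structure(list(value_ml = 0, windows = list(window),
                          n_boundary_voxels = 0L), class = "bsi_result"))
  }
  cb <- pmin(pmax(pair$baseline[idx], window$I1), window$I2)
  cf <- pmin(pmax(pair$followup[idx], window$I1), window$I2)
  value <- pair$voxel_volume_ml / (window$I2 - window$I1) * sum(cb - cf)
  structure(list(value_ml = value, windows = list(window),
                 n_boundary_voxels = length(idx)),
            class = "bsi_result")
}

#' @export
print.bsi_result <- function(x, ...) {
  cat(sprintf("BSI: %.4f ml over %d boundary voxels\n",
              x$value_ml, x$n_boundary_voxels))
  for (w in x$windows) {
    cat(sprintf("  window: [%.4f, %.4f]\n", w$I1, w$I2))
  }
  invisible(x)
}

# Window rule shared by the composed variants: a symmetric window centred on
# the midpoint of two adjacent tissue centroids with half-width a fraction of
# their separation.
window_between <- function(c_lo, c_hi, half_fraction = 0.25) {
  mid <- (c_lo + c_hi) / 2
  delta <- half_fraction * (c_hi - c_lo)
  intensity_window(mid - delta, mid + delta)
}

#' KN-BSI: k-means normalised boundary shift integral
#'
#' The robust whole-brain variant: estimates three tissue centroids (CSF, GM,
#' WM) by k-means within the union brain mask on each timepoint, normalises
#' both volumes so CSF and WM land on `target_means`, and integrates over the
#' brain boundary shell with a window centred between the normalised CSF and
#' GM centroids (half-width 0.25 of their separation; window and width are
#' configurable).
#'
#' @param pair An [image_pair()] (raw intensities).
#' @param mask_base,mask_follow Brain masks at the two timepoints.
#' @param dilate,erode Boundary shell morphology rounds.
#' @param target_means Normalisation targets for (CSF, WM).
#' @param window_half_fraction Window half-width as a fraction of the
#'   CSF-to-GM centroid distance.
#' @return A `bsi_result` (positive = loss).
#' @export
kn_bsi <- function(pair, mask_base, mask_follow, dilate = 1, erode = 1,
                   target_means = c(0.2, 0.8), window_half_fraction = 0.25) {
  stopifnot(inherits(pair, "image_pair"))
  union_mask <- (mask_base > 0) | (mask_follow > 0)
  cb <- tissue_means_kmeans(pair$baseline, union_mask, k = 3)
  cf <- tissue_means_kmeans(pair$followup, union_mask, k = 3)
  norm <- normalise_pair(pair, cb, cf, target_means = target_means)
  cts <- (norm$centroids_baseline + norm$centroids_followup) / 2
  window <- window_between(cts[1], cts[2], window_half_fraction)
  region <- boundary_region(mask_base, mask_follow, dilate, erode)
  clipped_bsi(norm$pair, region, window)
}

#' Fixed-window BSI for the ventricular (CSF/tissue) boundary
#'
#' Normalises both volumes so CSF maps to 0 and WM to 1 (centroids estimated
#' by k-means within the brain mask) and integrates over the ventricular
#' boundary shell with a preset window, `(0.25, 0.75)` by default.
#'
#' @param pair An [image_pair()] (raw intensities).
#' @param vent_base,vent_follow Ventricle masks at the two timepoints.
#' @param brain_mask Mask within which tissue centroids are estimated.
#' @param window Preset [intensity_window()] in normalised units.
#' @param dilate,erode Boundary shell morphology rounds.
#' @return A `bsi_result` (positive = expansion).
#' @export
fixed_window_bsi <- function(pair, vent_base, vent_follow, brain_mask,
                             window = intensity_window(0.25, 0.75),
                             dilate = 1, erode = 1) {
  stopifnot(inherits(pair, "image_pair"))
  cb <- tissue_means_kmeans(pair$baseline, brain_mask, k = 3)
  cf <- tissue_means_kmeans(pair$followup, brain_mask, k = 3)
  norm <- normalise_pair(pair, cb, cf, target_means = c(0, 1))
  region <- boundary_region(vent_base, vent_follow, dilate, erode)
  res <- clipped_bsi(norm$pair, region, window)
  # CSF advancing into tissue makes baseline brighter than follow-up inside
  # the shell, so the raw integral is already positive for expansion
  res
}

#' Double-window BSI for structures with two tissue interfaces
#'
#' Sums the clipped integral over a CSF/GM window and a GM/WM window on the
#' same boundary shell, each scaled by its own window width; used for the
#' hippocampus, whose surface borders both CSF and white matter.
#'
#' @param pair A normalised [image_pair()].
#' @param mask_base,mask_follow Structure masks at the two timepoints.
#' @param window_csf_gm,window_gm_wm Non-overlapping [intensity_window()]s
#'   (the upper bound of the first must not exceed the lower bound of the
#'   second).
#' @param dilate,erode Boundary shell morphology rounds.
#' @param gm_wm_sign `"same"` adds the GM/WM window contribution as-is (the
#'   plain two-window sum); `"reversed"` negates it, which encodes the loss
#'   sign convention for a grey-matter structure darker than the white matter
#'   around it (its loss appears as an intensity increase at the WM
#'   interface).
#' @return A `bsi_result` carrying both windows.
#' @export
double_window_bsi <- function(pair, mask_base, mask_follow,
                              window_csf_gm, window_gm_wm,
                              dilate = 1, erode = 1,
                              gm_wm_sign = c("same", "reversed")) {
  stopifnot(inherits(pair, "image_pair"),
            inherits(window_csf_gm, "intensity_window"),
            inherits(window_gm_wm, "intensity_window"))
  gm_wm_sign <- match.arg(gm_wm_sign)
  if (window_csf_gm$I2 > window_gm_wm$I1) {
    stop("overlapping windows: CSF/GM window must lie below the GM/WM window")
  }
  region <- boundary_region(mask_base, mask_follow, dilate, erode)
  r1 <- clipped_bsi(pair, region, window_csf_gm)
  r2 <- clipped_bsi(pair, region, window_gm_wm)
  s2 <- if (gm_wm_sign == "same") 1 else -1
  structure(list(value_ml = r1$value_ml + s2 * r2$value_ml,
                 windows = list(window_csf_gm, window_gm_wm),
                 n_boundary_voxels = r1$n_boundary_voxels),
            class = "bsi_result")
}

#' Hippocampal double-window BSI from raw intensities
#'
#' Convenience composition: k-means centroids within the brain mask,
#' normalisation to `target_means`, then [double_window_bsi()] with windows
#' centred between the normalised CSF/GM and GM/WM centroid pairs.
#'
#' @inheritParams kn_bsi
#' @param hippo_base,hippo_follow Hippocampus masks at the two timepoints.
#' @param brain_mask Mask within which tissue centroids are estimated.
#' @return A `bsi_result` (positive = loss).
#' @export
hippo_bsi <- function(pair, hippo_base, hippo_follow, brain_mask,
                      dilate = 1, erode = 1, target_means = c(0.2, 0.8),
                      window_half_fraction = 0.25) {
  stopifnot(inherits(pair, "image_pair"))
  cb <- tissue_means_kmeans(pair$baseline, brain_mask, k = 3)
  cf <- tissue_means_kmeans(pair$followup, brain_mask, k = 3)
  norm <- normalise_pair(pair, cb, cf, target_means = target_means)
  cts <- (norm$centroids_baseline + norm$centroids_followup) / 2
  w1 <- window_between(cts[1], cts[2], window_half_fraction)
  w2 <- window_between(cts[2], cts[3], window_half_fraction)
  # the hippocampus is grey matter: darker than the WM around it, so the
  # GM/WM window term is reversed to report loss as positive
  double_window_bsi(norm$pair, hippo_base, hippo_follow, w1, w2,
                    dilate = dilate, erode = erode, gm_wm_sign = "reversed")
}

#' Differential bias correction
#'
#' Estimates the smooth multiplicative intensity-field difference between the
#' two volumes as the Gaussian-low-pass-filtered log-ratio within the mask and
#' divides it out symmetrically (half applied to each timepoint). An identical
#' pair is a fixed point, and the correction is approximately idempotent.
#'
#' @param pair An [image_pair()] with strictly positive intensities under the
#'   mask.
#' @param mask Logical array delimiting the field estimation region.
#' @param smoothing_fwhm Full width at half maximum of the smoothing kernel,
#'   mm.
#' @param voxel_size Voxel edge lengths in mm.
#' @param refine Number of residual re-smoothing (van Cittert) passes that
#'   sharpen the field estimate near the mask edge, where a single smoothing
#'   pass is biased.
#' @return A corrected [image_pair()].
#' @export
differential_bias_correct <- function(pair, mask, smoothing_fwhm = 15,
                                      voxel_size = c(1, 1, 1), refine = 2L) {
  stopifnot(inherits(pair, "image_pair"))
  m <- mask > 0
  if (any(pair$baseline[m] <= 0) || any(pair$followup[m] <= 0)) {
    stop("non-positive masked intensities; bias correction needs positive signal")
  }
  logratio <- array(0, dim = dim(pair$baseline))
  logratio[m] <- log(pair$followup[m] / pair$baseline[m])
  field <- smooth_gaussian_masked(logratio, m, smoothing_fwhm, voxel_size)
  for (i in seq_len(refine)) {
    resid <- array(0, dim = dim(field))
    resid[m] <- logratio[m] - field[m]
    field <- field + smooth_gaussian_masked(resid, m, smoothing_fwhm,
                                            voxel_size)
  }
  half <- exp(field / 2)
  image_pair(pair$baseline * half, pair$followup / half, pair$voxel_volume_ml)
}
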