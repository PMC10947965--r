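#' Fuzzy c-means configuration for WMH segmentation
#'
#' Two clusters (low / high intensity) are fixed by the segmentation model.
#' The fuzzifier defaults to the classical m = 2; centroids are initialised
#' deterministically at the 10th and 90th percentiles of in-mask
#' intensities, so no random seed is involved and cluster labels cannot
#' swap between runs. Convergence is declared when the largest centroid
#' movement in one iteration drops below `tol`.
#'
#' @param fuzzifier Fuzziness exponent m > 1.
#' @param tol Convergence tolerance on maximum centroid movement
#'   (normalized-intensity units).
#' @param max_iter Iteration cap; exceeding it returns a result flagged
#'   `converged = FALSE` with a warning.
#' @return A list of class `uwmc_fcm_config`.
#' @export
fcm_config <- function(fuzzifier = 2, tol = 1e-5, max_iter = 300L) {
  if (fuzzifier <= 1) abort("`fuzzifier` must be > 1")
  if (tol <= 0) abort("`tol` must be positive")
  structure(list(n_clusters = 2L, fuzzifier = fuzzifier, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "uwmc_fcm_config")
}

#' Normalize a FLAIR image to a reference-tissue intensity scale
#'
#' Every voxel is rescaled to z-units of the reference tissue:
#' `(x - mean(ref)) / sd(ref)`, where the reference is typically cerebellar
#' white matter, a region spared by supratentorial small vessel disease.
#' After normalization the reference voxels have mean 0 and SD 1, putting
#' subjects with different scanner scaling on one intensity scale before
#' clustering.
#'
#' @param flair An `uwmc_intensity` volume.
#' @param reference_mask An `uwmc_mask` on the same grid with at least two
#'   true voxels and nonzero intensity variance.
#' @return An `uwmc_intensity` volume of normalized intensities.
#' @export
normalize_flair <- function(flair, reference_mask) {
  stopifnot_same_grid(flair, reference_mask)
  ref <- flair$data[reference_mask$data]
  if (length(ref) < 2) abort("reference mask must contain at least 2 voxels")
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) abort("reference voxels have zero intensity variance")
  intensity_volume((flair$data - mean(ref)) / s, flair$affine)
}

#' Two-class fuzzy c-means membership of cerebral voxels
#'
#' Runs standard fuzzy c-means on the one-dimensional intensity values of
#' in-mask voxels, minimising `sum_i sum_k u_ik^m (x_i - c_k)^2` with
#' memberships `u_ik = 1 / sum_j ((x_i - c_k) / (x_i - c_j))^(2/(m-1))`.
#' A voxel landing exactly on a centroid gets membership 1 for that
#' cluster. The "high" cluster is the one with the larger converged
#' centroid, so the result is invariant to initialisation order. Clustering
#' is on intensity only, with no spatial regularisation. Voxels outside the
#' cerebral mask get high-intensity membership 0.
#'
#' @param normalized An `uwmc_intensity` volume (see [normalize_flair()]).
#' @param cerebral_mask An `uwmc_mask` selecting the voxels to classify.
#' @param cfg An [fcm_config()].
#' @return An object of class `uwmc_fcm`: `centroids` (named low/high),
#'   `membership_high` (3-D array in \[0, 1\]), `n_iter`, `converged`,
#'   `objective` (per-iteration trace), and the input `affine`.
#' @export
fcm_membership <- function(normalized, cerebral_mask, cfg = fcm_config()) {
  stopifnot_same_grid(normalized, cerebral_mask)
  inmask <- which(cerebral_mask$data)
  if (!length(inmask)) abort("cerebral mask is empty")
  x <- normalized$data[inmask]
  if (!all(is.finite(x))) abort("non-finite intensities inside cerebral mask")
  if (max(x) == min(x)) abort("all in-mask intensities identical; clustering is degenerate")
  m <- cfg$fuzzifier
  centers <- unname(stats::quantile(x, c(0.1, 0.9)))
  if (centers[1] == centers[2]) centers <- range(x)

  memberships <- function(centers) {
    d <- abs(outer(x, centers, "-"))
    w <- d^(-2 / (m - 1))
    zero <- d == 0
    if (any(zero)) {            # on-centroid points: crisp assignment
      w[rowSums(zero) > 0, ] <- 0
      w[zero] <- 1
    }
    w / rowSums(w)
  }

  obj <- numeric(0)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    u <- memberships(centers)
    um <- u^m
    new_centers <- colSums(um * x) / colSums(um)
    obj <- c(obj, sum(um * abs(outer(x, new_centers, "-"))^2))
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    n_iter <- it
    if (moved < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("fuzzy c-means did not converge in %d iterations", cfg$max_iter))
  u <- memberships(centers)
  hi <- which.max(centers)
  mem <- array(0, dim = dim(normalized$data))
  mem[inmask] <- u[, hi]
  structure(list(
    centroids = c(low = min(centers), high = max(centers)),
    membership_high = mem,
    n_iter = n_iter,
    converged = converged,
    objective = obj,
    affine = normalized$affine
  ), class = "uwmc_fcm")
}

#' @export
print.uwmc_fcm <- function(x, ...) {
  cat(sprintf("<uwmc_fcm> centroids low %.4f / high %.4f; %d iterations (%s)\n",
              x$centroids["low"], x$centroids["high"], x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.uwmc_fcm <- function(object, bins = 60, ...) {
  mem <- object$membership_high[object$membership_high > 0]
  ggplot2::ggplot(data.frame(membership = mem),
                  ggplot2::aes(x = .data$membership)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.75, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "high-intensity membership", y = "voxels (log scale)") +
    ggplot2::theme_minimal()
}

#' Threshold high-intensity membership into a WMH mask
#'
#' A voxel is labelled WMH iff its high-intensity membership strictly
#' exceeds the threshold (default 0.75 with a strict `>`, so a membership of
#' exactly 0.75 is not WMH). Set `strict = FALSE` for `>=`.
#'
#' @param result An `uwmc_fcm` object.
#' @param value Threshold in (0, 1).
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return An `uwmc_mask`.
#' @export
threshold_wmh <- function(result, value = 0.75, strict = TRUE) {
  if (value <= 0 || value >= 1) abort("`value` must be in (0, 1)")
  hit <- if (strict) result$membership_high > value else result$membership_high >= value
  binary_mask(hit, result$affine)
}

#' Lobar WMH volume normalized to intracranial volume
#'
#' Per-lobe WMH volume is the count of lesion voxels carrying that lobe's
#' label times the voxel volume (`|det| of the affine 3x3 block`, so
#' anisotropic voxels are handled). Lesion voxels falling outside the four
#' lobes (unlabeled or "other" territory) are tallied under `other`, never
#' dropped. Each volume is divided by ICV (mask voxel count times voxel
#' volume), a unitless ratio; `display_multiplier` rescales it for
#' reporting only.
#'
#' @param wmh An `uwmc_mask` lesion mask.
#' @param lobe_labels An `uwmc_labels` volume whose table maps labels to
#'   lobes.
#' @param icv_mask An `uwmc_mask` of intracranial voxels (must be
#'   non-empty).
#' @param display_multiplier Multiplier applied to the normalized ratio in
#'   the `normalized` column (default 1).
#' @return A tibble with columns `lobe`, `wmh_mm3`, `icv_mm3`,
#'   `normalized`.
#' @export
lobar_wmh_volume <- function(wmh, lobe_labels, icv_mask, display_multiplier = 1) {
  stopifnot_same_grid(wmh, lobe_labels)
  stopifnot_same_grid(wmh, icv_mask)
  vox <- voxel_volume_mm3(wmh$affine)
  icv <- sum(icv_mask$data) * vox
  if (icv == 0) abort("ICV mask is empty")
  lab_at_wmh <- lobe_labels$data[wmh$data]
  lobe_map <- stats::setNames(lobe_labels$table$lobe, lobe_labels$table$id)
  lobes <- ifelse(lab_at_wmh == 0L, "other", unname(lobe_map[as.character(lab_at_wmh)]))
  lobes[is.na(lobes)] <- "other"
  cnt <- table(factor(lobes, levels = VALID_LOBES))
  tibble(lobe = VALID_LOBES,
         wmh_mm3 = as.numeric(cnt) * vox,
         icv_mm3 = icv,
         normalized = as.numeric(cnt) * vox / icv * display_multiplier)
}
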