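#' Build a connectivity phantom with known lesion-crossing ground truth
#'
#' Constructs, on one voxel grid: spherical labeled regions; smooth
#' streamline bundles running region-to-region with endpoints strictly
#' inside their spheres (so endpoint labeling is unambiguous without
#' dilation); a lesion mask planted so that each bundle's lesion-crossing
#' fraction equals its target exactly; and a synthetic FLAIR in which
#' background voxels are N(0, 1), lesion voxels are N(shift, 1), and a
#' disjoint reference block (standing in for cerebellar white matter) is
#' N(0, 1).
#'
#' Planting works by giving each designated crossing streamline one lesion
#' voxel near its midpoint that no other streamline visits (visits computed
#' by dense sampling at a tenth of the voxel size, independently of the
#' package's intersection test), which makes the planted per-bundle
#' crossing counts exact by construction; the generator re-verifies them
#' and errors if planting is infeasible for the requested geometry.
#'
#' @param regions Data frame: `id`, `name`, `lobe`, `hemisphere`,
#'   `center_x`, `center_y`, `center_z` (world mm), `radius` (mm),
#'   `in_abeta_set`, `in_tau_set`.
#' @param bundles Data frame: `a`, `b` (region ids), `n_streamlines`,
#'   `target_uwmc`; `target_uwmc * n_streamlines` must be whole.
#' @param grid_shape Grid dimensions (3 integers).
#' @param voxel_mm Voxel edge lengths in mm (3 positive reals).
#' @param lesion_intensity_shift Lesion intensity mean in background-SD
#'   units (default 6, a well-separated mixture).
#' @param bundle_spread Maximum mid-course perpendicular offset (mm)
#'   separating streamlines within a bundle.
#' @param lesion_bulk_fraction Additional lesion voxels, as a fraction of
#'   cerebral volume, placed in voxels no streamline visits (default 0).
#'   They give the lesion a realistic volume for segmentation-mode runs
#'   without changing any bundle's crossing pattern.
#' @param seed Seed; the phantom is a deterministic function of it.
#' @return An object of class `uwmc_phantom`: `labels`, `wmh`, `flair`,
#'   `cerebellar_mask`, `cerebral_mask`, `streamlines`, and `truth` (a
#'   tibble with per-bundle `a`, `b`, `total`, `unhealthy`, `uwmc`).
#' @export
make_phantom <- function(regions, bundles,
                         grid_shape = c(40L, 40L, 20L), voxel_mm = c(1, 1, 1),
                         lesion_intensity_shift = 6, bundle_spread = 3,
                         lesion_bulk_fraction = 0, seed = 1L) {
  regions <- as_tibble(regions)
  bundles <- as_tibble(bundles)
  k_cross <- bundles$target_uwmc * bundles$n_streamlines
  if (any(abs(k_cross - round(k_cross)) > 1e-9))
    abort("target_uwmc * n_streamlines must be an integer for exact planting")
  k_cross <- as.integer(round(k_cross))
  affine <- diag(c(voxel_mm, 1))
  dm <- as.integer(grid_shape)

  # labeled spheres (voxel centers within radius), refusing overlaps
  lab <- array(0L, dim = dm)
  ctr <- as.matrix(regions[, c("center_x", "center_y", "center_z")])
  idx_grid <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1), k = 0:(dm[3] - 1)))
  world <- voxel_to_world(idx_grid, affine)
  for (r in seq_len(nrow(regions))) {
    d2 <- rowSums(sweep(world, 2, ctr[r, ], "-")^2)
    inside <- which(d2 <= regions$radius[r]^2)
    if (any(lab[inside] != 0L)) abort("region spheres overlap; adjust centers or radii")
    lab[inside] <- regions$id[r]
  }
  label_tab <- tibble(id = as.integer(regions$id), name = regions$name,
                      lobe = regions$lobe, hemisphere = regions$hemisphere,
                      in_abeta_set = regions$in_abeta_set,
                      in_tau_set = regions$in_tau_set)
  labels <- label_volume(lab, affine, label_tab)

  out <- withr::with_seed(seed, {
    streamlines <- list()
    owner <- integer(0)                      # bundle index per streamline
    for (bi in seq_len(nrow(bundles))) {
      ra <- regions[regions$id == bundles$a[bi], ]
      rb <- regions[regions$id == bundles$b[bi], ]
      if (!nrow(ra) || !nrow(rb)) abort("bundle references unknown region id")
      ca <- as.numeric(ra[, c("center_x", "center_y", "center_z")])
      cb <- as.numeric(rb[, c("center_x", "center_y", "center_z")])
      d <- cb - ca; d <- d / sqrt(sum(d^2))
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      u <- c(d[2] * ref[3] - d[3] * ref[2],
             d[3] * ref[1] - d[1] * ref[3],
             d[1] * ref[2] - d[2] * ref[1])
      u <- u / sqrt(sum(u^2))
      v <- c(d[2] * u[3] - d[3] * u[2],
             d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      n <- bundles$n_streamlines[bi]
      for (s in seq_len(n)) {
        jit_a <- stats::runif(3, -1, 1) * ra$radius * 0.3
        jit_b <- stats::runif(3, -1, 1) * rb$radius * 0.3
        phi <- 2 * pi * (s - 1) / max(n, 1) + stats::runif(1, 0, 0.3)
        mag <- bundle_spread * (0.35 + 0.65 * (s - 1) / max(n - 1, 1))
        off <- mag * (cos(phi) * u + sin(phi) * v)
        tt <- seq(0, 1, length.out = 25)
        pts <- outer(1 - tt, ca + jit_a) + outer(tt, cb + jit_b) +
          outer(sin(pi * tt), off)
        streamlines[[length(streamlines) + 1L]] <- pts
        owner <- c(owner, bi)
      }
    }

    # two visit maps per streamline: an independent fine dense sampling
    # (candidate planting voxels + final verification) and the complete
    # geometric cell set (exclusivity: no other streamline may touch a
    # planted voxel even by an arbitrarily short chord)
    fine <- min(voxel_mm) / 10
    inv_aff <- solve(affine)
    flatten <- function(idx) {
      ok <- idx[, 1] >= 0 & idx[, 1] < dm[1] & idx[, 2] >= 0 &
        idx[, 2] < dm[2] & idx[, 3] >= 0 & idx[, 3] < dm[3]
      idx <- idx[ok, , drop = FALSE]
      unique(idx[, 1] + dm[1] * (idx[, 2] + dm[2] * idx[, 3]) + 1)
    }
    visits <- lapply(streamlines, function(p)
      flatten(world_to_voxel(densify_polyline(p, fine), affine)))
    cells <- lapply(streamlines, function(p) flatten(polyline_cells(p, inv_aff)))
    cell_count <- table(unlist(cells))

    lesion <- array(FALSE, dim = dm)
    chosen <- logical(length(streamlines))
    for (bi in seq_len(nrow(bundles))) {
      if (k_cross[bi] == 0L) next
      members <- which(owner == bi)
      candidates <- lapply(members, function(s) {
        vs <- visits[[s]]
        vs[cell_count[as.character(vs)] == 1 & lab[vs] == 0L]
      })
      usable <- which(lengths(candidates) > 0)
      if (length(usable) < k_cross[bi])
        abort(sprintf(
          "infeasible lesion planting for bundle %d-%d: only %d of %d streamlines have an exclusive voxel",
          bundles$a[bi], bundles$b[bi], length(usable), length(members)))
      for (j in usable[seq_len(k_cross[bi])]) {
        s <- members[j]
        vs <- visits[[s]]
        exclusive <- candidates[[j]]
        mid <- exclusive[which.min(abs(match(exclusive, vs) - length(vs) / 2))]
        lesion[mid] <- TRUE
        chosen[s] <- TRUE
      }
    }
    # independent verification of the planted crossing pattern
    crossed <- vapply(visits, function(vs) any(lesion[vs]), logical(1))
    if (!identical(crossed, chosen))
      abort("lesion planting verification failed")

    if (lesion_bulk_fraction > 0) {
      cereb0 <- array(FALSE, dim = dm); cereb0[1:2, 1:2, ] <- TRUE
      untouched <- setdiff(which(!lesion & lab == 0L & !cereb0),
                           unlist(cells))
      n_extra <- round(lesion_bulk_fraction * sum(!cereb0))
      if (n_extra > length(untouched))
        abort("lesion_bulk_fraction too large for the unvisited volume")
      lesion[sample(untouched, n_extra)] <- TRUE
      crossed2 <- vapply(visits, function(vs) any(lesion[vs]), logical(1))
      if (!identical(crossed2, chosen))
        abort("bulk lesion placement altered a crossing pattern")
    }

    # synthetic FLAIR + reference block in the unlabeled corner
    flair_dat <- array(stats::rnorm(prod(dm)), dim = dm)
    flair_dat[lesion] <- stats::rnorm(sum(lesion), mean = lesion_intensity_shift)
    cereb <- array(FALSE, dim = dm)
    cereb[1:2, 1:2, ] <- TRUE
    if (any(lab[cereb] != 0L) || any(lesion[cereb]))
      abort("reference block collides with regions or lesion; move regions off the corner")
    list(streamlines = streamlines, owner = owner, chosen = chosen,
         lesion = lesion, flair_dat = flair_dat, cereb = cereb)
  })

  truth <- dplyr::mutate(bundles[, c("a", "b", "n_streamlines")],
                         total = as.integer(.data$n_streamlines),
                         unhealthy = k_cross, uwmc = k_cross / .data$n_streamlines)
  truth <- dplyr::select(truth, "a", "b", "total", "unhealthy", "uwmc")

  structure(list(
    labels = labels,
    wmh = binary_mask(out$lesion, affine),
    flair = intensity_volume(out$flair_dat, affine),
    cerebellar_mask = binary_mask(out$cereb, affine),
    cerebral_mask = binary_mask(array(!out$cereb, dim = dm), affine),
    streamlines = streamline_set(out$streamlines),
    truth = truth,
    seed = seed
  ), class = "uwmc_phantom")
}

#' @export
print.uwmc_phantom <- function(x, ...) {
  cat(sprintf("<uwmc_phantom> %d regions, %d streamlines, %d lesion voxels\n",
              nrow(x$labels$table), length(x$streamlines), sum(x$wmh$data)))
  print(x$truth)
  invisible(x)
}

#' Canonical two-region, four-streamline worked example
#'
#' Two spherical regions joined by four streamlines, two of which cross a
#' planted lesion: pairwise, lobar, and global UWMC all equal 0.5.
#'
#' @param seed Seed passed to [make_phantom()].
#' @return An `uwmc_phantom`.
#' @export
phantom_figure1c <- function(seed = 1L) {
  regions <- tibble(
    id = c(1L, 2L),
    name = c("region_a", "region_b"),
    lobe = c("frontal", "frontal"),
    hemisphere = c("L", "R"),
    center_x = c(8, 32), center_y = c(20, 20), center_z = c(10, 10),
    radius = c(5, 5),
    in_abeta_set = TRUE, in_tau_set = FALSE)
  bundles <- tibble(a = 1L, b = 2L, n_streamlines = 4L, target_uwmc = 0.5)
  make_phantom(regions, bundles, seed = seed)
}

#' Multi-bundle phantom preset with mixed crossing fractions
#'
#' Three regions in different lobes joined by three bundles with distinct
#' lesion-crossing targets, exercising inter-lobe aggregation.
#'
#' @param targets Per-bundle crossing fractions.
#' @param sizes Per-bundle streamline counts.
#' @param seed Seed passed to [make_phantom()].
#' @return An `uwmc_phantom`.
#' @export
phantom_multibundle <- function(targets = c(0.3, 0, 1), sizes = c(10L, 6L, 8L),
                                seed = 1L) {
  regions <- tibble(
    id = 1:3,
    name = c("frontal_roi", "parietal_roi", "temporal_roi"),
    lobe = c("frontal", "parietal", "temporal"),
    hemisphere = c("L", "L", "L"),
    center_x = c(10, 38, 24), center_y = c(10, 10, 38), center_z = c(10, 10, 10),
    radius = c(5, 5, 5),
    in_abeta_set = c(TRUE, TRUE, FALSE), in_tau_set = c(FALSE, FALSE, TRUE))
  bundles <- tibble(a = c(1L, 1L, 2L), b = c(2L, 3L, 3L),
                    n_streamlines = as.integer(sizes), target_uwmc = targets)
  make_phantom(regions, bundles, grid_shape = c(48L, 48L, 20L), seed = seed)
}

#' Write a phantom's files to a directory
#'
#' Emits `flair.nii.gz`, `wmh.nii.gz`, `cerebellar_wm.nii.gz`,
#' `cerebral_mask.nii.gz`, `labels.nii.gz`, `labels.tsv`, `tract.tck`, and
#' `truth.json`.
#'
#' @param phantom An `uwmc_phantom`.
#' @param dir Output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    flair = file.path(dir, "flair.nii.gz"),
    wmh = file.path(dir, "wmh.nii.gz"),
    cerebellar_wm = file.path(dir, "cerebellar_wm.nii.gz"),
    cerebral_mask = file.path(dir, "cerebral_mask.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    label_table = file.path(dir, "labels.tsv"),
    tractogram = file.path(dir, "tract.tck"),
    truth = file.path(dir, "truth.json"))
  write_volume(phantom$flair, paths$flair)
  write_volume(phantom$wmh, paths$wmh)
  write_volume(phantom$cerebellar_mask, paths$cerebellar_wm)
  write_volume(phantom$cerebral_mask, paths$cerebral_mask)
  write_volume(phantom$labels, paths$labels)
  write_label_table(phantom$labels$table, paths$label_table)
  write_streamlines(phantom$streamlines, paths$tractogram)
  jsonlite::write_json(phantom$truth, paths$truth, digits = NA)
  invisible(paths)
}

#' Intensity phantom for segmentation recovery
#'
#' A two-component Gaussian mixture on a grid: background voxels N(0, 1), a
#' random `lesion_fraction` of cerebral voxels at N(`shift`, 1), plus a
#' disjoint reference block at N(0, 1). Ground-truth lesion labels are
#' returned for Dice evaluation of the segmentation chain.
#'
#' @param grid_shape Grid dimensions.
#' @param lesion_fraction Fraction of cerebral voxels that are lesion.
#' @param shift Lesion mean in background-SD units.
#' @param seed Seed.
#' @return List with `flair` (`uwmc_intensity`), `truth` (`uwmc_mask`),
#'   `cerebral_mask`, `cerebellar_mask`.
#' @export
make_segmentation_phantom <- function(grid_shape = c(32L, 32L, 32L),
                                      lesion_fraction = 0.05, shift = 6,
                                      seed = 1L) {
  dm <- as.integer(grid_shape)
  affine <- diag(4)
  withr::with_seed(seed, {
    cereb <- array(FALSE, dim = dm)
    cereb[1:2, 1:2, ] <- TRUE
    cerebral <- !cereb
    n_cer <- sum(cerebral)
    lesion_idx <- sample(which(cerebral), round(lesion_fraction * n_cer))
    truth <- array(FALSE, dim = dm)
    truth[lesion_idx] <- TRUE
    dat <- array(stats::rnorm(prod(dm)), dim = dm)
    dat[truth] <- stats::rnorm(sum(truth), mean = shift)
    list(flair = intensity_volume(dat, affine),
         truth = binary_mask(truth, affine),
         cerebral_mask = binary_mask(cerebral, affine),
         cerebellar_mask = binary_mask(cereb, affine))
  })
}

default_covariate_effects <- function() {
  list(age = -0.05, sex = 0.3, group = -1.5, education = 0.15,
       physical_activity = 0.3, diabetes = -0.5, hypertension = -0.3,
       high_cholesterol = -0.2, apoe4 = -0.5)
}

#' Simulate a cohort with known connectivity-cognition structure
#'
#' Draws participant covariates from distributions matched to a
#' community-dwelling older-adult cohort (age uniform 50-89; prevalences
#' for female sex 0.667, BA group 0.497, hypertension 0.383, high
#' cholesterol 0.353, APOE e4 0.313, diabetes 0.169; education around 14
#' years; weekly activity log-normal with median ~9.3 h). Per-pair UWMC
#' features are Beta(2, 8) - right-skewed with mass near 0, the shape lobar
#' connectivity fractions show in practice - zero-inflated at
#' `zero_inflation`, with an optional location shift of the Beta mean for
#' the BA group. The cognition score is
#' `intercept + sum(beta_j * ln(feature_j, 0 -> 0.05)) + covariate terms +
#' N(0, noise_sd)`, clipped to \[0, 30\] and rounded to an integer.
#' Covariate terms apply to age centered at 65 and to ln(activity); binary
#' terms are on the indicator.
#'
#' @param n_participants Cohort size.
#' @param n_features Number of UWMC feature columns (`uwmc_001`, ...).
#' @param active_betas Named numeric vector of nonzero effects; names must
#'   be feature column names.
#' @param effect_scale `"log"`: betas are per unit ln(UWMC);
#'   `"standardized"`: betas are rescaled so each active feature's
#'   standardized (unit-SD ln scale) effect equals the stated value in the
#'   generated sample.
#' @param covariate_effects Named list of covariate coefficients (see
#'   `default_covariate_effects()`).
#' @param intercept Latent score at covariate reference values.
#' @param noise_sd Residual SD (> 0).
#' @param group_uwmc_shift Added to the Beta mean of every feature for BA
#'   participants (precision held fixed).
#' @param zero_inflation Probability a feature value is exactly 0.
#' @param seed Seed; the cohort is a deterministic function of it.
#' @return A tibble (`moca`, covariates, feature columns) with a `truth`
#'   attribute recording every generating parameter, including the betas
#'   as applied on the log scale.
#' @export
make_cohort <- function(n_participants = 201L, n_features = 50L,
                        active_betas = c(), effect_scale = c("log", "standardized"),
                        covariate_effects = default_covariate_effects(),
                        intercept = 26, noise_sd = 2,
                        group_uwmc_shift = 0.04, zero_inflation = 0.05,
                        seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  if (noise_sd <= 0) abort("`noise_sd` must be positive")
  n <- as.integer(n_participants)
  feat_names <- sprintf("uwmc_%03d", seq_len(n_features))
  if (length(active_betas) && !all(names(active_betas) %in% feat_names))
    abort("names of `active_betas` must be feature column names (uwmc_###)")
  withr::with_seed(seed, {
    group <- ifelse(stats::rbinom(n, 1, 0.497) == 1, "BA", "nHW")
    age <- stats::runif(n, 50, 89)
    sex <- stats::rbinom(n, 1, 0.667)
    education <- pmin(pmax(round(stats::rnorm(n, 14, 2.5)), 8), 20)
    physical_activity <- stats::rlnorm(n, log(9.3), 0.8)
    diabetes <- stats::rbinom(n, 1, 0.169)
    hypertension <- stats::rbinom(n, 1, 0.383)
    high_cholesterol <- stats::rbinom(n, 1, 0.353)
    apoe4 <- stats::rbinom(n, 1, 0.313)

    nu <- 10; m0 <- 2 / nu                       # Beta(2, 8): mean 0.2
    mu <- ifelse(group == "BA", pmin(m0 + group_uwmc_shift, 0.95), m0)
    feats <- matrix(0, n, n_features, dimnames = list(NULL, feat_names))
    for (j in seq_len(n_features)) {
      v <- stats::rbeta(n, mu * nu, (1 - mu) * nu)
      v[stats::runif(n) < zero_inflation] <- 0
      feats[, j] <- v
    }

    lf <- log_transform(feats)
    betas_log <- stats::setNames(numeric(length(active_betas)), names(active_betas))
    signal <- numeric(n)
    for (nm in names(active_betas)) {
      b <- active_betas[[nm]]
      if (effect_scale == "standardized") b <- b / stats::sd(lf[, nm])
      betas_log[nm] <- b
      signal <- signal + b * lf[, nm]
    }
    ce <- covariate_effects
    lin <- intercept + signal +
      ce$age * (age - 65) + ce$sex * sex + ce$group * (group == "BA") +
      ce$education * (education - 14) +
      ce$physical_activity * log_transform(physical_activity) +
      ce$diabetes * diabetes + ce$hypertension * hypertension +
      ce$high_cholesterol * high_cholesterol + ce$apoe4 * apoe4
    moca <- pmin(pmax(round(lin + stats::rnorm(n, 0, noise_sd)), 0), 30)

    out <- tibble(moca = as.integer(moca), age = age, sex = sex, group = group,
                  education = education, physical_activity = physical_activity,
                  diabetes = diabetes, hypertension = hypertension,
                  high_cholesterol = high_cholesterol, apoe4 = apoe4)
    out <- dplyr::bind_cols(out, as_tibble(feats))
    attr(out, "truth") <- list(
      active_betas_log = betas_log, effect_scale = effect_scale,
      covariate_effects = covariate_effects, intercept = intercept,
      noise_sd = noise_sd, group_uwmc_shift = group_uwmc_shift,
      zero_inflation = zero_inflation, seed = seed)
    out
  })
}
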