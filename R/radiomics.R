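#' First-order histogram features of a VOI
#'
#' Computes nine histogram-based first-order statistics over the in-VOI
#' voxels of a gray-level-quantized volume: mean, SD (population), skewness,
#' kurtosis (Pearson, non-excess), median, 10th and 90th percentiles,
#' Shannon entropy (bits) of the `n_levels`-bin histogram, and uniformity
#' (histogram energy). With fewer than 2 voxels, or a constant region, the
#' moment-based features that would be undefined (SD, skewness, kurtosis)
#' are flagged as 0 with a warning.
#'
#' @param volume An [mr_volume()] quantized to `n_levels` integer levels.
#' @param voi A non-empty [voi_mask()] aligned to `volume`.
#' @param n_levels Number of gray levels used for the histogram entropy and
#'   uniformity (default 256).
#' @return Named numeric vector of length 9.
#' @export
first_order_features <- function(volume, voi, n_levels = 256L) {
  stopifnot(inherits(volume, "mr_volume"), inherits(voi, "voi_mask"))
  check_aligned(volume, voi)
  x <- as.vector(volume$intensities[voi$mask])
  if (length(x) == 0) stopf("VOI is empty")
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)        # population variance
  if (n < 2 || v == 0) {
    if (n < 2) warnf("VOI has < 2 voxels; dispersion features flagged as 0")
    sdev <- 0
    skew <- 0
    kurt <- 0
  } else {
    sdev <- sqrt(v)
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2
  }
  # histogram over the quantized levels
  h <- tabulate(pmin(pmax(as.integer(round(x)), 0L), n_levels - 1L) + 1L,
                nbins = n_levels)
  p <- h[h > 0] / n
  c(
    mean = m,
    sd = sdev,
    skewness = skew,
    kurtosis = kurt,
    median = median(x),
    p10 = quantile(x, 0.10, names = FALSE),
    p90 = quantile(x, 0.90, names = FALSE),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2)
  )
}

# Mesh surface area of a binary mask: the mask indicator is lightly
# Gaussian-smoothed in index space (to suppress the voxel staircase, which
# otherwise inflates the area of the raw indicator isosurface by several
# percent), then the 0.5-level isosurface of the trilinear interpolant is
# tessellated finely and its triangle areas summed.
mask_mesh_area <- function(mask, spacing, sigma = 0.6, subdiv = 4L) {
  pad <- as.integer(ceiling(3 * sigma) + 1L)
  d <- dim(mask)
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  f <- gauss_smooth3d(f, rep(sigma, 3))
  .iso_surface_area(as.vector(f), dim(f), as.numeric(spacing),
                    level = 0.5, subdiv = subdiv)
}

#' Shape features of a VOI
#'
#' Seven mask-geometry descriptors: volume (mL), mesh surface area (mm^2,
#' from a fine tessellation of the 0.5-level isosurface of the trilinear
#' mask interpolant), sphericity `pi^(1/3) (6V)^(2/3) / A`, maximum 3-D
#' diameter (mm, over surface voxel centres), elongation and flatness
#' (square roots of the second/third-to-first principal-moment ratios of
#' the voxel coordinates), and surface-to-volume ratio (1/mm).
#'
#' @param voi A non-empty [voi_mask()].
#' @param spacing Voxel pitch in mm (length 3).
#' @return Named numeric vector of length 7.
#' @export
shape_features <- function(voi, spacing) {
  stopifnot(inherits(voi, "voi_mask"))
  if (!any(voi$mask)) stopf("VOI is empty")
  spacing <- as.numeric(spacing)
  vox_mm3 <- prod(spacing)
  nvox <- sum(voi$mask)
  vol_mm3 <- nvox * vox_mm3
  area <- mask_mesh_area(voi$mask, spacing)
  sphericity <- pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area

  idx <- which(voi$mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  # surface voxels: at least one 6-neighbour outside the mask
  on_surface <- rep(FALSE, nrow(idx))
  d <- dim(voi$mask)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      inside <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      val <- rep(FALSE, nrow(idx))
      val[inside] <- voi$mask[nb[inside, , drop = FALSE]]
      on_surface <- on_surface | !val
    }
  }
  sc <- coords[on_surface, , drop = FALSE]
  max_diam <- if (nrow(sc) > 1) max(stats::dist(sc)) else 0

  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(coords) * (nvox - 1) / nvox,
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elongation <- 1
    flatness <- 1
  }
  c(
    volume_ml = vol_mm3 / 1000,
    surface_area_mm2 = area,
    sphericity = sphericity,
    max_diameter_mm = max_diam,
    elongation = elongation,
    flatness = flatness,
    surface_to_volume = area / vol_mm3
  )
}

#' Lesion location features
#'
#' Center of mass of the VOI in world coordinates (voxel index times
#' spacing). In the emulated study these coordinates live in a standard
#' atlas space; for synthetic cohorts the generator's aligned grid stands
#' in for the atlas.
#'
#' @param voi A non-empty [voi_mask()].
#' @param spacing Voxel pitch in mm (length 3).
#' @return Named numeric vector `c(loc_x, loc_y, loc_z)` of length 3.
#' @export
location_features <- function(voi, spacing) {
  stopifnot(inherits(voi, "voi_mask"))
  if (!any(voi$mask)) stopf("VOI is empty")
  idx <- which(voi$mask, arr.ind = TRUE)
  ctr <- colMeans(idx) * as.numeric(spacing)
  setNames(as.numeric(ctr), c("loc_x", "loc_y", "loc_z"))
}

# The six image channels feeding the first-order block.
RADIOMIC_CHANNELS <- c("T1W", "T2W", "GdT1W", "FLAIR", "T2Edge", "Gdzscore")

#' Build the six radiomic image channels for one patient
#'
#' Applies the radiomic normalization dialects (top-0.1% clip for T1W,
#' GdT1W and FLAIR; full range for T2W), then constructs the derived
#' channels: T2Edge as the Prewitt gradient magnitude of the normalized
#' T2W, and Gdzscore as the brain-masked z-score of the GdT1W minus T1W
#' difference. Both derived channels are re-quantized with the clip dialect
#' so every channel is on a 256-level integer scale.
#'
#' @param volumes Named list of the four acquired sequences.
#' @param n_levels Gray levels (default 256).
#' @return Named list of six quantized [mr_volume()]s.
#' @export
radiomic_channels <- function(volumes, n_levels = 256L) {
  if (!all(MR_SEQUENCES %in% names(volumes))) {
    stopf("volumes must contain %s", paste(MR_SEQUENCES, collapse = ", "))
  }
  clip <- norm_params("radiomics_clip", n_levels)
  fullr <- norm_params("radiomics_fullrange", n_levels)
  t1n <- normalize_volume(volumes$T1W, clip)
  t2n <- normalize_volume(volumes$T2W, fullr)
  gdn <- normalize_volume(volumes$GdT1W, clip)
  fln <- normalize_volume(volumes$FLAIR, clip)
  # brain mask: voxels clearly above background on the raw T1W
  braw <- volumes$T1W$intensities
  brain <- braw > (min(braw) + 0.25 * (max(braw) - min(braw)))
  if (!any(brain)) brain <- array(TRUE, dim(braw))
  edge <- normalize_volume(t2edge(t2n), clip)
  gz <- normalize_volume(gdzscore(t1n, gdn, brain), clip)
  list(T1W = t1n, T2W = t2n, GdT1W = gdn, FLAIR = fln,
       T2Edge = edge, Gdzscore = gz)
}

#' The default radiomic feature registry
#'
#' Declarative list of the conventional feature set: 9 first-order
#' statistics for each of the 6 image channels (54), 7 shape descriptors
#' (61 radiomic features in total) and 3 location coordinates, i.e. 64
#' values per patient. The registry fixes the feature names and their
#' order; an alternative composition can be supplied to
#' [patient_radiomic_features()] if a different handcrafted set is wanted.
#'
#' @return Character vector of 64 feature names in canonical order.
#' @export
radiomic_registry <- function() {
  fo <- c("mean", "sd", "skewness", "kurtosis", "median", "p10", "p90",
          "entropy", "uniformity")
  c(
    as.vector(vapply(RADIOMIC_CHANNELS,
                     function(ch) paste(ch, fo, sep = "_"),
                     character(length(fo)))),
    paste0("shape_", c("volume_ml", "surface_area_mm2", "sphericity",
                       "max_diameter_mm", "elongation", "flatness",
                       "surface_to_volume")),
    c("loc_x", "loc_y", "loc_z")
  )
}

#' Conventional radiomic feature vector for one patient
#'
#' @param patient A patient record (see [generate_cohort()]).
#' @param n_levels Gray levels for quantization and histograms.
#' @return Named numeric vector of length 64 ordered as
#'   [radiomic_registry()].
#' @export
patient_radiomic_features <- function(patient, n_levels = 256L) {
  chans <- radiomic_channels(patient$volumes, n_levels)
  voi <- patient$lesion_voi
  sp <- patient$volumes$T1W$spacing
  fo <- unlist(lapply(RADIOMIC_CHANNELS, function(ch) {
    f <- first_order_features(chans[[ch]], voi, n_levels)
    setNames(f, paste(ch, names(f), sep = "_"))
  }))
  sh <- shape_features(voi, sp)
  names(sh) <- paste0("shape_", names(sh))
  out <- c(fo, sh, location_features(voi, sp))
  stopifnot(identical(names(out), radiomic_registry()))
  out
}

#' Radiomic feature matrix for a cohort
#'
#' @param cohort A `glioma_cohort`.
#' @param n_levels Gray levels.
#' @return Numeric matrix, one row per patient (rownames = patient ids),
#'   64 columns named as [radiomic_registry()].
#' @export
cohort_radiomic_features <- function(cohort, n_levels = 256L) {
  reg <- radiomic_registry()
  out <- t(vapply(cohort, patient_radiomic_features,
                  numeric(length(reg)), n_levels = n_levels))
  rownames(out) <- vapply(cohort, `[[`, "", "patient_id")
  out
}
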