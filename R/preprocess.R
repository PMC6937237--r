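#' Intensity-normalization parameters
#'
#' Three dialects are used in the pipeline:
#' \describe{
#'   \item{`radiomics_clip`}{Voxels in the top 0.1% of the intensity
#'     histogram are treated as high-signal noise; the surviving range is
#'     reallocated linearly to `n_levels` integer gray levels and the noise
#'     voxels are mapped to the top level. Used for T1W, GdT1W and FLAIR in
#'     the radiomic branch.}
#'   \item{`radiomics_fullrange`}{100% of the data range is reallocated to
#'     `n_levels` gray levels (no noise deletion). Used for T2W.}
#'   \item{`cnn_percentile`}{Linear rescale so the 2.5th percentile maps to
#'     0 and the 97.5th to 1, clipping outside; computed per volume. Used
#'     for the convolutional feature branch of every sequence.}
#' }
#'
#' @param dialect One of `"radiomics_clip"`, `"radiomics_fullrange"`,
#'   `"cnn_percentile"`.
#' @param n_levels Number of gray levels for the radiomics dialects
#'   (default 256; must be >= 2).
#' @return A `norm_params` list.
#' @export
norm_params <- function(dialect = c("radiomics_clip", "radiomics_fullrange",
                                    "cnn_percentile"),
                        n_levels = 256L) {
  dialect <- match.arg(dialect)
  if (n_levels < 2) stopf("`n_levels` must be >= 2")
  structure(list(dialect = dialect, n_levels = as.integer(n_levels)),
            class = "norm_params")
}

# level = floor((x - lo) / (hi - lo) * n) capped at n - 1; constant input
# maps everything to level 0 (documented convention).
quantize_levels <- function(x, lo, hi, n) {
  if (hi <= lo) {
    return(rep(0L, length(x)))
  }
  pmin(as.integer(floor((pmin(pmax(x, lo), hi) - lo) / (hi - lo) * n)),
       n - 1L)
}

#' Normalize an MR volume
#'
#' Applies one of the three intensity-normalization dialects (see
#' [norm_params()]). The radiomics dialects return integer gray levels in
#' `[0, n_levels - 1]`, monotone in the input intensity; the clip dialect
#' flags the top 0.1% of voxels as noise (the count is attached as
#' attribute `n_noise` and the flagged voxels map to the top level, keeping
#' the grid dense). The CNN dialect returns values in `[0, 1]`.
#'
#' @param volume An [mr_volume()].
#' @param params A [norm_params()].
#' @return A normalized [mr_volume()]; clip dialect attaches `n_noise`.
#' @export
normalize_volume <- function(volume, params) {
  stopifnot(inherits(volume, "mr_volume"), inherits(params, "norm_params"))
  x <- volume$intensities
  n <- length(x)
  out <- switch(params$dialect,
    radiomics_fullrange = {
      array(quantize_levels(x, min(x), max(x), params$n_levels), dim(x))
    },
    radiomics_clip = {
      k <- floor(0.001 * n)
      s <- sort(as.vector(x))
      cutoff <- s[n - k]         # k-th largest values lie strictly above
      noise <- x > cutoff
      lev <- quantize_levels(x, min(x), cutoff, params$n_levels)
      lev[noise] <- params$n_levels - 1L
      res <- array(lev, dim(x))
      attr(res, "n_noise") <- sum(noise)
      res
    },
    cnn_percentile = {
      q <- quantile(x, c(0.025, 0.975), names = FALSE)
      if (q[2] <= q[1]) {
        array(0, dim(x))
      } else {
        array(pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1), dim(x))
      }
    }
  )
  v <- mr_volume(out, volume$spacing, volume$sequence)
  if (!is.null(attr(out, "n_noise"))) {
    attr(v, "n_noise") <- attr(out, "n_noise")
  }
  v
}

# 3x3 convolution of a matrix with replicate (edge-clamp) padding.
conv3x3_replicate <- function(m, kernel) {
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      out <- out + kernel[di + 2, dj + 2] *
        pad[seq_len(nr) + 1 + di, seq_len(nc) + 1 + dj]
    }
  }
  out
}

#' T2 edge map (Prewitt gradient magnitude)
#'
#' Builds the derived T2Edge channel: for each axial slice of the
#' (normalized) T2W volume, the 2-D Prewitt gradient magnitude
#' `sqrt(Gx^2 + Gy^2)` with replicate padding at the slice borders.
#'
#' @param t2 A normalized T2W [mr_volume()].
#' @return An [mr_volume()] tagged `"T2Edge"`.
#' @export
t2edge <- function(t2) {
  stopifnot(inherits(t2, "mr_volume"))
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # gradient along rows
  ky <- t(kx)
  x <- t2$intensities
  out <- array(0, dim(x))
  for (k in seq_len(dim(x)[3])) {
    gx <- conv3x3_replicate(x[, , k], kx)
    gy <- conv3x3_replicate(x[, , k], ky)
    out[, , k] <- sqrt(gx^2 + gy^2)
  }
  mr_volume(out, t2$spacing, "T2Edge")
}

#' Contrast-enhancement z-score map
#'
#' Builds the derived Gdzscore channel: the voxelwise difference between the
#' contrast-enhanced and non-contrast T1-weighted volumes, standardized by
#' the mean and SD of that difference within the brain mask.
#'
#' @param t1 Non-contrast T1W [mr_volume()], normalized.
#' @param gdt1 Contrast-enhanced GdT1W [mr_volume()], normalized to the same
#'   scale and aligned to `t1`.
#' @param brain_mask A [voi_mask()] (or logical array) of brain voxels over
#'   which the difference moments are computed.
#' @return An [mr_volume()] tagged `"Gdzscore"`. If the within-mask SD of
#'   the difference is zero, an all-zero map is returned with a warning.
#' @export
gdzscore <- function(t1, gdt1, brain_mask) {
  stopifnot(inherits(t1, "mr_volume"), inherits(gdt1, "mr_volume"))
  mask <- if (inherits(brain_mask, "voi_mask")) brain_mask$mask else brain_mask
  if (!identical(dim(t1$intensities), dim(gdt1$intensities)) ||
      !identical(dim(t1$intensities), dim(mask))) {
    stopf("t1, gdt1 and brain_mask must share the same grid")
  }
  if (!any(mask)) stopf("brain mask is empty")
  d <- gdt1$intensities - t1$intensities
  mu <- mean(d[mask])
  sdd <- sd(as.vector(d[mask]))
  if (!is.finite(sdd) || sdd == 0) {
    warnf("zero variance of Gd-T1 difference within brain mask; returning zeros")
    return(mr_volume(array(0, dim(d)), t1$spacing, "Gdzscore"))
  }
  mr_volume((d - mu) / sdd, t1$spacing, "Gdzscore")
}

# Bilinear resize with centre-aligned sampling: output pixel i samples input
# coordinate (i + 0.5) * n_in / n_out - 0.5 (clamped), which makes the
# operation commute with axis flips.
resize_bilinear <- function(m, out_r, out_c) {
  nr <- nrow(m)
  nc <- ncol(m)
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sr <- src(out_r, nr)
  sc <- src(out_c, nc)
  r0 <- pmin(floor(sr), nr - 1)
  c0 <- pmin(floor(sc), nc - 1)
  fr <- sr - r0
  fc <- sc - c0
  r1 <- pmin(r0 + 1, nr - 1)
  c1 <- pmin(c0 + 1, nc - 1)
  # 1-based corners
  a <- m[cbind(rep(r0 + 1, out_c), rep(c0 + 1, each = out_r))]
  b <- m[cbind(rep(r1 + 1, out_c), rep(c0 + 1, each = out_r))]
  cc <- m[cbind(rep(r0 + 1, out_c), rep(c1 + 1, each = out_r))]
  d <- m[cbind(rep(r1 + 1, out_c), rep(c1 + 1, each = out_r))]
  wfr <- rep(fr, out_c)
  wfc <- rep(fc, each = out_r)
  matrix((1 - wfr) * (1 - wfc) * a + wfr * (1 - wfc) * b +
           (1 - wfr) * wfc * cc + wfr * wfc * d, out_r, out_c)
}

#' Cut the lesion image from a volume
#'
#' On the center slice of the VOI in the axial direction (the middle index
#' of the VOI's occupied slice range, ties broken toward the lower index),
#' crops the tight 2-D bounding box of the VOI and resizes it to
#' `size x size` pixels by bilinear interpolation, regardless of aspect
#' ratio.
#'
#' @param volume An [mr_volume()] (CNN-percentile normalized for the
#'   convolutional branch).
#' @param voi A non-empty [voi_mask()] aligned to `volume`.
#' @param size Output side length in pixels (default 243).
#' @return A `lesion_image`: list with `pixels` (`size x size` matrix),
#'   `sequence`, `slice_index` and `source_bbox` (row/col ranges).
#' @export
cut_lesion_image <- function(volume, voi, size = 243L) {
  stopifnot(inherits(volume, "mr_volume"), inherits(voi, "voi_mask"))
  check_aligned(volume, voi)
  if (!any(voi$mask)) stopf("VOI is empty")
  occ <- which(apply(voi$mask, 3, any))
  center <- as.integer(floor((min(occ) + max(occ)) / 2))
  if (!center %in% occ) {       # hollow shapes: nearest occupied slice, low tie
    center <- occ[which.min(abs(occ - center))]
  }
  sl <- voi$mask[, , center]
  rows <- range(which(apply(sl, 1, any)))
  cols <- range(which(apply(sl, 2, any)))
  crop <- volume$intensities[rows[1]:rows[2], cols[1]:cols[2], center,
                             drop = FALSE]
  crop <- matrix(crop, nrow = rows[2] - rows[1] + 1)
  structure(
    list(
      pixels = resize_bilinear(crop, size, size),
      sequence = volume$sequence,
      slice_index = center,
      source_bbox = list(rows = rows, cols = cols)
    ),
    class = "lesion_image"
  )
}
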