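#' MR volume container
#'
#' A 3-D intensity grid with voxel spacing and a sequence tag. This is the
#' unit every preprocessing and feature-extraction step consumes.
#'
#' @param intensities 3-D numeric array of voxel intensities (all finite).
#' @param spacing Numeric length-3, voxel pitch in mm per axis.
#' @param sequence Sequence tag, e.g. `"T1W"`, `"T2W"`, `"GdT1W"`, `"FLAIR"`,
#'   `"T2Edge"` or `"Gdzscore"`.
#' @return An object of class `mr_volume`.
#' @export
mr_volume <- function(intensities, spacing = c(1, 1, 1), sequence = "T1W") {
  if (length(dim(intensities)) != 3L) {
    stopf("`intensities` must be a 3-D array")
  }
  if (!all(is.finite(intensities))) {
    stopf("`intensities` must be finite")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("`spacing` must be 3 positive values (mm)")
  }
  structure(
    list(
      intensities = intensities,
      spacing = as.numeric(spacing),
      sequence = as.character(sequence)
    ),
    class = "mr_volume"
  )
}

#' @export
print.mr_volume <- function(x, ...) {
  cat(sprintf(
    "<mr_volume %s: %s voxels @ %s mm, range [%.3g, %.3g]>\n",
    x$sequence, paste(dim(x$intensities), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' Binary 3-D mask aligned to an [mr_volume()]; `role` distinguishes the
#' traced lesion from its sagittally mirrored normal-tissue control.
#'
#' @param mask 3-D logical array.
#' @param role `"lesion"` or `"normal"`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, role = c("lesion", "normal")) {
  role <- match.arg(role)
  if (length(dim(mask)) != 3L) stopf("`mask` must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stopf("`mask` must not contain NA")
  if (role == "lesion" && !any(mask)) stopf("lesion VOI must be non-empty")
  structure(list(mask = mask, role = role), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf(
    "<voi_mask %s: %d/%d voxels>\n", x$role, sum(x$mask), length(x$mask)
  ))
  invisible(x)
}

check_aligned <- function(volume, voi) {
  if (!identical(dim(volume$intensities), dim(voi$mask))) {
    stopf(
      "volume (%s) and VOI (%s) shapes differ",
      paste(dim(volume$intensities), collapse = "x"),
      paste(dim(voi$mask), collapse = "x")
    )
  }
  invisible(TRUE)
}
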