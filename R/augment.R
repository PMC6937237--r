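rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rotate_k <- function(m, k) {
  k <- k %% 4L
  while (k > 0L) {
    m <- rot90_cw(m)
    k <- k - 1L
  }
  m
}

hflip <- function(m) m[, ncol(m):1, drop = FALSE]

#' Augment a lesion image by cropping, rotating and flipping
#'
#' From a 243 x 243 lesion image, crops nine 227 x 227 images with shifts of
#' 0 or +/-8 pixels in the x/y direction from the centre, then rotates each
#' crop by 0/90/180/270 degrees and either horizontally flips it or not,
#' yielding 72 augmented images. Enumeration order is fixed: crops row-major
#' over (dy, dx) in {-8, 0, +8}^2, then rotation, then flip state. Exactly
#' one output (dx = dy = 0, rotation 0, no flip) carries `is_center = TRUE`;
#' only that sample is used when scoring a classifier.
#'
#' @param image A `lesion_image` from [cut_lesion_image()] (or a bare
#'   243 x 243 matrix).
#' @param crop_size Side of the cropped images (default 227).
#' @param shift Crop shift magnitude in pixels (default 8).
#' @return List of 72 `augmented_image` objects: `pixels`
#'   (`crop_size x crop_size`), `transform` (list `dx`, `dy`, `rotation`,
#'   `hflip`) and `is_center`.
#' @export
augment <- function(image, crop_size = 227L, shift = 8L) {
  px <- if (inherits(image, "lesion_image")) image$pixels else image
  if (!is.matrix(px) || nrow(px) != ncol(px)) {
    stopf("augment() expects a square lesion image")
  }
  n <- nrow(px)
  if (n < crop_size + 2L * shift) {
    stopf("image side %d too small for %d crops with shift %d",
          n, crop_size, shift)
  }
  base <- (n - crop_size) %/% 2L   # 0-based start of the centre crop
  out <- vector("list", 9L * 4L * 2L)
  i <- 0L
  for (dy in c(-shift, 0L, shift)) {
    for (dx in c(-shift, 0L, shift)) {
      crop <- px[base + dy + seq_len(crop_size),
                 base + dx + seq_len(crop_size)]
      for (rot in c(0L, 90L, 180L, 270L)) {
        rotated <- rotate_k(crop, rot %/% 90L)
        for (fl in c(FALSE, TRUE)) {
          i <- i + 1L
          out[[i]] <- structure(
            list(
              pixels = if (fl) hflip(rotated) else rotated,
              transform = list(dx = dx, dy = dy, rotation = rot, hflip = fl),
              is_center = dx == 0L && dy == 0L && rot == 0L && !fl
            ),
            class = "augmented_image"
          )
        }
      }
    }
  }
  out
}

#' Centre crop of a lesion image
#'
#' The single `is_center` member of [augment()]'s output (no shift, no
#' rotation, no flip), used for scoring.
#'
#' @inheritParams augment
#' @return An `augmented_image`.
#' @export
center_crop <- function(image, crop_size = 227L) {
  px <- if (inherits(image, "lesion_image")) image$pixels else image
  base <- (nrow(px) - crop_size) %/% 2L
  structure(
    list(
      pixels = px[base + seq_len(crop_size), base + seq_len(crop_size)],
      transform = list(dx = 0L, dy = 0L, rotation = 0L, hflip = FALSE),
      is_center = TRUE
    ),
    class = "augmented_image"
  )
}
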