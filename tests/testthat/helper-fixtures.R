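# Shared fixtures, built in code at test time.

# A small cohort on a reduced grid (fast to generate, full pipeline still
# runs on it).
small_cohort <- function(n = 12, texture_effect = 2, seed = 101, ...) {
  generate_cohort(synthetic_config(
    n_patients = n, texture_effect = texture_effect,
    volume_shape = c(32, 32, 20), seed = seed, ...
  ))
}

# Digitized sphere mask of radius r (mm) at isotropic spacing sp (mm).
sphere_mask <- function(r, sp = 1) {
  n <- ceiling(2 * r / sp) + 7
  c0 <- (n + 1) / 2
  g <- seq_len(n)
  outer(outer((g - c0)^2, (g - c0)^2, `+`), (g - c0)^2, `+`) <= (r / sp)^2
}

# Ellipsoid VOI occupying a controlled axial slice range.
slab_ellipsoid_voi <- function(shape = c(40, 40, 30), zmin = 10, zmax = 20) {
  ctr <- c(shape[1] / 2, shape[2] / 2, (zmin + zmax) / 2)
  semi <- c(8, 6, (zmax - zmin) / 2)
  m <- array(FALSE, shape)
  for (k in seq_len(shape[3])) {
    dz2 <- ((k - ctr[3]) / semi[3])^2
    if (dz2 > 1) next
    dx <- (seq_len(shape[1]) - ctr[1]) / semi[1]
    dy <- (seq_len(shape[2]) - ctr[2]) / semi[2]
    m[, , k] <- outer(dx^2, dy^2, `+`) <= 1 - dz2
  }
  voi_mask(m, "lesion")
}

# A tiny deterministic "planted feature" extractor for layer-selection
# tests: one layer carries image summary statistics (separable), the other
# is constant noise-free padding (uninformative).
planted_extractor <- function(planted = "layB", dim_each = 8L) {
  layers <- c("layA", "layB")
  structure(
    list(
      kind = "planted",
      layer_names = layers,
      layer_dims = setNames(rep(as.integer(dim_each), 2), layers),
      forward = function(pixels, layers_req = NULL) {
        if (is.null(layers_req)) layers_req <- layers
        px <- if (length(dim(pixels)) == 3) pixels[, , 1] else pixels
        info <- c(mean(px), sd(as.vector(px)), median(px),
                  mean(px[px >= median(px)]), quantile(px, 0.9, names = FALSE),
                  quantile(px, 0.1, names = FALSE), max(px), min(px))
        out <- list(
          layA = rep(0.5, dim_each),
          layB = info[seq_len(dim_each)]
        )
        if (planted == "layA") out <- list(layA = out$layB, layB = out$layA)
        out[layers_req]
      }
    ),
    class = "feature_extractor"
  )
}

# Independent brute-force average precision: O(n^2) threshold enumeration,
# precision/recall recounted from scratch at every distinct score.
auprc_bruteforce <- function(scores, positives) {
  npos <- sum(positives)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    called <- scores >= t
    prec <- sum(positives & called) / sum(called)
    rec <- sum(positives & called) / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
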