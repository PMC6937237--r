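test_that("augmentation yields 72 images: 9 crops x 4 rotations x 2 flips", {
  set.seed(15)
  img <- matrix(runif(243 * 243), 243, 243)
  aug <- augment(img)
  expect_length(aug, 72)
  tr <- lapply(aug, `[[`, "transform")
  offs <- unique(vapply(tr, function(t) paste(t$dx, t$dy), ""))
  expect_length(offs, 9)
  expect_identical(sum(vapply(aug, `[[`, FALSE, "is_center")), 1L)
  # all transform tuples distinct
  keys <- vapply(tr, function(t) paste(t$dx, t$dy, t$rotation, t$hflip), "")
  expect_identical(anyDuplicated(keys), 0L)
  for (a in aug) expect_identical(dim(a$pixels), c(227L, 227L))
  # the centre sample equals the plain centre crop
  ctr <- aug[[which(vapply(aug, `[[`, FALSE, "is_center"))]]
  expect_identical(ctr$pixels, center_crop(img)$pixels)
  expect_identical(ctr$pixels, img[9:235, 9:235])
  expect_error(augment(matrix(0, 240, 240)), "too small")
})

test_that("flipping twice undoes the flip; rotations compose mod 360", {
  set.seed(16)
  img <- matrix(runif(243 * 243), 243, 243)
  aug <- augment(img)
  key <- function(t) paste(t$dx, t$dy, t$rotation, t$hflip)
  by_key <- setNames(aug, vapply(aug, function(a) key(a$transform), ""))
  for (k0 in c("0 0 0", "8 -8 90", "-8 8 270")) {
    plain <- by_key[[paste(k0, "FALSE")]]$pixels
    flipped <- by_key[[paste(k0, "TRUE")]]$pixels
    expect_identical(flipped[, 227:1], plain)   # hflip is an involution
  }
  # rotating the 90-degree image three more quarter-turns returns the crop
  r90 <- by_key[["0 0 90 FALSE"]]$pixels
  r0 <- by_key[["0 0 0 FALSE"]]$pixels
  expect_identical(rgpipe:::rotate_k(r90, 3), r0)
})

test_that("constant input collapses pixel content but not transforms", {
  aug <- augment(matrix(1, 243, 243))
  expect_true(all(vapply(aug, function(a) all(a$pixels == 1), TRUE)))
  keys <- vapply(aug, function(a) {
    paste(a$transform$dx, a$transform$dy, a$transform$rotation,
          a$transform$hflip)
  }, "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("extractor is deterministic and respects the layer contract", {
  ext <- random_conv_extractor(seed = 5)
  expect_identical(names(ext$layer_dims), ext$layer_names)
  expect_false(any(grepl("relu|dropout", ext$layer_names)))
  set.seed(17)
  img <- matrix(runif(227 * 227), 227, 227)
  v1 <- extract_features(img, ext, "conv5")
  v2 <- extract_features(img, ext, "conv5")
  expect_identical(v1, v2)
  expect_length(v1, ext$layer_dims[["conv5"]])
  expect_error(extract_features(img, ext, "conv99"), "unknown layer")
  # same seed -> same weights; different seed -> different features
  ext2 <- random_conv_extractor(seed = 5)
  expect_identical(extract_features(img, ext2, "conv3"),
                   extract_features(img, ext, "conv3"))
  ext3 <- random_conv_extractor(seed = 6)
  expect_false(identical(extract_features(img, ext3, "conv3"),
                         extract_features(img, ext, "conv3")))
})

test_that("zero-weight extractor returns zero activations", {
  ext <- random_conv_extractor(seed = 1)
  ext$weights <- lapply(ext$weights, function(w) {
    list(W = w$W * 0, b = w$b * 0)
  })
  img <- matrix(runif(227 * 227), 227, 227)
  expect_true(all(extract_features(img, ext, "conv1") == 0))
  expect_true(all(extract_features(img, ext, "fc7") == 0))
})

test_that("conv1 activations match direct convolution arithmetic", {
  ext <- random_conv_extractor(seed = 23)
  set.seed(24)
  img <- matrix(runif(227 * 227), 227, 227)
  act <- extract_features(img, ext, "conv1")
  W <- ext$weights$conv1$W
  # oracle: direct dot product over the 11x11x3 receptive field; channels
  # are the replicated grayscale. Output (oi, oj, oc) flattens column-major.
  oh <- 55L
  direct <- function(oi, oj, oc) {
    acc <- 0
    for (c0 in 0:2) for (ki in 0:10) for (kj in 0:10) {
      acc <- acc + img[(oi - 1) * 4 + ki + 1, (oj - 1) * 4 + kj + 1] *
        W[(c0 * 11 + ki) * 11 + kj + 1, oc]
    }
    acc
  }
  for (pt in list(c(1, 1, 1), c(10, 3, 5), c(55, 55, 12), c(7, 40, 2))) {
    flat <- pt[1] + oh * (pt[2] - 1) + oh * oh * (pt[3] - 1)
    expect_equal(act[flat], direct(pt[1], pt[2], pt[3]), tolerance = 1e-10)
  }
})

test_that("neuron sampling is fixed and concatenation is order-stable", {
  ext <- random_conv_extractor(seed = 2)
  ns1 <- neuron_sample("conv5", ext$layer_dims[["conv5"]], 50, seed = 9)
  ns2 <- neuron_sample("conv5", ext$layer_dims[["conv5"]], 50, seed = 9)
  expect_identical(ns1, ns2)
  expect_identical(anyDuplicated(ns1$indices), 0L)
  expect_true(all(ns1$indices <= ext$layer_dims[["conv5"]]))
  expect_error(neuron_sample("conv5", 100, 101, 1), "cannot sample")

  set.seed(30)
  per_seq <- setNames(lapply(1:4, function(i) rnorm(4056)),
                      c("T1W", "T2W", "GdT1W", "FLAIR"))
  v <- concat_sequences(per_seq, ns1)
  expect_length(v, 200)
  # permuting the input map order does not change the output
  v2 <- concat_sequences(per_seq[c(3, 1, 4, 2)], ns1)
  expect_identical(v, v2)
  # fixed concatenation order T1W | T2W | GdT1W | FLAIR
  expect_identical(unname(v[1:50]), per_seq$T1W[ns1$indices])
  expect_identical(unname(v[151:200]), per_seq$FLAIR[ns1$indices])
  expect_error(concat_sequences(per_seq[1:3], ns1), "missing sequence")
  # single-sequence variant
  expect_length(concat_sequences(per_seq, ns1, sequences = "T2W"), 50)
})

test_that("centre-crop features equal the is_center augmented features", {
  ext <- planted_extractor()
  co <- small_cohort(n = 3, seed = 41)
  f_aug <- cohort_cnn_features(co, ext, "layB", k = 4, seed = 1,
                               augmented = TRUE)
  f_ctr <- cohort_cnn_features(co, ext, "layB", k = 4, seed = 1,
                               augmented = FALSE)
  expect_identical(nrow(f_aug$x), 3L * 72L)
  expect_identical(nrow(f_ctr$x), 3L)
  expect_equal(f_aug$x[f_aug$is_center, ], f_ctr$x, ignore_attr = TRUE)
})

test_that("layer selection finds the planted informative layer", {
  co <- small_cohort(n = 14, seed = 43)
  for (planted in c("layA", "layB")) {
    ext <- planted_extractor(planted)
    sel <- suppressWarnings(select_layer(
      co, ext, k = 4, seed = 3, outer_k = 3, inner_k = 2,
      cost_grid = c(0.1, 10)
    ))
    expect_identical(sel$best_layer, planted)
    expect_identical(nrow(sel$summary), 2L)
    expect_true(all(c("accuracy", "ci95", "auprc") %in%
                      colnames(sel$summary)))
  }
})
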