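test_that("full-range quantization matches the direct formula", {
  vals <- 0:999
  vol <- mr_volume(array(as.numeric(vals), c(10, 10, 10)))
  out <- normalize_volume(vol, norm_params("radiomics_fullrange"))
  # oracle: closed-form fixed-bin-count rule over all 1000 values
  expected <- pmin(floor((vals - 0) / (999 - 0) * 256), 255)
  expect_identical(as.vector(out$intensities), as.integer(expected))
  expect_identical(range(out$intensities), c(0L, 255L))
})

test_that("clip dialect deletes exactly the top 0.1% of voxels", {
  set.seed(3)
  x <- sample(seq_len(10000))          # 10,000 distinct intensities
  vol <- mr_volume(array(as.numeric(x), c(100, 100, 1)))
  out <- normalize_volume(vol, norm_params("radiomics_clip"))
  expect_identical(attr(out, "n_noise"), 10L)
  expect_identical(sum(out$intensities == 255L & x > sort(x)[9990]), 10L)
})

test_that("constant volumes map to a uniform output in every dialect", {
  vol <- mr_volume(array(7, c(5, 5, 5)))
  for (d in c("radiomics_clip", "radiomics_fullrange", "cnn_percentile")) {
    out <- normalize_volume(vol, norm_params(d))
    expect_identical(length(unique(as.vector(out$intensities))), 1L)
  }
})

test_that("cnn percentile dialect maps the 2.5/97.5 percentiles to 0/1", {
  set.seed(9)
  x <- rnorm(8000)
  vol <- mr_volume(array(x, c(20, 20, 20)))
  out <- normalize_volume(vol, norm_params("cnn_percentile"))
  q <- quantile(x, c(0.025, 0.975), names = FALSE)
  expect_equal(range(out$intensities), c(0, 1))
  mid <- x > q[1] & x < q[2]
  expect_equal(out$intensities[mid], (x[mid] - q[1]) / (q[2] - q[1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalization is monotone and bounded to n_levels values", {
  set.seed(21)
  for (d in c("radiomics_clip", "radiomics_fullrange", "cnn_percentile")) {
    x <- c(rnorm(4000), rep(2.5, 96))   # include ties
    vol <- mr_volume(array(x, c(16, 16, 16)))
    out <- normalize_volume(vol, norm_params(d))
    o <- order(x)
    expect_true(all(diff(as.vector(out$intensities)[o]) >= 0))
    if (d != "cnn_percentile") {
      expect_lte(length(unique(as.vector(out$intensities))), 256)
    }
  }
})

test_that("prewitt edge map matches explicit 3x3 convolution", {
  # constant slice -> zero edge
  cvol <- mr_volume(array(4, c(8, 8, 2)))
  expect_true(all(t2edge(cvol)$intensities == 0))
  expect_identical(t2edge(cvol)$sequence, "T2Edge")

  # oracle: direct 3x3 convolution with replicate padding at chosen pixels
  set.seed(5)
  sl <- matrix(rnorm(100), 10, 10)
  vol <- mr_volume(array(sl, c(10, 10, 1)))
  edge <- t2edge(vol)$intensities[, , 1]
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)
  ky <- t(kx)
  conv_at <- function(img, kern, i, j) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nrow(img))
      jj <- min(max(j + dj, 1), ncol(img))
      acc <- acc + kern[di + 2, dj + 2] * img[ii, jj]
    }
    acc
  }
  for (px in list(c(1, 1), c(5, 5), c(10, 3), c(2, 10))) {
    gx <- conv_at(sl, kx, px[1], px[2])
    gy <- conv_at(sl, ky, px[1], px[2])
    expect_equal(edge[px[1], px[2]], sqrt(gx^2 + gy^2), tolerance = 1e-12)
  }

  # unit vertical step edge: response equals the Prewitt column-kernel sum
  st <- matrix(0, 9, 9)
  st[, 6:9] <- 1
  sv <- mr_volume(array(st, c(9, 9, 1)))
  e <- t2edge(sv)$intensities[, , 1]
  expect_equal(e[5, 5], sum(abs(kx[, 3])), tolerance = 1e-12)
})

test_that("gdzscore standardizes the masked difference field", {
  set.seed(8)
  d <- array(rnorm(4000), c(20, 20, 10))
  t1 <- mr_volume(array(5, c(20, 20, 10)))
  gd <- mr_volume(t1$intensities + d)
  mask <- array(TRUE, c(20, 20, 10))
  z <- gdzscore(t1, gd, mask)
  expect_identical(z$sequence, "Gdzscore")
  # oracle: recompute moments directly
  expect_equal(mean(z$intensities), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z$intensities)), 1, tolerance = 1e-12)
  expect_equal(z$intensities, (d - mean(d)) / sd(as.vector(d)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # gdt1 == t1 -> zeros (with zero-variance warning)
  expect_warning(z0 <- gdzscore(t1, t1, mask), "zero variance")
  expect_true(all(z0$intensities == 0))
})

test_that("edge and z-score maps commute with spatial flips", {
  set.seed(12)
  x <- array(rnorm(20 * 18 * 6), c(20, 18, 6))
  flip1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  v <- mr_volume(x)
  expect_equal(t2edge(mr_volume(flip1(x)))$intensities,
               flip1(t2edge(v)$intensities), tolerance = 1e-12)
  gd <- mr_volume(x + array(rnorm(length(x), 0, 0.3), dim(x)))
  mask <- array(TRUE, dim(x))
  expect_equal(gdzscore(mr_volume(flip1(x)), mr_volume(flip1(gd$intensities)),
                        mask)$intensities,
               flip1(gdzscore(v, gd, mask)$intensities), tolerance = 1e-12)
})

test_that("lesion image cutting picks the centre slice and resizes to 243", {
  voi <- slab_ellipsoid_voi(zmin = 10, zmax = 20)
  set.seed(2)
  vol <- mr_volume(array(runif(prod(dim(voi$mask))), dim(voi$mask)))
  li <- cut_lesion_image(vol, voi)
  # oracle: middle of the occupied axial range
  occ <- which(apply(voi$mask, 3, any))
  expect_identical(li$slice_index, as.integer(floor((min(occ) + max(occ)) / 2)))
  expect_identical(li$slice_index, 15L)
  expect_identical(dim(li$pixels), c(243L, 243L))

  # odd-length range ties break low
  voi2 <- slab_ellipsoid_voi(zmin = 10, zmax = 21)
  expect_identical(cut_lesion_image(vol, voi2)$slice_index, 15L)

  # 1-voxel VOI -> constant image
  m1 <- array(FALSE, c(12, 12, 6))
  m1[4, 7, 3] <- TRUE
  v1 <- mr_volume(array(seq_len(12 * 12 * 6) / 100, c(12, 12, 6)))
  li1 <- cut_lesion_image(v1, voi_mask(m1, "lesion"))
  expect_identical(length(unique(as.vector(li1$pixels))), 1L)
  expect_equal(li1$pixels[1, 1], v1$intensities[4, 7, 3])
})

test_that("lesion cutting commutes with in-plane flips", {
  voi <- slab_ellipsoid_voi()
  set.seed(4)
  vol <- mr_volume(array(runif(prod(dim(voi$mask))), dim(voi$mask)))
  flip1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  li <- cut_lesion_image(vol, voi)
  lif <- cut_lesion_image(mr_volume(flip1(vol$intensities)),
                          voi_mask(flip1(voi$mask), "lesion"))
  expect_equal(lif$pixels, li$pixels[243:1, ], tolerance = 1e-6)
})
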