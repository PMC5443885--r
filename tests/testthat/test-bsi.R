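# BSI building blocks: k-means centroids, normalisation, boundary shell,
# clipped integral, composed variants, differential bias correction.

test_that("k-means recovers three well-separated intensity modes", {
  set.seed(31)
  vals <- c(rnorm(2000, 10, 1), rnorm(2000, 50, 1), rnorm(2000, 90, 1))
  img <- array(vals, dim = c(30, 20, 10))
  mask <- array(TRUE, dim = dim(img))
  cts <- tissue_means_kmeans(img, mask, k = 3)
  expect_equal(cts, c(10, 50, 90), tolerance = 0.1)

  # independent cross-check against the stock k-means on the same data
  km <- sort(unname(kmeans(vals, centers = cts)$centers[, 1]))
  expect_equal(cts, km, tolerance = 1e-3)
})

test_that("k-means degenerate inputs error and k = 1 is the masked mean", {
  img <- array(5, dim = c(4, 4, 4))
  mask <- array(TRUE, dim = dim(img))
  expect_error(tissue_means_kmeans(img, mask, k = 2), "distinct")
  expect_error(tissue_means_kmeans(img, array(FALSE, dim(img)), k = 2),
               "empty mask")
  img2 <- array(seq_len(64), dim = c(4, 4, 4))
  expect_equal(tissue_means_kmeans(img2, mask, k = 1), mean(seq_len(64)))
})

test_that("normalisation maps centroids onto targets and is affine", {
  ph <- default_phantom()
  pair <- image_pair(ph$baseline, ph$followup, ph$voxel_volume_ml)
  cts <- c(20, 45, 65)
  norm <- normalise_pair(pair, cts, cts, target_means = c(0.2, 0.8))
  expect_equal(norm$centroids_baseline[1], 0.2, tolerance = 1e-9)
  expect_equal(norm$centroids_baseline[3], 0.8, tolerance = 1e-9)

  # doubling the intensities is undone exactly by normalising with 2x centroids
  pair2 <- image_pair(ph$baseline, 2 * ph$baseline, ph$voxel_volume_ml)
  norm2 <- normalise_pair(pair2, cts, 2 * cts)
  expect_equal(norm2$pair$baseline, norm2$pair$followup, tolerance = 1e-12)

  # already at target: identity
  norm3 <- normalise_pair(norm$pair, norm$centroids_baseline,
                          norm$centroids_followup, target_means = c(0.2, 0.8))
  expect_equal(norm3$pair$baseline, norm$pair$baseline, tolerance = 1e-12)

  expect_error(normalise_pair(pair, c(1, 1, 2), c(1, 1, 2)), "coincident|ascending")
})

test_that("boundary shell matches a brute-force morphology oracle", {
  coords <- serialbsi:::voxel_coords_mm(c(32L, 32L, 32L), c(1, 1, 1))
  r2 <- serialbsi:::quad_field(coords)
  m1 <- r2 <= 10^2
  m2 <- r2 <= 9^2
  shell <- boundary_region(m1, m2, dilate = 1, erode = 1)
  oracle <- brute_dilate(m1 | m2) & !brute_erode(m1 & m2)
  expect_identical(shell, oracle)

  # equal masks: a 2-voxel-thick shell around the surface
  shell_eq <- boundary_region(m1, m1, 1, 1)
  expect_identical(shell_eq, brute_dilate(m1) & !brute_erode(m1))
  expect_true(all(shell_eq[m1 & !brute_erode(m1)]))

  # disjoint masks: region contains both dilated masks
  a <- array(FALSE, c(32, 32, 32)); a[5:8, 5:8, 5:8] <- TRUE
  b <- array(FALSE, c(32, 32, 32)); b[20:24, 20:24, 20:24] <- TRUE
  reg <- boundary_region(a, b, 1, 1)
  expect_true(all(reg[brute_dilate(a)]))
  expect_true(all(reg[brute_dilate(b)]))

  expect_error(boundary_region(m1, m2, dilate = -1), ">= 0")
  expect_error(boundary_region(m1, m2[1:16, , ]), "grid mismatch")
})

test_that("clipped BSI: identity, single-voxel analytic case, empty region", {
  d <- c(16, 16, 16)
  base <- array(0.5, d)
  region <- array(FALSE, d); region[8, 8, 8] <- TRUE
  w <- intensity_window(0.3, 0.7)

  same <- clipped_bsi(image_pair(base, base, 0.001), region, w)
  expect_identical(same$value_ml, 0)

  # one region voxel from I2 to I1 with 1 mm^3 voxels: exactly 0.001 ml
  follow <- base; base2 <- base
  base2[8, 8, 8] <- 0.7; follow[8, 8, 8] <- 0.3
  r <- clipped_bsi(image_pair(base2, follow, 0.001), region, w)
  expect_identical(r$value_ml, 0.001)
  expect_identical(r$n_boundary_voxels, 1L)

  expect_warning(
    r0 <- clipped_bsi(image_pair(base, base, 0.001), array(FALSE, d), w),
    "empty"
  )
  expect_identical(r0$value_ml, 0)
  expect_error(intensity_window(0.7, 0.3), "I2 > I1")
})

test_that("clipped BSI is antisymmetric, bounded and window-scale invariant", {
  set.seed(99)
  d <- c(12, 12, 12)
  a <- array(runif(prod(d)), d)
  b <- array(runif(prod(d)), d)
  region <- array(runif(prod(d)) < 0.3, d)
  w <- intensity_window(0.25, 0.75)
  r_ab <- clipped_bsi(image_pair(a, b, 0.001), region, w)
  r_ba <- clipped_bsi(image_pair(b, a, 0.001), region, w)
  expect_equal(r_ab$value_ml, -r_ba$value_ml, tolerance = 1e-12)
  expect_lte(abs(r_ab$value_ml), 0.001 * r_ab$n_boundary_voxels)

  # joint affine rescale of intensities and window leaves the value unchanged
  s <- 3.7; o <- 1.2
  w2 <- intensity_window(s * 0.25 + o, s * 0.75 + o)
  r_scaled <- clipped_bsi(image_pair(s * a + o, s * b + o, 0.001), region, w2)
  expect_equal(r_scaled$value_ml, r_ab$value_ml, tolerance = 1e-9)
})

test_that("KN-BSI recovers phantom truth", {
  ph <- default_phantom()
  pair0 <- image_pair(ph$baseline, ph$followup, ph$voxel_volume_ml)
  r0 <- kn_bsi(pair0, ph$masks$brain_base, ph$masks$brain_follow)
  expect_lt(abs(r0$value_ml - ph$truth$brain_loss_ml), 1e-6)

  zero <- make_phantom_pair(phantom_spec(atrophy_ml = 0,
                                         ventricle_growth_ml = 0,
                                         hippo_atrophy_ml = 0))
  rz <- kn_bsi(image_pair(zero$baseline, zero$followup, zero$voxel_volume_ml),
               zero$masks$brain_base, zero$masks$brain_follow)
  expect_lt(abs(rz$value_ml), 1e-6)

  noisy <- noisy_pair(ph, snr = 25, seed = 5)
  rn <- kn_bsi(noisy, ph$masks$brain_base, ph$masks$brain_follow)
  expect_lt(abs(rn$value_ml - ph$truth$brain_loss_ml) /
              ph$truth$brain_loss_ml, 0.1)
})

test_that("fixed-window BSI recovers ventricular expansion", {
  ph <- default_phantom()
  noisy <- noisy_pair(ph, snr = 25, seed = 8)
  bu <- ph$masks$brain_base | ph$masks$brain_follow
  r <- fixed_window_bsi(noisy, ph$masks$ventricle_base,
                        ph$masks$ventricle_follow, bu)
  expect_lt(abs(r$value_ml - ph$truth$ventricle_growth_ml) /
              ph$truth$ventricle_growth_ml, 0.1)
})

test_that("double-window BSI: additivity, overlap guard, hippocampal truth", {
  d <- c(16, 16, 16)
  base <- array(0.5, d); follow <- base
  base[8, 8, 8] <- 0.75; follow[8, 8, 8] <- 0.62
  m <- array(FALSE, d); m[7:9, 7:9, 7:9] <- TRUE
  w1 <- intensity_window(0.28, 0.45)
  w2 <- intensity_window(0.55, 0.78)
  pair <- image_pair(base, follow, 0.001)
  dw <- double_window_bsi(pair, m, m, w1, w2)
  single <- clipped_bsi(pair, boundary_region(m, m, 1, 1), w2)
  expect_equal(dw$value_ml, single$value_ml, tolerance = 1e-12)

  same <- double_window_bsi(image_pair(base, base, 0.001), m, m, w1, w2)
  expect_identical(same$value_ml, 0)
  expect_error(double_window_bsi(pair, m, m, intensity_window(0.3, 0.6), w2),
               "overlapping")

  ph <- default_phantom()
  noisy <- noisy_pair(ph, snr = 25, seed = 13)
  bu <- ph$masks$brain_base | ph$masks$brain_follow
  rh <- hippo_bsi(noisy, ph$masks$hippo_base, ph$masks$hippo_follow, bu)
  expect_lt(abs(rh$value_ml - ph$truth$hippo_loss_ml) /
              ph$truth$hippo_loss_ml, 0.35)
})

test_that("differential bias correction removes a smooth multiplicative field", {
  ph <- default_phantom()
  mask <- ph$masks$brain_base
  pair_same <- image_pair(ph$baseline, ph$baseline, ph$voxel_volume_ml)
  fixed <- differential_bias_correct(pair_same, mask, smoothing_fwhm = 15)
  expect_lt(max(abs(fixed$baseline - ph$baseline)), 1e-9)

  # construct a very smooth field and verify a >= 10x reduction in ratio SD
  coords <- serialbsi:::voxel_coords_mm(dim(ph$baseline), c(1, 1, 1))
  r2 <- serialbsi:::quad_field(coords)
  field <- exp(0.2 * (r2 / max(r2)))
  biased <- image_pair(ph$baseline, ph$baseline * field, ph$voxel_volume_ml)
  corr <- differential_bias_correct(biased, mask, smoothing_fwhm = 6)
  ratio_pre <- (biased$followup / biased$baseline)[mask]
  ratio_post <- (corr$followup / corr$baseline)[mask]
  expect_gt(sd(ratio_pre) / sd(ratio_post), 10)

  # idempotence within the mask (where the field is defined), 1e-3 relative
  corr2 <- differential_bias_correct(corr, mask, smoothing_fwhm = 6)
  expect_lt(max(abs(corr2$baseline - corr$baseline)[mask]) /
              max(abs(corr$baseline[mask])), 1e-3)

  neg <- ph$baseline; neg[mask][1] <- -1
  expect_error(differential_bias_correct(
    image_pair(neg, ph$baseline, ph$voxel_volume_ml), mask
  ), "non-positive")
})

test_that("image pair construction enforces grid and volume contracts", {
  a <- array(1, c(8, 8, 8))
  expect_error(image_pair(a, array(1, c(8, 8, 4)), 0.001), "grid mismatch")
  expect_error(image_pair(a, a, -1), "> 0")
  inf <- a; inf[1] <- Inf
  expect_error(image_pair(a, inf, 0.001), "finite")
})
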