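test_that("identical bead lists match perfectly", {
  set.seed(3)
  a <- cbind(runif(50, 0, 100), runif(50, 0, 80), runif(50, 0, 50))
  m <- matchBeads(a, a)
  expect_equal(nrow(m$pairs), 50)
  expect_equal(m$residual_um, 0)
  expect_equal(m$pairs[, "a"], m$pairs[, "b"])
})

test_that("a known translation is matched when given as init", {
  set.seed(4)
  a <- cbind(runif(40, 0, 60), runif(40, 0, 60), runif(40, 0, 40))
  shift <- c(3.2, -1.1, 2.4)
  b <- sweep(a, 2, shift, "+")
  init <- AffineTransform3D(offset = -shift)  # maps b back onto a
  m <- matchBeads(a, b, init = init, radius_um = 0.5)
  expect_equal(nrow(m$pairs), 40)
  expect_lt(m$residual_um, 1e-9)
  # without init nothing should pair at this radius
  m0 <- matchBeads(a, b, radius_um = 0.5)
  expect_equal(nrow(m0$pairs), 0)
})

test_that("jittered beads match mutually with no false pairs", {
  set.seed(5)
  n <- 200
  a <- cbind(runif(n, 0, 150), runif(n, 0, 120), runif(n, 0, 80))
  b <- a + matrix(rnorm(3 * n, 0, 0.1), ncol = 3)
  perm <- sample(n)
  m <- matchBeads(a, b[perm, ], radius_um = 1)
  expect_gte(nrow(m$pairs), 0.95 * n)
  # verify against the ground-truth correspondence
  expect_true(all(perm[m$pairs[, "b"]] == m$pairs[, "a"]))
})

test_that("estimateAffine recovers exact and noisy transforms", {
  set.seed(6)
  a <- cbind(runif(100, 0, 80), runif(100, 0, 60), runif(100, 0, 40))
  # identity correspondences give the identity transform
  tf0 <- estimateAffine(list(points_a = a, points_b = a), type = "affine")
  expect_equal(tf0@matrix, diag(3), tolerance = 1e-9)
  expect_equal(tf0@offset, c(0, 0, 0), tolerance = 1e-8)

  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  M <- 1.02 * R
  off <- c(4, -2, 1.5)
  b_exact <- a %*% t(M) + matrix(off, 100, 3, byrow = TRUE)
  for (type in c("similarity", "affine")) {
    tf <- estimateAffine(list(points_a = a, points_b = b_exact), type = type)
    expect_equal(tf@matrix, M, tolerance = 1e-6)
    expect_equal(tf@offset, off, tolerance = 1e-6)
    expect_lt(attr(tf, "residual_um"), 1e-6)
  }
  # 0.05 um noise: matrix entries recovered to 1e-3, residual ~ noise
  b_noisy <- b_exact + matrix(rnorm(300, 0, 0.05), ncol = 3)
  tf <- estimateAffine(list(points_a = a, points_b = b_noisy),
                       type = "affine")
  expect_lt(max(abs(tf@matrix - M)), 1e-3)
  expect_lt(abs(attr(tf, "residual_um") - 0.05 * sqrt(3)), 0.03)
})

test_that("degenerate correspondence sets are rejected", {
  a3 <- cbind(runif(3), runif(3), runif(3))
  expect_error(estimateAffine(list(points_a = a3, points_b = a3)),
               "at least 4")
  coplanar <- cbind(runif(20, 0, 10), runif(20, 0, 10), 5)
  expect_error(estimateAffine(list(points_a = coplanar,
                                   points_b = coplanar)), "coplanar")
})

test_that("fusing a volume with itself under identity reproduces it", {
  ph <- fixedBeadPhantom(c(14.2, 25.3, 7.1))
  vol <- deskew(renderView(ph$truth, ph$spec, 1L, noise = FALSE),
                c(0.41, 0.4, 0.5))
  fu <- fuseViews(vol, vol)
  expect_equal(voxels(fu$volume)[fu$overlap], voxels(vol)[fu$overlap],
               tolerance = 1e-9)
  # conservative mask transport keeps the overlap inside the valid region,
  # trimming at most a one-voxel border
  expect_true(!any(fu$overlap & !validMask(vol)))
  expect_gt(sum(fu$overlap) / sum(validMask(vol)), 0.9)
})

test_that("disjoint footprints give an empty overlap mask", {
  a <- ImageVolume(array(1, c(5, 5, 5)), c(1, 1, 1), origin_um = c(0, 0, 0))
  b <- ImageVolume(array(1, c(5, 5, 5)), c(1, 1, 1),
                   origin_um = c(100, 100, 100))
  expect_warning(fu <- fuseViews(a, b), "empty overlap")
  expect_false(any(fu$overlap))
})

test_that("the overlap mask is the intersection of the validity masks", {
  ph <- fixedBeadPhantom(c(15.1, 25.05, 7.03))
  v1 <- deskew(renderView(ph$truth, ph$spec, 1L, noise = FALSE),
               c(0.41, 0.4, 0.5))
  v2 <- deskew(renderView(ph$truth, ph$spec, 2L, noise = FALSE),
               c(0.41, 0.4, 0.5))
  fu <- fuseViews(v1, v2)
  # the overlap is contained in view 1 validity and, geometrically, in the
  # parallelepiped imaged by both sheared footprints: view 1 covers
  # y - z >= 0 and view 2 covers y + z <= sweep length
  expect_true(!any(fu$overlap & !validMask(v1)))
  idx <- which(fu$overlap, arr.ind = TRUE)
  ox <- origin(fu$volume); w <- voxelSize(fu$volume)
  y <- ox[2] + (idx[, 2] - 1) * w[2]
  z <- ox[3] + (idx[, 1] - 1) * w[3]
  sweep_len <- (dim(voxels(renderView(ph$truth, ph$spec, 2L,
                                      noise = FALSE)))[1] - 1) *
    ph$spec@scan_step_um
  expect_true(all(y - z >= -1e-6))
  expect_true(all(y + z <= sweep_len + 1e-6))
})

test_that("dual-view fusion improves SNR by about sqrt(2)", {
  pos <- rbind(c(10.1, 24.3, 6.2), c(20.3, 30.1, 8.4))
  ph <- fixedBeadPhantom(pos)
  spec_noisy <- PhantomSpec(extent_um = c(30, 40, 14), n_beads = 0L,
                            intensity_cv = 0, read_noise_sd = 2,
                            background = 10, seed = 31L)
  ref <- fuseBothViews(ph$truth, ph$spec, noise = FALSE)
  noisy <- fuseBothViews(ph$truth, spec_noisy, noise = TRUE)
  v1 <- deskew(renderView(ph$truth, spec_noisy, 1L, noise = TRUE),
               c(0.205, 0.205, 0.25))
  ov <- noisy$overlap & ref$overlap
  noise_single <- sd(voxels(v1)[ov] - voxels(ref$volume)[ov])
  noise_fused <- sd(voxels(noisy$volume)[ov] - voxels(ref$volume)[ov])
  expect_gt(noise_single / noise_fused, 1.3)
  rm(ref, noisy, v1); gc()
})

test_that("transforms serialize and restore exactly", {
  tf <- AffineTransform3D(matrix = matrix(rnorm(9) + diag(3), 3, 3),
                          offset = c(1.25, -3.5, 0.125))
  path <- tempfile(fileext = ".json")
  writeTransform(tf, path)
  back <- readTransform(path)
  expect_equal(back@matrix, tf@matrix)
  expect_equal(back@offset, tf@offset)
})
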