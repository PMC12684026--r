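test_that("acquisition indices map to world coordinates", {
  p <- acquisitionToWorld(1, 0, 0, 5, pixel_um = 1, scan_step_um = 1)
  expect_equal(unname(p[1, ]), c(5, 0, 0))
  p <- acquisitionToWorld(1, 3, 0, 0, pixel_um = 1, scan_step_um = 2)
  expect_equal(unname(p[1, ]), c(0, 6, 0))
  p <- acquisitionToWorld(1, 0, 10, 0, pixel_um = 0.205, scan_step_um = 0.5)
  expect_equal(unname(p[1, ]), c(0, 1.44957, 1.44957), tolerance = 1e-5)
  # view 2 mirrors the in-plane y component
  p2 <- acquisitionToWorld(2, 0, 10, 0, pixel_um = 0.205, scan_step_um = 0.5)
  expect_equal(unname(p2[1, ]), c(0, -1.44957, 1.44957), tolerance = 1e-5)
  expect_error(
    acquisitionToWorld(1, 10, 0, 0, 1, 1, dims = c(5, 5, 5)), "bounds")
})

test_that("the acquisition mapping is exactly affine and invertible", {
  for (view in 1:2) for (mode in c("remote", "stage")) {
    tf <- acquisitionAffine(view_id = view, pixel_um = 0.205,
                            scan_step_um = 0.4, tilt_deg = 45,
                            scan_mode = mode)
    idx <- cbind(n = c(0, 3, 17, 120), r = c(0, 5, 40, 333),
                 c = c(0, 7, 90, 1024))
    direct <- acquisitionToWorld(view, idx[, 1], idx[, 2], idx[, 3],
                                 0.205, 0.4, 45, mode)
    via_affine <- applyTransform(tf, idx)
    expect_equal(unname(via_affine), unname(direct), tolerance = 1e-12)
    # round trip: compose with inverse is identity to 1e-9 um
    rt <- composeTransform(invertTransform(tf), tf)
    back <- applyTransform(rt, idx)
    expect_lt(max(abs(back - idx)), 1e-9)
  }
})

test_that("deskew of an all-zero stack is an all-zero volume", {
  st <- ObliqueStack(array(0, c(10, 8, 6)), pixel_um = 0.5,
                     scan_step_um = 0.5)
  vol <- deskew(st, out_voxel_um = c(0.5, 0.5, 0.5))
  expect_true(all(voxels(vol) == 0))
  expect_true(any(validMask(vol)))
  expect_error(deskew(st, out_voxel_um = c(100, 100, 100)), "footprint")
})

test_that("trilinear deskew conserves the mass of a unit voxel", {
  px <- 0.205; step <- 0.3
  a <- array(0, c(14, 12, 10))
  a[7, 6, 5] <- 1
  st <- ObliqueStack(a, pixel_um = px, scan_step_um = step)
  vol <- deskew(st, out_voxel_um = c(px, step, px * sin(pi / 4)),
                interpolation = "trilinear")
  expect_equal(sum(voxels(vol)), 1, tolerance = 1e-6)
})

test_that("a deskewed bead lands at its ground-truth position", {
  ph <- fixedBeadPhantom(c(15.07, 25.13, 7.11))
  st <- renderView(ph$truth, ph$spec, 1L, noise = FALSE)
  out_voxel <- c(0.205, 0.205, 0.25)
  vol <- deskew(st, out_voxel)
  v <- voxels(vol); v[!validMask(vol)] <- 0
  cc <- voxelCentres(vol)
  tot <- sum(v)
  centroid <- c(sum(slice.index(v, 3) * v), sum(slice.index(v, 2) * v),
                sum(slice.index(v, 1) * v)) / tot
  world <- c(cc$x[1] + (centroid[1] - 1) * out_voxel[1],
             cc$y[1] + (centroid[2] - 1) * out_voxel[2],
             cc$z[1] + (centroid[3] - 1) * out_voxel[3])
  expect_lt(max(abs(world - c(15.07, 25.13, 7.11))),
            0.5 * max(out_voxel))
  # total intensity against the stack total (matched sampling densities)
  ratio <- prod(out_voxel) /
    (ph$spec@pixel_um^2 * sin(pi / 4) * ph$spec@scan_step_um)
  expect_equal(sum(v) * ratio, sum(voxels(st)), tolerance = 0.01)
})

test_that("the two views place the same bead at the same world position", {
  ph <- fixedBeadPhantom(rbind(c(10.11, 25.03, 6.41), c(20.6, 30.2, 8.77)))
  fu <- fuseBothViews(ph$truth, ph$spec)
  v1 <- deskew(renderView(ph$truth, ph$spec, 1L, noise = FALSE),
               c(0.205, 0.205, 0.25))
  v2 <- deskew(renderView(ph$truth, ph$spec, 2L, noise = FALSE),
               c(0.205, 0.205, 0.25))
  m1 <- measureBeads(v1)
  m2 <- measureBeads(v2)
  m1 <- m1[m1$flag == "accepted", ]; m2 <- m2[m2$flag == "accepted", ]
  expect_equal(nrow(m1), 2); expect_equal(nrow(m2), 2)
  m2 <- m2[order(m2$x_um), ]; m1 <- m1[order(m1$x_um), ]
  d <- sqrt(rowSums((m1[, c("x_um", "y_um", "z_um")] -
                     m2[, c("x_um", "y_um", "z_um")])^2))
  expect_lt(max(d), 0.5 * 0.25)
})

test_that("stage-scan reslice equals remote deskew of the reversed sweep", {
  ph <- fixedBeadPhantom(c(12.2, 20.1, 6.3), extent_um = c(24, 30, 12))
  st <- renderView(ph$truth, ph$spec, 1L, noise = FALSE)
  a <- voxels(st)
  rev_idx <- seq(dim(a)[1], 1)
  stage <- ObliqueStack(a[rev_idx, , ], pixel_um = pixelSize(st),
                        scan_step_um = scanStep(st), view_id = viewId(st),
                        scan_mode = "stage")
  vol_remote <- deskew(st, c(0.205, 0.205, 0.25))
  vol_stage <- stageScanReslice(stage, c(0.205, 0.205, 0.25))
  both <- validMask(vol_remote) & validMask(vol_stage)
  expect_gt(mean(both), 0.7)
  expect_equal(voxels(vol_stage)[both], voxels(vol_remote)[both],
               tolerance = 1e-9)
  # the world y origins differ by the sweep length
  expect_equal(origin(vol_stage)[2],
               origin(vol_remote)[2] - (dim(a)[1] - 1) * scanStep(st))
  expect_error(stageScanReslice(st, c(1, 1, 1)), "stage")
  rm(vol_remote, vol_stage, st, stage, a, both); gc()
})

test_that("voxel binning averages blocks and scales metadata", {
  a <- array(seq_len(8 * 8 * 8), c(8, 8, 8))
  st <- ObliqueStack(a, pixel_um = 0.5, scan_step_um = 0.5)
  expect_equal(voxels(binVoxels(st, c(1, 1, 1))), a)
  b <- binVoxels(st, c(2, 2, 2))
  expect_equal(dim(voxels(b)), c(4, 4, 4))
  expect_equal(pixelSize(b), 1.0)
  expect_equal(scanStep(b), 1.0)
  expect_equal(voxels(b)[1, 1, 1], mean(a[1:2, 1:2, 1:2]))
  # constant array stays constant; trailing partial blocks are dropped
  cst <- ObliqueStack(array(3, c(7, 9, 5)), pixel_um = 1, scan_step_um = 1)
  bb <- binVoxels(cst, c(2, 2, 2))
  expect_equal(dim(voxels(bb)), c(3, 4, 2))
  expect_true(all(voxels(bb) == 3))
  # 4x4 in-plane binning of a 2048-wide frame gives 512 columns
  wide <- ObliqueStack(array(0, c(2, 8, 2048)), pixel_um = 0.1,
                       scan_step_um = 1)
  expect_equal(dim(voxels(binVoxels(wide, c(1, 4, 4))))[3], 512)
  expect_error(binVoxels(st, c(16, 1, 1)), "exceeds")
})

test_that("binning commutes with reslicing on a smooth object", {
  ph <- fixedBeadPhantom(c(12.2, 20.1, 6.3), extent_um = c(24, 30, 12),
                         psf_fwhm_um = c(3, 3, 4), sheet_fwhm_um = 6,
                         halo_sigma_um = 3)
  st <- renderView(ph$truth, ph$spec, 1L, noise = FALSE)
  w <- c(0.41, 0.4, 0.29)
  binned <- deskew(binVoxels(st, c(2, 2, 2)), w)
  # a binned stack voxel centre sits half an unbinned block into the sweep
  # and the tilted plane; sample the unbinned deskew on the shifted grid
  px <- pixelSize(st); step <- scanStep(st)
  shift <- c(0.5 * px, 0.5 * (step + px * cos(pi / 4)),
             0.5 * px * sin(pi / 4))
  o <- origin(binned) + shift
  nb <- dim(voxels(binned))
  direct <- deskew(st, w, bbox = list(min = o,
                                      max = o + (nb[c(3, 2, 1)] - 1) * w))
  n <- pmin(dim(voxels(direct)), nb)
  d <- voxels(direct)[1:n[1], 1:n[2], 1:n[3]]
  b <- voxels(binned)[1:n[1], 1:n[2], 1:n[3]]
  ok <- validMask(direct)[1:n[1], 1:n[2], 1:n[3]] &
        validMask(binned)[1:n[1], 1:n[2], 1:n[3]]
  expect_gt(mean(ok), 0.5)
  expect_lt(max(abs(d[ok] - b[ok])) / max(d), 0.01)
  rm(direct, binned, d, b, ok); gc()
})
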