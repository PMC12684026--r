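sep_gauss_cuboid <- function(sx = 0.5, sy = 0.7, sz = 1.2,
                             voxel = c(0.2, 0.2, 0.25), half = c(10, 10, 12),
                             amp = 1000, offset = 0) {
  x <- (-half[1]:half[1]) * voxel[1]
  y <- (-half[2]:half[2]) * voxel[2]
  z <- (-half[3]:half[3]) * voxel[3]
  vals <- offset + amp * outer(outer(exp(-z^2 / (2 * sz^2)),
                                     exp(-y^2 / (2 * sy^2))),
                               exp(-x^2 / (2 * sx^2)))
  dim(vals) <- c(length(z), length(y), length(x))
  list(values = vals, x = x, y = y, z = z,
       centre_index = half[c(3, 2, 1)] + 1)
}

test_that("detection finds isolated beads and applies the QC rules", {
  # empty volume -> no candidates
  vol0 <- ImageVolume(array(0, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(nrow(detectBeads(vol0)), 0)

  pos <- rbind(c(12.1, 30.2, 7.3), c(24.6, 45.3, 6.1), c(36.2, 58.7, 8.2))
  ph <- fixedBeadPhantom(pos, extent_um = c(48, 70, 15))
  vol <- deskew(renderView(ph$truth, ph$spec, 2L, noise = FALSE),
                c(0.205, 0.205, 0.25))
  det <- detectBeads(vol, half_size_um = c(4, 4, 5))
  cand <- det[det$flag == "candidate", ]
  expect_equal(nrow(cand), 3)
  cand <- cand[order(cand$x_um), ]
  for (i in 1:3)
    expect_lt(max(abs(as.numeric(cand[i, 1:3]) - pos[i, ])), 0.26)

  # two beads 1 um apart with min_sep 3 um are both flagged doublet
  close_pos <- rbind(c(20.1, 40.2, 7.3), c(20.1, 41.2, 7.3))
  ph2 <- fixedBeadPhantom(close_pos, extent_um = c(40, 70, 15))
  vol2 <- deskew(renderView(ph2$truth, ph2$spec, 2L, noise = FALSE),
                 c(0.205, 0.205, 0.25))
  det2 <- detectBeads(vol2, min_sep_um = 3)
  expect_true(all(det2$flag %in% c("doublet", "edge")))
  expect_gte(sum(det2$flag == "doublet"), 2)
})

test_that("cuboid extraction crops exactly and flags edges", {
  vol <- ImageVolume(array(seq_len(40 * 40 * 40), c(40, 40, 40)),
                     c(1, 1, 1))
  cub <- extractCuboid(vol, c(20, 20, 20), half_size_um = c(10, 10, 10))
  expect_equal(dim(cub$values), c(21, 21, 21))
  # content identity with the source
  expect_equal(cub$values[1, 1, 1], vol@voxels[11, 11, 11])
  expect_equal(cub$values[21, 21, 21], vol@voxels[31, 31, 31])
  # centre 2 voxels from the boundary -> no crop
  expect_null(extractCuboid(vol, c(2, 20, 20), half_size_um = c(10, 10, 10)))
})

test_that("the laterally-integrated profile sums x and y per z-slice", {
  cub <- sep_gauss_cuboid()
  prof <- axialIntegratedProfile(cub)
  expect_equal(length(prof), dim(cub$values)[1])
  # separable Gaussian: integrated profile keeps the axial sigma
  fit <- fitGaussian1d(prof, cub$z)
  expect_equal(fit$sigma_um, 1.2, tolerance = 1e-6)
  # constant subvolume integrates to a constant
  cst <- list(values = array(2, c(9, 4, 4)))
  expect_true(all(axialIntegratedProfile(cst) == 32))
})

test_that("Gaussian fitting is exact on noiseless data and flags junk", {
  u <- (0:30) * 0.25
  v <- 5 + 80 * exp(-(u - 3.8)^2 / (2 * 0.5^2))
  fit <- fitGaussian1d(v, 0.25)
  expect_equal(fit$sigma_um, 0.5, tolerance = 1e-6)
  expect_equal(fit$centre_um, 3.8, tolerance = 1e-6)
  expect_equal(fit$amplitude, 80, tolerance = 1e-5)
  expect_equal(fit$offset, 5, tolerance = 1e-5)
  expect_equal(fit$flag, "ok")
  expect_gt(fit$r2, 0.999999)

  expect_equal(fitGaussian1d(rep(3, 15), 0.25)$flag, "poor_fit")
  expect_error(fitGaussian1d(c(1, 2, 3), 0.25), "at least 7")
  expect_error(fitGaussian1d(c(1, NA, 3, 4, 5, 6, 7), 0.25), "finite")
})

test_that("fit precision tracks the Cramer-Rao bound", {
  set.seed(77)
  u <- (0:40) * 0.25
  A <- 1; mu <- 5.05; s <- 0.5; b <- 0
  model <- b + A * exp(-(u - mu)^2 / (2 * s^2))
  eps <- 0.05                      # 5% additive noise
  # numerical Fisher information for (A, mu, s, b)
  J <- cbind(exp(-(u - mu)^2 / (2 * s^2)),
             A * (u - mu) / s^2 * exp(-(u - mu)^2 / (2 * s^2)),
             A * (u - mu)^2 / s^3 * exp(-(u - mu)^2 / (2 * s^2)),
             1)
  crb_sigma <- eps * sqrt(solve(t(J) %*% J)[3, 3])
  est <- replicate(200, {
    fit <- fitGaussian1d(model + rnorm(length(u), 0, eps), u)
    fit$sigma_um
  })
  expect_lt(abs(mean(est) - s) / s, 0.01)          # bias < 1%
  expect_lt(sd(est) / crb_sigma, 1.5)              # efficiency
  expect_gt(sd(est) / crb_sigma, 1 / 1.5)
})

test_that("FWHM conversion is the Gaussian closed form", {
  expect_equal(fwhmFromSigma(1), 2.3548, tolerance = 1e-4)
  expect_equal(fwhmFromSigma(0), 0)
  expect_equal(fwhmFromSigma(0.2123), 0.4999, tolerance = 1e-4)
  expect_error(fwhmFromSigma(-1), ">= 0")
})

test_that("measureBead recovers symmetric widths and flags saturation", {
  cub <- sep_gauss_cuboid(sx = 0.5, sy = 0.5, sz = 1.0)
  m <- measureBead(cub)
  expect_equal(m$flag, "accepted")
  expect_equal(m$fwhm_x_um, m$fwhm_y_um, tolerance = 1e-6)
  expect_equal(m$fwhm_z_um, fwhmFromSigma(1.0), tolerance = 1e-6)
  # Z* of a separable Gaussian equals Z
  expect_equal(m$fwhm_zstar_um, m$fwhm_z_um, tolerance = 1e-6)

  clipped <- sep_gauss_cuboid()
  clipped$values <- pmin(clipped$values, 0.6 * max(clipped$values))
  expect_equal(measureBead(clipped)$flag, "saturated")
})

test_that("binning reproduces brute-force per-bin statistics", {
  set.seed(88)
  n <- 400
  meas <- data.frame(
    x_um = runif(n, 0, 480), y_um = runif(n, 0, 320),
    z_um = runif(n, 0, 300),
    fwhm_x_um = rnorm(n, 0.5, 0.05), fwhm_y_um = rnorm(n, 0.6, 0.05),
    fwhm_z_um = rnorm(n, 1.2, 0.1), fwhm_zstar_um = rnorm(n, 3.5, 0.2),
    flag = "accepted", stringsAsFactors = FALSE)
  edges <- resolutionBinEdges(c(480, 320, 300))
  expect_equal(vapply(edges, function(e) length(e) - 1L, integer(1)),
               c(15L, 10L, 5L))
  expect_equal(diff(edges[[1]])[1], 32)
  expect_equal(diff(edges[[3]])[1], 60)
  rm3 <- binMeasurements(meas, edges, metric = "fwhm_z_um")
  # brute-force oracle: point-in-box counting and per-box medians
  for (k in 1:25) {
    i <- c(sample(15, 1), sample(10, 1), sample(5, 1))
    inb <- meas$x_um > edges[[1]][i[1]] & meas$x_um <= edges[[1]][i[1] + 1] &
           meas$y_um > edges[[2]][i[2]] & meas$y_um <= edges[[2]][i[2] + 1] &
           meas$z_um > edges[[3]][i[3]] & meas$z_um <= edges[[3]][i[3] + 1]
    expect_equal(rm3@count[i[1], i[2], i[3]], sum(inb))
    if (sum(inb))
      expect_equal(rm3@median[i[1], i[2], i[3]],
                   median(meas$fwhm_z_um[inb]))
  }
  # empty bins are NA, never zero
  empty <- rm3@count == 0L
  if (any(empty)) expect_true(all(is.na(rm3@median[empty])))

  # depth-collapsed 2D variant: 30 x 20 lateral bins
  edges2 <- resolutionBinEdges(c(480, 320, 300), collapse_depth = TRUE)
  expect_equal(vapply(edges2, function(e) length(e) - 1L, integer(1)),
               c(30L, 20L, 1L))
  expect_equal(diff(edges2[[1]])[1], 16)
})

test_that("summaries use interpolated quartiles and respect flags", {
  meas <- data.frame(fwhm_x_um = c(1, 2, 3, 4), fwhm_y_um = c(2, 2, 2, 2),
                     fwhm_z_um = c(1, 2, 3, 4),
                     fwhm_zstar_um = c(1, 2, 3, 4),
                     x_um = 1:4, y_um = 1:4, z_um = 1:4,
                     flag = "accepted", stringsAsFactors = FALSE)
  s <- summarizeBeads(meas)
  expect_equal(s$median[s$metric == "fwhm_z_um"], 2.5)
  expect_equal(s$iqr[s$metric == "fwhm_z_um"], 1.5)
  expect_equal(s$iqr[s$metric == "fwhm_y_um"], 0)
  expect_equal(unique(s$n), 4L)
  meas$flag[1] <- "doublet"
  expect_equal(unique(summarizeBeads(meas)$n), 3L)
  meas$flag <- "poor_fit"
  expect_error(summarizeBeads(meas), "no accepted")
})

test_that("a single all-covering bin agrees with the global summary", {
  set.seed(99)
  n <- 60
  meas <- data.frame(
    x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
    z_um = runif(n, 0, 100),
    fwhm_x_um = rnorm(n, 0.5, 0.02), fwhm_y_um = rnorm(n, 0.6, 0.02),
    fwhm_z_um = rnorm(n, 1.2, 0.05), fwhm_zstar_um = rnorm(n, 3.5, 0.1),
    flag = "accepted", stringsAsFactors = FALSE)
  one_bin <- lapply(1:3, function(i) c(0, 100))
  rm1 <- binMeasurements(meas, one_bin, metric = "fwhm_zstar_um")
  s <- summarizeBeads(meas)
  expect_equal(rm1@median[1, 1, 1],
               s$median[s$metric == "fwhm_zstar_um"])
  expect_equal(rm1@iqr[1, 1, 1], s$iqr[s$metric == "fwhm_zstar_um"])
  expect_equal(rm1@count[1, 1, 1], unique(s$n))
})

test_that("resolution maps can be written and plotted", {
  meas <- data.frame(
    x_um = runif(50, 0, 64), y_um = runif(50, 0, 64),
    z_um = runif(50, 0, 60),
    fwhm_x_um = rnorm(50, 0.5, 0.02), fwhm_y_um = rnorm(50, 0.6, 0.02),
    fwhm_z_um = rnorm(50, 1.2, 0.05), fwhm_zstar_um = rnorm(50, 3.5, 0.1),
    flag = "accepted", stringsAsFactors = FALSE)
  edges <- resolutionBinEdges(c(64, 64, 60), bin_um = c(32, 32, 60))
  rm1 <- binMeasurements(meas, edges, metric = "fwhm_z_um")
  path <- tempfile(fileext = ".tif")
  writeResolutionMap(rm1, path)
  frames <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(frames), 1L)
  expect_equal(dim(frames[[1]]), c(2, 2))
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  plotResolutionMap(rm1)
  grDevices::dev.off()
  expect_true(file.exists(png_path))
})
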