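# Independent oracles and shared fixtures, built in code at test time.

# Brute-force collection-NA oracle: rasterizes the sample-side pupil
# geometry instead of using closed forms. The longitudinal component
# rasterizes the angle-interval rule on a fine 1D grid; the latitudinal
# component rasterizes the two pupil discs on an n x n sine-space grid and
# takes the maximum half-height of their intersection. An empty angular
# overlap means no common ray, so both components are zero.
oracleCollectionNA <- function(na1, n_sample, na3, n_remote, tilt_deg,
                               n = 2000) {
  a1 <- asin(na1 / n_sample)
  a3 <- asin(na3 / n_remote)
  tau <- tilt_deg * pi / 180
  th <- seq(-pi / 2, pi / 2, length.out = 4 * n * n / 1000 + 1)
  inside <- (th >= -a1 & th <= a1) & (th >= tau - a3 & th <= tau + a3)
  if (!any(inside)) return(c(latitudinal = 0, longitudinal = 0))
  na_long <- n_sample * (sin(max(th[inside])) - sin(min(th[inside]))) / 2

  r1 <- na1
  r2 <- n_sample * sin(a3)
  cx <- n_sample * sin(tau)
  xs <- seq(min(-r1, cx - r2), max(r1, cx + r2), length.out = n)
  ys <- seq(0, max(r1, r2), length.out = n)
  na_lat <- 0
  for (x in xs) {                     # rasterize column by column
    both <- (x^2 + ys^2 <= r1^2) & ((x - cx)^2 + ys^2 <= r2^2)
    if (any(both)) na_lat <- max(na_lat, max(ys[both]))
  }
  c(latitudinal = na_lat, longitudinal = na_long)
}

randomOpticalConfig <- function() {
  n_sample <- runif(1, 1.33, 1.52)
  OpticalConfig(na_primary = runif(1, 0.3, min(1.3, n_sample - 0.01)),
                n_immersion = n_sample, n_sample = n_sample,
                na_secondary = runif(1, 0.3, 0.95), n_remote = 1.0,
                tilt_deg = runif(1, 10, 60))
}

# Noise-free miniature phantom with beads at given positions.
fixedBeadPhantom <- function(positions, extent_um = c(30, 40, 14),
                             intensities = NULL, ...) {
  positions <- matrix(positions, ncol = 3)
  if (is.null(intensities)) intensities <- rep(2000, nrow(positions))
  spec <- PhantomSpec(extent_um = extent_um, n_beads = 0L,
                      intensity_cv = 0, read_noise_sd = 0, background = 0,
                      ...)
  truth <- new("GroundTruth", positions_um = positions,
               intensities = intensities)
  list(spec = spec, truth = truth)
}

# Deskew both views of a truth/spec pair and fuse them (no registration;
# the two deskews share the world frame by construction).
fuseBothViews <- function(truth, spec, out_voxel = c(0.205, 0.205, 0.25),
                          noise = FALSE, interpolation = "cubic") {
  v1 <- deskew(renderView(truth, spec, 1L, noise = noise),
               out_voxel, interpolation = interpolation)
  v2 <- deskew(renderView(truth, spec, 2L, noise = noise),
               out_voxel, interpolation = interpolation)
  fuseViews(v1, v2, interpolation = interpolation)
}
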