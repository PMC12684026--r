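# 1D Gaussian fitting of bead-image line profiles and per-bead measurement.

#' FWHM of a Gaussian from its sigma
#'
#' @param sigma_um Gaussian sigma in um (vectorised).
#' @return `2 * sqrt(2 * log(2)) * sigma_um`.
#' @examples
#' fwhmFromSigma(1)
#' @export
fwhmFromSigma <- function(sigma_um) {
  if (any(sigma_um < 0, na.rm = TRUE))
    stop("'sigma_um' must be >= 0", call. = FALSE)
  2 * sqrt(2 * log(2)) * sigma_um
}

#' Fit a 1D Gaussian with offset to a sampled profile
#'
#' Least-squares fit of `offset + A * exp(-(u - mu)^2 / (2 sigma^2))` by
#' Levenberg-Marquardt, initialised from intensity-weighted moments. Fits
#' that do not converge, or that return a sigma below half the sample
#' spacing (unresolvable by the sampling), are flagged `poor_fit`.
#'
#' @param profile numeric vector of samples (>= 7, finite).
#' @param coords_um sample positions in um, or a single spacing (um) for a
#'   uniform grid starting at 0.
#' @return List with `centre_um`, `sigma_um`, `amplitude`, `offset`, `r2`,
#'   and `flag` (`"ok"` or `"poor_fit"`).
#' @examples
#' u <- seq(-3, 3, by = 0.25)
#' fitGaussian1d(exp(-u^2 / 2), u)
#' @export
fitGaussian1d <- function(profile, coords_um) {
  v <- as.numeric(profile)
  if (length(v) < 7L) stop("at least 7 samples required", call. = FALSE)
  if (any(!is.finite(v))) stop("profile must be finite", call. = FALSE)
  u <- if (length(coords_um) == 1L)
    (seq_along(v) - 1) * coords_um else as.numeric(coords_um)
  if (length(u) != length(v))
    stop("'coords_um' must match the profile length", call. = FALSE)
  spacing <- min(diff(u))
  bad <- list(centre_um = NA_real_, sigma_um = NA_real_,
              amplitude = NA_real_, offset = NA_real_, r2 = NA_real_,
              flag = "poor_fit")

  # baseline-robust moment initialisation: moments of the profile above
  # 10% of its dynamic range, so baseline noise does not inflate sigma0
  b0 <- quantile(v, 0.25, names = FALSE)
  w <- pmax(v - (b0 + 0.1 * (max(v) - b0)), 0)
  if (sum(w) <= 0) return(bad)
  mu0 <- sum(w * u) / sum(w)
  s0 <- sqrt(max(sum(w * (u - mu0)^2) / sum(w), (0.25 * spacing)^2))
  resid_fn <- function(p) v - (p[4] + p[1] * exp(-(u - p[2])^2 /
                                                  (2 * p[3]^2)))
  run <- function(par) tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok_fit <- function(f) !is.null(f) && f$info %in% 1:3 &&
    abs(f$par[3]) >= 0.5 * spacing && f$par[1] > 0
  fit <- run(c(max(v) - b0, mu0, s0, b0))
  if (!ok_fit(fit)) # restart from a wide width if LM found a spike minimum
    fit <- run(c(max(v) - min(v), mu0, diff(range(u)) / 6, min(v)))
  if (is.null(fit) || !fit$info %in% 1:3) return(bad)
  cf <- fit$par
  sigma <- abs(cf[3])
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  if (sigma < 0.5 * spacing || cf[1] <= 0) {
    bad$r2 <- r2
    return(bad)
  }
  list(centre_um = cf[2], sigma_um = sigma, amplitude = cf[1],
       offset = cf[4], r2 = r2, flag = "ok")
}

# Saturation rule: a clipped peak shows as an exact plateau at the maximum.
.is_saturated <- function(values, sat_level = NULL, plateau_min = 5L) {
  mx <- max(values)
  if (!is.null(sat_level) && mx >= sat_level) return(TRUE)
  sum(values >= mx * (1 - 1e-9)) >= plateau_min
}

#' Measure one bead image
#'
#' Fits 1D Gaussians to the x, y and z single-voxel line profiles through
#' the bead image centre (the intensity-weighted centre voxel of the
#' cuboid) and to the laterally-integrated axial (Z*) profile, and converts
#' the fitted sigmas to FWHM. A measurement is accepted only if all four
#' fits converge with `r2 >= r2_min`; otherwise it carries the offending
#' flag (`poor_fit`, `saturated`).
#'
#' @param cuboid list from [extractCuboid()].
#' @param r2_min minimum per-axis goodness of fit.
#' @param sat_level optional saturation level (counts); a clipped plateau at
#'   the maximum is flagged regardless.
#' @return One-row data.frame with the fitted centre (um, world), the four
#'   FWHMs (um), per-axis `r2`, and `flag` (`"accepted"`, `"poor_fit"` or
#'   `"saturated"`).
#' @export
measureBead <- function(cuboid, r2_min = 0.9, sat_level = NULL) {
  if (is.null(cuboid)) stop("'cuboid' is NULL (edge case)", call. = FALSE)
  v <- cuboid$values
  if (.is_saturated(v, sat_level))
    return(.bead_row(flag = "saturated"))
  # intensity-weighted centre voxel, refined locally around the detected
  # peak (the cuboid centre) so that neither the background plateau nor a
  # neighbouring bead elsewhere in the cuboid can pull the centroid off
  # this bead's core
  d <- dim(v)
  ctr <- cuboid$centre_index
  win <- 3L
  rz <- max(1L, ctr[1] - win):min(d[1], ctr[1] + win)
  ry <- max(1L, ctr[2] - win):min(d[2], ctr[2] + win)
  rx <- max(1L, ctr[3] - win):min(d[3], ctr[3] + win)
  loc <- v[rz, ry, rx, drop = FALSE]
  w <- pmax(loc - min(loc), 0)
  tot <- sum(w)
  if (tot <= 0) return(.bead_row(flag = "poor_fit"))
  iz <- rz[1] - 1L + round(sum(slice.index(loc, 1) * w) / tot)
  iy <- ry[1] - 1L + round(sum(slice.index(loc, 2) * w) / tot)
  ix <- rx[1] - 1L + round(sum(slice.index(loc, 3) * w) / tot)
  iz <- min(max(iz, 1L), d[1]); iy <- min(max(iy, 1L), d[2])
  ix <- min(max(ix, 1L), d[3])

  fx <- fitGaussian1d(v[iz, iy, ], cuboid$x)
  fy <- fitGaussian1d(v[iz, , ix], cuboid$y)
  fz <- fitGaussian1d(v[, iy, ix], cuboid$z)
  fzs <- fitGaussian1d(apply(v, 1, sum), cuboid$z)
  fits <- list(fx, fy, fz, fzs)
  r2s <- vapply(fits, function(f) f$r2, numeric(1))
  ok <- all(vapply(fits, function(f) identical(f$flag, "ok"), logical(1))) &&
    all(r2s >= r2_min)
  .bead_row(
    x_um = fx$centre_um, y_um = fy$centre_um, z_um = fz$centre_um,
    fwhm_x_um = fwhmFromSigma(fx$sigma_um),
    fwhm_y_um = fwhmFromSigma(fy$sigma_um),
    fwhm_z_um = fwhmFromSigma(fz$sigma_um),
    fwhm_zstar_um = fwhmFromSigma(fzs$sigma_um),
    amplitude = fx$amplitude, offset = fx$offset,
    r2_x = fx$r2, r2_y = fy$r2, r2_z = fz$r2, r2_zstar = fzs$r2,
    flag = if (ok) "accepted" else "poor_fit")
}

.bead_row <- function(x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
                      fwhm_x_um = NA_real_, fwhm_y_um = NA_real_,
                      fwhm_z_um = NA_real_, fwhm_zstar_um = NA_real_,
                      amplitude = NA_real_, offset = NA_real_,
                      r2_x = NA_real_, r2_y = NA_real_, r2_z = NA_real_,
                      r2_zstar = NA_real_, flag = "poor_fit") {
  data.frame(x_um = x_um, y_um = y_um, z_um = z_um,
             fwhm_x_um = fwhm_x_um, fwhm_y_um = fwhm_y_um,
             fwhm_z_um = fwhm_z_um, fwhm_zstar_um = fwhm_zstar_um,
             amplitude = amplitude, offset = offset,
             r2_x = r2_x, r2_y = r2_y, r2_z = r2_z, r2_zstar = r2_zstar,
             flag = flag, stringsAsFactors = FALSE)
}

#' Detect and measure all beads in a volume
#'
#' Runs [detectBeads()], extracts a cuboid around every unflagged candidate
#' and measures it with [measureBead()]. Detection flags (`doublet`,
#' `edge`) are carried through; only `"accepted"` rows enter summaries.
#'
#' @param vol an [ImageVolume-class].
#' @param mask optional analysis mask (e.g. the dual-view overlap).
#' @param min_sep_um,threshold_rel detection parameters; see
#'   [detectBeads()].
#' @param half_size_um cuboid half size (x, y, z), um.
#' @param r2_min minimum per-axis goodness of fit.
#' @param sat_level optional saturation level.
#' @return data.frame with one row per detected candidate: the measurement
#'   columns of [measureBead()] plus `det_x_um`, `det_y_um`, `det_z_um`
#'   (detection position) and `flag`.
#' @export
measureBeads <- function(vol, mask = NULL, min_sep_um = 3,
                         threshold_rel = 0.2, half_size_um = c(4, 4, 5),
                         r2_min = 0.9, sat_level = NULL) {
  det <- detectBeads(vol, mask = mask, min_sep_um = min_sep_um,
                     threshold_rel = threshold_rel,
                     half_size_um = half_size_um)
  if (!nrow(det)) {
    out <- cbind(.bead_row()[0, ], det_x_um = numeric(),
                 det_y_um = numeric(), det_z_um = numeric())
    return(out)
  }
  rows <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    if (det$flag[i] != "candidate") {
      rows[[i]] <- .bead_row(flag = det$flag[i])
      next
    }
    cub <- extractCuboid(vol, c(det$x_um[i], det$y_um[i], det$z_um[i]),
                         half_size_um = half_size_um, mask = mask)
    rows[[i]] <- if (is.null(cub)) .bead_row(flag = "edge")
                 else measureBead(cub, r2_min = r2_min, sat_level = sat_level)
  }
  out <- do.call(rbind, rows)
  out$det_x_um <- det$x_um
  out$det_y_um <- det$y_um
  out$det_z_um <- det$z_um
  rownames(out) <- NULL
  out
}
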