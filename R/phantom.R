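# Synthetic bead-phantom generator: ground-truth bead fields and their
# two-view oblique-plane acquisitions.

.fwhm2sigma <- function(f) f / (2 * sqrt(2 * log(2)))
.sigma2fwhm <- function(s) s * 2 * sqrt(2 * log(2))

#' Bead image FWHM of a phantom
#'
#' Folds the finite bead size into the detection-PSF widths by Gaussian
#' quadrature, using the projected-sphere FWHM `0.866 * d` for a bead of
#' diameter `d`: `fwhm_image = sqrt(fwhm_psf^2 + (0.866 d)^2)` per axis.
#'
#' @param spec a [PhantomSpec-class].
#' @return Numeric(3): generative bead-image FWHM (x, y, z) in um.
#' @export
beadImageFwhm <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  sqrt(spec@psf_fwhm_um^2 + (0.866 * spec@bead_diameter_um)^2)
}

#' Depth-dependent axial broadening factor
#'
#' Phenomenological refractive-index-mismatch model: the axial widths of the
#' bead image are multiplied by
#' `1 + mismatch_coeff * |depth - focus_depth|`, so aberration grows
#' linearly with remote-refocus distance from the zero-refocus plane and
#' vanishes for a matched sample (`mismatch_coeff = 0`).
#'
#' @param depth_um depth(s) beyond the coverslip in um.
#' @param spec a [PhantomSpec-class].
#' @return Broadening factor(s) >= 1.
#' @examples
#' aberrationScale(150, PhantomSpec())
#' @export
aberrationScale <- function(depth_um, spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (any(depth_um < 0)) stop("'depth_um' must be >= 0", call. = FALSE)
  1 + spec@mismatch_coeff * abs(depth_um - spec@focus_depth_um)
}

#' Generate a ground-truth bead field
#'
#' Draws `n_beads` positions uniformly inside the phantom extent and
#' log-normal per-bead brightness, deterministically from the spec's seed.
#' Positions and intensities come from the geometry substream, so they are
#' reproducible independently of the acquisition noise settings.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [GroundTruth-class].
#' @examples
#' truth <- generateGroundTruth(PhantomSpec(extent_um = c(50, 40, 30),
#'                                          n_beads = 10L))
#' @export
generateGroundTruth <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@n_beads
  set.seed(spec@seed)
  pos <- cbind(x = runif(n, 0, spec@extent_um[1]),
               y = runif(n, 0, spec@extent_um[2]),
               z = runif(n, 0, spec@extent_um[3]))
  if (spec@intensity_cv > 0) {
    sdl <- sqrt(log(1 + spec@intensity_cv^2))
    ints <- rlnorm(n, meanlog = log(spec@intensity_mean) - sdl^2 / 2,
                   sdlog = sdl)
  } else {
    ints <- rep(spec@intensity_mean, n)
  }
  new("GroundTruth", positions_um = pos, intensities = ints)
}

# Internal: model sigmas for a spec. Core sigmas are the generative image
# FWHMs (bead folded in); the sectioning halo is laterally Gaussian with
# sigma halo_sigma_um and axially shaped so that the laterally-integrated
# profile of the full image is a Gaussian of FWHM = sheet_fwhm_um scaled by
# halo_energy_factor (see the methods vignette).
.model_sigmas <- function(spec) {
  fw <- beadImageFwhm(spec)
  list(sx = .fwhm2sigma(fw[1]), sy = .fwhm2sigma(fw[2]),
       sz = .fwhm2sigma(fw[3]), sh = spec@halo_sigma_um,
       st = .fwhm2sigma(spec@sheet_fwhm_um), kappa = spec@halo_energy_factor)
}

#' Render one oblique view of a bead phantom
#'
#' Evaluates the two-component bead image model (diffraction core plus
#' optical-sectioning halo; see the methods vignette) on the sheared
#' acquisition grid of the requested view, then applies Poisson shot noise
#' and Gaussian read noise from the spec's noise substream. View 1 images
#' the +tilt plane, view 2 the -tilt plane; both sweep along +y. The number
#' of frames is chosen so the sweep covers the full phantom extent for
#' either view.
#'
#' @param truth a [GroundTruth-class].
#' @param spec a [PhantomSpec-class].
#' @param view_id 1 or 2.
#' @param noise logical; render the noise-free expectation when `FALSE`.
#' @param scan_mode `"remote"` (default) or `"stage"`.
#' @return An [ObliqueStack-class].
#' @examples
#' spec <- PhantomSpec(extent_um = c(20, 20, 10), n_beads = 2L)
#' st <- renderView(generateGroundTruth(spec), spec, 1L, noise = FALSE)
#' @export
renderView <- function(truth, spec, view_id, noise = TRUE,
                       scan_mode = "remote") {
  stopifnot(is(truth, "GroundTruth"), is(spec, "PhantomSpec"),
            view_id %in% c(1, 2))
  validObject(spec)
  sg <- .model_sigmas(spec)
  if (any(spec@psf_fwhm_um <= 0) || spec@sheet_fwhm_um <= 0)
    stop("PSF and sheet FWHM must be > 0", call. = FALSE)
  tau <- spec@tilt_deg * pi / 180
  amax <- aberrationScale(c(0, spec@extent_um[3]), spec)
  margin <- 4.5 * max(amax) * max(sg$st, sg$sh)
  n_frames <- as.integer(ceiling(
    (spec@extent_um[2] + spec@extent_um[3] / tan(tau) + margin) /
      spec@scan_step_um)) + 1L
  n_rows <- as.integer(floor(spec@extent_um[3] /
                               (spec@pixel_um * sin(tau)))) + 1L
  n_cols <- as.integer(floor(spec@extent_um[1] / spec@pixel_um)) + 1L
  dims <- c(n_frames, n_rows, n_cols)
  vox <- array(0, dim = dims)
  if (nrow(truth@positions_um)) {
    vox <- .renderBeads(vox, dims, truth@positions_um, truth@intensities,
                        spec@pixel_um, spec@scan_step_um, spec@tilt_deg,
                        .view_sign(as.integer(view_id)),
                        .sweep_sign(scan_mode),
                        sg$sx, sg$sy, sg$sz, sg$sh, sg$st, sg$kappa,
                        spec@mismatch_coeff, spec@focus_depth_um, 4.5)
  }
  if (noise) {
    set.seed(spec@seed + 977L * as.integer(view_id))
    vox <- .addCameraNoise(vox, spec@background, spec@read_noise_sd)
  } else if (spec@background > 0) {
    vox <- vox + spec@background
  }
  ObliqueStack(vox, pixel_um = spec@pixel_um,
               scan_step_um = spec@scan_step_um, tilt_deg = spec@tilt_deg,
               view_id = as.integer(view_id), scan_mode = scan_mode)
}
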