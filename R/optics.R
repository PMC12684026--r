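# Closed-form calculators for the remote-refocusing relay and the tilted
# dual-objective collection geometry.

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (!is.numeric(args[[nm]]) || any(!is.finite(args[[nm]])) ||
        any(args[[nm]] <= 0))
      stop(sprintf("'%s' must be positive and finite", nm), call. = FALSE)
  invisible(TRUE)
}

#' Remote-refocusing relay magnification from refractive indices
#'
#' Aberration-free remote refocusing requires the lateral (and axial)
#' magnification of the relay to equal the ratio of the sample to
#' remote-space refractive indices.
#'
#' @param n_sample refractive index of the sample medium.
#' @param n_remote refractive index of the remote image space.
#' @return The required relay magnification `n_sample / n_remote`.
#' @examples
#' remoteRefocusMagnification(1.406, 1.0)
#' @export
remoteRefocusMagnification <- function(n_sample, n_remote) {
  .check_positive(n_sample = n_sample, n_remote = n_remote)
  n_sample / n_remote
}

#' Overall system magnification
#'
#' @param m_rf lateral magnification of the remote refocusing relay.
#' @param m3 magnification of the third microscope relay.
#' @return `m_rf * m3`.
#' @examples
#' overallMagnification(1.407, 22.57)
#' @export
overallMagnification <- function(m_rf, m3) {
  .check_positive(m_rf = m_rf, m3 = m3)
  m_rf * m3
}

#' Effective pixel size in sample space
#'
#' @param camera_pitch_um physical camera pixel pitch in um.
#' @param overall_mag overall system magnification.
#' @return Sample-space pixel size in um.
#' @examples
#' effectivePixelSize(6.5, 31.75)
#' @export
effectivePixelSize <- function(camera_pitch_um, overall_mag) {
  .check_positive(camera_pitch_um = camera_pitch_um, overall_mag = overall_mag)
  camera_pitch_um / overall_mag
}

#' Collection NA of the overlapping tilted objective cones
#'
#' Computes the effective numerical aperture of the intersection of the O1
#' and O2/3 collection cones, referred to sample space. The longitudinal
#' component (within the tilt plane) intersects the angular intervals
#' `[-a1, a1]` and `[tilt - a3, tilt + a3]`, with `a1 = asin(na1/n_sample)`
#' and `a3 = asin(na3/n_remote)`, and reports
#' `n_sample * (sin(theta_max) - sin(theta_min)) / 2`. The latitudinal
#' component (perpendicular to the tilt plane) is the maximum half-height of
#' the intersection, in sample-side sine space, of the O1 pupil disc (radius
#' `na1`, centred at the origin) with the O2/3 pupil disc (radius
#' `n_sample * sin(a3)`, centred at `(n_sample * sin(tilt), 0)`).
#'
#' @param cfg an [OpticalConfig-class].
#' @return Named numeric vector `c(latitudinal, longitudinal)`. `(0, 0)` if
#'   the cones do not overlap.
#' @examples
#' collectionNA(OpticalConfig())
#' @export
collectionNA <- function(cfg) {
  stopifnot(is(cfg, "OpticalConfig"))
  validObject(cfg)
  if (cfg@na_primary > cfg@n_sample)
    stop("'na_primary' exceeds 'n_sample': collection cone undefined",
         call. = FALSE)
  if (cfg@na_secondary > cfg@n_remote)
    stop("'na_secondary' exceeds 'n_remote': collection cone undefined",
         call. = FALSE)
  a1 <- asin(cfg@na_primary / cfg@n_sample)
  a3 <- asin(cfg@na_secondary / cfg@n_remote)
  tau <- cfg@tilt_deg * pi / 180

  # longitudinal: overlap of the two angular intervals in the tilt plane
  lo <- max(-a1, tau - a3)
  hi <- min(a1, tau + a3)
  na_long <- if (hi <= lo) 0 else cfg@n_sample * (sin(hi) - sin(lo)) / 2

  # latitudinal: max half-height of the pupil-disc intersection in sine space
  r1 <- cfg@na_primary
  r2 <- cfg@n_sample * sin(a3)
  cx <- cfg@n_sample * sin(tau)
  na_lat <- .disc_intersection_halfheight(r1, r2, cx)
  if (na_long == 0 && na_lat > 0) {
    # angular overlap empty implies no common ray despite sine-space overlap
    na_lat <- 0
  }
  c(latitudinal = na_lat, longitudinal = na_long)
}

# Maximum half-height of the intersection of disc radius r1 centred at 0 and
# disc radius r2 centred at (cx, 0). Closed form: the maximum of
# min(h1(x), h2(x)) is attained at an enclosed disc's apex or at the boundary
# crossing x = (r1^2 - r2^2 + cx^2) / (2 cx).
.disc_intersection_halfheight <- function(r1, r2, cx) {
  cx <- abs(cx)
  if (cx >= r1 + r2) return(0)
  if (cx + r2 <= r1) return(r2)      # disc 2 inside disc 1
  if (cx + r1 <= r2) return(r1)      # disc 1 inside disc 2
  h1 <- function(x) sqrt(pmax(r1^2 - x^2, 0))
  h2 <- function(x) sqrt(pmax(r2^2 - (x - cx)^2, 0))
  cand <- numeric()
  if (cx > 1e-12) {
    xc <- (r1^2 - r2^2 + cx^2) / (2 * cx)
    if (xc > cx - r2 && xc < r1) cand <- c(cand, min(h1(xc), h2(xc)))
  }
  if (0 >= cx - r2) cand <- c(cand, min(r1, h2(0)))      # apex of disc 1
  if (cx <= r1) cand <- c(cand, min(h1(cx), r2))         # apex of disc 2
  if (!length(cand)) 0 else max(cand)
}

#' Diffraction-limited lateral FWHM
#'
#' Abbe-type estimate `0.51 * lambda / NA` of the lateral full-width at
#' half-maximum of the point spread function.
#'
#' @param wavelength_nm emission wavelength in nm.
#' @param na numerical aperture.
#' @return FWHM in um.
#' @examples
#' diffractionLimitFwhm(525, 1.07)
#' diffractionLimitFwhm(525, 0.72)
#' @export
diffractionLimitFwhm <- function(wavelength_nm, na) {
  .check_positive(wavelength_nm = wavelength_nm, na = na)
  0.51 * (wavelength_nm / 1000) / na
}

.check_cc <- function(cc, model) {
  stopifnot(is(model, "CCModel"))
  validObject(model)
  if (!is.numeric(cc) || any(!is.finite(cc)) ||
      any(cc < model@cc_min) || any(cc > model@cc_max))
    stop(sprintf("collar position must lie within [%g, %g]",
                 model@cc_min, model@cc_max), call. = FALSE)
  invisible(TRUE)
}

#' Widefield magnification at a correction-collar position
#'
#' Linear collar response: the magnification changes by a total fraction
#' `mag_fractional_span` across the full collar travel, passing through
#' `m_nominal` at the nominal position.
#'
#' @param cc collar position.
#' @param model a [CCModel-class].
#' @param m_nominal magnification at the nominal collar position.
#' @return Magnification at `cc`.
#' @examples
#' ccWidefieldMagnification(0.23, CCModel(), 1.406)
#' @export
ccWidefieldMagnification <- function(cc, model = CCModel(),
                                     m_nominal = 1.406) {
  .check_cc(cc, model)
  .check_positive(m_nominal = m_nominal)
  span <- model@cc_max - model@cc_min
  m_nominal * (1 + model@mag_fractional_span * (cc - model@cc_nominal) / span)
}

#' Focal-plane shift at a correction-collar position
#'
#' Linear collar response: the O1 focal plane shifts by a total of
#' `focal_shift_span_um` across the full collar travel, with zero shift at
#' the nominal position.
#'
#' @inheritParams ccWidefieldMagnification
#' @return Focal shift in um (signed).
#' @examples
#' ccFocalShift(0.23, CCModel())
#' @export
ccFocalShift <- function(cc, model = CCModel()) {
  .check_cc(cc, model)
  span <- model@cc_max - model@cc_min
  model@focal_shift_span_um * (cc - model@cc_nominal) / span
}

#' Predicted remote-refocusing mirror translation
#'
#' Axial translation of the remote mirror needed to refocus by
#' `defocus_sample_um` in sample space. In the index-matched remote-refocus
#' condition the axial magnification equals the lateral relay magnification,
#' so the translation is `fold_factor * m_rf * defocus_sample_um`. The
#' double-pass fold convention is exposed through `fold_factor` (default 1).
#'
#' @param defocus_sample_um sample-space defocus in um (signed).
#' @param m_rf lateral magnification of the remote refocusing relay.
#' @param fold_factor multiplicative constant for the folded-path convention.
#' @return Mirror translation in um.
#' @examples
#' predictedMirrorTranslation(10, 1.406)
#' @export
predictedMirrorTranslation <- function(defocus_sample_um, m_rf,
                                       fold_factor = 1) {
  .check_positive(m_rf = m_rf, fold_factor = fold_factor)
  fold_factor * m_rf * defocus_sample_um
}

#' Derived optical quantities report
#'
#' Evaluates all closed-form calculators for one configuration and returns
#' them as a table, as printed by the command-line `optics report`.
#'
#' @param cfg an [OpticalConfig-class].
#' @param cc_model a [CCModel-class].
#' @return A data.frame with columns `quantity`, `value`, `unit`.
#' @examples
#' opticsReport(OpticalConfig())
#' @export
opticsReport <- function(cfg = OpticalConfig(), cc_model = CCModel()) {
  m <- overallMagnification(cfg@m_rf, cfg@m3)
  nas <- collectionNA(cfg)
  data.frame(
    quantity = c("index-matching relay magnification",
                 "overall magnification",
                 "effective pixel size",
                 "latitudinal NA", "longitudinal NA",
                 "diffraction-limited FWHM (x)",
                 "diffraction-limited FWHM (y)",
                 "CC magnification tuning (min)",
                 "CC magnification tuning (max)",
                 "CC focal shift (min)", "CC focal shift (max)"),
    value = c(remoteRefocusMagnification(cfg@n_sample, cfg@n_remote),
              m,
              effectivePixelSize(cfg@camera_pitch_um, m),
              nas[["latitudinal"]], nas[["longitudinal"]],
              diffractionLimitFwhm(cfg@wavelength_nm, nas[["latitudinal"]]),
              diffractionLimitFwhm(cfg@wavelength_nm, nas[["longitudinal"]]),
              ccWidefieldMagnification(cc_model@cc_min, cc_model, cfg@m_rf),
              ccWidefieldMagnification(cc_model@cc_max, cc_model, cfg@m_rf),
              ccFocalShift(cc_model@cc_min, cc_model),
              ccFocalShift(cc_model@cc_max, cc_model)),
    unit = c("", "", "um", "NA", "NA", "um", "um", "", "", "um", "um"),
    stringsAsFactors = FALSE)
}
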