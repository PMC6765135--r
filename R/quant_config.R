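#' Quantification configuration
#'
#' Parameters of the per-cell dot/background measurement. The ring geometry
#' is in pixels; the depth of field (DOF) converts the ring's area times
#' its integrated intensity into a molecule count for the diffuse pool.
#'
#' @param dof depth of field, um
#' @param ring_inner_radius,ring_outer_radius annulus radii enclosing the
#'   dot, px (`outer > inner > dot_integration_radius_xy` is not required,
#'   but `outer > inner >= dot_integration_radius_xy` is enforced so the
#'   ring excludes the integration disc)
#' @param dot_integration_radius_xy radius of the disc over which the dot is
#'   integrated at each z, px
#' @param bright_discard_factor dots brighter than this multiple of the
#'   robust population average are discarded as replicated arrays
#' @param autofluorescence_level per-pixel autofluorescence, subtracted from
#'   every slice before any integration; estimate it from matched unlabeled
#'   cells with [estimate_autofluorescence()]
#' @param pixel_size um per pixel
#' @param psf_sigma_xy lateral PSF width, um, used for the aperture
#'   correction of the disc photometry (the fraction of a dot's photons
#'   falling outside the integration disc, and the fraction leaking into
#'   the local-background annulus, are computed from it and divided out).
#'   Set to `NA` to disable the correction.
#' @param prominence_sigmas a candidate dot must exceed the in-cell median
#'   of the composite by this many robust standard deviations (MAD) to
#'   count as detected
#' @return a validated list of class `"quant_config"`
#' @export
quant_config <- function(dof = 1.6,
                         ring_inner_radius = 4,
                         ring_outer_radius = 8,
                         dot_integration_radius_xy = 4,
                         bright_discard_factor = 1.8,
                         autofluorescence_level = 0,
                         pixel_size = 0.1,
                         psf_sigma_xy = 0.12,
                         prominence_sigmas = 5) {
  cfg <- list(dof = dof, ring_inner_radius = ring_inner_radius,
              ring_outer_radius = ring_outer_radius,
              dot_integration_radius_xy = dot_integration_radius_xy,
              bright_discard_factor = bright_discard_factor,
              autofluorescence_level = autofluorescence_level,
              pixel_size = pixel_size, psf_sigma_xy = psf_sigma_xy,
              prominence_sigmas = prominence_sigmas)
  if (any(vapply(cfg, function(v) !is.numeric(v) || length(v) != 1,
                 logical(1))))
    stop("all quant_config fields must be single numbers")
  if (!(cfg$ring_outer_radius > cfg$ring_inner_radius &&
          cfg$ring_inner_radius >= cfg$dot_integration_radius_xy))
    stop("need ring_outer_radius > ring_inner_radius >= ",
         "dot_integration_radius_xy")
  if (cfg$dof <= 0 || cfg$pixel_size <= 0 ||
        cfg$dot_integration_radius_xy <= 0)
    stop("dof, pixel_size and dot_integration_radius_xy must be positive")
  if (cfg$bright_discard_factor <= 0)
    stop("bright_discard_factor must be positive")
  if (cfg$autofluorescence_level < 0)
    stop("autofluorescence_level must be non-negative")
  structure(cfg, class = "quant_config")
}
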