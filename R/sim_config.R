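#' Simulation configuration for synthetic FROS z-stacks
#'
#' Bundles and validates all parameters of the forward model used by
#' [simulate_population()]. Defaults reproduce the study conditions of the
#' reference measurement: 268 cells carrying a 256x operator array imaged in
#' nine z-slices, with cell-to-cell variability in free fluorophore
#' concentration spanning the binding curve.
#'
#' @param n_cells number of cells to render
#' @param lacO_repeats operator repeats in the array (each repeat binds one
#'   labeled dimer, i.e. 2 molecules at full occupancy)
#' @param true_kd ground-truth apparent Kd, nM
#' @param true_hill_n ground-truth Hill coefficient
#' @param conc_distribution law for per-cell free concentration:
#'   `list(law = "log-uniform", low, high)` (nM) or
#'   `list(law = "log-normal", mean, cv)` (nM, coefficient of variation)
#' @param photons_per_molecule integrated photons contributed by one
#'   fluorophore over the stack (arbitrary camera units / molecule). Free
#'   parameter of the simulation; downstream estimates are ratios so its
#'   value cancels.
#' @param autofluorescence_rate autofluorescence photons per pixel per slice
#'   inside cells (matched unlabeled cells carry only this term)
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF widths, um
#' @param pixel_size um per pixel
#' @param z_spacing um between consecutive z slices
#' @param n_z number of z slices (>= 3)
#' @param dof depth of field, um: the axial extent over which diffuse
#'   fluorophores contribute to the in-focus background of one slice
#' @param replicated_dot_fraction fraction of cells whose array has
#'   replicated (two co-localized dots, each at the full bound count), in
#'   `[0, 1]`
#' @param poisson_noise apply per-voxel Poisson (shot) noise?
#' @param seed integer seed; identical seeds give bit-identical output
#' @param cells_per_field cells packed per simulated field of view
#' @param cell_semiaxes_px ellipse semi-axes (y, x) of the cell masks, px
#' @return a validated list of class `"sim_config"`
#' @export
sim_config <- function(n_cells = 268,
                       lacO_repeats = 256,
                       true_kd = 592,
                       true_hill_n = 2.93,
                       conc_distribution = list(law = "log-uniform",
                                                low = 30, high = 1500),
                       photons_per_molecule = 100,
                       autofluorescence_rate = 20,
                       psf_sigma_xy = 0.12,
                       psf_sigma_z = 0.35,
                       pixel_size = 0.1,
                       z_spacing = 0.4,
                       n_z = 9,
                       dof = 1.6,
                       replicated_dot_fraction = 0.1,
                       poisson_noise = TRUE,
                       seed = 1L,
                       cells_per_field = 16,
                       cell_semiaxes_px = c(17, 14)) {
  cfg <- list(n_cells = n_cells, lacO_repeats = lacO_repeats,
              true_kd = true_kd, true_hill_n = true_hill_n,
              conc_distribution = conc_distribution,
              photons_per_molecule = photons_per_molecule,
              autofluorescence_rate = autofluorescence_rate,
              psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
              pixel_size = pixel_size, z_spacing = z_spacing,
              n_z = as.integer(n_z), dof = dof,
              replicated_dot_fraction = replicated_dot_fraction,
              poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed),
              cells_per_field = as.integer(cells_per_field),
              cell_semiaxes_px = cell_semiaxes_px)

  pos <- c("n_cells", "lacO_repeats", "true_kd", "true_hill_n",
           "photons_per_molecule", "psf_sigma_xy", "psf_sigma_z",
           "pixel_size", "z_spacing", "n_z", "dof", "cells_per_field")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (cfg$autofluorescence_rate < 0)
    stop("`autofluorescence_rate` must be non-negative")
  if (cfg$replicated_dot_fraction < 0 || cfg$replicated_dot_fraction > 1)
    stop("`replicated_dot_fraction` must be in [0, 1]")
  if (cfg$n_z < 3)
    stop("`n_z` must be >= 3 so a peak-vs-off-focus z profile exists")
  if (length(cfg$cell_semiaxes_px) != 2 || any(cfg$cell_semiaxes_px <= 0))
    stop("`cell_semiaxes_px` must be two positive numbers")
  law <- conc_distribution$law
  if (identical(law, "log-uniform")) {
    if (!(conc_distribution$low > 0 && conc_distribution$high >
            conc_distribution$low))
      stop("log-uniform law needs 0 < low < high")
  } else if (identical(law, "log-normal")) {
    if (!(conc_distribution$mean > 0 && conc_distribution$cv > 0))
      stop("log-normal law needs positive mean and cv")
  } else stop("conc_distribution$law must be 'log-uniform' or 'log-normal'")

  structure(cfg, class = "sim_config")
}

#' Configuration for a saturated calibration strain
#'
#' Convenience wrapper around [sim_config()]: the same imaging model, with
#' free concentrations drawn well above Kd so the array is fully occupied.
#' Used to build the reference population for [calibrate_saturation()].
#'
#' @param lacO_repeats operator repeats of the calibration array
#' @param n_cells number of cells
#' @param conc_low,conc_high log-uniform concentration range, nM (defaults
#'   several-fold above the default Kd so occupancy is > 0.98 everywhere)
#' @param ... further arguments passed to [sim_config()]
#' @return a `"sim_config"`
#' @export
saturated_sim_config <- function(lacO_repeats = 256, n_cells = 40,
                                 conc_low = 3000, conc_high = 5000, ...) {
  sim_config(n_cells = n_cells, lacO_repeats = lacO_repeats,
             conc_distribution = list(law = "log-uniform",
                                      low = conc_low, high = conc_high),
             ...)
}
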