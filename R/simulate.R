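# Forward model: renders labeled + matched unlabeled z-stacks with ground
# truth. Expected photons per voxel decompose as
#   autofluorescence + free-background + dot,
# where the free background of one slice is density * pixel_area * DOF
# (diffuse molecules within the depth of field contribute to every slice)
# and the dot is a pixel-integrated separable 3D Gaussian whose total equals
# photons_per_molecule * bound count.

# fraction of a 1D Gaussian falling into unit-width bins centred on `idx`
gauss_bin_weights <- function(idx, center, sigma) {
  pnorm(idx + 0.5, center, sigma) - pnorm(idx - 0.5, center, sigma)
}

# offset of the second dot of a replicated (post-replication, co-localized)
# array, in px: close enough that both dots fall in one integration disc,
# so the measured intensity is ~2x a singleton
REPLICATED_DOT_OFFSET_PX <- c(1.5, 1.5)

#' Simulate a FROS cell population with ground truth
#'
#' Renders multi-cell fields of view as (y, x, z) photon-count stacks: a
#' labeled stack (dot + free background + autofluorescence), a matched
#' unlabeled control stack (autofluorescence only), and an integer label
#' mask per field, plus a ground-truth table. Per-cell free concentrations
#' are drawn from `config$conc_distribution`; the bound count follows the
#' Hill occupancy at the ground-truth Kd times two molecules per operator
#' repeat; a `replicated_dot_fraction` minority of cells carries two
#' co-localized dots at the full bound count each.
#'
#' @param config a [sim_config()]
#' @return an object of class `"fros_population"`: a list with
#'   * `fields`: list of fields, each `list(labeled, control, mask,
#'     cell_ids)` where stacks are arrays `(y, x, z)` and `mask` is an
#'     integer label matrix (0 = background);
#'   * `truth`: data frame with `cell_id`, `field`, `true_free_conc` (nM),
#'     `true_bound_count` (molecules actually rendered; twice the singleton
#'     count for replicated cells), `dot_z`, `dot_y`, `dot_x` (1-based,
#'     continuous), `is_replicated`, `nucleus_y`, `nucleus_x`;
#'   * `config`: the input configuration.
#' @seealso [quantify_population()] for the measurement side,
#'   [write_population()] to serialize to TIFF/JSON/YAML.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  set.seed(config$seed)

  n <- config$n_cells
  cd <- config$conc_distribution
  conc <- switch(cd$law,
    "log-uniform" = exp(runif(n, log(cd$low), log(cd$high))),
    "log-normal" = {
      sdlog <- sqrt(log(1 + cd$cv^2))
      stats::rlnorm(n, log(cd$mean) - sdlog^2 / 2, sdlog)
    })
  is_rep <- runif(n) < config$replicated_dot_fraction
  theta <- occupancy(conc, config$true_kd, config$true_hill_n)
  bound_single <- round(2 * config$lacO_repeats * theta)

  cpf <- config$cells_per_field
  ncol_g <- ceiling(sqrt(cpf))
  nrow_g <- ceiling(cpf / ncol_g)
  ry <- config$cell_semiaxes_px[1]
  rx <- config$cell_semiaxes_px[2]
  spacing <- 2 * max(ry, rx) + 10
  n_fields <- ceiling(n / cpf)

  field_of <- rep(seq_len(n_fields), each = cpf)[seq_len(n)]
  slot_of <- ((seq_len(n) - 1) %% cpf)
  row_g <- slot_of %/% ncol_g + 1
  col_g <- slot_of %% ncol_g + 1
  cy <- (row_g - 0.5) * spacing
  cx <- (col_g - 0.5) * spacing
  dot_y <- cy + runif(n, -1.5, 1.5)
  dot_x <- cx + runif(n, -1.5, 1.5)
  dot_z <- (config$n_z + 1) / 2 + runif(n, -1, 1)

  ppm <- config$photons_per_molecule
  px <- config$pixel_size
  bg_per_px_per_nM <- ppm * molecules_per_um3_per_nM * px^2 * config$dof
  sxy <- config$psf_sigma_xy / px           # PSF width in px
  sz <- config$psf_sigma_z / config$z_spacing  # PSF width in slices
  ny <- nrow_g * spacing
  nx <- ncol_g * spacing
  n_z <- config$n_z
  wz_all <- vapply(seq_len(n), function(i)
    gauss_bin_weights(seq_len(n_z), dot_z[i], sz), numeric(n_z))

  inside_cell <- function(y, x, i) {
    ((y - cy[i]) / ry)^2 + ((x - cx[i]) / rx)^2 <= 1
  }

  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    ids <- which(field_of == f)
    mask <- matrix(0L, ny, nx)
    bg2d <- matrix(0, ny, nx)
    af2d <- matrix(0, ny, nx)
    for (i in ids) {
      yy <- seq(max(1, floor(cy[i] - ry)), min(ny, ceiling(cy[i] + ry)))
      xx <- seq(max(1, floor(cx[i] - rx)), min(nx, ceiling(cx[i] + rx)))
      grid <- expand.grid(y = yy, x = xx)
      inside <- inside_cell(grid$y, grid$x, i)
      idx <- cbind(grid$y[inside], grid$x[inside])
      mask[idx] <- i
      af2d[idx] <- config$autofluorescence_rate
      bg2d[idx] <- config$autofluorescence_rate +
        bg_per_px_per_nM * conc[i]
    }
    lam <- array(bg2d, dim = c(ny, nx, n_z))
    for (i in ids) {
      if (bound_single[i] == 0) next
      centers <- rbind(c(dot_y[i], dot_x[i]))
      if (is_rep[i])
        centers <- rbind(centers, centers[1, ] + REPLICATED_DOT_OFFSET_PX)
      for (k in seq_len(nrow(centers))) {
        if (!inside_cell(centers[k, 1], centers[k, 2], i))
          stop("dot placed outside cell mask (cell ", i, ")")
        half <- ceiling(4 * sxy + 1)
        yy <- seq(max(1, floor(centers[k, 1] - half)),
                  min(ny, ceiling(centers[k, 1] + half)))
        xx <- seq(max(1, floor(centers[k, 2] - half)),
                  min(nx, ceiling(centers[k, 2] + half)))
        wy <- gauss_bin_weights(yy, centers[k, 1], sxy)
        wx <- gauss_bin_weights(xx, centers[k, 2], sxy)
        spot2d <- ppm * bound_single[i] * (wy %o% wx)
        for (z in seq_len(n_z))
          lam[yy, xx, z] <- lam[yy, xx, z] + spot2d * wz_all[z, i]
      }
    }
    lam_ctrl <- array(af2d, dim = c(ny, nx, n_z))
    if (config$poisson_noise) {
      labeled <- array(rpois(length(lam), lam), dim(lam))
      control <- array(rpois(length(lam_ctrl), lam_ctrl), dim(lam_ctrl))
    } else {
      labeled <- lam
      control <- lam_ctrl
    }
    fields[[f]] <- list(labeled = labeled, control = control,
                        mask = mask, cell_ids = ids)
  }

  truth <- data.frame(
    cell_id = seq_len(n), field = field_of,
    true_free_conc = conc,
    true_bound_count = bound_single * ifelse(is_rep, 2L, 1L),
    dot_z = dot_z, dot_y = dot_y, dot_x = dot_x,
    is_replicated = is_rep, nucleus_y = cy, nucleus_x = cx)

  structure(list(fields = fields, truth = truth, config = config),
            class = "fros_population")
}

#' @export
print.fros_population <- function(x, ...) {
  cat("FROS population:", nrow(x$truth), "cells in", length(x$fields),
      "fields;", x$config$lacO_repeats, "x array, true Kd",
      x$config$true_kd, "nM, Hill n", x$config$true_hill_n, "\n")
  invisible(x)
}
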