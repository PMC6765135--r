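# Per-cell measurement: max-intensity composite -> dot localization ->
# per-z disc integration with local ring background -> ring background at
# the best-focus slice -> free concentration via the saturation reference.

# Fraction of a pixel-binned 2D Gaussian dot captured by disc photometry
# with annulus background subtraction, averaged over subpixel dot
# positions. Photons outside the disc are lost; photons leaking into the
# annulus inflate the background estimate and are subtracted disc-area
# times over. Dividing the raw photometry by this factor makes the
# integrated dot intensity an unbiased estimate of the total photons.
aperture_capture <- function(sigma_px, r_disc, r_in, r_out) {
  if (!is.finite(sigma_px) || sigma_px <= 0) return(1)
  half <- ceiling(r_out + 1)
  d <- seq(-half, half)
  n_disc <- sum(outer(d, d, function(a, b) a^2 + b^2 <= r_disc^2))
  n_ring <- sum(outer(d, d, function(a, b) {
    r2 <- a^2 + b^2
    r2 > r_in^2 & r2 <= r_out^2
  }))
  offs <- seq(-0.45, 0.45, by = 0.1)  # stratum midpoints over [-0.5, 0.5]
  caps <- vapply(offs, function(oy) vapply(offs, function(ox) {
    wy <- gauss_bin_weights(d, oy, sigma_px)
    wx <- gauss_bin_weights(d, ox, sigma_px)
    W <- wy %o% wx
    r2 <- outer(d, d, function(a, b) a^2 + b^2)
    sum(W[r2 <= r_disc^2]) -
      (n_disc / n_ring) * sum(W[r2 > r_in^2 & r2 <= r_out^2])
  }, numeric(1)), numeric(length(offs)))
  mean(caps)
}

# relative (dy, dx) offsets of pixels with inner < r <= outer
annulus_offsets <- function(inner, outer) {
  d <- seq(-ceiling(outer), ceiling(outer))
  g <- expand.grid(dy = d, dx = d)
  r2 <- g$dy^2 + g$dx^2
  keep <- r2 <= outer^2 & r2 > inner^2
  cbind(dy = g$dy[keep], dx = g$dx[keep])
}

disc_offsets <- function(radius) {
  d <- seq(-ceiling(radius), ceiling(radius))
  g <- expand.grid(dy = d, dx = d)
  keep <- g$dy^2 + g$dx^2 <= radius^2
  cbind(dy = g$dy[keep], dx = g$dx[keep])
}

#' Maximum-intensity composite of a z-stack
#'
#' Builds the 2D image used for dot localization: each pixel inside the
#' cell mask takes the maximum intensity of that pixel across the z-stack;
#' pixels outside the mask are set to 0.
#'
#' @param stack numeric array `(y, x, z)`
#' @param mask logical or integer matrix; nonzero/TRUE marks the cell
#' @return numeric matrix of the same (y, x) size
#' @export
max_composite <- function(stack, mask) {
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("`stack` must be a (y, x, z) array with at least one slice")
  m <- mask > 0
  if (!any(m)) stop("empty mask")
  comp <- Reduce(pmax, lapply(seq_len(dim(stack)[3]),
                              function(z) stack[, , z]))
  comp[!m] <- 0
  comp
}

#' Locate the chromosome dot in a composite image
#'
#' Returns the brightest in-cell pixel provided it exceeds a
#' local-background prominence threshold (median plus
#' `prominence_sigmas` x MAD of the in-cell composite). Absence of a
#' detectable dot (the dim-dot regime) is a valid result, reported as
#' `NULL`. A second qualifying maximum farther than twice the integration
#' radius from the first is reported through `n_peaks`, so downstream code
#' can flag multi-dot cells.
#'
#' @param composite matrix from [max_composite()]
#' @param mask cell mask (nonzero/TRUE inside)
#' @param config a [quant_config()]
#' @return `NULL` when no pixel passes, else `list(y, x, value, n_peaks)`
#' @export
detect_dot <- function(composite, mask, config = quant_config()) {
  m <- mask > 0
  if (!any(m)) stop("empty mask")
  vals <- composite[m]
  med <- median(vals)
  thr <- med + config$prominence_sigmas * mad(vals)
  work <- composite
  work[!m] <- -Inf
  i1 <- arrayInd(which.max(work), dim(work))
  v1 <- work[i1]
  if (!(v1 > thr)) return(NULL)
  # blank a neighbourhood of the first peak, look for a second one
  excl <- 2 * config$dot_integration_radius_xy
  off <- disc_offsets(excl)
  yy <- i1[1] + off[, "dy"]
  xx <- i1[2] + off[, "dx"]
  ok <- yy >= 1 & yy <= nrow(work) & xx >= 1 & xx <= ncol(work)
  work[cbind(yy[ok], xx[ok])] <- -Inf
  v2 <- max(work)
  # a second dot must clear the threshold with a prominence comparable to
  # the main peak's (a replicated array gives two dots of similar
  # brightness); this keeps PSF tails from counting as peaks
  second <- is.finite(v2) && v2 > thr && (v2 - med) > 0.25 * (v1 - med)
  list(y = i1[1], x = i1[2], value = v1,
       n_peaks = if (second) 2L else 1L)
}

#' Per-z dot intensity scan
#'
#' For each z slice, subtracts the autofluorescence level, integrates the
#' dot over a disc of radius `dot_integration_radius_xy` around `pos`, and
#' subtracts the local background (mean over the enclosing annulus times
#' the disc area). The slice with the largest dot intensity is the
#' best-focus slice; the sum of the per-z dot intensities is the volume
#' under the intensity-scan peak, i.e. all photons generated by the bound
#' molecules.
#'
#' @param stack numeric array `(y, x, z)`
#' @param pos `c(y, x)` dot position in pixels
#' @param config a [quant_config()]
#' @return `list(profile, best_z, dot_total, dot_sd)` where `profile` is a
#'   data frame with `z`, `dot_intensity`, `local_background` (per-pixel
#'   mean) and `dot_sd` is the photon-statistics standard deviation of
#'   `dot_total`
#' @export
dot_profile <- function(stack, pos, config = quant_config()) {
  dims <- dim(stack)
  r <- config$dot_integration_radius_xy
  if (pos[1] - r < 1 || pos[1] + r > dims[1] ||
        pos[2] - r < 1 || pos[2] + r > dims[2])
    stop("integration disc clipped by the image edge")
  disc <- disc_offsets(r)
  ring <- annulus_offsets(config$ring_inner_radius, config$ring_outer_radius)
  didx <- cbind(pos[1] + disc[, "dy"], pos[2] + disc[, "dx"])
  ridx <- cbind(pos[1] + ring[, "dy"], pos[2] + ring[, "dx"])
  rok <- ridx[, 1] >= 1 & ridx[, 1] <= dims[1] &
    ridx[, 2] >= 1 & ridx[, 2] <= dims[2]
  ridx <- ridx[rok, , drop = FALSE]
  n_z <- dims[3]
  capture <- aperture_capture(config$psf_sigma_xy / config$pixel_size, r,
                              config$ring_inner_radius,
                              config$ring_outer_radius)
  dot_int <- numeric(n_z)
  loc_bg <- numeric(n_z)
  var_tot <- 0
  n_disc <- nrow(disc)
  n_ring <- nrow(ridx)
  for (z in seq_len(n_z)) {
    raw <- stack[, , z]
    sl <- raw - config$autofluorescence_level
    loc_bg[z] <- mean(sl[ridx])
    dot_int[z] <- (sum(sl[didx]) - loc_bg[z] * n_disc) / capture
    # Poisson photon statistics of the disc sum and the scaled ring mean
    var_tot <- var_tot + sum(raw[didx]) +
      (n_disc^2 / n_ring) * mean(raw[ridx])
  }
  list(profile = data.frame(z = seq_len(n_z), dot_intensity = dot_int,
                            local_background = loc_bg),
       best_z = which.max(dot_int),
       dot_total = sum(dot_int),
       dot_sd = sqrt(max(var_tot, 0)) / capture)
}

#' Ring background at the best-focus slice
#'
#' Integrates the autofluorescence-subtracted intensity over an annulus
#' enclosing the dot at the best-focus slice; this "total background
#' intensity" represents the free protein in the vicinity of the dot. If the ring leaves the cell mask it is shrunk (outer radius
#' reduced) until it fits; if even the smallest ring does not fit the cell
#' is marked unusable. A ring pixel far brighter than the ring's robust
#' level (e.g. a second, well-separated dot) marks the ring contaminated
#' and the cell unusable.
#'
#' @param stack numeric array `(y, x, z)`
#' @param pos `c(y, x)` dot position in pixels
#' @param best_z best-focus slice index
#' @param mask cell mask (nonzero/TRUE inside)
#' @param config a [quant_config()]
#' @return `list(ring_total, ring_area, n_pixels, outer_radius, usable,
#'   contaminated)`; `ring_area` in um^2
#' @export
ring_background <- function(stack, pos, best_z, mask,
                            config = quant_config()) {
  dims <- dim(stack)
  m <- mask > 0
  inner <- config$ring_inner_radius
  outer <- config$ring_outer_radius
  sl <- stack[, , best_z] - config$autofluorescence_level
  repeat {
    ring <- annulus_offsets(inner, outer)
    yy <- pos[1] + ring[, "dy"]
    xx <- pos[2] + ring[, "dx"]
    in_img <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
    fits <- all(in_img) && all(m[cbind(yy, xx)])
    if (fits) break
    outer <- outer - 1
    if (outer <= inner)
      return(list(ring_total = NA_real_, ring_area = NA_real_,
                  n_pixels = 0L, outer_radius = NA_real_,
                  usable = FALSE, contaminated = FALSE))
  }
  vals <- sl[cbind(yy, xx)]
  med <- median(vals)
  noise_floor <- sqrt(max(med + config$autofluorescence_level, 1))
  contaminated <- max(vals) > med + 6 * max(mad(vals), noise_floor)
  list(ring_total = sum(vals),
       ring_area = length(vals) * config$pixel_size^2,
       n_pixels = length(vals), outer_radius = outer,
       usable = !contaminated, contaminated = contaminated)
}

#' Estimate the autofluorescence level from unlabeled cells
#'
#' Mean per-pixel intensity inside the cell masks of matched unlabeled
#' control stacks, pooled over fields and slices.
#'
#' @param x a `"fros_population"` (its `control` stacks are used), or a
#'   list of `(y, x, z)` arrays
#' @param masks list of mask matrices, one per stack (ignored when `x` is a
#'   population)
#' @return scalar autofluorescence level, photons per pixel per slice
#' @export
estimate_autofluorescence <- function(x, masks = NULL) {
  if (inherits(x, "fros_population")) {
    stacks <- lapply(x$fields, `[[`, "control")
    masks <- lapply(x$fields, `[[`, "mask")
  } else stacks <- x
  tot <- 0
  npx <- 0
  for (i in seq_along(stacks)) {
    m <- masks[[i]] > 0
    n_z <- dim(stacks[[i]])[3]
    for (z in seq_len(n_z)) {
      tot <- tot + sum(stacks[[i]][, , z][m])
      npx <- npx + sum(m)
    }
  }
  if (npx == 0) stop("no in-mask pixels in the control stacks")
  tot / npx
}

quantify_cell <- function(stack, mask_cell, config, cell_id,
                          centroid = NULL) {
  comp <- max_composite(stack, mask_cell)
  det <- detect_dot(comp, mask_cell, config)
  detected <- !is.null(det)
  if (detected) {
    pos <- c(det$y, det$x)
    n_peaks <- det$n_peaks
  } else {
    # dim-dot regime: integrate at the cell centroid so near-zero
    # occupancies still enter the binding curve
    if (is.null(centroid)) {
      w <- which(mask_cell > 0, arr.ind = TRUE)
      centroid <- round(colMeans(w))
    }
    pos <- as.numeric(centroid)
    n_peaks <- 0L
  }
  prof <- dot_profile(stack, pos, config)
  ring <- ring_background(stack, pos, prof$best_z, mask_cell, config)
  dot_total <- prof$dot_total
  clipped <- dot_total < 0
  if (clipped) dot_total <- 0
  data.frame(cell_id = cell_id, dot_y = pos[1], dot_x = pos[2],
             best_z = prof$best_z, dot_total = dot_total,
             dot_sd = prof$dot_sd,
             ring_total = ring$ring_total, ring_area = ring$ring_area,
             dot_detected = detected, n_peaks = n_peaks,
             clipped = clipped, ring_contaminated = ring$contaminated,
             usable = ring$usable, discarded = FALSE)
}

#' Quantify every cell of a field
#'
#' Runs the full per-cell measurement (composite, dot localization, per-z
#' scan, ring background) for each label in `mask`.
#'
#' @param stack labeled `(y, x, z)` array
#' @param mask integer label matrix (0 = background)
#' @param config a [quant_config()] carrying the autofluorescence level
#' @return data frame of per-cell records (one row per label)
#' @export
quantify_stack <- function(stack, mask, config = quant_config()) {
  ids <- sort(setdiff(unique(as.integer(mask)), 0L))
  if (length(ids) == 0) stop("mask contains no cells")
  pad <- config$ring_outer_radius + config$dot_integration_radius_xy + 2
  out <- lapply(ids, function(id) {
    w <- which(mask == id, arr.ind = TRUE)
    y0 <- max(1, min(w[, 1]) - pad); y1 <- min(nrow(mask), max(w[, 1]) + pad)
    x0 <- max(1, min(w[, 2]) - pad); x1 <- min(ncol(mask), max(w[, 2]) + pad)
    sub <- stack[y0:y1, x0:x1, , drop = FALSE]
    msub <- mask[y0:y1, x0:x1] == id
    rec <- quantify_cell(sub, msub, config, id)
    rec$dot_y <- rec$dot_y + y0 - 1
    rec$dot_x <- rec$dot_x + x0 - 1
    rec
  })
  do.call(rbind, out)
}

#' Quantify a simulated population
#'
#' Convenience wrapper: estimates the autofluorescence level from the
#' population's matched unlabeled control stacks (unless given), then runs
#' [quantify_stack()] on every field.
#'
#' @param pop a `"fros_population"`
#' @param config a [quant_config()]; its `autofluorescence_level` is
#'   overridden by `autofluorescence` when supplied
#' @param autofluorescence optional scalar per-pixel autofluorescence; by
#'   default estimated from the control stacks
#' @return data frame of per-cell records across all fields
#' @export
quantify_population <- function(pop, config = quant_config(),
                                autofluorescence = NULL) {
  if (!inherits(pop, "fros_population")) stop("`pop` must be a fros_population")
  if (is.null(autofluorescence))
    autofluorescence <- estimate_autofluorescence(pop)
  config$autofluorescence_level <- autofluorescence
  recs <- lapply(pop$fields, function(fld)
    quantify_stack(fld$labeled, fld$mask, config))
  do.call(rbind, recs)
}

#' Discard extra-bright dots
#'
#' Flags records whose dot intensity exceeds `factor` times the robust
#' population average (the median) as replicated arrays. With `group`, the
#' median is taken within each group (e.g. concentration bins), so cells
#' are compared to peers at the same expected occupancy. Only usable
#' records whose dot passed detection are considered; flagged records are
#' otherwise untouched, and a second application changes nothing.
#'
#' @param records data frame from [quantify_stack()] (needs `dot_total`;
#'   `usable` and `dot_detected` are honoured when present)
#' @param factor discard threshold as a multiple of the median (default
#'   1.8; `Inf` disables)
#' @param group optional grouping vector, one entry per record
#' @return `records` with an updated logical `discarded` column
#' @export
discard_bright <- function(records, factor = 1.8, group = NULL) {
  if (nrow(records) < 3) stop("need at least 3 records")
  usable <- if (!is.null(records$usable)) records$usable
            else rep(TRUE, nrow(records))
  # only cells with a detected dot can be "extra-bright"; the reference
  # median is taken over all usable cells so marginal detection does not
  # inflate it
  eligible <- usable
  if (!is.null(records$dot_detected))
    eligible <- eligible & records$dot_detected
  if (is.null(group)) group <- rep(1L, nrow(records))
  discarded <- rep(FALSE, nrow(records))
  for (g in unique(group[eligible])) {
    in_g <- eligible & group == g
    med <- median(records$dot_total[usable & group == g])
    discarded[in_g] <- records$dot_total[in_g] > factor * med
  }
  if (!is.null(records$discarded))
    discarded <- discarded | records$discarded
  records$discarded <- discarded
  if (all(discarded[eligible]) && any(eligible))
    stop("degenerate population: every record was discarded")
  records
}

#' Calibrate the intensity-per-molecule scale from a saturated strain
#'
#' Under saturating labeled-protein concentration the array is fully
#' occupied, binding two molecules per operator repeat (512 for a 256x
#' array), so the mean dot intensity divided by `2 * lacO_repeats` gives
#' the integrated intensity of a single molecule. Saturation is sanity
#' checked: at saturation the dot intensity must not correlate with the
#' background intensity; a significant Pearson correlation above
#' `cor_threshold` raises a warning.
#'
#' @param records per-cell records of the saturated strain (after
#'   [discard_bright()])
#' @param lacO_repeats operator repeats of the calibration array
#' @param cor_threshold absolute Pearson correlation above which (with
#'   p < 0.05) the saturation check warns
#' @return intensity per molecule (scalar)
#' @export
calibrate_saturation <- function(records, lacO_repeats,
                                 cor_threshold = 0.5) {
  keep <- records$usable & !records$discarded
  if (!is.null(records$dot_detected)) keep <- keep & records$dot_detected
  rec <- records[keep, ]
  if (nrow(rec) < 10)
    stop("need at least 10 usable records to calibrate (got ",
         nrow(rec), ")")
  ct <- suppressWarnings(cor.test(rec$dot_total, rec$ring_total))
  # a correlation only matters if the implied systematic variation of the
  # dot intensity across the sampled background range is non-negligible
  trend <- coef(lm(rec$dot_total ~ rec$ring_total))[2]
  rel_span <- abs(trend) * diff(range(rec$ring_total)) / mean(rec$dot_total)
  if (is.finite(ct$estimate) && abs(ct$estimate) > cor_threshold &&
        ct$p.value < 0.05 && rel_span > 0.05)
    warning("saturation check failed: dot intensity correlates with ",
            "background (Pearson R = ", signif(ct$estimate, 3),
            "); the calibration strain may not be saturated")
  mean(rec$dot_total) / (2 * lacO_repeats)
}

#' Convert per-cell intensities to concentration and occupancy
#'
#' Applies the saturation bookkeeping: the bound count is the dot intensity
#' divided by the per-molecule reference; the free molecules in the ring
#' volume are the ring intensity divided by the same reference; the free
#' number density is that count over `ring_area * DOF`, converted to nM via
#' 0.6022 molecules/um^3 per nM. The estimated free concentration is the
#' diffusive plus transiently non-specifically bound pool seen by the
#' microscope. Occupancy is the bound count over `2 * lacO_repeats`.
#'
#' @param records per-cell records
#' @param saturated_reference intensity per molecule from
#'   [calibrate_saturation()]
#' @param lacO_repeats operator repeats of the measured array
#' @param config a [quant_config()] (supplies the DOF)
#' @return `records` with added `n_bound_est`, `free_conc_est` (nM),
#'   `occupancy_est` and `flag_overshoot` (occupancy beyond 1.05)
#' @export
estimate_concentration <- function(records, saturated_reference,
                                   lacO_repeats,
                                   config = quant_config()) {
  if (!is.numeric(saturated_reference) || saturated_reference <= 0)
    stop("`saturated_reference` must be positive")
  if (any(records$ring_area[records$usable] <= 0, na.rm = TRUE))
    stop("zero ring area in usable records")
  records$n_bound_est <- records$dot_total / saturated_reference
  n_free <- records$ring_total / saturated_reference
  density <- n_free / (records$ring_area * config$dof)
  records$free_conc_est <- pmax(density / molecules_per_um3_per_nM, 0)
  records$occupancy_est <- records$n_bound_est / (2 * lacO_repeats)
  records$flag_overshoot <- records$occupancy_est > 1.05
  records
}
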