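# Per-cell measurement: composite, localization, z-scan, ring background,
# bright-dot discard, saturation calibration, concentration estimation.

test_that("max composite takes the per-pixel z-maximum inside the mask", {
  mask <- matrix(TRUE, 5, 5)
  one <- array(3, dim = c(5, 5, 1))
  expect_equal(max_composite(one, mask), matrix(3, 5, 5))
  st <- array(7, dim = c(5, 5, 4))
  expect_equal(max_composite(st, mask), matrix(7, 5, 5))
  st[2, 3, 2] <- 99
  comp <- max_composite(st, mask)
  expect_equal(comp[2, 3], 99)
  # outside the mask the composite is zero
  mask2 <- mask
  mask2[1, ] <- FALSE
  expect_true(all(max_composite(st, mask2)[1, ] == 0))
  expect_error(max_composite(st, mask & FALSE), "empty mask")
})

test_that("composite argmax lands on the rendered dot", {
  pop <- small_pop(seed = 41, n_cells = 8, replicated_dot_fraction = 0,
                   conc_distribution = list(law = "log-uniform",
                                            low = 500, high = 1500))
  fld <- pop$fields[[1]]
  for (id in fld$cell_ids) {
    comp <- max_composite(fld$labeled, fld$mask == id)
    pk <- arrayInd(which.max(comp), dim(comp))
    tr <- pop$truth[pop$truth$cell_id == id, ]
    expect_lte(max(abs(pk - c(tr$dot_y, tr$dot_x))), 1)
  }
})

test_that("dot detection: flat image gives none, rendered dot is found, two dots flag multiplicity", {
  mask <- matrix(TRUE, 41, 41)
  flat <- matrix(5, 41, 41)
  expect_null(detect_dot(flat, mask))
  pop <- small_pop(seed = 42, n_cells = 4, replicated_dot_fraction = 0,
                   conc_distribution = list(law = "log-uniform",
                                            low = 800, high = 1500))
  fld <- pop$fields[[1]]
  id <- fld$cell_ids[1]
  det <- detect_dot(max_composite(fld$labeled, fld$mask == id),
                    fld$mask == id)
  tr <- pop$truth[pop$truth$cell_id == id, ]
  expect_equal(c(det$y, det$x), round(c(tr$dot_y, tr$dot_x)))
  expect_equal(det$n_peaks, 1L)
  # two well-separated dots: brighter one wins, multiplicity flagged
  two <- flat
  two[15, 15] <- 60
  two[30, 28] <- 80
  det2 <- detect_dot(two, mask)
  expect_equal(c(det2$y, det2$x), c(30, 28))
  expect_equal(det2$n_peaks, 2L)
})

test_that("z-scan recovers the photon total and the focus slice", {
  cfg <- sim_config(n_cells = 6, poisson_noise = FALSE, seed = 43,
                    replicated_dot_fraction = 0,
                    conc_distribution = list(law = "log-uniform",
                                             low = 400, high = 1500))
  pop <- simulate_population(cfg)
  qc <- quant_config(autofluorescence_level = cfg$autofluorescence_rate)
  fld <- pop$fields[[1]]
  for (id in fld$cell_ids) {
    tr <- pop$truth[pop$truth$cell_id == id, ]
    prof <- dot_profile(fld$labeled, round(c(tr$dot_y, tr$dot_x)), qc)
    expect_equal(prof$dot_total,
                 cfg$photons_per_molecule * tr$true_bound_count,
                 tolerance = 0.02)
    expect_equal(prof$best_z, round(tr$dot_z))
  }
  # no dot: scan stays at the noise floor (exactly 0 noise-free)
  zpop <- simulate_population(
    sim_config(n_cells = 1, poisson_noise = FALSE, seed = 44,
               replicated_dot_fraction = 0,
               conc_distribution = list(law = "log-uniform",
                                        low = 50, high = 50.5)))
  ztr <- zpop$truth
  expect_equal(ztr$true_bound_count, 0)
  zprof <- dot_profile(zpop$fields[[1]]$labeled,
                       round(c(ztr$dot_y, ztr$dot_x)),
                       quant_config(autofluorescence_level = 20))
  expect_lt(abs(zprof$dot_total), 1e-6)
  # disc clipped by the image edge is an error
  expect_error(dot_profile(fld$labeled, c(2, 2), qc), "clipped")
})

test_that("ring background measures the local free-protein level", {
  cfg <- sim_config(n_cells = 4, poisson_noise = FALSE, seed = 45,
                    replicated_dot_fraction = 0, true_kd = 1e9,
                    conc_distribution = list(law = "log-uniform",
                                             low = 200, high = 1000))
  pop <- simulate_population(cfg)  # huge Kd: background only, no dots
  qc <- quant_config(autofluorescence_level = cfg$autofluorescence_rate)
  fld <- pop$fields[[1]]
  for (id in fld$cell_ids) {
    tr <- pop$truth[pop$truth$cell_id == id, ]
    pos <- round(c(tr$dot_y, tr$dot_x))
    ring <- ring_background(fld$labeled, pos, 5, fld$mask == id, qc)
    expect_true(ring$usable)
    # closed form: density * pixel_area * DOF per pixel
    expected <- cfg$photons_per_molecule * tr$true_free_conc *
      molecules_per_um3_per_nM * cfg$pixel_size^2 * cfg$dof * ring$n_pixels
    expect_equal(ring$ring_total, expected, tolerance = 1e-9)
    expect_equal(ring$ring_area, ring$n_pixels * cfg$pixel_size^2)
  }
  # autofluorescence-only cell: ring total is zero after subtraction
  ctrl <- fld$control
  tr <- pop$truth[pop$truth$cell_id == fld$cell_ids[1], ]
  ring0 <- ring_background(ctrl, round(c(tr$dot_y, tr$dot_x)), 5,
                           fld$mask == fld$cell_ids[1], qc)
  expect_equal(ring0$ring_total, 0, tolerance = 1e-9)
})

test_that("a ring that exits the mask shrinks, and a contaminated ring is unusable", {
  cfg <- sim_config(n_cells = 1, poisson_noise = FALSE, seed = 46,
                    replicated_dot_fraction = 0,
                    conc_distribution = list(law = "log-uniform",
                                             low = 500, high = 501))
  pop <- simulate_population(cfg)
  fld <- pop$fields[[1]]
  tr <- pop$truth
  qc <- quant_config(autofluorescence_level = cfg$autofluorescence_rate)
  # position near the cell edge: outer radius must shrink below default
  edge <- c(round(tr$nucleus_y) - 14, round(tr$nucleus_x))
  rr <- ring_background(fld$labeled, edge, 5, fld$mask > 0, qc)
  expect_true(is.na(rr$outer_radius) || rr$outer_radius <
                qc$ring_outer_radius)
  # a second bright dot inside the ring contaminates it
  st <- fld$labeled
  pos <- round(c(tr$dot_y, tr$dot_x))
  st[pos[1] + 6, pos[2], 5] <- st[pos[1] + 6, pos[2], 5] + 5e4
  rc <- ring_background(st, pos, 5, fld$mask > 0, qc)
  expect_true(rc$contaminated)
  expect_false(rc$usable)
})

test_that("bright-dot discard flags exactly the doubled dots and is idempotent", {
  rec <- data.frame(dot_total = c(rep(1000, 90), rep(2000, 10)),
                    usable = TRUE, discarded = FALSE)
  out <- discard_bright(rec, 1.8)
  expect_equal(which(out$discarded), 91:100)
  # idempotent
  expect_equal(discard_bright(out, 1.8)$discarded, out$discarded)
  # permutation invariant
  perm <- c(seq(51, 100), seq(1, 50))
  out_p <- discard_bright(rec[perm, ], 1.8)
  expect_equal(out_p$discarded, out$discarded[perm])
  # equal intensities: nothing discarded; infinite factor: identity
  eq <- data.frame(dot_total = rep(5, 20), usable = TRUE, discarded = FALSE)
  expect_false(any(discard_bright(eq, 1.8)$discarded))
  expect_false(any(discard_bright(rec, Inf)$discarded))
  # degenerate: everything above factor * median
  expect_error(discard_bright(eq, 0.5), "degenerate")
  expect_error(discard_bright(rec[1:2, ], 1.8), "at least 3")
})

test_that("grouped discard compares cells to peers at the same concentration", {
  # low-occupancy group: singletons at 100, replicated at 200
  # high-occupancy group: singletons at 5000 (> 1.8x global median)
  rec <- data.frame(
    dot_total = c(rep(100, 18), 200, 200, rep(5000, 10)),
    usable = TRUE, discarded = FALSE)
  grp <- c(rep(1, 20), rep(2, 10))
  out <- discard_bright(rec, 1.8, group = grp)
  expect_equal(which(out$discarded), c(19, 20))
  # ungrouped, the saturated singletons would be lost
  out_flat <- discard_bright(rec, 1.8)
  expect_true(all(out_flat$discarded[21:30]))
})

test_that("saturation calibration recovers the intensity per molecule", {
  cal <- small_cal(seed = 47, n_cells = 24)
  rec <- discard_bright(quantify_population(cal, quant_config()), 1.8)
  ref <- calibrate_saturation(rec, 256)
  expect_equal(ref, cal$config$photons_per_molecule, tolerance = 0.02)
  # denominator is 2 molecules per repeat
  toy <- data.frame(dot_total = rep(6400, 12), ring_total = runif(12),
                    usable = TRUE, discarded = FALSE, dot_detected = TRUE)
  expect_equal(calibrate_saturation(toy, 32), 6400 / 64)
  expect_error(calibrate_saturation(toy[1:5, ], 32), "at least 10")
})

test_that("an unsaturated calibration strain triggers the saturation warning", {
  cal <- simulate_population(
    saturated_sim_config(n_cells = 30, conc_low = 300, conc_high = 1200,
                         seed = 48))
  rec <- discard_bright(quantify_population(cal, quant_config()), 1.8)
  expect_warning(calibrate_saturation(rec, 256), "saturation check failed")
})

test_that("concentration estimation applies the saturation bookkeeping", {
  qc <- quant_config()
  # dot = ring and 512 bound molecules: C * area * DOF = 512 molecules
  ref <- 100
  rec <- data.frame(dot_total = 512 * ref, ring_total = 512 * ref,
                    ring_area = 1.48, usable = TRUE, discarded = FALSE)
  est <- estimate_concentration(rec, ref, 256, qc)
  expect_equal(est$n_bound_est, 512)
  expect_equal(
    est$free_conc_est * molecules_per_um3_per_nM * rec$ring_area * qc$dof,
    512)
  expect_equal(est$occupancy_est, 1)
  # zero background means zero concentration
  rec0 <- data.frame(dot_total = 100, ring_total = 0, ring_area = 1.48,
                     usable = TRUE, discarded = FALSE)
  expect_equal(estimate_concentration(rec0, ref, 256, qc)$free_conc_est, 0)
  expect_error(estimate_concentration(rec, 0, 256, qc), "positive")
})

test_that("noise-free pipeline recovers concentration and bound count within 5%", {
  pop <- small_pop(seed = 49, n_cells = 16)
  cal <- small_cal(seed = 50, n_cells = 16)
  est <- quantified(pop, cal)
  m <- merge(est, pop$truth, by = "cell_id")
  ok <- m$usable & !m$is_replicated
  expect_true(all(abs(m$free_conc_est[ok] / m$true_free_conc[ok] - 1) < 0.05))
  okb <- ok & m$true_bound_count >= 10
  expect_true(all(abs(m$n_bound_est[okb] / m$true_bound_count[okb] - 1) < 0.05))
})

test_that("with shot noise the per-cell estimates stay within 15%", {
  pop <- small_pop(seed = 51, n_cells = 24, noise = TRUE)
  cal <- small_cal(seed = 52, n_cells = 20, noise = TRUE)
  est <- quantified(pop, cal)
  m <- merge(est, pop$truth, by = "cell_id")
  ok <- m$usable & !m$is_replicated
  expect_true(all(abs(m$free_conc_est[ok] / m$true_free_conc[ok] - 1) < 0.15))
  okb <- ok & m$true_bound_count >= 50
  expect_true(all(abs(m$n_bound_est[okb] / m$true_bound_count[okb] - 1) < 0.15))
})
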