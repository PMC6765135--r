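# Binding-curve construction and Hill fitting: per-cell records are binned
# into fixed concentration windows, the per-bin medians are fitted by
# I(C) = I_max * C^n / (Kd^n + C^n) weighted by bin occupancy counts.

#' Bin per-cell records into concentration windows
#'
#' Half-open bins `[k*w, (k+1)*w)` over the estimated free concentration;
#' empty bins are omitted. Per bin: the number of cells, the median
#' concentration of its members (used as the fit abscissa; the median
#' commutes with the monotone binding curve so medians-on-medians is
#' unbiased), the median normalized dot intensity (occupancy) and its 5th
#' and 95th percentiles. Only usable, non-discarded records enter.
#'
#' @param records data frame with `free_conc_est` and `occupancy_est`
#'   (from [estimate_concentration()])
#' @param bin_width window width, nM (default 100)
#' @return data frame with `bin`, `conc_lo`, `conc_hi`, `conc_median`,
#'   `occ_median`, `occ_p5`, `occ_p95`, `n`
#' @export
bin_cells <- function(records, bin_width = 100) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  keep <- rep(TRUE, nrow(records))
  if (!is.null(records$usable)) keep <- keep & records$usable
  if (!is.null(records$discarded)) keep <- keep & !records$discarded
  rec <- records[keep, ]
  if (nrow(rec) == 0) stop("no usable records to bin")
  bin <- floor(rec$free_conc_est / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    occ <- rec$occupancy_est[bin == b]
    cc <- rec$free_conc_est[bin == b]
    data.frame(bin = b, conc_lo = b * bin_width,
               conc_hi = (b + 1) * bin_width,
               conc_median = median(cc), occ_median = median(occ),
               occ_p5 = quantile(occ, 0.05, names = FALSE),
               occ_p95 = quantile(occ, 0.95, names = FALSE),
               n = length(occ))
  }))
  if (nrow(out) < 2)
    stop("all cells fall in a single concentration bin; ",
         "the binding curve cannot be fitted")
  rownames(out) <- NULL
  out
}

#' Fit a Hill binding curve to binned data
#'
#' Weighted least squares of `I(C) = I_max * C^n / (Kd^n + C^n)` on the bin
#' medians, with bin counts as weights. Initialisation: Kd at the
#' concentration where the observed curve crosses half its maximum, n = 2.
#' Bounds: Kd in (1e-3, 1e5) nM, n in (0.2, 10). Standard errors come from
#' the fit covariance. If the data never cross half of the fitted
#' saturation level the Kd is only a bound, and a warning says in which
#' direction.
#'
#' @param binned data frame from [bin_cells()] (or any data frame with
#'   `conc_median`, `occ_median`, `n`)
#' @param start optional named list overriding the self-starting values
#'   (`kd`, `hill_n`, `i_max`)
#' @return an object of class `"hill_fit"`: a list with `kd`, `hill_n`,
#'   `i_max`, `se_kd`, `se_n`, `se_imax`, `n_cells`, `binned` and the
#'   underlying `nls` fit
#' @export
fit_hill <- function(binned, start = NULL) {
  if (nrow(binned) < 3) stop("need at least 3 bins to fit a Hill curve")
  x <- binned$conc_median
  y <- binned$occ_median
  w <- binned$n
  imax0 <- max(y)
  half <- imax0 / 2
  above <- which(y >= half)
  kd0 <- if (length(above) > 0) x[min(above)] else max(x)
  st <- list(i_max = imax0, kd = kd0, hill_n = 2)
  st[names(start)] <- start
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i_max * x^hill_n / (kd^hill_n + x^hill_n),
      start = st[c("i_max", "kd", "hill_n")], weights = w,
      lower = c(i_max = 1e-6, kd = 1e-3, hill_n = 0.2),
      upper = c(i_max = 10, kd = 1e5, hill_n = 10),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)),
    error = function(e)
      stop("Hill fit did not converge: ", conditionMessage(e),
           " [", nrow(binned), " bins, conc ", signif(min(x), 3), "-",
           signif(max(x), 3), " nM, occupancy ", signif(min(y), 3), "-",
           signif(max(y), 3), "]", call. = FALSE))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (max(y) < est[["i_max"]] / 2)
    warning("binding never reaches half of the fitted saturation level: ",
            "the fitted Kd is a lower bound (true Kd may lie above the ",
            "sampled concentration range)")
  else if (min(y) > est[["i_max"]] / 2)
    warning("binding is above half-saturation at every sampled ",
            "concentration: the fitted Kd is an upper bound (true Kd may ",
            "lie below the sampled concentration range)")
  structure(list(kd = est[["kd"]], hill_n = est[["hill_n"]],
                 i_max = est[["i_max"]],
                 se_kd = se[["kd"]], se_n = se[["hill_n"]],
                 se_imax = se[["i_max"]],
                 n_cells = sum(binned$n), bin_width =
                   if (!is.null(binned$conc_hi))
                     binned$conc_hi[1] - binned$conc_lo[1] else NA_real_,
                 binned = binned, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("Hill fit (%d cells, %d bins):\n",
                     "  Kd    = %.4g +/- %.2g nM\n",
                     "  n     = %.3g +/- %.2g\n",
                     "  I_max = %.3g +/- %.2g\n"),
              x$n_cells, nrow(x$binned), x$kd, x$se_kd, x$hill_n, x$se_n,
              x$i_max, x$se_imax))
  invisible(x)
}

#' Linearity of saturated dot intensity in array size
#'
#' Pearson correlation between the operator repeat number and the saturated
#' dot intensity, plus the fitted slope per repeat (intensity gained per
#' additional operator). Internal-consistency check: at saturation the dot
#' intensity must scale linearly with the repeat number.
#'
#' @param repeat_counts operator repeats per array (>= 3 values)
#' @param intensities matching saturated dot intensities
#' @return `list(r, slope_per_repeat, intercept)`
#' @export
linearity_check <- function(repeat_counts, intensities) {
  if (length(repeat_counts) != length(intensities))
    stop("inputs must have equal length")
  if (length(repeat_counts) < 3) stop("need at least 3 array sizes")
  if (sd(repeat_counts) == 0 || sd(intensities) == 0)
    stop("zero variance: correlation undefined")
  fit <- lm(intensities ~ repeat_counts)
  list(r = cor(repeat_counts, intensities),
       slope_per_repeat = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}
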