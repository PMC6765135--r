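#' Hill occupancy
#'
#' Fractional occupancy of a binding site at free ligand concentration
#' `conc`: theta = C^n / (Kd^n + C^n). The apparent Kd is the concentration
#' at which half the sites are occupied, so `occupancy(kd, kd, n) == 0.5`
#' for any Hill coefficient.
#'
#' @param conc free-protein concentration, nM (vectorised, >= 0)
#' @param kd apparent dissociation constant, nM (> 0)
#' @param n Hill coefficient (> 0)
#' @return occupancy in `[0, 1]`, same length as `conc`
#' @examples
#' occupancy(592, 592, 2.93)   # 0.5 at C = Kd
#' occupancy(1184, 592, 1)     # 2/3
#' @export
occupancy <- function(conc, kd, n) {
  if (any(conc < 0)) stop("`conc` must be non-negative")
  if (kd <= 0) stop("`kd` must be positive")
  if (n <= 0) stop("`n` must be positive")
  r <- (conc / kd)^n
  theta <- r / (1 + r)
  theta[is.infinite(r)] <- 1
  theta
}
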