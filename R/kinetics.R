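# Closed-form models connecting binding kinetics, active degradation and
# non-specific genomic-DNA competition to the apparent Kd.

#' Kinetic rate bundle
#'
#' Association, dissociation and degradation rates for a simple binding
#' reaction. Units: `kon` in per-(nM s), `koff` and `kdeg` in per-s;
#' `kdeg = 0` describes a stable protein.
#'
#' @param kon association rate, nM^-1 s^-1 (> 0)
#' @param koff dissociation rate, s^-1 (>= 0)
#' @param kdeg degradation rate, s^-1 (>= 0; default 0)
#' @return a list of class `"kinetic_rates"`
#' @export
kinetic_rates <- function(kon, koff, kdeg = 0) {
  if (!is.numeric(kon) || kon <= 0) stop("`kon` must be positive")
  if (koff < 0 || kdeg < 0) stop("`koff` and `kdeg` must be non-negative")
  structure(list(kon = kon, koff = koff, kdeg = kdeg),
            class = "kinetic_rates")
}

#' Degradation rate from a half-life
#'
#' `kdeg = ln(2) / t_half`. A 12-minute half-life gives
#' `9.6e-4 s^-1` (2 s.f.).
#'
#' @param t_half protein half-life, s (> 0)
#' @return degradation rate, s^-1
#' @export
kdeg_from_halflife <- function(t_half) {
  if (!is.numeric(t_half) || any(t_half <= 0))
    stop("`t_half` must be positive")
  log(2) / t_half
}

#' Apparent Kd of a binding reaction with active degradation
#'
#' For d theta/dt = kon * C * (1 - theta) - (koff + kdeg) * theta
#' (degradation removes bound protein; the free concentration C is the
#' externally maintained steady-state level), the steady-state
#' half-occupancy concentration is `(koff + kdeg) / kon`. With `kdeg = 0`
#' this reduces to the equilibrium Kd `koff / kon`.
#'
#' @param rates a [kinetic_rates()]
#' @return apparent Kd, nM
#' @export
apparent_kd_with_degradation <- function(rates) {
  if (!inherits(rates, "kinetic_rates"))
    stop("`rates` must be a kinetic_rates object")
  (rates$koff + rates$kdeg) / rates$kon
}

#' Fold-increase of the apparent Kd due to degradation
#'
#' `1 + kdeg / koff`: the ratio of the apparent Kd with degradation to the
#' equilibrium Kd. At `koff = 1e-4 s^-1` and `kdeg = 9.6e-4 s^-1` (the
#' slow-dissociation end with a 12-min half-life) the increase is ~10.6x.
#'
#' @param koff dissociation rate, s^-1 (> 0)
#' @param kdeg degradation rate, s^-1 (>= 0)
#' @return dimensionless fold-increase
#' @export
degradation_fold <- function(koff, kdeg) {
  if (!is.numeric(koff) || any(koff <= 0)) stop("`koff` must be positive")
  if (any(kdeg < 0)) stop("`kdeg` must be non-negative")
  1 + kdeg / koff
}

#' Equilibrium Kd from rates
#'
#' `Kd = koff / kon` in nM when `kon` is in per-(nM s) and `koff` in per-s.
#'
#' @param kon association rate, nM^-1 s^-1 (> 0)
#' @param koff dissociation rate, s^-1
#' @return Kd, nM
#' @export
kd_from_rates <- function(kon, koff) {
  if (!is.numeric(kon) || any(kon <= 0)) stop("`kon` must be positive")
  koff / kon
}

#' Dissociation rate from a mean bound dwell time
#'
#' `koff = 1 / t_off`. A 9.3-minute dwell time gives 0.0018 s^-1 (2 s.f.).
#'
#' @param t_off mean dwell time in the bound state, s (> 0)
#' @return dissociation rate, s^-1
#' @export
koff_from_dwell <- function(t_off) {
  if (!is.numeric(t_off) || any(t_off <= 0)) stop("`t_off` must be positive")
  1 / t_off
}

#' Association-rate unit conversions
#'
#' Exact conversions between the molar convention (M^-1 s^-1, the usual
#' literature unit for diffusion-limited rates, 1e7-1e8 M^-1 s^-1) and the
#' per-(nM s) convention used throughout this package:
#' 1 nM^-1 s^-1 = 1e9 M^-1 s^-1.
#'
#' @param kon_molar rate in M^-1 s^-1
#' @param kon rate in nM^-1 s^-1
#' @return the converted rate
#' @export
kon_from_molar <- function(kon_molar) kon_molar * 1e-9

#' @rdname kon_from_molar
#' @export
kon_to_molar <- function(kon) kon * 1e9

#' Concentration of competitive genomic DNA
#'
#' Treats each base pair of the accessible fraction of the genome as one
#' non-specific binding site and converts the site count in the nuclear
#' volume to a concentration. With a 12.1 Mbp genome, 50% competitive
#' fraction and a 3.0 um^3 nucleus this is about 3.3 mM.
#'
#' @param genome_bp genome size, base pairs
#' @param competitive_fraction fraction of the genome acting as competitor,
#'   in `[0, 1]` (nucleosome-free and otherwise accessible DNA)
#' @param nuclear_volume nuclear volume, um^3
#' @return concentration of non-specific sites, nM
#' @export
gdna_concentration <- function(genome_bp = 12.1e6,
                               competitive_fraction = 0.5,
                               nuclear_volume = 3.0) {
  if (genome_bp <= 0 || nuclear_volume <= 0)
    stop("`genome_bp` and `nuclear_volume` must be positive")
  if (competitive_fraction < 0 || competitive_fraction > 1)
    stop("`competitive_fraction` must be in [0, 1]")
  density <- genome_bp * competitive_fraction / nuclear_volume
  density / molecules_per_um3_per_nM
}

#' Non-specific competition model
#'
#' Parameters of the two-site competition scheme: a specific site with
#' dissociation constant `kd_s`, an excess of non-specific genomic sites
#' with `kd_n = kd_s / kd_ratio` at concentration `gdna`. The measured
#' free pool is the diffusive protein plus the part transiently bound to
#' non-specific DNA, which inflates the apparent Kd to
#' `kd_s * (1 + gdna / kd_n) = kd_s + kd_ratio * gdna`.
#'
#' @param kd_s specific-site dissociation constant, nM (> 0)
#' @param kd_ratio `kd_s / kd_n`, in (0, 1) (2.5e-7 for the lac repressor)
#' @param gdna concentration of competitive genomic DNA, nM (>= 0)
#' @return a list of class `"competition_model"` (with derived `kd_n`)
#' @export
competition_model <- function(kd_s, kd_ratio, gdna) {
  if (kd_s <= 0) stop("`kd_s` must be positive")
  if (kd_ratio <= 0 || kd_ratio >= 1) stop("`kd_ratio` must be in (0, 1)")
  if (gdna < 0) stop("`gdna` must be non-negative")
  structure(list(kd_s = kd_s, kd_ratio = kd_ratio, gdna = gdna,
                 kd_n = kd_s / kd_ratio),
            class = "competition_model")
}

#' Apparent Kd under non-specific competition
#'
#' Forward map: `kd_apparent = kd_s * (1 + gdna / kd_n)`, algebraically
#' `kd_s + kd_ratio * gdna`. The additive term `kd_ratio * gdna` is the
#' competition floor: no specific site can show an apparent Kd below it.
#'
#' @param model a [competition_model()]
#' @return apparent Kd, nM
#' @export
apparent_kd_competition <- function(model) {
  if (!inherits(model, "competition_model"))
    stop("`model` must be a competition_model")
  model$kd_s * (1 + model$gdna / model$kd_n)
}

#' Specific-site Kd from an apparent Kd
#'
#' Inverse of [apparent_kd_competition()]:
#' `kd_s = kd_apparent - kd_ratio * gdna`. Errors if the apparent Kd lies
#' at or below the competition floor.
#'
#' @param kd_apparent measured apparent Kd, nM
#' @param kd_ratio `kd_s / kd_n`
#' @param gdna competitive genomic DNA concentration, nM
#' @return specific-site Kd, nM
#' @export
specific_from_apparent <- function(kd_apparent, kd_ratio, gdna) {
  kd_s <- kd_apparent - kd_ratio * gdna
  if (any(kd_s <= 0))
    stop("apparent Kd below competition floor (", kd_ratio * gdna,
         " nM): no positive specific Kd exists")
  kd_s
}
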