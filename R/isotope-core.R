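#' Site preference of N2O
#'
#' The intramolecular \eqn{^{15}}N difference between the central (alpha) and
#' outer (beta) nitrogen atom of the linear N2O molecule,
#' \eqn{SP = \delta^{15}N^\alpha - \delta^{15}N^\beta}. SP is diagnostic of
#' the production pathway: bacterial denitrification and
#' nitrifier-denitrification yield low/negative SP, while fungal
#' denitrification, chemodenitrification and hydroxylamine decomposition
#' during ammonia oxidation yield high SP.
#'
#' @param d15n_alpha delta-15N of the central (alpha) N, permil vs air-N2.
#' @param d15n_beta delta-15N of the outer (beta) N, permil vs air-N2.
#' @return Site preference in permil. Vectorised.
#' @examples
#' site_preference(10, 4)
#' @export
site_preference <- function(d15n_alpha, d15n_beta) {
  check_finite(d15n_alpha, "d15n_alpha")
  check_finite(d15n_beta, "d15n_beta")
  d15n_alpha - d15n_beta
}

#' Recover alpha/beta delta-15N from bulk and site preference
#'
#' Inverts the definitions \eqn{\delta^{15}N^{bulk} = (\alpha + \beta)/2} and
#' \eqn{SP = \alpha - \beta}.
#'
#' @param d15n_bulk bulk delta-15N of N2O, permil.
#' @param sp site preference, permil.
#' @return A tibble with columns `d15n_alpha` and `d15n_beta`.
#' @examples
#' d15n_alpha_beta(-0.7, -5.3)
#' @export
d15n_alpha_beta <- function(d15n_bulk, sp) {
  check_finite(d15n_bulk, "d15n_bulk")
  check_finite(sp, "sp")
  tibble::tibble(d15n_alpha = d15n_bulk + sp / 2,
                 d15n_beta  = d15n_bulk - sp / 2)
}

#' 17O-excess (cap-delta-17O)
#'
#' Deviation of delta-17O from the mass-dependent relation with delta-18O.
#' Mass-dependent (kinetic or equilibrium) fractionation changes delta-17O
#' about half as much as delta-18O, so cap-delta-17O is conserved through such
#' processes and is diluted only by incorporation of O atoms carrying
#' cap-delta-17O near 0 (O2, H2O). Two conventions are supported: the linear
#' form \eqn{\Delta^{17}O = \delta^{17}O - \lambda\,\delta^{18}O} (the
#' dominant convention in nitrate work, the default) and the logarithmic form
#' \eqn{\Delta^{17}O = 1000\,[(1+\delta^{17}O/1000)/(1+\delta^{18}O/1000)^{\lambda} - 1]}.
#'
#' @param d17o delta-17O, permil vs VSMOW.
#' @param d18o delta-18O, permil vs VSMOW.
#' @param lambda mass-dependent slope, dimensionless; must lie in (0.5, 0.535].
#' @param form `"linear"` (default) or `"logarithmic"`.
#' @return cap-delta-17O in permil. Vectorised over `d17o`/`d18o`.
#' @examples
#' cap_delta_17o(10, 10)            # 10 - 0.52 * 10 = 4.8
#' cap_delta_17o(5.2, 10)           # on the mass-dependent line: 0
#' @export
cap_delta_17o <- function(d17o, d18o, lambda = 0.52, form = c("linear", "logarithmic")) {
  form <- match.arg(form)
  check_finite(d17o, "d17o")
  check_finite(d18o, "d18o")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0.5 || lambda > 0.535) {
    stop_invalid("`lambda` must be a single value in (0.5, 0.535].",
                 class = "n2osource_config_error")
  }
  if (form == "linear") {
    d17o - lambda * d18o
  } else {
    1000 * ((1 + d17o / 1000) / (1 + d18o / 1000)^lambda - 1)
  }
}

#' Conservative mixing of pools
#'
#' Concentration-weighted mean of a tracer value across pools, e.g. mixing a
#' 17O-anomalous nitrate amendment into background seawater nitrate.
#'
#' @param concentration pool concentrations, micromolar; all non-negative with
#'   positive total.
#' @param value tracer values (permil) of the same length.
#' @return The mixed tracer value, permil.
#' @examples
#' mix_pools(c(120, 20), c(18.5, 0))
#' @export
mix_pools <- function(concentration, value) {
  check_finite(concentration, "concentration")
  check_finite(value, "value")
  if (length(concentration) != length(value)) {
    stop_invalid("`concentration` and `value` must have equal length.")
  }
  if (any(concentration < 0)) {
    stop_invalid("pool concentrations must be non-negative.")
  }
  total <- sum(concentration)
  if (total <= 0) {
    stop_invalid("total concentration must be positive.",
                 class = "n2osource_degenerate_input")
  }
  sum(concentration * value) / total
}

#' Fraction of N2O oxygen derived from a 17O-anomalous precursor
#'
#' Because cap-delta-17O passes unchanged through mass-dependent
#' fractionation, the ratio of the N2O anomaly to the precursor (NO3- or
#' NO2-) anomaly measures the fraction of N2O O atoms that originally derive
#' from that precursor pool. The ratio is returned unclamped; values outside
#' \[0, 1\] indicate mass-balance violation and are left to the caller.
#'
#' @param cap17o_n2o cap-delta-17O of N2O, permil.
#' @param cap17o_precursor cap-delta-17O of the precursor pool, permil; its
#'   magnitude must exceed `floor` for the ratio to be informative.
#' @param floor minimum precursor anomaly magnitude, permil (default 1).
#' @return The precursor fraction (dimensionless). Vectorised.
#' @examples
#' precursor_fraction(6.5, 8.5)
#' @export
precursor_fraction <- function(cap17o_n2o, cap17o_precursor, floor = 1) {
  check_finite(cap17o_n2o, "cap17o_n2o")
  check_finite(cap17o_precursor, "cap17o_precursor")
  check_number(floor, "floor", min = 0)
  if (any(abs(cap17o_precursor) < floor)) {
    abort(sprintf(
      "precursor cap-delta-17O magnitude below the informative floor (%.3g permil).",
      floor), class = c("n2osource_uninformative_tracer", "n2osource_error"))
  }
  cap17o_n2o / cap17o_precursor
}

#' delta-15N of total reduced nitrogen by mass balance
#'
#' Removes the molar contribution of NO3- and NO2- from the total dissolved
#' nitrogen (TDN) pool to recover the delta-15N of the reduced remainder
#' (TRN = NH4+ + dissolved organic N), which serves as a proxy for the
#' delta-15N of the ammonium substrate of nitrification.
#'
#' @param conc_tdn,d15n_tdn TDN concentration (micromolar) and delta-15N (permil).
#' @param conc_no3,d15n_no3 NO3- concentration and delta-15N.
#' @param conc_no2,d15n_no2 NO2- concentration and delta-15N.
#' @return delta-15N of TRN, permil. Vectorised.
#' @examples
#' trn_d15n(100, 10, 50, 5, 10, 0)
#' @export
trn_d15n <- function(conc_tdn, d15n_tdn, conc_no3, d15n_no3, conc_no2, d15n_no2) {
  check_finite(conc_tdn, "conc_tdn"); check_finite(d15n_tdn, "d15n_tdn")
  check_finite(conc_no3, "conc_no3"); check_finite(d15n_no3, "d15n_no3")
  check_finite(conc_no2, "conc_no2"); check_finite(d15n_no2, "d15n_no2")
  conc_trn <- conc_tdn - conc_no3 - conc_no2
  if (any(conc_trn <= 0)) {
    abort("TRN concentration ([TDN] - [NO3] - [NO2]) must be positive.",
          class = c("n2osource_degenerate_input", "n2osource_error"))
  }
  (d15n_tdn * conc_tdn - d15n_no3 * conc_no3 - d15n_no2 * conc_no2) / conc_trn
}
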