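#' Effective shear rate in the oscillating channel
#'
#' Order-of-magnitude flow-strength estimate from the mean cell velocity and
#' the average channel width: gamma_eff = 2 v / w. With the measured
#' v = 5.1 mm/s and w_av = (10 + 20)/2 = 15 um this gives 680 1/s.
#'
#' @param vRbcMmPerS mean cell velocity (mm/s, > 0 unless exactly 0)
#' @param wAvUm average channel width (um, > 0)
#' @return effective shear rate (1/s)
#' @examples
#' effectiveShearRate(5.1, 15)  # 680
#' @export
effectiveShearRate <- function(vRbcMmPerS, wAvUm) {
  stopifnot(vRbcMmPerS >= 0, wAvUm > 0)
  2 * (vRbcMmPerS * 1e-3) / (wAvUm * 1e-6)
}

#' Effective shear stress
#'
#' tau_eff = eta * gamma_eff; with eta = 1.5 mPa s and gamma_eff = 680 1/s
#' this gives 1.02 Pa (1.0 Pa at two significant figures).
#'
#' @param etaMPaS suspension viscosity (mPa s)
#' @param gammaEffPerS effective shear rate (1/s)
#' @return effective shear stress (Pa)
#' @examples
#' effectiveShearStress(1.5, effectiveShearRate(5.1, 15))
#' @export
effectiveShearStress <- function(etaMPaS, gammaEffPerS) {
  stopifnot(etaMPaS >= 0, gammaEffPerS >= 0)
  (etaMPaS * 1e-3) * gammaEffPerS
}

#' Flow conditions of an experiment
#'
#' Bundles the measured flow parameters with the derived effective shear
#' rate and stress. The average width is the mean of the narrow and wide
#' channel openings.
#'
#' @param vRbcMmPerS mean cell velocity (mm/s)
#' @param narrowWidthUm,wideWidthUm channel openings (um)
#' @param etaMPaS suspension viscosity (mPa s)
#' @param pressureMbar driving pressure (mbar)
#' @param densityGPerMl suspension density (g/mL)
#' @param osmolarityMOsmPerL suspension osmolarity (mOsm/L)
#' @return a [FlowConditions-class]
#' @examples
#' flowConditions()
#' @export
flowConditions <- function(vRbcMmPerS = 5.1, narrowWidthUm = 10,
                           wideWidthUm = 20, etaMPaS = 1.5,
                           pressureMbar = 20, densityGPerMl = 1.080,
                           osmolarityMOsmPerL = 317) {
  wAv <- mean(c(narrowWidthUm, wideWidthUm))
  gamma <- effectiveShearRate(vRbcMmPerS, wAv)
  new("FlowConditions", vRbcMmPerS = vRbcMmPerS, wAvUm = wAv,
      etaMPaS = etaMPaS, gammaEffPerS = gamma,
      tauEffPa = effectiveShearStress(etaMPaS, gamma),
      pressureMbar = pressureMbar, densityGPerMl = densityGPerMl,
      osmolarityMOsmPerL = osmolarityMOsmPerL)
}
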