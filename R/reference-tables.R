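#' Reference PDL creep parameters by region
#'
#' Fitted nonlinear creep parameters (g0, g2, eta, R^2) for human PDL
#' samples from the neck, middle and apical root regions, two samples per
#' region, obtained under the normalized fitting context
#' (Etf = Em = sigma0 = 1, g1 = 1). Used as generating truth by the
#' synthetic study and for parameter-recovery round trips.
#'
#' @format A data.frame with 6 rows and columns `sample` (e.g. "neck_1"),
#'   `region`, `g0`, `g2` (negative in the creep regime), `eta` (MPa s under
#'   the normalized context) and `r_squared`.
#' @export
pdl_creep_parameters <- data.frame(
  sample = c("neck_1", "neck_2", "middle_1", "middle_2", "apex_1", "apex_2"),
  region = c("neck", "neck", "middle", "middle", "apex", "apex"),
  g0  = c(0.0049, 0.0057, 0.0030, 0.0034, 0.0081, 0.0098),
  g2  = c(-0.0096, -0.0118, -0.0060, -0.0082, -0.0124, -0.0242),
  eta = c(260.8893, 289.5958, 264.3402, 254.2570, 370.6347, 191.9794),
  r_squared = c(0.995, 0.997, 0.9985, 0.995, 0.996, 0.993),
  stringsAsFactors = FALSE)

#' Reference per-slice collagen fiber content by region
#'
#' Measured collagen volume fractions (percent) for five Masson-stained
#' slices in each root region of human PDL. Used as per-slice targets by the
#' synthetic image generator and as fixture input for region averaging.
#'
#' @format A data.frame with 15 rows and columns `region`, `slice` (1-5) and
#'   `vf` (percent).
#' @export
pdl_fiber_content <- data.frame(
  region = rep(c("apex", "middle", "neck"), each = 5L),
  slice = rep(1:5, times = 3L),
  vf = c(62.198, 59.01, 41.2, 51.417, 46.116,
         58.249, 65.771, 65.65, 61.369, 64.669,
         60.007, 51.991, 53.889, 67.895, 67.78),
  stringsAsFactors = FALSE)

#' Reference reduced elastic moduli by region and plane
#'
#' Flat-punch Oliver-Pharr reduced moduli (MPa) of human PDL per root
#' region and sectioning plane. These depend on specimen thicknesses not
#' derivable from synthetic data; they are provided for reporting context
#' only.
#'
#' @format A data.frame with columns `region`, `transverse_MPa`,
#'   `longitudinal_MPa`.
#' @export
pdl_reduced_modulus <- data.frame(
  region = c("neck", "middle", "apex"),
  transverse_MPa = c(4.28, 5.08, 1.03),
  longitudinal_MPa = c(2.98, 4.79, 0.39),
  stringsAsFactors = FALSE)
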