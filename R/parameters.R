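#' Standard-linear-solid parameters for the PDL
#'
#' The periodontal ligament is modelled as a collagen fiber spring (modulus
#' `Etf`) in parallel with a Maxwell branch representing the matrix (spring
#' `Em` in series with a dashpot of viscosity `eta`). This three-element
#' solid governs the linear creep compliance returned by
#' [creep_compliance()].
#'
#' @param Etf Fiber elastic modulus, MPa. Must be positive.
#' @param Em Matrix elastic modulus, MPa. Must be positive.
#' @param eta Matrix viscosity, MPa s. Must be positive.
#' @return An object of class `"sls_parameters"`.
#' @examples
#' sls_parameters(Etf = 1, Em = 1, eta = 260.89)
#' @export
sls_parameters <- function(Etf, Em, eta) {
  for (nm in c("Etf", "Em", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  structure(list(Etf = Etf, Em = Em, eta = eta), class = "sls_parameters")
}

#' @export
print.sls_parameters <- function(x, ...) {
  cat("Standard linear solid (fiber || Maxwell matrix)\n")
  cat(sprintf("  Etf = %g MPa, Em = %g MPa, eta = %g MPa*s\n",
              x$Etf, x$Em, x$eta))
  invisible(x)
}

#' Schapery nonlinear factors
#'
#' Dimensionless factors scaling the instantaneous (`g0`), transient (`g1`)
#' and loading (`g2`) terms of the nonlinear strain response. `g0` and `g2`
#' track collagen fiber content; `g1` is determined from rebound strains
#' (see [g1_from_strains()]) and equals 1 when the tissue fully rebounds.
#' Fitted `g2` values for creeping PDL are negative.
#'
#' @param g0 Instantaneous factor, dimensionless and finite.
#' @param g2 Loading factor, dimensionless and finite; may be negative.
#' @param g1 Transient factor, must be non-negative. Default 1.
#' @return An object of class `"schapery_parameters"`.
#' @examples
#' schapery_parameters(g0 = 0.0049, g2 = -0.0096)
#' @export
schapery_parameters <- function(g0, g2, g1 = 1) {
  for (nm in c("g0", "g1", "g2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (g1 < 0) stop("'g1' must be non-negative", call. = FALSE)
  structure(list(g0 = g0, g1 = g1, g2 = g2), class = "schapery_parameters")
}

#' @export
print.schapery_parameters <- function(x, ...) {
  cat(sprintf("Schapery factors: g0 = %g, g1 = %g, g2 = %g\n",
              x$g0, x$g1, x$g2))
  invisible(x)
}

#' Step load applied during the hold stage
#'
#' The indentation protocol holds a constant load, so the stress history is a
#' step `sigma(t) = sigma0 * H(t)`. The step stress can be given directly in
#' MPa, or derived from the held force and the effective contact area as
#' `sigma0 = F / S` (a flat cylindrical punch of radius R has S = pi R^2).
#'
#' @param sigma0 Step stress, MPa. Either this or both `F_mN` and `S_mm2`.
#' @param F_mN Held force, mN.
#' @param S_mm2 Effective section area, mm^2.
#' @return An object of class `"step_load"` with element `sigma0` (MPa).
#' @examples
#' step_load(sigma0 = 1)
#' step_load(F_mN = 3, S_mm2 = pi * 0.1^2)  # 3 mN flat punch, R = 100 um
#' @export
step_load <- function(sigma0 = NULL, F_mN = NULL, S_mm2 = NULL) {
  if (is.null(sigma0)) {
    if (is.null(F_mN) || is.null(S_mm2))
      stop("supply 'sigma0' or both 'F_mN' and 'S_mm2'", call. = FALSE)
    sigma0 <- stress_from_load(F_mN, S_mm2) / 1000  # kPa -> MPa
  }
  if (!is.numeric(sigma0) || length(sigma0) != 1L || !is.finite(sigma0) ||
      sigma0 < 0)
    stop("'sigma0' must be a single non-negative finite number", call. = FALSE)
  structure(list(sigma0 = sigma0), class = "step_load")
}

#' Step stress from force and effective area
#'
#' `sigma0 = F / S`. With force in mN and area in mm^2 the result is in kPa
#' (1 mN / mm^2 = 1 kPa).
#'
#' @param F_mN Force, mN (non-negative).
#' @param S_mm2 Effective section area, mm^2 (positive).
#' @return Stress in kPa.
#' @examples
#' stress_from_load(3, pi * 0.1^2)  # ~95.5 kPa under the 3 mN peak load
#' @export
stress_from_load <- function(F_mN, S_mm2) {
  if (!is.numeric(S_mm2) || any(!is.finite(S_mm2)) || any(S_mm2 <= 0))
    stop("'S_mm2' must be positive and finite", call. = FALSE)
  if (!is.numeric(F_mN) || any(!is.finite(F_mN)) || any(F_mN < 0))
    stop("'F_mN' must be non-negative and finite", call. = FALSE)
  F_mN / S_mm2
}

#' Transient factor g1 from creep and rebound strains
#'
#' `g1 = (d_eps_c - eps_p) / (d_eps_c - eps0 - eps_p)` with
#' `eps0 = eps_b0 - eps_r0`, where `d_eps_c` is the creep deformation,
#' `eps_p` the plastic deformation, `eps_b0` the unloading rebound and
#' `eps_r0` the loading elastic deformation. When the tissue rebounds fully
#' (`eps_b0 == eps_r0`, so `eps0 = 0`) this reduces to `g1 = 1`, the value
#' used for PDL below its fiber damage threshold.
#'
#' @param delta_eps_c Creep deformation (strain).
#' @param eps_p Plastic deformation (strain).
#' @param eps_b0 Unloading rebound deformation (strain).
#' @param eps_r0 Loading elastic deformation (strain).
#' @return `g1`, dimensionless.
#' @examples
#' g1_from_strains(0.01, 0, 0.005, 0.005)  # full rebound -> 1
#' @export
g1_from_strains <- function(delta_eps_c, eps_p, eps_b0, eps_r0) {
  eps0 <- eps_b0 - eps_r0
  den <- delta_eps_c - eps0 - eps_p
  if (abs(den) < .Machine$double.eps * max(1, abs(delta_eps_c)))
    stop("degenerate strains: denominator (d_eps_c - eps0 - eps_p) is zero",
         call. = FALSE)
  (delta_eps_c - eps_p) / den
}
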