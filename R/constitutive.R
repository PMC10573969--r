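#' Creep compliance of the fiber-matrix standard linear solid
#'
#' Closed-form creep compliance of the three-element solid: a fiber spring
#' `Etf` in parallel with a Maxwell matrix branch (`Em` in series with dashpot
#' `eta`). Under a unit step stress the strain is governed by
#' \deqn{D(t) = 1/E_{tf} - \frac{E_m}{E_{tf}(E_{tf}+E_m)}
#'   \exp\!\left(-\frac{E_{tf} E_m\, t}{\eta (E_{tf}+E_m)}\right).}
#' It starts at the glassy value `1/(Etf+Em)` (both springs carry load),
#' increases monotonically as the dashpot relaxes the matrix branch, and
#' approaches the equilibrium `1/Etf` (fiber spring alone).
#'
#' @param sls An [sls_parameters()] object.
#' @param t Time(s) in seconds, non-negative; vectorized.
#' @return Compliance `D(t)` in 1/MPa, same length as `t`.
#' @examples
#' sls <- sls_parameters(1, 1, 1)
#' creep_compliance(sls, 0)    # 0.5 = 1/(Etf+Em)
#' creep_compliance(sls, 1e6)  # -> 1 = 1/Etf
#' @seealso [kelvin_voigt_from_sls()], [strain_response()]
#' @export
creep_compliance <- function(sls, t) {
  stopifnot(inherits(sls, "sls_parameters"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  Etf <- sls$Etf; Em <- sls$Em; eta <- sls$eta
  rate <- Etf * Em / (eta * (Etf + Em))
  1 / Etf - (Em / (Etf * (Etf + Em))) * exp(-rate * t)
}

#' Generalized Kelvin-Voigt reparameterization
#'
#' Matches a first-order generalized Kelvin-Voigt compliance
#' `D'(t) = D0' + D1'(1 - exp(-t/tau1))` to the fiber-matrix solid:
#' \deqn{D_0' = \frac{2E_m + E_{tf}}{E_{tf}(E_{tf}+E_m)},\qquad
#'       D_1' = -\frac{E_m}{E_{tf}(E_{tf}+E_m)},\qquad
#'       \tau_1 = \frac{\eta (E_{tf}+E_m)}{E_{tf} E_m}.}
#' The identity `D0' + D1' = 1/Etf` (equilibrium consistency) holds exactly,
#' and `tau1` equals the exponential timescale of [creep_compliance()].
#' Note that this `D0'` is *not* the instantaneous SLS compliance
#' `1/(Etf+Em)`; the nonlinear strain response ([strain_response()]) is
#' defined in terms of this reparameterization, and the fitted Schapery
#' factors absorb the offset. See the package vignette.
#'
#' @param sls An [sls_parameters()] object.
#' @return An object of class `"kelvin_voigt_parameters"`: list with `D0p`,
#'   `D1p` (1/MPa) and `tau1` (s, positive by convention).
#' @examples
#' kelvin_voigt_from_sls(sls_parameters(1, 1, 1))  # D0p 1.5, D1p -0.5, tau1 2
#' @export
kelvin_voigt_from_sls <- function(sls) {
  stopifnot(inherits(sls, "sls_parameters"))
  Etf <- sls$Etf; Em <- sls$Em; eta <- sls$eta
  structure(list(
    D0p  = (2 * Em + Etf) / (Etf * (Etf + Em)),
    D1p  = -Em / (Etf * (Etf + Em)),
    tau1 = eta * (Etf + Em) / (Etf * Em)
  ), class = "kelvin_voigt_parameters")
}

#' @export
print.kelvin_voigt_parameters <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt compliance: D0' = %g 1/MPa, D1' = %g 1/MPa, tau1 = %g s\n",
              x$D0p, x$D1p, x$tau1))
  invisible(x)
}

#' Nonlinear (Schapery-form) strain response under a step load
#'
#' Hold-stage strain of the PDL under a step stress `sigma0`:
#' \deqn{\varepsilon(t) = g_0 D_0' \sigma_0 -
#'   g_1 g_2 |D_1'| \left(1 - e^{-t/\tau_1}\right) \sigma_0,}
#' with `D0'`, `D1'`, `tau1` from [kelvin_voigt_from_sls()]. For the fitted
#' creep regime (`g1 > 0`, `g2 < 0`) the strain is non-decreasing from
#' `g0 * D0' * sigma0` towards `g0*D0'*sigma0 + g1*|g2|*|D1'|*sigma0`.
#'
#' With `g0 = g1 = 1`, `g2 = -1` the response is `sigma0 * (D0' + |D1'|(1 -
#' exp(-t/tau1)))`, whose long-time value `(3Em+Etf)/(Etf(Etf+Em))` exceeds
#' the linear-solid equilibrium compliance `1/Etf`: a consequence of the sign
#' structure of the nonlinear form, documented rather than "fixed" because
#' the fitted parameter tables presuppose it.
#'
#' @param sch A [schapery_parameters()] object.
#' @param sls An [sls_parameters()] object.
#' @param load A [step_load()] object.
#' @param t Time(s) since hold onset, seconds, non-negative; vectorized.
#' @return Strain (dimensionless), same length as `t`.
#' @examples
#' sch <- schapery_parameters(g0 = 0.0049, g2 = -0.0096)
#' sls <- sls_parameters(1, 1, 260.8893)
#' strain_response(sch, sls, step_load(sigma0 = 1), c(0, 100, 200))
#' @export
strain_response <- function(sch, sls, load, t) {
  stopifnot(inherits(sch, "schapery_parameters"),
            inherits(sls, "sls_parameters"),
            inherits(load, "step_load"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  kv <- kelvin_voigt_from_sls(sls)
  s0 <- load$sigma0
  sch$g0 * kv$D0p * s0 -
    sch$g1 * sch$g2 * abs(kv$D1p) * (1 - exp(-t / kv$tau1)) * s0
}

#' Identifiable reduced parameterization of the strain response
#'
#' A single hold-stage curve identifies only three quantities of the
#' nonlinear response: `eps(t) = A + B (1 - exp(-t/tau))` with
#' `A = g0 * D0' * sigma0` (instantaneous strain), `B = -g1 * g2 * |D1'| *
#' sigma0` (transient amplitude) and `tau = tau1` (retardation time). For
#' fixed `(Etf, Em, sigma0, g1)` the map `(g0, g2, eta) -> (A, B, tau)` is a
#' bijection; [schapery_from_reduced()] inverts it. Fitting is performed in
#' this reduced space.
#'
#' @param sch,sls,load As in [strain_response()].
#' @return An object of class `"reduced_creep_parameters"`: list with `A`,
#'   `B` (strain) and `tau` (s).
#' @examples
#' red <- reduced_from_full(schapery_parameters(1, -1),
#'                          sls_parameters(1, 1, 2), step_load(sigma0 = 1))
#' red$A  # 1.5
#' @export
reduced_from_full <- function(sch, sls, load) {
  stopifnot(inherits(sch, "schapery_parameters"),
            inherits(sls, "sls_parameters"),
            inherits(load, "step_load"))
  kv <- kelvin_voigt_from_sls(sls)
  structure(list(
    A   = sch$g0 * kv$D0p * load$sigma0,
    B   = -sch$g1 * sch$g2 * abs(kv$D1p) * load$sigma0,
    tau = kv$tau1
  ), class = "reduced_creep_parameters")
}

#' Invert the reduced parameterization
#'
#' Maps reduced creep parameters `(A, B, tau)` back to `(g0, g2, eta)` for a
#' fixed context `(Etf, Em, sigma0, g1)`.
#'
#' @param red A `"reduced_creep_parameters"` object or list with `A`, `B`,
#'   `tau`.
#' @param sls An [sls_parameters()] object giving `Etf`, `Em` (the `eta` slot
#'   is ignored; `eta` is recovered from `tau`).
#' @param load A [step_load()] object.
#' @param g1 Fixed transient factor; must be positive unless `B` is 0.
#' @return A list with `g0`, `g2`, `eta`.
#' @examples
#' sls <- sls_parameters(1, 1, 1); ld <- step_load(sigma0 = 1)
#' schapery_from_reduced(list(A = 1.5, B = 0.5, tau = 4), sls, ld)
#' @export
schapery_from_reduced <- function(red, sls, load, g1 = 1) {
  stopifnot(inherits(sls, "sls_parameters"), inherits(load, "step_load"))
  A <- red$A; B <- red$B; tau <- red$tau
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (load$sigma0 <= 0) stop("'sigma0' must be positive to invert", call. = FALSE)
  kv <- kelvin_voigt_from_sls(sls)
  if (g1 == 0 && B != 0)
    stop("cannot invert: g1 = 0 but transient amplitude B != 0", call. = FALSE)
  g2 <- if (B == 0) 0 else -B / (g1 * abs(kv$D1p) * load$sigma0)
  list(
    g0  = A / (kv$D0p * load$sigma0),
    g2  = g2,
    eta = tau * sls$Etf * sls$Em / (sls$Etf + sls$Em)
  )
}
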