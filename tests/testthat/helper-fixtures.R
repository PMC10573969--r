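# Shared fixtures: hold-stage curves generated from the built-in regional
# parameter table under the normalized fitting context.

norm_sls <- function(eta) sls_parameters(Etf = 1, Em = 1, eta = eta)
unit_load <- step_load(sigma0 = 1)

# curve from one row of pdl_creep_parameters (201 points, 0..200 s default)
table_curve <- function(row, n = 201L, t_end = 200, noise_sd = 0,
                        seed = NULL) {
  p <- pdl_creep_parameters[row, ]
  tt <- seq(0, t_end, length.out = n)
  eps <- strain_response(schapery_parameters(p$g0, p$g2), norm_sls(p$eta),
                         unit_load, tt)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    eps <- eps + rnorm(n, 0, noise_sd)
  }
  creep_curve(tt, eps, sample_id = p$sample, region = p$region)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# observed strain range (max - min) of the noiseless hold curve for a row
table_range <- function(row, n = 201L, t_end = 200) {
  diff(range(table_curve(row, n = n, t_end = t_end)$strain))
}

# numerical ODE oracle for the fiber-matrix solid under unit step stress:
# d(eps)/dt = Em (1 - Etf*eps) / (eta (Em + Etf)), eps(0) = 1/(Etf+Em)
ode_compliance <- function(sls, times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  rhs <- function(t, y, parms)
    list(parms$Em * (1 - parms$Etf * y) / (parms$eta * (parms$Em + parms$Etf)))
  out <- deSolve::lsoda(
    y = 1 / (sls$Etf + sls$Em), times = times, func = rhs,
    parms = list(Etf = sls$Etf, Em = sls$Em, eta = sls$eta),
    rtol = 1e-11, atol = 1e-13)
  out[, 2L]
}
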