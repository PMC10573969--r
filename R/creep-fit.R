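#' Hold-stage creep curve
#'
#' Container for a strain-time series recorded during the constant-load hold
#' stage of a nano-indentation test. Time is the hold-stage clock (t = 0 at
#' hold onset).
#'
#' @param time_s Strictly increasing time vector, s, first value >= 0.
#' @param strain Dimensionless strain, same length as `time_s` (>= 4 points).
#' @param sample_id Optional sample identifier.
#' @param region One of `"neck"`, `"middle"`, `"apex"` or `NA`.
#' @param plane One of `"transverse"`, `"longitudinal"` or `NA`.
#' @return An object of class `"creep_curve"` (a data.frame with columns
#'   `time_s`, `strain` and metadata attributes).
#' @examples
#' creep_curve(0:10, 0.01 + 0.001 * (1 - exp(-(0:10) / 3)))
#' @export
creep_curve <- function(time_s, strain, sample_id = NA_character_,
                        region = NA_character_, plane = NA_character_) {
  if (!is.numeric(time_s) || !is.numeric(strain))
    stop("'time_s' and 'strain' must be numeric", call. = FALSE)
  if (length(time_s) != length(strain))
    stop("'time_s' and 'strain' must have equal length", call. = FALSE)
  if (length(time_s) < 4L)
    stop("a creep curve needs at least 4 points", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(strain)))
    stop("times and strains must be finite", call. = FALSE)
  if (time_s[1L] < 0 || any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing with t[1] >= 0", call. = FALSE)
  if (!is.na(region) && !region %in% c("neck", "middle", "apex"))
    stop("'region' must be one of neck/middle/apex", call. = FALSE)
  if (!is.na(plane) && !plane %in% c("transverse", "longitudinal"))
    stop("'plane' must be transverse or longitudinal", call. = FALSE)
  structure(
    data.frame(time_s = as.numeric(time_s), strain = as.numeric(strain)),
    sample_id = as.character(sample_id), region = as.character(region),
    plane = as.character(plane),
    class = c("creep_curve", "data.frame"))
}

#' Fixed context for creep fitting
#'
#' The moduli `Etf`, `Em`, the step stress `sigma0` and the transient factor
#' `g1` are not identifiable from a single hold-stage curve and are held
#' fixed during fitting. The default normalization `Etf = Em = sigma0 = 1`,
#' `g1 = 1` makes the recovered `(g0, g2, eta)` directly comparable to
#' published parameter tables obtained under the same convention; measured
#' values may be substituted when available.
#'
#' @param Etf,Em Fixed moduli, MPa.
#' @param sigma0 Fixed step stress, MPa.
#' @param g1 Fixed transient factor (1 for fully rebounding tissue).
#' @return An object of class `"creep_context"`.
#' @export
creep_context <- function(Etf = 1, Em = 1, sigma0 = 1, g1 = 1) {
  sls <- sls_parameters(Etf, Em, eta = 1)  # eta placeholder; fitted later
  ld <- step_load(sigma0 = sigma0)
  if (!is.numeric(g1) || length(g1) != 1L || !is.finite(g1) || g1 < 0)
    stop("'g1' must be a single non-negative number", call. = FALSE)
  structure(list(sls = sls, load = ld, g1 = g1), class = "creep_context")
}

#' Fit the nonlinear creep model to a hold-stage strain-time curve
#'
#' Recovers the viscoelastic parameters `(g0, g2, eta)` by least-squares
#' fitting of the step-load strain response
#' `eps(t) = g0 D0' sigma0 - g1 g2 |D1'| (1 - exp(-t/tau1)) sigma0`
#' to an observed hold-stage curve. The optimizer works in the identifiable
#' reduced space `(A, B, tau)` (see [reduced_from_full()]) using bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm]), then maps back via
#' [schapery_from_reduced()]. Initial guesses: `A = eps[1]`,
#' `B = eps[n] - eps[1]`, `tau = span/3`.
#'
#' A flat curve (zero strain variance) has no transient: `g2` is reported as
#' 0, `g0` from the mean level, `eta` and `r_squared` as `NA`.
#' Non-convergence is flagged (`converged = FALSE`), not raised. Fits with
#' negative transient amplitude (strain decreasing, outside the creep
#' regime) are allowed but flagged via `creep_regime = FALSE`.
#'
#' @param curve A [creep_curve()], or a data.frame with columns `time_s` and
#'   `strain`.
#' @param context A [creep_context()]; default normalized context.
#' @param control List overriding optimizer settings: `maxiter` (default
#'   1000) and `ftol` (cost tolerance, default 1e-10).
#' @return An object of class `"creep_fit"` with components `g0`, `g2`,
#'   `eta`, `r_squared`, `converged`, `creep_regime`, `reduced` (the fitted
#'   `(A, B, tau)`), `fixed_context`, `curve`, `fitted_values`, `residuals`.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot` and `simulate`.
#' @examples
#' ctx <- creep_context()
#' tt <- seq(0, 200, by = 1)
#' eps <- strain_response(schapery_parameters(0.0049, -0.0096),
#'                        sls_parameters(1, 1, 260.8893),
#'                        step_load(sigma0 = 1), tt)
#' fit <- fit_creep(creep_curve(tt, eps), ctx)
#' coef(fit)  # recovers g0, g2, eta
#' @export
fit_creep <- function(curve, context = creep_context(), control = list()) {
  if (!inherits(curve, "creep_curve")) {
    if (is.data.frame(curve) && all(c("time_s", "strain") %in% names(curve)))
      curve <- creep_curve(curve$time_s, curve$strain,
                           sample_id = if ("sample_id" %in% names(curve))
                             as.character(curve$sample_id[1L]) else NA_character_,
                           region = if ("region" %in% names(curve))
                             as.character(curve$region[1L]) else NA_character_,
                           plane = if ("plane" %in% names(curve))
                             as.character(curve$plane[1L]) else NA_character_)
    else stop("'curve' must be a creep_curve or a data.frame with time_s/strain",
              call. = FALSE)
  }
  stopifnot(inherits(context, "creep_context"))
  ctrl <- utils::modifyList(list(maxiter = 1000L, ftol = 1e-10), control)

  tt <- curve$time_s - curve$time_s[1L]  # re-zero hold clock
  eps <- curve$strain
  n <- length(tt)
  span <- tt[n]

  out <- list(curve = curve, fixed_context = context,
              optimizer = "levenberg-marquardt (reduced A,B,tau space)")
  class(out) <- "creep_fit"

  if (stats::sd(eps) == 0) {
    # no transient and no variance: level fixes g0, R^2 undefined
    kv <- kelvin_voigt_from_sls(context$sls)
    out$reduced <- list(A = eps[1L], B = 0, tau = NA_real_)
    out$g0 <- eps[1L] / (kv$D0p * context$load$sigma0)
    out$g2 <- 0
    out$eta <- NA_real_
    out$r_squared <- NA_real_
    out$converged <- TRUE
    out$creep_regime <- TRUE
    out$fitted_values <- rep(eps[1L], n)
    out$residuals <- rep(0, n)
    return(out)
  }

  model <- function(p, t) p[1L] + p[2L] * (1 - exp(-t / p[3L]))
  start <- c(A = eps[1L], B = eps[n] - eps[1L], tau = max(span / 3, 1e-6))
  lm_fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) eps - model(p, tt),
    lower = c(-Inf, -Inf, 1e-9),
    upper = c(Inf, Inf, 1e6 * max(span, 1)),
    control = minpack.lm::nls.lm.control(
      maxiter = ctrl$maxiter, ftol = ctrl$ftol, ptol = 1e-12))

  p <- lm_fit$par
  fitted_values <- model(p, tt)
  res <- eps - fitted_values
  ss_res <- sum(res^2)
  ss_tot <- sum((eps - mean(eps))^2)

  inv <- schapery_from_reduced(list(A = p[[1L]], B = p[[2L]], tau = p[[3L]]),
                               context$sls, context$load, g1 = context$g1)
  out$reduced <- list(A = p[[1L]], B = p[[2L]], tau = p[[3L]])
  out$g0 <- inv$g0
  out$g2 <- inv$g2
  out$eta <- inv$eta
  out$r_squared <- 1 - ss_res / ss_tot
  out$converged <- lm_fit$info %in% 1:4
  out$creep_regime <- p[[2L]] >= 0
  out$niter <- lm_fit$niter
  out$fitted_values <- fitted_values
  out$residuals <- res
  out
}

#' @export
print.creep_fit <- function(x, digits = 6, ...) {
  cat("Nonlinear viscoelastic creep fit (step-load hold stage)\n")
  meta <- attr(x$curve, "sample_id")
  if (!is.na(meta)) cat("  sample:", meta,
                        paste0("(", attr(x$curve, "region"), ", ",
                               attr(x$curve, "plane"), ")"), "\n")
  cat(sprintf("  g0 = %s, g2 = %s, eta = %s MPa*s\n",
              format(x$g0, digits = digits), format(x$g2, digits = digits),
              format(x$eta, digits = digits)))
  cat(sprintf("  R^2 = %s, converged: %s\n",
              format(x$r_squared, digits = digits), x$converged))
  if (!x$creep_regime)
    cat("  note: strain decreasing over hold (outside creep regime)\n")
  invisible(x)
}

#' @export
coef.creep_fit <- function(object, ...) {
  c(g0 = object$g0, g2 = object$g2, eta = object$eta)
}

#' @export
fitted.creep_fit <- function(object, ...) object$fitted_values

#' @export
residuals.creep_fit <- function(object, ...) object$residuals

#' Predict strain from a fitted creep model
#'
#' @param object A `"creep_fit"`.
#' @param newdata Optional data.frame with a `time_s` column (hold-stage
#'   clock, s); defaults to the fitted curve's grid.
#' @param ... Unused.
#' @return Predicted strain vector.
#' @export
predict.creep_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$curve$time_s - object$curve$time_s[1L]
        else newdata$time_s
  if (any(tt < 0)) stop("'time_s' must be non-negative", call. = FALSE)
  r <- object$reduced
  if (is.na(r$tau)) return(rep(r$A, length(tt)))
  r$A + r$B * (1 - exp(-tt / r$tau))
}

#' Simulate noisy hold-stage curves from a fitted creep model
#'
#' Draws `nsim` replicate curves on the fitted time grid with i.i.d.
#' Gaussian noise of standard deviation `noise_sd` (strain units) added to
#' the fitted response.
#'
#' @param object A `"creep_fit"`.
#' @param nsim Number of replicate curves.
#' @param seed Optional integer seed.
#' @param noise_sd Noise standard deviation in strain units; defaults to the
#'   residual standard deviation of the fit.
#' @param ... Unused.
#' @return A data.frame with one column per replicate (`sim_1`, ...),
#'   attribute `time_s`.
#' @export
simulate.creep_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  mu <- object$fitted_values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "time_s") <- object$curve$time_s
  out
}

#' @export
summary.creep_fit <- function(object, ...) {
  structure(list(fit = object,
                 rse = stats::sd(object$residuals),
                 n = nrow(object$curve)), class = "summary.creep_fit")
}

#' @export
print.summary.creep_fit <- function(x, ...) {
  print(x$fit)
  ctx <- x$fit$fixed_context
  cat(sprintf("  fixed context: Etf = %g, Em = %g MPa, sigma0 = %g MPa, g1 = %g\n",
              ctx$sls$Etf, ctx$sls$Em, ctx$load$sigma0, ctx$g1))
  cat(sprintf("  reduced parameters: A = %g, B = %g, tau = %g s\n",
              x$fit$reduced$A, x$fit$reduced$B, x$fit$reduced$tau))
  cat(sprintf("  n = %d points, residual sd = %g\n", x$n, x$rse))
  invisible(x)
}

#' Plot a fitted creep curve
#'
#' Observed hold-stage strain with the fitted model curve overlaid.
#'
#' @param x A `"creep_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.creep_fit <- function(x, ...) {
  tt <- x$curve$time_s
  graphics::plot(tt, x$curve$strain, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "hold time (s)", ylab = "strain", ...)
  graphics::lines(tt, x$fitted_values, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", legend = c("observed", "fitted"),
                   col = c("grey40", "firebrick"), pch = c(16, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Fit the creep model to a batch of curves
#'
#' Applies [fit_creep()] to each curve and returns one row per curve, in
#' input order, shaped like a published parameter table and serializable to
#' CSV.
#'
#' @param curves A list of [creep_curve()] objects (or data.frames).
#' @param context A [creep_context()].
#' @param control Optimizer control, see [fit_creep()].
#' @return A data.frame with columns `sample_id`, `region`, `plane`, `g0`,
#'   `g2`, `eta`, `r_squared`, `converged`.
#' @export
fit_all <- function(curves, context = creep_context(), control = list()) {
  if (!is.list(curves) || length(curves) == 0L)
    stop("'curves' must be a non-empty list", call. = FALSE)
  rows <- lapply(curves, function(cv) {
    f <- fit_creep(cv, context, control)
    data.frame(sample_id = attr(f$curve, "sample_id"),
               region = attr(f$curve, "region"),
               plane = attr(f$curve, "plane"),
               g0 = f$g0, g2 = f$g2, eta = f$eta,
               r_squared = f$r_squared, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read hold-stage creep curves from CSV
#'
#' Expects columns `time_s`, `strain` and optionally `sample_id`, `region`,
#' `plane`; rows are grouped into curves by `sample_id` (one curve if
#' absent).
#'
#' @param path CSV file path.
#' @return A list of [creep_curve()] objects.
#' @export
read_creep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "strain") %in% names(df)))
    stop("CSV must have columns 'time_s' and 'strain'", call. = FALSE)
  if (!"sample_id" %in% names(df)) df$sample_id <- "curve_1"
  ids <- unique(df$sample_id)
  lapply(ids, function(id) {
    d <- df[df$sample_id == id, , drop = FALSE]
    creep_curve(d$time_s, d$strain, sample_id = id,
                region = if ("region" %in% names(d)) d$region[1L] else NA_character_,
                plane = if ("plane" %in% names(d)) d$plane[1L] else NA_character_)
  })
}
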