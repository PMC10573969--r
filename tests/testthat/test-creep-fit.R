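test_that("noiseless curves from the regional parameter table round-trip", {
  ctx <- creep_context()
  for (row in seq_len(nrow(pdl_creep_parameters))) {
    p <- pdl_creep_parameters[row, ]
    fit <- fit_creep(table_curve(row), ctx)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$g0, p$g0), 1e-6)
    expect_lt(rel_err(fit$g2, p$g2), 1e-6)
    expect_lt(rel_err(fit$eta, p$eta), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("random creep parameters are recovered to 1e-5 without noise", {
  ctx <- creep_context()
  tt <- seq(0, 200, by = 1)
  set.seed(19)
  for (i in 1:15) {
    g0 <- runif(1, 0.001, 0.02); g2 <- runif(1, -0.03, -0.001)
    # tau = eta/2 under the normalized context; keep tau < 5x hold
    eta <- runif(1, 100, 500)
    eps <- strain_response(schapery_parameters(g0, g2), norm_sls(eta),
                           unit_load, tt)
    fit <- fit_creep(creep_curve(tt, eps), ctx)
    expect_lt(rel_err(fit$g0, g0), 1e-5)
    expect_lt(rel_err(fit$g2, g2), 1e-5)
    expect_lt(rel_err(fit$eta, eta), 1e-5)
  }
})

test_that("a flat curve yields g2 = 0 and undefined R^2", {
  ctx <- creep_context()
  fit <- fit_creep(creep_curve(0:10, rep(0.012, 11)), ctx)
  expect_true(fit$converged)
  expect_equal(fit$g2, 0)
  expect_equal(fit$g0, 0.012 / 1.5)  # level / (D0' sigma0)
  expect_true(is.na(fit$r_squared))
  expect_true(is.na(fit$eta))
  expect_equal(residuals(fit), rep(0, 11))
})

test_that("fit is invariant to doubling the sampling density", {
  ctx <- creep_context()
  f1 <- fit_creep(table_curve(1, n = 201L), ctx)
  f2 <- fit_creep(table_curve(1, n = 401L), ctx)
  expect_lt(rel_err(f2$g0, f1$g0), 1e-4)
  expect_lt(rel_err(f2$g2, f1$g2), 1e-4)
  expect_lt(rel_err(f2$eta, f1$eta), 1e-4)
})

test_that("1% strain-range noise keeps median recovery error below 5%", {
  ctx <- creep_context()
  p <- pdl_creep_parameters[1, ]
  strain_range <- table_range(1)  # max - min of the noiseless hold curve
  errs <- matrix(NA_real_, 40, 3)
  r2 <- numeric(40)
  for (r in 1:40) {
    fit <- fit_creep(table_curve(1, noise_sd = 0.01 * strain_range,
                                 seed = 100 + r), ctx)
    errs[r, ] <- c(rel_err(fit$g0, p$g0), rel_err(fit$g2, p$g2),
                   rel_err(fit$eta, p$eta))
    r2[r] <- fit$r_squared
  }
  expect_true(all(apply(errs, 2, median) < 0.05))
  expect_gte(median(r2), 0.99)
})

test_that("recovery error degrades monotonically with noise amplitude", {
  ctx <- creep_context()
  p <- pdl_creep_parameters[1, ]
  strain_range <- table_range(1)
  med_err <- sapply(c(0, 0.005, 0.01, 0.02), function(frac) {
    errs <- sapply(1:25, function(r) {
      fit <- fit_creep(table_curve(1, noise_sd = frac * strain_range,
                                   seed = 500 + r), ctx)
      rel_err(fit$eta, p$eta)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) >= 0))
})

test_that("fit_all produces one stable row per curve", {
  ctx <- creep_context()
  curves <- lapply(1:6, table_curve)
  tab <- fit_all(curves, ctx)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$sample_id, pdl_creep_parameters$sample)
  expect_equal(tab$g0, pdl_creep_parameters$g0, tolerance = 1e-6)
  expect_equal(tab$eta, pdl_creep_parameters$eta, tolerance = 1e-6)
  # single curve matches fit_creep; duplicates give identical rows
  one <- fit_all(curves[1], ctx)
  f <- fit_creep(curves[[1]], ctx)
  expect_equal(one$g2, f$g2)
  dup <- fit_all(curves[c(1, 1)], ctx)
  expect_equal(unname(unlist(dup[1, c("g0", "g2", "eta", "r_squared")])),
               unname(unlist(dup[2, c("g0", "g2", "eta", "r_squared")])))
  expect_error(fit_all(list()), "non-empty")
})

test_that("model methods are mutually consistent", {
  ctx <- creep_context()
  fit <- fit_creep(table_curve(3), ctx)
  expect_named(coef(fit), c("g0", "g2", "eta"))
  expect_equal(fitted(fit) + residuals(fit), table_curve(3)$strain)
  expect_equal(predict(fit), fitted(fit))
  # predict at new times equals the constitutive response at the fit
  nd <- data.frame(time_s = c(0, 50, 400))
  p <- coef(fit)
  expect_equal(predict(fit, nd),
               strain_response(schapery_parameters(p[["g0"]], p[["g2"]]),
                               norm_sls(p[["eta"]]), unit_load, nd$time_s),
               tolerance = 1e-8)
  # simulate is reproducible under a seed and centered on the fit
  s1 <- simulate(fit, nsim = 3, seed = 5, noise_sd = 1e-4)
  s2 <- simulate(fit, nsim = 3, seed = 5, noise_sd = 1e-4)
  expect_identical(s1, s2)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.creep_fit")
  expect_output(print(sm), "reduced parameters")
})

test_that("creep curves are validated and CSV round-trips preserve them", {
  expect_error(creep_curve(c(0, 1, 1, 2), rep(0, 4)), "strictly increasing")
  expect_error(creep_curve(0:2, rep(0, 3)), "at least 4")
  expect_error(creep_curve(0:4, rep(0, 5), region = "root"), "neck/middle/apex")
  tmp <- tempfile(fileext = ".csv")
  cv <- table_curve(2)
  df <- data.frame(time_s = cv$time_s, strain = cv$strain,
                   sample_id = attr(cv, "sample_id"),
                   region = attr(cv, "region"))
  write.csv(df, tmp, row.names = FALSE)
  back <- read_creep_csv(tmp)
  expect_length(back, 1L)
  expect_equal(back[[1L]]$strain, cv$strain)
  expect_equal(attr(back[[1L]], "region"), "neck")
})
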