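test_that("creep compliance has the closed-form limits and values", {
  sls <- sls_parameters(1, 1, 1)
  expect_equal(creep_compliance(sls, 0), 0.5)                 # 1/(Etf+Em)
  expect_equal(creep_compliance(sls, 1), 1 - 0.5 * exp(-0.5))
  sls2 <- sls_parameters(2, 3, 5)
  expect_equal(creep_compliance(sls2, 1e9), 0.5, tolerance = 1e-12)  # 1/Etf
  expect_equal(creep_compliance(sls2, 0), 1 / 5)
  expect_error(creep_compliance(sls, -1), "non-negative")
  expect_error(sls_parameters(-1, 1, 1), "positive")
  expect_error(sls_parameters(1, 0, 1), "positive")
})

test_that("creep compliance is monotone non-decreasing for random parameters", {
  set.seed(42)
  tt <- seq(0, 500, length.out = 200)
  for (i in 1:25) {
    sls <- sls_parameters(runif(1, 0.1, 10), runif(1, 0.1, 10),
                          runif(1, 1, 1000))
    D <- creep_compliance(sls, tt)
    expect_true(all(diff(D) >= 0))
    expect_equal(D[1L], 1 / (sls$Etf + sls$Em))
  }
})

test_that("creep compliance matches a numerical ODE oracle to 1e-8", {
  set.seed(7)
  tt <- seq(0, 200, length.out = 51)
  for (i in 1:20) {
    sls <- sls_parameters(runif(1, 0.2, 5), runif(1, 0.2, 5),
                          runif(1, 10, 500))
    D_closed <- creep_compliance(sls, tt)
    D_ode <- ode_compliance(sls, tt)
    expect_lt(max(abs(D_closed - D_ode) / abs(D_ode)), 1e-8)
  }
})

test_that("Kelvin-Voigt reparameterization satisfies its identities", {
  kv <- kelvin_voigt_from_sls(sls_parameters(1, 1, 1))
  expect_equal(kv$D0p, 1.5)
  expect_equal(kv$D1p, -0.5)
  expect_equal(kv$tau1, 2)
  # vanishing matrix: D0' -> 1/Etf, D1' -> 0
  kv0 <- kelvin_voigt_from_sls(sls_parameters(2, 1e-9, 1))
  expect_equal(kv0$D0p, 0.5, tolerance = 1e-8)
  expect_equal(kv0$D1p, 0, tolerance = 1e-9)
  # algebraic identity and timescale consistency over random parameters
  set.seed(11)
  for (i in 1:20) {
    sls <- sls_parameters(runif(1, 0.1, 10), runif(1, 0.1, 10),
                          runif(1, 1, 1000))
    kv <- kelvin_voigt_from_sls(sls)
    expect_equal(kv$D0p + kv$D1p, 1 / sls$Etf)
    # exponent timescale of D(t): D(tau1) - D(inf) = (D(0) - D(inf))/e
    d <- creep_compliance(sls, c(0, kv$tau1))
    expect_equal((d[2L] - 1 / sls$Etf) / (d[1L] - 1 / sls$Etf), exp(-1))
  }
})

test_that("strain response evaluates the nonlinear step-load form", {
  sls <- sls_parameters(1, 1, 260.8893)
  ld <- step_load(sigma0 = 1)
  # zero stress gives zero strain
  expect_equal(strain_response(schapery_parameters(0.0049, -0.0096), sls,
                               step_load(sigma0 = 0), c(0, 10, 100)),
               rep(0, 3))
  # normalized neck-region parameters: eps(0) and eps(inf)
  sch <- schapery_parameters(0.0049, -0.0096)
  expect_equal(strain_response(sch, sls, ld, 0), 0.0049 * 1.5)
  expect_equal(strain_response(sch, sls, ld, 1e9),
               0.00735 + 0.0096 * 0.5, tolerance = 1e-12)
  # g0 = g1 = 1, g2 = -1 collapses to A + B(1 - exp(-t/tau))
  tt <- seq(0, 100, by = 5)
  kv <- kelvin_voigt_from_sls(sls)
  expect_equal(strain_response(schapery_parameters(1, -1), sls, ld, tt),
               kv$D0p + abs(kv$D1p) * (1 - exp(-tt / kv$tau1)))
  # creep regime: non-decreasing, bounded by eps(0) + g1|g2||D1'|sigma0
  eps <- strain_response(sch, sls, ld, seq(0, 2000, by = 10))
  expect_true(all(diff(eps) >= 0))
  expect_true(all(eps <= 0.0049 * kv$D0p + 0.0096 * abs(kv$D1p) + 1e-12))
})

test_that("reduced parameterization round-trips (g0, g2, eta)", {
  sls <- sls_parameters(1, 1, 2)
  ld <- step_load(sigma0 = 1)
  red <- reduced_from_full(schapery_parameters(1, -1), sls, ld)
  expect_equal(red$A, 1.5)
  expect_equal(red$B, 0.5)
  expect_equal(red$tau, 4)
  # g2 = 0 gives a flat hold curve
  expect_equal(reduced_from_full(schapery_parameters(1, 0), sls, ld)$B, 0)
  # inversion error when g1 = 0 but B != 0
  expect_error(schapery_from_reduced(list(A = 1, B = 0.1, tau = 2),
                                     sls, ld, g1 = 0), "g1 = 0")
  # round-trip identity to 1e-10 over random parameters
  set.seed(3)
  for (i in 1:20) {
    g0 <- runif(1, 0.001, 0.02); g2 <- runif(1, -0.03, -0.001)
    eta <- runif(1, 100, 500)
    slsi <- sls_parameters(1, 1, eta)
    red <- reduced_from_full(schapery_parameters(g0, g2), slsi, ld)
    back <- schapery_from_reduced(red, slsi, ld, g1 = 1)
    expect_equal(back$g0, g0, tolerance = 1e-10)
    expect_equal(back$g2, g2, tolerance = 1e-10)
    expect_equal(back$eta, eta, tolerance = 1e-10)
  }
})

test_that("g1 follows the rebound-strain definition", {
  # full rebound (eps_b0 == eps_r0) gives g1 = 1 regardless of eps_p
  expect_equal(g1_from_strains(0.01, 0, 0.005, 0.005), 1)
  expect_equal(g1_from_strains(0.02, 0.003, 0.011, 0.011), 1)
  # partial rebound
  expect_equal(g1_from_strains(0.01, 0, 0.005, 0), 2)
  # zero numerator
  expect_equal(g1_from_strains(0.01, 0.01, 0, 0.005), 0)
  expect_error(g1_from_strains(0.01, 0, 0.01, 0), "degenerate")
})

test_that("step stress follows F/S with flat-punch area", {
  expect_equal(stress_from_load(3, pi * 0.1^2), 3 / (pi * 0.01))  # ~95.49 kPa
  expect_equal(stress_from_load(0, 1), 0)
  expect_equal(stress_from_load(1, 1), 1)
  expect_error(stress_from_load(1, 0), "positive")
  expect_error(stress_from_load(-1, 1), "non-negative")
  # step_load converts kPa to MPa
  expect_equal(step_load(F_mN = 3, S_mm2 = pi * 0.01)$sigma0,
               3 / (pi * 0.01) / 1000)
})
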