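test_that("semi-infinite model limits are exact", {
  pr <- optical_properties(0.15, 4)
  tau <- c(0, default_tau())
  g1 <- g1_semi_infinite(2.5, tau, pr, 5.18e-8)
  expect_equal(g1[1], 1)
  expect_equal(g1_semi_infinite(2.5, tau, pr, 0), rep(1, length(tau)))
  expect_true(all(diff(g1) < 0))
  expect_true(all(g1 > 0 & g1 <= 1))
})

test_that("early-lag decay rate matches the analytic series slope", {
  # d(-log g1)/dtau at tau -> 0 from the closed form, against the chain
  # rule dK/dtau * d(-log G)/dK evaluated analytically
  pr <- optical_properties(0.15, 4)
  bfi <- 5.18e-8
  rho <- 2.5
  k0 <- wavenumber(850, pr$n)
  z0 <- 1.5 / pr$musp
  zb <- dcslayers:::extrapolation_length(pr$musp, pr$n)
  cf <- dcslayers:::boundary_coefficients(pr$n)
  D <- 1 / (3 * pr$musp)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  K0 <- sqrt(3 * pr$mua * pr$musp)
  # partial-current reflectance and its analytic K-derivative
  G <- cf["c_phi"] / D * (exp(-K0 * r1) / r1 - exp(-K0 * rb) / rb) +
    cf["c_j"] * (z0 * (K0 + 1 / r1) * exp(-K0 * r1) / r1^2 +
                 (z0 + 2 * zb) * (K0 + 1 / rb) * exp(-K0 * rb) / rb^2)
  dG_dK <- cf["c_phi"] / D * (-exp(-K0 * r1) + exp(-K0 * rb)) +
    cf["c_j"] * (-z0 * K0 * exp(-K0 * r1) / r1 -
                 (z0 + 2 * zb) * K0 * exp(-K0 * rb) / rb)
  dK_dtau <- 3 * pr$musp^2 * k0^2 * bfi / K0
  slope_analytic <- unname(-dG_dK / G * dK_dtau)
  h <- 1e-9
  slope_fd <- -(log(g1_semi_infinite(rho, h, pr, bfi))) / h
  expect_lt(abs(slope_fd - slope_analytic) / slope_analytic, 0.01)
})

test_that("three-layer model degenerates to the semi-infinite solution", {
  pr <- standard_properties()
  tau <- default_tau()
  st <- layer_stack3(0.6, 0.6, pr$brain, pr$brain, pr$brain,
                     5e-8, 5e-8, 5e-8)
  for (rho in c(1, 2.5)) {
    d <- max(abs(g1_three_layer(rho, tau, st) -
                 g1_semi_infinite(rho, tau, pr$brain, 5e-8)))
    expect_lt(d, 1e-6)
  }
})

test_that("a very thick top layer hides the deeper layers", {
  pr <- standard_properties()
  tau <- default_tau()
  st <- layer_stack3(10, 0.6, pr$scalp, pr$skull, pr$brain, 1e-8, 0, 5e-8)
  for (rho in c(1, 2.5)) {
    d <- max(abs(g1_three_layer(rho, tau, st) -
                 g1_semi_infinite(rho, tau, pr$scalp, 1e-8)))
    expect_lt(d, 1e-6)
  }
})

test_that("analytic layered solution matches the brute-force ODE oracle", {
  st <- standard_stack()
  tau <- exp(seq(log(1e-7), log(1e-3), length.out = 8))
  for (rho in c(2.5)) {
    go <- oracle_three_layer_g1(rho, tau, st, h = 1e-3)
    gp <- g1_three_layer(rho, tau, st)
    expect_lt(max(abs(gp - go)), 1e-5)
  }
})

test_that("layered g1 is a valid decreasing autocorrelation", {
  tau <- default_tau()
  set.seed(11)
  for (rep in 1:4) {
    st <- standard_stack(sbfi = stats::runif(1, 2.5e-9, 3e-8),
                         cbfi = stats::runif(1, 2e-8, 9e-8))
    g1 <- g1_three_layer(2.5, tau, st)
    expect_true(all(g1 > 0 & g1 <= 1))
    expect_true(all(diff(g1) < 0))
  }
})

test_that("brain-flow sensitivity grows with separation", {
  tau <- c(1e-6, 3e-6, 1e-5)
  st_lo <- standard_stack(cbfi = 5.18e-8)
  st_hi <- standard_stack(cbfi = 5.18e-8 * 1.05)
  for (t1 in tau) {
    d1 <- abs(g1_three_layer(1, t1, st_hi) - g1_three_layer(1, t1, st_lo))
    d25 <- abs(g1_three_layer(2.5, t1, st_hi) - g1_three_layer(2.5, t1, st_lo))
    expect_gt(d25, d1)
  }
})

test_that("effective reflection coefficient matches the known n = 1.4 value", {
  expect_equal(effective_reflection(1.4), 0.493, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(effective_reflection(1.0), 0, tolerance = 1e-6,
               ignore_attr = TRUE)
})
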