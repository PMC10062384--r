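test_that("three-layer fits recover generating flows on exact data", {
  set.seed(5)
  props <- standard_fit_props()
  tau <- default_tau()
  for (rep in 1:6) {
    sbfi <- stats::runif(1, 2.5e-9, 3e-8)
    cbfi <- stats::runif(1, 2e-8, 9e-8)
    curves <- make_curves(standard_stack(sbfi = sbfi, cbfi = cbfi), tau)
    fit <- fit_three_layer(curves, 0.6, 0.6, props)
    expect_true(fit$converged)
    expect_lt(abs(fit$sbfi / sbfi - 1), 1e-3)
    expect_lt(abs(fit$cbfi / cbfi - 1), 1e-3)
  }
})

test_that("homogeneous fits recover the generating flow on exact data", {
  set.seed(6)
  pr <- optical_properties(0.15, 4)
  tau <- default_tau()
  for (rep in 1:6) {
    bfi <- stats::runif(1, 2e-8, 9e-8)
    cv <- to_g2(g1_semi_infinite(2.5, tau, pr, bfi), tau, 2.5, 0.5)
    fit <- fit_homogeneous(cv, pr)
    expect_true(fit$converged)
    expect_lt(abs(fit$cbfi / bfi - 1), 1e-3)
  }
})

test_that("recovered flows scale with the generating flows", {
  props <- standard_fit_props()
  tau <- default_tau()
  f1 <- fit_three_layer(make_curves(standard_stack(sbfi = 8e-9,
                                                   cbfi = 4e-8), tau),
                        0.6, 0.6, props)
  f2 <- fit_three_layer(make_curves(standard_stack(sbfi = 2 * 8e-9,
                                                   cbfi = 2 * 4e-8), tau),
                        0.6, 0.6, props)
  expect_equal(f2$cbfi / f1$cbfi, 2, tolerance = 1e-3)
  expect_equal(f2$sbfi / f1$sbfi, 2, tolerance = 1e-3)
})

test_that("fits are deterministic", {
  props <- standard_fit_props()
  curves <- make_curves(standard_stack())
  a <- fit_three_layer(curves, 0.6, 0.6, props)
  b <- fit_three_layer(curves, 0.6, 0.6, props)
  expect_identical(a[c("cbfi", "sbfi", "residual", "n_iter")],
                   b[c("cbfi", "sbfi", "residual", "n_iter")])
})

test_that("a mis-set coherence factor strictly worsens the fit", {
  pr <- optical_properties(0.15, 4)
  tau <- default_tau()
  cv <- to_g2(g1_semi_infinite(2.5, tau, pr, 5e-8), tau, 2.5, 0.5)
  fit_ok <- fit_homogeneous(cv, pr)
  cv_bad <- cv
  cv_bad$beta <- 0.6  # model now assumes the wrong intercept
  fit_bad <- fit_homogeneous(cv_bad, pr)
  expect_gt(fit_bad$residual, fit_ok$residual)
})

test_that("partial-volume contamination brackets the homogeneous estimate", {
  # two-layer medium, scalp flow far below brain flow: the bulk fit at
  # 2.5 cm must land between the two
  ens <- twolayer_ensemble()
  tau <- default_tau()
  sbfi <- 5e-9; cbfi <- 6e-8
  g1 <- g1_from_ensemble(ens, flow_assignment(c(scalp = sbfi, brain = cbfi)),
                         tau, 2)
  cv <- to_g2(g1, tau, 2.5, 0.5)
  fit <- fit_homogeneous(cv, standard_properties()$brain)
  expect_true(fit$converged)
  expect_gt(fit$cbfi, sbfi)
  expect_lt(fit$cbfi, cbfi)
})
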