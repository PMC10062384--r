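test_that("Siegert relation maps g1 to g2", {
  tau <- default_tau(n = 3)
  expect_equal(to_g2(c(1, 1, 1), tau, 1)$g2, rep(1.5, 3))
  expect_equal(to_g2(c(0, 0, 0), tau, 1)$g2, rep(1, 3))
  expect_equal(to_g2(c(0.6, 0.6, 0.6), tau, 1, beta = 0.5)$g2, rep(1.18, 3))
  expect_error(to_g2(c(0.5, 0.5, 0.5), tau, 1, beta = 0), "beta")
  expect_error(to_g2(c(0.5, 0.5, 0.5), tau, 1, beta = 1.2), "beta")
})

test_that("static media and vanishing lags leave g1 at unity", {
  ens <- homog_ensemble()
  tau <- default_tau()
  g1_static <- g1_from_ensemble(ens, flow_assignment(c(bulk = 0)), tau, 1)
  expect_equal(g1_static, rep(1, length(tau)))
  g1_tiny <- g1_from_ensemble(ens, flow_assignment(c(bulk = 5e-8)),
                              1e-15, 1)
  expect_equal(g1_tiny, 1, tolerance = 1e-6)
})

test_that("g1 is monotone in lag and in every layer flow", {
  ens <- csf_small_ensemble()
  tau <- default_tau()
  set.seed(7)
  for (rep in 1:5) {
    bfi <- stats::runif(4, 1e-9, 1e-7)
    fa <- flow_assignment(c(scalp = bfi[1], skull = bfi[2], csf = bfi[3],
                            brain = bfi[4]))
    g1 <- g1_from_ensemble(ens, fa, tau, 2)
    expect_true(all(diff(g1) <= 1e-15))
    expect_true(all(g1 >= 0 & g1 <= 1))
    # raising any single layer's flow can only speed decorrelation
    for (layer in c("scalp", "brain")) {
      up <- bfi; names(up) <- c("scalp", "skull", "csf", "brain")
      up[layer] <- up[layer] * 3
      g1_up <- g1_from_ensemble(ens, flow_assignment(up), tau, 2)
      expect_true(all(g1_up <= g1 + 1e-15))
    }
  }
})

test_that("scaling flows and inversely scaling lags leaves g1 unchanged", {
  ens <- csf_small_ensemble()
  tau <- default_tau()
  fa <- flow_assignment(c(scalp = 1e-8, skull = 1e-10, csf = 1e-10,
                          brain = 5e-8))
  fa4 <- flow_assignment(c(scalp = 4e-8, skull = 4e-10, csf = 4e-10,
                           brain = 2e-7))
  expect_equal(g1_from_ensemble(ens, fa, tau, 2),
               g1_from_ensemble(ens, fa4, tau / 4, 2))
})

test_that("MC-derived g1 agrees with the semi-infinite diffusion solution", {
  ens <- homog_ensemble()
  tau <- default_tau()
  pr <- optical_properties(0.1, 10)
  bfi <- 5.18e-8
  for (d in 1:2) {
    g1mc <- g1_from_ensemble(ens, flow_assignment(c(bulk = bfi)), tau, d)
    g1th <- g1_semi_infinite(c(1, 2.5)[d], tau, pr, bfi)
    keep <- g1th > 0.1
    rms <- sqrt(mean((g1mc[keep] - g1th[keep])^2))
    expect_lt(rms, 0.02)
  }
})

test_that("absorption reweighting matches re-deriving weights directly", {
  # downstream mua override must equal recomputing exp(-sum mua l) from the
  # stored pathlengths (consistency of the continuous-absorption design)
  ens <- csf_small_ensemble()
  tau <- default_tau()
  fa <- flow_assignment(c(scalp = 1e-8, skull = 1e-10, csf = 1e-10,
                          brain = 5e-8))
  mua2 <- c(scalp = 0.2, skull = 0.1, csf = 0.04, brain = 0.15)
  g1a <- g1_from_ensemble(ens, fa, tau, 1, mua_per_layer = as.list(mua2))
  det <- ens$detectors[[1]]
  w <- det$weight * exp(-drop(det$pathlengths %*% mua2[ens$layer_names]))
  k0 <- wavenumber(ens$wavelength_nm, 1.4)
  a <- 2 * k0^2 * drop(det$momentum_transfer %*%
                         unlist(fa$bfi_per_layer)[ens$layer_names])
  g1b <- as.vector(crossprod(exp(-outer(a, tau)), w) / sum(w))
  expect_equal(g1a, g1b, tolerance = 1e-12)
})

test_that("correlation curves survive a text round trip", {
  dir <- withr::local_tempdir()
  tau <- default_tau()
  g1 <- g1_semi_infinite(2.5, tau, optical_properties(0.15, 4), 5e-8)
  cv <- to_g2(g1, tau, 2.5, 0.5)
  path <- file.path(dir, "curve.tsv")
  write_curve(cv, path, metadata = list(scenario = "unit-test"))
  back <- read_curve(path)
  expect_equal(back$tau, cv$tau)
  expect_equal(back$g2, cv$g2)
  expect_equal(back$beta, cv$beta)
  expect_equal(back$separation, cv$separation)
})
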