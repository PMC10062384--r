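test_that("identical seeds give bit-identical ensembles", {
  geom <- make_csf_scenarios(2)[[1]]
  lay <- two_det_layout()
  a <- simulate_slab(geom, lay, 2e4, seed = 9)
  b <- simulate_slab(geom, lay, 2e4, seed = 9)
  expect_identical(a$detectors, b$detectors)
  d <- simulate_slab(geom, lay, 2e4, seed = 10)
  expect_false(identical(a$detectors, d$detectors))
  sph <- make_sphere_scenarios(7)[[1]]
  sa <- simulate_sphere(sph, lay, 2e4, seed = 9)
  sb <- simulate_sphere(sph, lay, 2e4, seed = 9)
  expect_identical(sa$detectors, sb$detectors)
})

test_that("photon counts are conserved", {
  for (ens in list(csf_small_ensemble(),
                   simulate_sphere(make_sphere_scenarios(7)[[1]],
                                   two_det_layout(), 5e4, seed = 1))) {
    detected <- sum(vapply(ens$detectors, function(d) d$n_detected, 0))
    expect_identical(detected + ens$n_escaped_other + ens$n_capped +
                       ens$n_rouletted, ens$n_launched)
  }
})

test_that("Henyey-Greenstein sampling has mean cosine g", {
  for (g in c(0.89, 0.5)) {
    draws <- dcslayers:::mc_sample_hg(1e6, g, seed = 4)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - g), 3 * se)
    expect_true(all(draws >= -1 & draws <= 1))
  }
  # isotropic limit
  draws0 <- dcslayers:::mc_sample_hg(1e6, 0, seed = 4)
  expect_lt(abs(mean(draws0)), 3 / sqrt(12) / sqrt(1e6) * 3)
})

test_that("doubling the scattering coefficient halves sampled free paths", {
  s1 <- dcslayers:::mc_sample_steps(1e5, 10, seed = 8)
  s2 <- dcslayers:::mc_sample_steps(1e5, 20, seed = 8)
  expect_equal(s1, 2 * s2)  # same uniforms, exact scaling
})

test_that("Fresnel reflectance matches the normal-incidence closed form", {
  expect_equal(dcslayers:::mc_fresnel_reflectance(1, 1.4, 1),
               ((1.4 - 1) / (1.4 + 1))^2, tolerance = 1e-12)
  # beyond the critical angle: total internal reflection
  expect_equal(dcslayers:::mc_fresnel_reflectance(cos(asin(1 / 1.4) + 0.01),
                                                  1.4, 1), 1)
  # grazing the critical angle from below stays below 1
  expect_lt(dcslayers:::mc_fresnel_reflectance(cos(asin(1 / 1.4) - 0.05),
                                               1.4, 1), 1)
})

test_that("invalid geometries are rejected before launch", {
  pr <- standard_properties()
  expect_error(tissue_layer("x", pr$scalp, 0))
  expect_error(slab_geometry(list(tissue_layer("a", pr$scalp, 0.5))),
               "semi-infinite")
  expect_error(slab_geometry(list(tissue_layer("a", pr$scalp, Inf),
                                  tissue_layer("b", pr$brain, Inf))))
})

test_that("an empty detector raises a warning, not silence", {
  pr <- standard_properties()
  geom <- slab_geometry(list(tissue_layer("bulk", pr$scalp, Inf)))
  lay <- detector_layout(c(1, 6), distance_convention = "line")
  expect_warning(simulate_slab(geom, lay, 100, seed = 1), "no photons")
})

test_that("azimuthal symmetry licenses annular detectors", {
  # disk detection at (rho, 0) scaled by the annulus/disk area ratio must
  # match annulus detection within Poisson error
  pr <- optical_properties(0.1, 10)
  geom <- slab_geometry(list(tissue_layer("bulk", pr, Inf)))
  lay <- detector_layout(1, detector_width = 0.2, distance_convention = "line")
  n <- 3e5
  ann <- simulate_slab(geom, lay, n, seed = 21, detector_shape = "annulus")
  dsk <- simulate_slab(geom, lay, n, seed = 22, detector_shape = "disk")
  n_ann <- ann$detectors[[1]]$n_detected
  n_dsk <- dsk$detectors[[1]]$n_detected
  # annulus area 2 pi rho w vs disk area pi (w/2)^2
  ratio <- (2 * pi * 1 * 0.2) / (pi * 0.1^2)
  expect_gt(n_dsk, 0)
  z <- (n_ann - ratio * n_dsk) / sqrt(n_ann + ratio^2 * n_dsk)
  expect_lt(abs(z), 4)
})

test_that("deep photons at 2.5 cm traverse the CSF layer", {
  ens <- csf_small_ensemble()
  csf_path <- ens$detectors[[2]]$pathlengths[, "csf"]
  expect_gt(mean(csf_path), 0)
  expect_gt(mean(csf_path > 0), 0.05)  # a solid fraction dives below 1.2 cm
})

test_that("momentum transfer is zero iff no scattering in a layer", {
  ens <- csf_small_ensemble()
  for (d in 1:2) {
    pm <- ens$detectors[[d]]$pathlengths
    mm <- ens$detectors[[d]]$momentum_transfer
    expect_true(all(pm >= 0) && all(mm >= 0))
    # no path in a layer implies no momentum transfer there
    expect_true(all(mm[pm == 0] == 0))
  }
})

test_that("pathlength histograms are unit-mass and mean matches diffusion", {
  ens <- homog_ensemble()
  h <- pathlength_histogram(ens, 1, "total", breaks = 64)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_error(pathlength_histogram(ens, 1, "nonexistent"), "unknown layer")
  # diffusion-theory mean pathlength oracle: -d log R / d mua for the
  # extrapolated-boundary semi-infinite reflectance
  musp <- 10; mua <- 0.1
  phi <- function(m) {
    K <- sqrt(3 * m * musp)
    z0 <- 1 / musp
    zb <- dcslayers:::extrapolation_length(musp, 1.4)
    r1 <- sqrt(1 + z0^2); rb <- sqrt(1 + (z0 + 2 * zb)^2)
    exp(-K * r1) / r1 - exp(-K * rb) / rb
  }
  lbar <- -(log(phi(mua + 5e-5)) - log(phi(mua - 5e-5))) / 1e-4
  expect_lt(abs(h$mean - lbar) / lbar, 0.10)
})

test_that("sphere arc-to-chord geometry and the flat limit hold", {
  expect_equal(chord_distance(2.5, 7), 2 * 7 * sin(2.5 / 14))
  expect_equal(round(chord_distance(2.5, 7), 4), 2.4867)
  # a very large sphere with slab-equivalent layers reproduces slab
  # momentum-transfer statistics at 2.5 cm
  pr <- standard_properties()
  shells <- list(tissue_layer("scalp", pr$scalp, 0.6),
                 tissue_layer("skull", pr$skull, 0.6),
                 tissue_layer("brain", pr$brain, Inf))
  big <- sphere_geometry(100, shells)
  lay <- two_det_layout()
  es <- simulate_sphere(big, lay, 6e5, seed = 31)
  ef <- simulate_slab(make_flat_scenario(), lay, 6e5, seed = 32)
  ys <- rowSums(es$detectors[[2]]$momentum_transfer)
  yf <- rowSums(ef$detectors[[2]]$momentum_transfer)
  expect_gt(length(ys), 200)
  expect_gt(suppressWarnings(stats::ks.test(ys, yf))$p.value, 0.01)
})

test_that("ensemble parquet round trip is lossless", {
  skip_if_not_installed("arrow")
  dir <- withr::local_tempdir()
  ens <- csf_small_ensemble()
  write_ensemble(ens, file.path(dir, "ens"))
  back <- read_ensemble(file.path(dir, "ens"))
  for (d in 1:2) {
    expect_equal(back$detectors[[d]]$pathlengths,
                 ens$detectors[[d]]$pathlengths)
    expect_equal(back$detectors[[d]]$momentum_transfer,
                 ens$detectors[[d]]$momentum_transfer)
    expect_equal(back$detectors[[d]]$weight, ens$detectors[[d]]$weight)
    expect_equal(back$detectors[[d]]$n_detected,
                 ens$detectors[[d]]$n_detected)
  }
  expect_equal(back$geometry, ens$geometry)
  expect_equal(back$layout, ens$layout)
  expect_equal(back$n_launched, ens$n_launched)
})
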