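test_that("standard optical properties match the study's head model", {
  pr <- standard_properties()
  expect_equal(pr$scalp$mua, 0.1)
  expect_equal(pr$scalp$musp, 10)
  expect_equal(pr$skull$mua, 0.1)
  expect_equal(pr$skull$musp, 10)
  expect_equal(pr$csf$mua, 0.04)
  expect_equal(pr$csf$musp, 0.036)
  expect_equal(pr$brain$mua, 0.15)
  expect_equal(pr$brain$musp, 4)
  for (p in pr) {
    expect_equal(p$g, 0.89)
    expect_equal(p$n, 1.4)
    expect_true(is.finite(mus(p)) && mus(p) > 0)
  }
  expect_equal(pr$brain$mua / pr$scalp$mua, 1.5)
})

test_that("optical property invariants are enforced", {
  expect_error(optical_properties(-0.1, 10))
  expect_error(optical_properties(0.1, 0))
  expect_error(optical_properties(0.1, 10, g = 1))
  expect_error(optical_properties(0.1, 10, n = 0.9))
})

test_that("CSF slab scenarios follow the four-layer construction", {
  sc <- make_csf_scenarios()
  expect_length(sc, 4L)
  for (i in 1:4) {
    layers <- sc[[i]]$layers
    expect_equal(vapply(layers, function(l) l$name, ""),
                 c("scalp", "skull", "csf", "brain"))
    expect_equal(interface_depths(sc[[i]]), c(0.6, 1.2, 1.2 + i / 10))
    expect_true(is.infinite(layers[[4]]$thickness))
    expect_equal(layers[[3]]$bfi, 1e-10)
    expect_equal(layers[[2]]$bfi, 1e-10)
  }
  # identical optical properties across the four media
  props1 <- lapply(sc[[1]]$layers, function(l) l$props)
  for (i in 2:4)
    expect_identical(lapply(sc[[i]]$layers, function(l) l$props), props1)
  expect_equal(interface_depths(sc[[1]])[3], 1.3)
})

test_that("sphere scenarios have three shells and no CSF", {
  sc <- make_sphere_scenarios()
  expect_equal(vapply(sc, function(g) g$outer_radius, 0), c(7, 8, 9, 10))
  for (g in sc) {
    expect_equal(vapply(g$shells, function(l) l$name, ""),
                 c("scalp", "skull", "brain"))
    expect_false("csf" %in% vapply(g$shells, function(l) l$name, ""))
  }
  # brain core radius for R = 7 cm
  expect_equal(7 - 0.6 - 0.6, 5.8)
  expect_error(sphere_geometry(1, make_sphere_scenarios(7)[[1]]$shells))
})

test_that("flow grid spans 72 combinations with the printed baseline", {
  grid <- make_flow_grid()
  expect_length(grid, 72L)
  tab <- flow_grid_table(grid)
  expect_equal(sort(unique(tab$divisor)), 3:8)
  expect_equal(length(unique(tab$cbfi)), 12L)
  expect_equal(range(tab$cbfi), c(2e-8, 9e-8))
  # 6th CBFi value and its k = 5 companion reproduce the baseline
  cb6 <- sort(unique(tab$cbfi))[6]
  expect_equal(cb6, 2e-8 + 5 * 7e-8 / 11)
  expect_equal(signif(cb6, 3), 5.18e-8)
  expect_equal(signif(cb6 / 5, 3), 1.04e-8)
  bl <- baseline_flow()
  expect_equal(bl$cbfi0, cb6)
  expect_equal(bl$sbfi0, cb6 / 5)
  # the baseline is a member of the grid
  expect_true(any(abs(tab$cbfi - bl$cbfi0) < 1e-20 &
                  abs(tab$sbfi - bl$sbfi0) < 1e-20))
  # skull and CSF flows pinned at the negligible value
  for (fa in grid) {
    expect_equal(fa$bfi_per_layer$skull, 1e-10)
    expect_equal(fa$bfi_per_layer$csf, 1e-10)
  }
})

test_that("relative-change span of the grid matches the printed ranges", {
  tab <- flow_grid_table()
  bl <- baseline_flow()
  r_cbfi <- round(rcbfi(tab$cbfi, bl))
  expect_equal(range(r_cbfi), c(-61, 74))
  r_sbfi <- round((tab$sbfi - bl$sbfi0) / bl$sbfi0 * 100)
  expect_equal(min(r_sbfi), -76)
  expect_equal(max(r_sbfi), 189)
})

test_that("pressure pair suppresses scalp flow only", {
  pp <- make_pressure_pair()
  expect_equal(attr(pp$off, "cbfi"), attr(pp$on, "cbfi"))
  expect_equal(attr(pp$off, "cbfi"), 5.2e-8)
  expect_equal(attr(pp$off, "sbfi"), 1.7e-8)
  expect_equal(attr(pp$on, "sbfi"), 6.5e-9)
  ratio <- attr(pp$on, "sbfi") / attr(pp$off, "sbfi")
  expect_equal(ratio, 6.5e-9 / 1.7e-8)
  expect_lt(abs(ratio - 0.38), 0.005)
  # symmetry: swapping states inverts the ratio
  expect_equal(attr(pp$off, "sbfi") / attr(pp$on, "sbfi"), 1 / ratio)
})

test_that("scenario YAML round trip is lossless", {
  dir <- withr::local_tempdir()
  lay <- detector_layout(c(1, 2.5), distance_convention = "line")
  for (geom in list(make_csf_scenarios(3)[[1]], make_sphere_scenarios(8)[[1]])) {
    path <- file.path(dir, "scenario.yaml")
    write_scenario(geom, path, layout = lay)
    back <- read_scenario(path)
    expect_equal(back$geometry, geom)
    expect_equal(back$layout, lay)
  }
})
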