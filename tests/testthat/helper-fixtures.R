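# Shared fixtures: small Monte Carlo ensembles are expensive enough that
# test files reuse them through a per-session cache.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

two_det_layout <- function(convention = "line")
  detector_layout(c(1, 2.5), distance_convention = convention)

# homogeneous scalp-like medium, modest photon count: used for MC-vs-theory
# comparisons and partial-volume checks
homog_ensemble <- function() fixture("homog", function() {
  pr <- optical_properties(0.1, 10)
  geom <- slab_geometry(list(tissue_layer("bulk", pr, Inf, 0)))
  simulate_slab(geom, two_det_layout(), 1.5e6, seed = 42)
})

# four-layer slab with 2 mm CSF, small run for structural checks
csf_small_ensemble <- function() fixture("csf_small", function() {
  simulate_slab(make_csf_scenarios(2)[[1]], two_det_layout(), 3e5, seed = 42)
})

# two-layer medium (scalp over brain) for partial-volume bracketing
twolayer_ensemble <- function() fixture("twolayer", function() {
  pr <- standard_properties()
  geom <- slab_geometry(list(tissue_layer("scalp", pr$scalp, 1.0),
                             tissue_layer("brain", pr$brain, Inf)))
  simulate_slab(geom, two_det_layout(), 1.5e6, seed = 43)
})

standard_stack <- function(L1 = 0.6, L2 = 0.6, sbfi = 1.04e-8,
                           cbfi = 5.18e-8, bfi2 = 0) {
  pr <- standard_properties()
  layer_stack3(L1, L2, pr$scalp, pr$skull, pr$brain, sbfi, bfi2, cbfi)
}

make_curves <- function(stack, tau = default_tau(), rho = c(1, 2.5),
                        beta = 0.5)
  lapply(rho, function(r) to_g2(g1_three_layer(r, tau, stack), tau, r, beta))
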