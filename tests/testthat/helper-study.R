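# Heavy study ensembles for the end-to-end reproduction tests. Each medium
# is simulated once per session at the study's scaled-down photon budgets
# and shared across test blocks via the fixture cache (helper-fixtures.R).

STUDY_TAU <- default_tau()

study_csf_ensemble <- function(t_mm) {
  fixture(sprintf("study_csf_%d", t_mm), function()
    simulate_slab(make_csf_scenarios(t_mm)[[1]],
                  two_det_layout("line"), 8e6, seed = 100 + t_mm,
                  roulette_start_cm = 25, max_store = 80000L))
}

study_sphere_ensemble <- function() {
  fixture("study_sphere7", function()
    simulate_sphere(make_sphere_scenarios(7)[[1]], two_det_layout("curve"),
                    2e7, seed = 201, roulette_start_cm = 25,
                    max_store = 80000L))
}

study_flat_ensemble <- function() {
  fixture("study_flat", function()
    simulate_slab(make_flat_scenario(), two_det_layout("line"), 4e6,
                  seed = 202, roulette_start_cm = 25, max_store = 80000L))
}

# three-layer slab of the CSF-breakdown illustration: 10 mm of scalp/skull
# tissue over 2 mm CSF over brain
study_csf_sandwich_ensemble <- function() {
  fixture("study_sandwich", function() {
    pr <- standard_properties()
    geom <- slab_geometry(list(
      tissue_layer("shallow", pr$scalp, 1.0),
      tissue_layer("csf", pr$csf, 0.2, 1e-10),
      tissue_layer("brain", pr$brain, Inf)))
    simulate_slab(geom, two_det_layout("line"), 3e6, seed = 203,
                  roulette_start_cm = 25)
  })
}

study_sweep <- function(ensemble, L1, L2, label, rho_fit = NULL,
                        curves_list = NULL) {
  sw <- sweep_three_layer(ensemble, make_flow_grid(), L1, L2,
                          standard_fit_props(), tau = STUDY_TAU,
                          label = label, rho_fit = rho_fit,
                          curves_list = curves_list)
  grid_error_table(cbind(scenario = label, sw))
}

study_curves_cache <- function(name, ensemble) {
  fixture(paste0("curves_", name), function()
    lapply(make_flow_grid(), function(fa) dcs_curves(ensemble, fa, STUDY_TAU)))
}

# interpolated lag at which a curve crosses a g2 level
tau_at_level <- function(tau, g2, level = 1.25) {
  stopifnot(any(g2 > level), any(g2 < level))
  i <- max(which(g2 > level))
  exp(stats::approx(g2[c(i, i + 1)], log(tau[c(i, i + 1)]), xout = level)$y)
}

weighted_layer_mean_path <- function(ensemble, detector, layers) {
  det <- ensemble$detectors[[detector]]
  mua <- vapply(ensemble_layers_pub(ensemble), function(l) l$props$mua, 0)
  names(mua) <- ensemble$layer_names
  w <- det$weight * exp(-drop(det$pathlengths %*% mua[ensemble$layer_names]))
  sum(colSums(det$pathlengths[, layers, drop = FALSE] * w) / sum(w))
}

ensemble_layers_pub <- function(ensemble) {
  if (ensemble$geometry$kind == "slab") ensemble$geometry$layers
  else ensemble$geometry$shells
}
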