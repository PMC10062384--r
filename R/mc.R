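#' @useDynLib dcslayers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DEFAULT_WAVELENGTH_NM <- 850
DEFAULT_MAX_PATH_CM <- 300
DEFAULT_ROULETTE_START_CM <- 25
DEFAULT_ROULETTE_STEP_CM <- 5

mc_layer_vectors <- function(layers) {
  list(name = vapply(layers, function(l) l$name, ""),
       thickness = vapply(layers, function(l) l$thickness, 0),
       mua = vapply(layers, function(l) l$props$mua, 0),
       mus = vapply(layers, function(l) mus(l$props), 0),
       g = vapply(layers, function(l) l$props$g, 0),
       n = vapply(layers, function(l) l$props$n, 0))
}

wrap_ensemble <- function(raw, geometry, layout, layer_names, n_photons,
                          seed, wavelength_nm, max_path_cm, detector_shape) {
  dets <- lapply(seq_along(raw$detectors), function(d) {
    x <- raw$detectors[[d]]
    colnames(x$pathlengths) <- layer_names
    colnames(x$momentum_transfer) <- layer_names
    x$n_stored <- nrow(x$pathlengths)
    x
  })
  n_det <- vapply(dets, function(x) x$n_detected, 0)
  if (any(n_det == 0))
    warning("no photons detected at separation(s) ",
            paste(layout$separations[n_det == 0], collapse = ", "), " cm")
  structure(list(
    detectors = dets,
    n_launched = raw$n_launched,
    n_escaped_other = raw$n_escaped_other,
    n_capped = raw$n_capped,
    n_rouletted = raw$n_rouletted,
    geometry = geometry,
    layout = layout,
    layer_names = layer_names,
    seed = seed,
    wavelength_nm = wavelength_nm,
    max_path_cm = max_path_cm,
    detector_shape = detector_shape), class = "photon_ensemble")
}

#' @export
print.photon_ensemble <- function(x, ...) {
  cat(sprintf("<photon_ensemble> %s geometry, %g photons launched (seed %s)\n",
              x$geometry$kind, x$n_launched, format(x$seed)))
  for (d in seq_along(x$detectors))
    cat(sprintf("  detector %d (%.3g cm, %s): %g detected, %d stored\n",
                d, x$layout$separations[d], x$detector_shape,
                x$detectors[[d]]$n_detected, x$detectors[[d]]$n_stored))
  cat(sprintf("  escaped elsewhere %g, path-capped %g (cap %.3g cm), rouletted %g\n",
              x$n_escaped_other, x$n_capped, x$max_path_cm, x$n_rouletted))
  invisible(x)
}

detector_bands <- function(layout) {
  hw <- layout$detector_width / 2
  list(lo = layout$separations - hw, hi = layout$separations + hw)
}

#' Monte Carlo photon transport in a layered slab
#'
#' A pencil beam is launched normally into the top layer at the origin.
#' Photons random-walk with exponential free paths (scattering coefficient
#' `mus = musp / (1 - g)`), Henyey-Greenstein deflection, index-matched
#' internal interfaces, and Fresnel reflection (with total internal
#' reflection) at the external tissue-air surface. Absorption is never
#' sampled: per-layer pathlengths and momentum transfer of detected photons
#' are returned, so survival weights and flow assignments are applied
#' analytically downstream.
#'
#' @param geometry A [slab_geometry()].
#' @param layout A [detector_layout()]; on a slab the separation is the
#'   radial exit distance.
#' @param n_photons Number of photons to launch.
#' @param seed Integer seed; identical seeds give bit-identical ensembles.
#' @param max_path_cm Hard cap on the total pathlength of a photon, cm.
#'   Photons exceeding the cap (or too deep to return within it) are
#'   terminated and counted.
#' @param roulette_start_cm,roulette_step_cm Pathlength roulette: beyond
#'   `roulette_start_cm` total pathlength a photon plays survival roulette
#'   (probability 1/2) every `roulette_step_cm`, doubling its stored
#'   `weight` when it survives. Unbiased for every weighted statistic and
#'   independent of absorption, so downstream `mua` reweighting stays
#'   exact; set `roulette_start_cm = Inf` to disable.
#' @param max_store Maximum number of detected photons stored per detector;
#'   detection counts are always exact.
#' @param detector_shape `"annulus"` (rings of width `detector_width`
#'   exploiting azimuthal symmetry) or `"disk"` (literal disks of diameter
#'   `detector_width` on the x axis).
#' @param wavelength_nm Laser wavelength, stored as ensemble metadata.
#' @return A `photon_ensemble` object.
#' @export
simulate_slab <- function(geometry, layout, n_photons, seed,
                          max_path_cm = DEFAULT_MAX_PATH_CM,
                          roulette_start_cm = DEFAULT_ROULETTE_START_CM,
                          roulette_step_cm = DEFAULT_ROULETTE_STEP_CM,
                          max_store = 150000L,
                          detector_shape = c("annulus", "disk"),
                          wavelength_nm = DEFAULT_WAVELENGTH_NM) {
  stopifnot(inherits(geometry, "slab_geometry"),
            inherits(layout, "detector_layout"), n_photons >= 1)
  detector_shape <- match.arg(detector_shape)
  lv <- mc_layer_vectors(geometry$layers)
  if (length(unique(lv$n)) != 1L)
    stop("internal interfaces are index-matched: all layer n must be equal")
  b <- detector_bands(layout)
  raw <- mc_slab_kernel(lv$thickness[-length(lv$thickness)], lv$mus, lv$g,
                        lv$n[1], 1.0, b$lo, b$hi, n_photons, seed,
                        max_path_cm, roulette_start_cm, roulette_step_cm,
                        as.integer(max_store), detector_shape == "disk")
  wrap_ensemble(raw, geometry, layout, lv$name, n_photons, seed,
                wavelength_nm, max_path_cm, detector_shape)
}

#' Monte Carlo photon transport in a concentric-sphere head model
#'
#' As [simulate_slab()], with spherical shells. The source enters radially
#' at a surface point; detectors capture photons leaving the outer surface
#' within a band of arc distance (measured along the surface) from the
#' source, and `exit_distance` records that arc length.
#'
#' @inheritParams simulate_slab
#' @param geometry A [sphere_geometry()].
#' @return A `photon_ensemble` object.
#' @export
simulate_sphere <- function(geometry, layout, n_photons, seed,
                            max_path_cm = DEFAULT_MAX_PATH_CM,
                            roulette_start_cm = DEFAULT_ROULETTE_START_CM,
                            roulette_step_cm = DEFAULT_ROULETTE_STEP_CM,
                            max_store = 150000L,
                            detector_shape = c("annulus", "disk"),
                            wavelength_nm = DEFAULT_WAVELENGTH_NM) {
  stopifnot(inherits(geometry, "sphere_geometry"),
            inherits(layout, "detector_layout"), n_photons >= 1)
  detector_shape <- match.arg(detector_shape)
  if (max(layout$separations) >= pi * geometry$outer_radius)
    stop("arc separation does not fit on the sphere surface")
  lv <- mc_layer_vectors(geometry$shells)
  if (length(unique(lv$n)) != 1L)
    stop("internal interfaces are index-matched: all layer n must be equal")
  radii <- geometry$outer_radius - c(0, cumsum(lv$thickness[-length(lv$thickness)]))
  b <- detector_bands(layout)
  raw <- mc_sphere_kernel(radii, lv$mus, lv$g, lv$n[1], 1.0, b$lo, b$hi,
                          n_photons, seed, max_path_cm, roulette_start_cm,
                          roulette_step_cm, as.integer(max_store),
                          detector_shape == "disk")
  wrap_ensemble(raw, geometry, layout, lv$name, n_photons, seed,
                wavelength_nm, max_path_cm, detector_shape)
}

ensemble_layers <- function(ensemble)
  if (ensemble$geometry$kind == "slab") ensemble$geometry$layers else ensemble$geometry$shells

ensemble_mua <- function(ensemble) {
  mu <- vapply(ensemble_layers(ensemble), function(l) l$props$mua, 0)
  names(mu) <- ensemble$layer_names
  mu
}

# survival weights exp(-sum_j mua_j l_j) for the stored photons
survival_weights <- function(det, mua) {
  det$weight * exp(-drop(det$pathlengths %*% mua))
}

#' Survival-weighted pathlength histogram of detected photons
#'
#' Histogram of per-layer or total pathlengths of the photons stored at one
#' detector, weighted by the analytic survival weight
#' `exp(-sum_j mua_j l_j)` and normalized to unit mass.
#'
#' @param ensemble A `photon_ensemble`.
#' @param detector Detector index (1-based).
#' @param layer A layer name or `"total"`.
#' @param breaks Passed to [graphics::hist()] semantics: either a bin count
#'   or a vector of bin edges, cm.
#' @param mua_per_layer Optional named absorption overrides, 1/cm; defaults
#'   to the geometry's own values.
#' @return List with `edges` (bin edges, cm), `mass` (probability mass per
#'   bin, summing to 1) and `mean` (weighted mean pathlength, cm).
#' @export
pathlength_histogram <- function(ensemble, detector, layer = "total",
                                 breaks = 50, mua_per_layer = NULL) {
  stopifnot(inherits(ensemble, "photon_ensemble"))
  det <- ensemble$detectors[[detector]]
  if (det$n_stored == 0) stop("no stored photons at this detector")
  mua <- ensemble_mua(ensemble)
  if (!is.null(mua_per_layer)) mua[names(mua_per_layer)] <- unlist(mua_per_layer)
  w <- survival_weights(det, mua)
  if (identical(layer, "total")) {
    l <- rowSums(det$pathlengths)
  } else {
    if (!layer %in% ensemble$layer_names)
      stop("unknown layer: ", layer)
    l <- det$pathlengths[, layer]
  }
  if (length(breaks) == 1L)
    breaks <- seq(0, max(l) * (1 + 1e-9), length.out = breaks + 1L)
  idx <- findInterval(l, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(w[idx == b]), 0)
  mass <- mass / sum(w)
  list(edges = breaks, mass = mass, mean = sum(w * l) / sum(w))
}

# ---------------------------------------------------------- ensemble I/O ----

#' Persist a photon ensemble to a columnar container
#'
#' Writes one Parquet table holding the per-detector photon records
#' (per-layer pathlengths and momentum transfer, exit distance, scatter
#' count) and a JSON metadata sidecar (geometry, layout, seed, counts).
#' Requires the `arrow` package.
#'
#' @param ensemble A `photon_ensemble`.
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for ensemble persistence")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(seq_along(ensemble$detectors), function(d) {
    det <- ensemble$detectors[[d]]
    pl <- as.data.frame(det$pathlengths)
    names(pl) <- paste0("path_", ensemble$layer_names)
    mt <- as.data.frame(det$momentum_transfer)
    names(mt) <- paste0("mt_", ensemble$layer_names)
    cbind(data.frame(detector = d), pl, mt,
          data.frame(exit_distance = det$exit_distance, weight = det$weight,
                     n_scatter = det$n_scatter))
  })
  arrow::write_parquet(do.call(rbind, tabs), file.path(dir, "records.parquet"))
  geom <- ensemble$geometry
  layers <- lapply(ensemble_layers(ensemble), layer_to_list)
  meta <- list(kind = geom$kind,
               outer_radius = if (geom$kind == "sphere") geom$outer_radius else NULL,
               layers = layers,
               separations = ensemble$layout$separations,
               detector_width = ensemble$layout$detector_width,
               distance_convention = ensemble$layout$distance_convention,
               detector_shape = ensemble$detector_shape,
               n_launched = ensemble$n_launched,
               n_escaped_other = ensemble$n_escaped_other,
               n_capped = ensemble$n_capped,
               n_rouletted = ensemble$n_rouletted,
               n_detected = vapply(ensemble$detectors, function(x) x$n_detected, 0),
               seed = ensemble$seed,
               wavelength_nm = ensemble$wavelength_nm,
               max_path_cm = ensemble$max_path_cm)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a photon ensemble written by [write_ensemble()]
#'
#' @param dir Directory containing `records.parquet` and `meta.json`.
#' @return A `photon_ensemble`.
#' @export
read_ensemble <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for ensemble persistence")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rec <- as.data.frame(arrow::read_parquet(file.path(dir, "records.parquet")))
  layers <- lapply(seq_len(nrow(meta$layers)), function(i)
    layer_from_list(as.list(meta$layers[i, ])))
  geometry <- if (meta$kind == "slab") slab_geometry(layers)
              else sphere_geometry(meta$outer_radius, layers)
  layout <- detector_layout(meta$separations, meta$detector_width,
                            meta$distance_convention)
  lnames <- vapply(layers, function(l) l$name, "")
  dets <- lapply(seq_along(meta$separations), function(d) {
    r <- rec[rec$detector == d, , drop = FALSE]
    pm <- as.matrix(r[paste0("path_", lnames)])
    mm <- as.matrix(r[paste0("mt_", lnames)])
    dimnames(pm) <- list(NULL, lnames)
    dimnames(mm) <- list(NULL, lnames)
    list(pathlengths = pm, momentum_transfer = mm,
         exit_distance = r$exit_distance, weight = r$weight,
         n_scatter = r$n_scatter,
         n_detected = meta$n_detected[d], n_stored = nrow(r))
  })
  structure(list(detectors = dets, n_launched = meta$n_launched,
                 n_escaped_other = meta$n_escaped_other,
                 n_capped = meta$n_capped, n_rouletted = meta$n_rouletted,
                 geometry = geometry,
                 layout = layout, layer_names = lnames, seed = meta$seed,
                 wavelength_nm = meta$wavelength_nm,
                 max_path_cm = meta$max_path_cm,
                 detector_shape = meta$detector_shape),
            class = "photon_ensemble")
}
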