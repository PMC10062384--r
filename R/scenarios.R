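#' Optical properties of a tissue layer
#'
#' Bundle of the absorption coefficient `mua` (1/cm), reduced scattering
#' coefficient `musp` (1/cm), scattering anisotropy `g` and refractive index
#' `n`. The (unreduced) scattering coefficient used by the Monte Carlo
#' engine is `mus = musp / (1 - g)`.
#'
#' @param mua Absorption coefficient, 1/cm (>= 0).
#' @param musp Reduced scattering coefficient, 1/cm (> 0).
#' @param g Scattering anisotropy, in `[0, 1)`.
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mua, musp, g = 0.89, n = 1.4) {
  stopifnot(is.numeric(mua), length(mua) == 1L, mua >= 0,
            is.numeric(musp), length(musp) == 1L, musp > 0,
            is.numeric(g), length(g) == 1L, g >= 0, g < 1,
            is.numeric(n), length(n) == 1L, n >= 1)
  structure(list(mua = mua, musp = musp, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mua=%.4g musp=%.4g g=%.3g n=%.3g (mus=%.4g) [1/cm]\n",
              x$mua, x$musp, x$g, x$n, mus(x)))
  invisible(x)
}

#' Scattering coefficient `mus = musp / (1 - g)`
#' @param props An `optical_properties` object.
#' @return Scattering coefficient, 1/cm.
#' @export
mus <- function(props) props$musp / (1 - props$g)

#' A single tissue layer
#'
#' @param name Layer label (e.g. "scalp", "skull", "csf", "brain").
#' @param props `optical_properties` of the layer.
#' @param thickness Thickness in cm; `Inf` marks the terminal
#'   (semi-infinite slab layer or sphere core) layer.
#' @param bfi Blood flow index, cm^2/s (>= 0).
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, props, thickness, bfi = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(props, "optical_properties"),
            is.numeric(thickness), length(thickness) == 1L, thickness > 0,
            is.numeric(bfi), length(bfi) == 1L, bfi >= 0)
  structure(list(name = name, props = props, thickness = thickness, bfi = bfi),
            class = "tissue_layer")
}

#' Layered slab geometry (surface downward)
#'
#' @param layers List of [tissue_layer()] ordered from the surface down;
#'   exactly the last one must have infinite thickness.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "tissue_layer")))
  th <- vapply(layers, function(l) l$thickness, 0)
  nl <- length(layers)
  if (!is.infinite(th[nl])) stop("terminal slab layer must be semi-infinite")
  if (nl > 1L && any(is.infinite(th[-nl])))
    stop("only the terminal layer may be semi-infinite")
  structure(list(layers = layers, kind = "slab"), class = "slab_geometry")
}

#' Concentric-sphere geometry (surface inward)
#'
#' @param outer_radius Outer radius, cm.
#' @param shells List of [tissue_layer()] from the surface inward; the last
#'   (thickness `Inf`) fills the core.
#' @return An object of class `sphere_geometry`.
#' @export
sphere_geometry <- function(outer_radius, shells) {
  stopifnot(is.numeric(outer_radius), outer_radius > 0,
            is.list(shells), length(shells) >= 1L,
            all(vapply(shells, inherits, TRUE, "tissue_layer")))
  th <- vapply(shells, function(l) l$thickness, 0)
  ns <- length(shells)
  if (!is.infinite(th[ns])) stop("core shell must have infinite thickness")
  if (ns > 1L && sum(th[-ns]) >= outer_radius)
    stop("shell thicknesses exceed the outer radius")
  structure(list(outer_radius = outer_radius, shells = shells, kind = "sphere"),
            class = "sphere_geometry")
}

#' Interface depths of a slab geometry
#' @param geometry A `slab_geometry`.
#' @return Cumulative depths (cm) of the internal interfaces.
#' @export
interface_depths <- function(geometry) {
  th <- vapply(geometry$layers, function(l) l$thickness, 0)
  cumsum(th[-length(th)])
}

#' Surface detector layout
#'
#' @param separations Source-detector separations, cm (strictly increasing).
#' @param detector_width Capture band width / disk diameter, cm.
#' @param distance_convention `"line"` (chord) or `"curve"` (arc along the
#'   surface); only meaningful for curved geometries.
#' @return An object of class `detector_layout`.
#' @export
detector_layout <- function(separations = c(1, 2.5), detector_width = 0.1,
                            distance_convention = c("curve", "line")) {
  distance_convention <- match.arg(distance_convention)
  stopifnot(is.numeric(separations), length(separations) >= 1L,
            all(separations > 0), !is.unsorted(separations, strictly = TRUE),
            is.numeric(detector_width), detector_width > 0)
  structure(list(separations = separations, detector_width = detector_width,
                 distance_convention = distance_convention),
            class = "detector_layout")
}

#' Chord (line) distance equivalent to an arc separation on a sphere
#' @param arc Arc distance along the surface, cm.
#' @param radius Sphere radius, cm.
#' @return Straight-line chord distance, cm.
#' @export
chord_distance <- function(arc, radius) 2 * radius * sin(arc / (2 * radius))

# flow index used for layers with physiologically negligible perfusion
BFI_NEGLIGIBLE <- 1e-10

#' Standard layer optical properties for the head model
#'
#' Scalp and skull share (mua, musp) = (0.1, 10) 1/cm, CSF is nearly
#' transparent at (0.04, 0.036), brain is (0.15, 4); every layer has
#' anisotropy 0.89 and refractive index 1.4.
#'
#' @return Named list of [optical_properties()] for scalp, skull, csf, brain.
#' @export
standard_properties <- function() {
  list(scalp = optical_properties(0.10, 10),
       skull = optical_properties(0.10, 10),
       csf   = optical_properties(0.04, 0.036),
       brain = optical_properties(0.15, 4))
}

#' Layer properties assumed by the three-layer fits
#'
#' The analysis models assume scalp properties in layer 1, skull in layer 2
#' and brain in layer 3.
#'
#' @return List of three [optical_properties()] (layers 1..3).
#' @export
standard_fit_props <- function() {
  pr <- standard_properties()
  list(pr$scalp, pr$skull, pr$brain)
}

#' Four-layer slab scenarios with varying CSF thickness
#'
#' Scalp 6 mm, skull 6 mm, CSF 1-4 mm, semi-infinite brain; standard
#' optical properties throughout. Flow indices are placeholders (zero for
#' all layers) since forward curves take an explicit flow assignment.
#'
#' @param csf_thickness_mm CSF thicknesses to generate, mm.
#' @return List of [slab_geometry()], one per CSF thickness.
#' @export
make_csf_scenarios <- function(csf_thickness_mm = 1:4) {
  pr <- standard_properties()
  lapply(csf_thickness_mm, function(t_mm) {
    slab_geometry(list(
      tissue_layer("scalp", pr$scalp, 0.6),
      tissue_layer("skull", pr$skull, 0.6, BFI_NEGLIGIBLE),
      tissue_layer("csf",   pr$csf,   t_mm / 10, BFI_NEGLIGIBLE),
      tissue_layer("brain", pr$brain, Inf)))
  })
}

#' Three-layer sphere scenarios with varying curvature
#'
#' Scalp 6 mm and skull 6 mm shells over a brain core, with outer radius
#' 7-10 cm; no CSF shell.
#'
#' @param outer_radius_cm Outer radii, cm.
#' @return List of [sphere_geometry()].
#' @export
make_sphere_scenarios <- function(outer_radius_cm = c(7, 8, 9, 10)) {
  pr <- standard_properties()
  lapply(outer_radius_cm, function(R) {
    sphere_geometry(R, list(
      tissue_layer("scalp", pr$scalp, 0.6),
      tissue_layer("skull", pr$skull, 0.6, BFI_NEGLIGIBLE),
      tissue_layer("brain", pr$brain, Inf)))
  })
}

#' Slab twin of the three-layer sphere scenarios
#'
#' Same layers as [make_sphere_scenarios()] but as a plane-parallel slab;
#' the zero-curvature reference for curvature comparisons.
#'
#' @return A [slab_geometry()].
#' @export
make_flat_scenario <- function() {
  pr <- standard_properties()
  slab_geometry(list(
    tissue_layer("scalp", pr$scalp, 0.6),
    tissue_layer("skull", pr$skull, 0.6, BFI_NEGLIGIBLE),
    tissue_layer("brain", pr$brain, Inf)))
}

#' Per-layer blood flow assignment
#'
#' @param bfi_per_layer Named numeric vector/list, layer name -> cm^2/s.
#' @return An object of class `flow_assignment`.
#' @export
flow_assignment <- function(bfi_per_layer) {
  v <- unlist(bfi_per_layer)
  stopifnot(is.numeric(v), !is.null(names(v)), all(v >= 0))
  structure(list(bfi_per_layer = as.list(v)), class = "flow_assignment")
}

#' Scalp/cerebral blood flow grid of the study
#'
#' 12 evenly spaced CBFi values on `[2, 9] x 1e-8` cm^2/s (endpoints
#' included) crossed with scalp flow SBFi = CBFi / k for
#' k in {8, 7, 6, 5, 4, 3}, giving 72 assignments. Skull and CSF flow are
#' fixed at the negligible value 1e-10 cm^2/s.
#'
#' @return List of 72 [flow_assignment()] objects; each carries attributes
#'   `cbfi`, `sbfi` and `divisor`.
#' @export
make_flow_grid <- function() {
  cbfi <- seq(2e-8, 9e-8, length.out = 12)
  ks <- c(8, 7, 6, 5, 4, 3)
  out <- vector("list", length(cbfi) * length(ks))
  i <- 0L
  for (cb in cbfi) for (k in ks) {
    i <- i + 1L
    fa <- flow_assignment(c(scalp = cb / k, skull = BFI_NEGLIGIBLE,
                            csf = BFI_NEGLIGIBLE, brain = cb))
    attr(fa, "cbfi") <- cb
    attr(fa, "sbfi") <- cb / k
    attr(fa, "divisor") <- k
    out[[i]] <- fa
  }
  out
}

#' Flow grid as a data frame
#' @param grid Output of [make_flow_grid()].
#' @return `data.frame` with columns `cbfi`, `sbfi`, `divisor`.
#' @export
flow_grid_table <- function(grid = make_flow_grid()) {
  data.frame(cbfi = vapply(grid, attr, 0, "cbfi"),
             sbfi = vapply(grid, attr, 0, "sbfi"),
             divisor = vapply(grid, attr, 0, "divisor"))
}

#' Baseline flow state used for relative-change metrics
#'
#' The baseline is a member of the flow grid: the 6th CBFi value
#' (5.18e-8 cm^2/s) with SBFi = CBFi / 5 (1.04e-8 cm^2/s).
#'
#' @return List with elements `cbfi0` and `sbfi0` (cm^2/s).
#' @export
baseline_flow <- function() {
  cb <- seq(2e-8, 9e-8, length.out = 12)[6]
  list(cbfi0 = cb, sbfi0 = cb / 5)
}

#' Pressure-modulation flow pair
#'
#' Scalp compression suppresses scalp flow by ~60% while cerebral flow is
#' unchanged: CBFi = 5.2e-8 cm^2/s in both states, SBFi = 1.7e-8 (off)
#' vs 6.5e-9 (on) cm^2/s.
#'
#' @return List with elements `off` and `on`, each a [flow_assignment()].
#' @export
make_pressure_pair <- function() {
  cb <- 5.2e-8
  mk <- function(sb) {
    fa <- flow_assignment(c(scalp = sb, skull = BFI_NEGLIGIBLE,
                            csf = BFI_NEGLIGIBLE, brain = cb))
    attr(fa, "cbfi") <- cb
    attr(fa, "sbfi") <- sb
    fa
  }
  list(off = mk(1.7e-8), on = mk(6.5e-9))
}

# ------------------------------------------------------------ config I/O ----

layer_to_list <- function(l)
  list(name = l$name, mua = l$props$mua, musp = l$props$musp, g = l$props$g,
       n = l$props$n,
       thickness = if (is.infinite(l$thickness)) "semi-infinite" else l$thickness,
       bfi = l$bfi)

layer_from_list <- function(x) {
  th <- if (identical(x$thickness, "semi-infinite")) Inf
        else as.numeric(x$thickness)
  tissue_layer(x$name, optical_properties(x$mua, x$musp, x$g, x$n), th, x$bfi)
}

#' Write a geometry (plus optional detector layout) to a YAML scenario file
#'
#' @param geometry A `slab_geometry` or `sphere_geometry`.
#' @param path File path to write.
#' @param layout Optional [detector_layout()].
#' @return `path`, invisibly.
#' @export
write_scenario <- function(geometry, path, layout = NULL) {
  x <- if (inherits(geometry, "slab_geometry")) {
    list(kind = "slab", layers = lapply(geometry$layers, layer_to_list))
  } else if (inherits(geometry, "sphere_geometry")) {
    list(kind = "sphere", outer_radius = geometry$outer_radius,
         layers = lapply(geometry$shells, layer_to_list))
  } else stop("unsupported geometry class")
  if (!is.null(layout))
    x$detectors <- list(separations = layout$separations,
                        detector_width = layout$detector_width,
                        distance_convention = layout$distance_convention)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Read a YAML scenario file written by [write_scenario()]
#'
#' @param path File path.
#' @return List with elements `geometry` and (possibly `NULL`) `layout`.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  layers <- lapply(x$layers, layer_from_list)
  geometry <- switch(x$kind,
    slab = slab_geometry(layers),
    sphere = sphere_geometry(x$outer_radius, layers),
    stop("unknown scenario kind: ", x$kind))
  layout <- NULL
  if (!is.null(x$detectors))
    layout <- detector_layout(unlist(x$detectors$separations),
                              x$detectors$detector_width,
                              x$detectors$distance_convention)
  list(geometry = geometry, layout = layout)
}
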