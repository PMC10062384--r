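#' Optical wavenumber in tissue
#'
#' `k0 = 2 pi n / lambda`, in 1/cm.
#'
#' @param wavelength_nm Wavelength in vacuum, nm.
#' @param n Refractive index of the medium.
#' @return Wavenumber, 1/cm.
#' @export
wavenumber <- function(wavelength_nm = DEFAULT_WAVELENGTH_NM, n = 1.4) {
  2 * pi * n / (wavelength_nm * 1e-7)
}

#' Default logarithmic lag-time grid
#'
#' @param from,to Range of lag times, s.
#' @param n Number of points.
#' @return Strictly increasing vector of lag times, s.
#' @export
default_tau <- function(from = 1e-7, to = 1e-1, n = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Field autocorrelation from a photon ensemble
#'
#' Computes the normalized electric-field autocorrelation
#' `g1(tau) = sum_p w_p exp(-2 k0^2 tau sum_j BFi_j Y_pj) / sum_p w_p`,
#' where `w_p = exp(-sum_j mua_j l_pj)` is the analytic survival weight and
#' `Y_pj` the accumulated dimensionless momentum transfer of photon `p` in
#' layer `j`. This is the Brownian-motion form: each layer's mean-square
#' displacement `<dr^2(tau)> = 6 BFi_j tau` enters the exponent as
#' `-(1/3) k0^2 <dr^2> Y`.
#'
#' @param ensemble A `photon_ensemble`.
#' @param flows A [flow_assignment()] naming every ensemble layer.
#' @param tau Lag times, s (positive, increasing).
#' @param detector Detector index.
#' @param mua_per_layer Optional named absorption overrides, 1/cm.
#' @param wavelength_nm Wavelength for `k0`; defaults to the ensemble's.
#' @return Numeric vector `g1(tau)` in `(0, 1]`.
#' @export
g1_from_ensemble <- function(ensemble, flows, tau, detector = 1L,
                             mua_per_layer = NULL, wavelength_nm = NULL) {
  stopifnot(inherits(ensemble, "photon_ensemble"),
            inherits(flows, "flow_assignment"),
            all(tau > 0), !is.unsorted(tau))
  det <- ensemble$detectors[[detector]]
  if (det$n_stored == 0) stop("no stored photons at detector ", detector)
  bfi <- unlist(flows$bfi_per_layer)[ensemble$layer_names]
  if (anyNA(bfi)) stop("flow assignment must name every ensemble layer")
  if (any(bfi < 0)) stop("negative blood flow index")
  mua <- ensemble_mua(ensemble)
  if (!is.null(mua_per_layer)) mua[names(mua_per_layer)] <- unlist(mua_per_layer)
  if (is.null(wavelength_nm)) wavelength_nm <- ensemble$wavelength_nm
  k0 <- wavenumber(wavelength_nm, ensemble_layers(ensemble)[[1]]$props$n)
  w <- survival_weights(det, mua)
  a <- 2 * k0^2 * drop(det$momentum_transfer %*% bfi)  # decay rate per photon
  sw <- sum(w)
  # chunk the photon x tau outer product to bound memory
  n <- length(a)
  acc <- numeric(length(tau))
  step <- max(1L, floor(4e6 / length(tau)))
  for (i0 in seq(1L, n, by = step)) {
    i1 <- min(i0 + step - 1L, n)
    acc <- acc + drop(crossprod(exp(-tcrossprod(a[i0:i1], tau)), w[i0:i1]))
  }
  acc / sw
}

#' Intensity autocorrelation curve via the Siegert relation
#'
#' `g2 = 1 + beta * g1^2`.
#'
#' @param g1 Normalized field autocorrelation values in `[0, 1]`.
#' @param tau Lag times, s.
#' @param separation Source-detector separation, cm.
#' @param beta Coherence factor in `(0, 1]`.
#' @return An object of class `correlation_curve` with fields `tau`, `g2`,
#'   `beta`, `separation`.
#' @export
to_g2 <- function(g1, tau, separation, beta = 0.5) {
  stopifnot(is.numeric(g1), all(g1 >= -1e-9), all(g1 <= 1 + 1e-9),
            length(g1) == length(tau), all(tau > 0), !is.unsorted(tau))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  structure(list(separation = separation, tau = tau,
                 g2 = 1 + beta * g1^2, beta = beta),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> rho=%.3g cm, beta=%.3g, %d lags in [%.3g, %.3g] s\n",
              x$separation, x$beta, length(x$tau), min(x$tau), max(x$tau)))
  invisible(x)
}

#' Synthesize measured g2 curves at every detector of an ensemble
#'
#' @inheritParams g1_from_ensemble
#' @param beta Coherence factor.
#' @return List of `correlation_curve`, one per detector.
#' @export
dcs_curves <- function(ensemble, flows, tau = default_tau(), beta = 0.5,
                       mua_per_layer = NULL) {
  lapply(seq_along(ensemble$detectors), function(d)
    to_g2(g1_from_ensemble(ensemble, flows, tau, d, mua_per_layer),
          tau, ensemble$layout$separations[d], beta))
}

#' Write a correlation curve as a plain-text table
#'
#' Two columns (tau, g2) preceded by `#`-prefixed metadata header lines
#' (format version, separation, beta).
#'
#' @param curve A `correlation_curve`.
#' @param path Output file path.
#' @param metadata Optional named list appended to the header.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, metadata = NULL) {
  hdr <- c("# dcslayers correlation_curve v1",
           sprintf("# separation_cm: %.17g", curve$separation),
           sprintf("# beta: %.17g", curve$beta))
  for (nm in names(metadata))
    hdr <- c(hdr, sprintf("# %s: %s", nm, format(metadata[[nm]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("tau\tg2", con)
  writeLines(sprintf("%.17g\t%.17g", curve$tau, curve$g2), con)
  invisible(path)
}

#' Read a correlation curve written by [write_curve()]
#'
#' @param path File path.
#' @return A `correlation_curve`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln[1]))
  }
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t")
  structure(list(separation = get("separation_cm"), tau = body$tau,
                 g2 = body$g2, beta = get("beta")),
            class = "correlation_curve")
}
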