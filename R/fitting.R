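## Inverse problem: recover scalp and cerebral blood flow indices from
## measured g2 curves by least squares against the CDE forward models.

FIT_BOUNDS <- c(1e-11, 1e-5)  # cm^2/s
FIT_STARTS <- c(1e-9, 1e-8, 1e-7)  # log-spaced multi-start values

# lag indices fitted: all tau where the curve has decayed by less than 99%
# of its intercept, i.e. g2 - 1 > 0.01 * beta
fit_window <- function(curve) which(curve$g2 - 1 > 0.01 * curve$beta)

fit_result <- function(model, cbfi, sbfi = NA_real_, residual, converged,
                       n_iter, message = "") {
  structure(list(model = model, cbfi = cbfi, sbfi = sbfi,
                 residual = residual, converged = converged,
                 n_iter = n_iter, message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s cbfi=%.4g sbfi=%s residual=%.4g %s (%d iter)\n",
              x$model, x$cbfi,
              if (is.na(x$sbfi)) "-" else sprintf("%.4g", x$sbfi),
              x$residual,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

run_lm <- function(residual_fun, start, lower, upper) {
  np <- length(start)
  fit <- try(minpack.lm::nls.lm(
    par = log10(start), lower = rep(log10(lower), np),
    upper = rep(log10(upper), np),
    fn = residual_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  fit
}

#' Fit the three-layer CDE model to g2 curves at two separations
#'
#' Simultaneous least squares over `(SBFi, CBFi)` on the lag window where
#' each curve retains more than 1% of its intercept, with the middle-layer
#' flow held fixed (zero by default). Optimization runs in log10 flow space
#' within bounds `[1e-11, 1e-5]` cm^2/s, from three log-spaced starts (or a
#' supplied warm start), keeping the best residual.
#'
#' @param curves List of two `correlation_curve` objects (the two
#'   separations), sharing the lag grid and coherence factor.
#' @param L1,L2 Assumed thicknesses of layers 1 and 2, cm.
#' @param props List of three [optical_properties()] for layers 1..3.
#' @param bfi2 Fixed middle-layer flow, cm^2/s.
#' @param start Optional `c(sbfi, cbfi)` warm start; when given, the
#'   multi-start is skipped.
#' @param wavelength_nm,s_max,n_panels,nodes Forward-model settings, see
#'   [g1_three_layer()].
#' @return A `fit_result` with fields `sbfi`, `cbfi`, `residual`,
#'   `converged`, `n_iter`.
#' @export
fit_three_layer <- function(curves, L1, L2, props, bfi2 = 0, start = NULL,
                            wavelength_nm = DEFAULT_WAVELENGTH_NM,
                            s_max = 250, n_panels = 60, nodes = 10) {
  stopifnot(length(curves) == 2L,
            all(vapply(curves, inherits, TRUE, "correlation_curve")),
            L1 > 0, L2 > 0, length(props) == 3L)
  if (!isTRUE(all.equal(curves[[1]]$tau, curves[[2]]$tau)) ||
      curves[[1]]$beta != curves[[2]]$beta)
    stop("both curves must share the lag grid and coherence factor")
  tau <- curves[[1]]$tau
  beta <- curves[[1]]$beta
  rho <- vapply(curves, `[[`, 0, "separation")
  win <- lapply(curves, fit_window)
  if (any(vapply(win, length, 0L) < 3L))
    stop("fit window too short; curves carry no decay information")
  tau_union <- sort(unique(tau[unique(unlist(win))]))
  # map each curve's window lags into the union grid
  idx <- lapply(win, function(ix) match(tau[ix], tau_union))
  data_g2 <- lapply(seq_along(curves), function(i) curves[[i]]$g2[win[[i]]])
  k0 <- wavenumber(wavelength_nm, props[[1]]$n)
  quad <- hankel_quadrature(s_max, n_panels, nodes)

  residual_fun <- function(lp) {
    bf <- 10^lp
    stack <- layer_stack3(L1, L2, props[[1]], props[[2]], props[[3]],
                          bfi1 = bf[1], bfi2 = bfi2, bfi3 = bf[2])
    G <- three_layer_G1(rho, c(0, tau_union), stack, k0, quad)
    unlist(lapply(seq_along(curves), function(i) {
      g1 <- G[-1, i][idx[[i]]] / G[1, i]
      (1 + beta * g1^2) - data_g2[[i]]
    }))
  }

  starts <- if (is.null(start)) lapply(FIT_STARTS, function(s0) c(s0, s0))
            else list(pmin(pmax(start, FIT_BOUNDS[1]), FIT_BOUNDS[2]))
  best <- NULL
  for (s0 in starts) {
    fit <- run_lm(residual_fun, s0, FIT_BOUNDS[1], FIT_BOUNDS[2])
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(fit_result("three_layer", NA_real_, NA_real_, NA_real_, FALSE,
                      0L, "optimizer failed at every start"))
  bf <- 10^best$par
  init_dev <- sum(residual_fun(log10(starts[[1]]))^2)
  converged <- best$info %in% 1:4 && best$deviance <= init_dev
  fit_result("three_layer", cbfi = bf[2], sbfi = bf[1],
             residual = best$deviance, converged = converged,
             n_iter = best$niter, message = best$message)
}

#' Fit the homogeneous semi-infinite CDE model to a single g2 curve
#'
#' One-parameter least squares for the bulk blood flow index with
#' [g1_semi_infinite()], on the same 1%-of-intercept lag window.
#'
#' @param curve A `correlation_curve`.
#' @param props Bulk [optical_properties()].
#' @param start Optional warm-start BFi, cm^2/s.
#' @param wavelength_nm Wavelength for the optical wavenumber.
#' @return A `fit_result` (field `sbfi` is `NA`).
#' @export
fit_homogeneous <- function(curve, props, start = NULL,
                            wavelength_nm = DEFAULT_WAVELENGTH_NM) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(props, "optical_properties"))
  win <- fit_window(curve)
  if (length(win) < 3L)
    stop("fit window too short; curve carries no decay information")
  tau_fit <- curve$tau[win]
  data_g2 <- curve$g2[win]
  beta <- curve$beta
  rho <- curve$separation

  residual_fun <- function(lp) {
    g1 <- g1_semi_infinite(rho, tau_fit, props, 10^lp, wavelength_nm)
    (1 + beta * g1^2) - data_g2
  }

  starts <- if (is.null(start)) as.list(FIT_STARTS)
            else list(min(max(start, FIT_BOUNDS[1]), FIT_BOUNDS[2]))
  best <- NULL
  for (s0 in starts) {
    fit <- run_lm(residual_fun, s0, FIT_BOUNDS[1], FIT_BOUNDS[2])
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(fit_result("semi_infinite", NA_real_, NA_real_, NA_real_, FALSE,
                      0L, "optimizer failed at every start"))
  init_dev <- sum(residual_fun(log10(starts[[1]]))^2)
  converged <- best$info %in% 1:4 && best$deviance <= init_dev
  fit_result("semi_infinite", cbfi = 10^best$par, residual = best$deviance,
             converged = converged, n_iter = best$niter,
             message = best$message)
}
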