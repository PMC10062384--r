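## Error metrics and flow-grid sweeps: the quantities behind the study's
## boxplots (absolute CBFi percentage error, relative-change rCBFi error).

#' Signed percentage error of an estimate
#'
#' `(est - known) / known * 100`.
#'
#' @param est Estimated value(s).
#' @param known True value(s), > 0.
#' @return Signed percentage error.
#' @export
percent_error <- function(est, known) {
  if (any(known <= 0)) stop("known value must be positive")
  (est - known) / known * 100
}

#' Relative change versus the study baseline, in percent
#'
#' `rCBFi = (CBFi - CBFi0) / CBFi0 * 100`.
#'
#' @param value Flow index value(s), cm^2/s.
#' @param baseline List with `cbfi0` (see [baseline_flow()]).
#' @return Signed percent change.
#' @export
rcbfi <- function(value, baseline = baseline_flow()) {
  (value - baseline$cbfi0) / baseline$cbfi0 * 100
}

#' Error in estimated relative change, percentage points
#'
#' `rCBFi` computed from the estimated flows (at a grid point and at the
#' baseline point) minus the true `rCBFi`. A common multiplicative bias in
#' the estimates cancels exactly.
#'
#' @param est_pair `c(cbfi_est, cbfi0_est)`: estimate at the grid point and
#'   at the baseline point.
#' @param known_pair `c(cbfi, cbfi0)`: the corresponding true values.
#' @return Error in percentage points.
#' @export
rcbfi_error <- function(est_pair, known_pair) {
  stopifnot(all(est_pair > 0), all(known_pair > 0))
  (est_pair[1] / est_pair[2] - known_pair[1] / known_pair[2]) * 100
}

#' Boxplot-style summary of an error vector
#'
#' Median and quartiles (linear-interpolation quantiles), whiskers at the
#' most extreme points within 1.5 IQR of the quartiles, points beyond the
#' whiskers listed as outliers.
#'
#' @param errors Numeric vector (percent or percentage points).
#' @return List of class `error_summary`: `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi`, `n`, `outliers`.
#' @export
summarize_errors <- function(errors) {
  stopifnot(length(errors) >= 1L, all(is.finite(errors)))
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- errors >= lo_fence & errors <= hi_fence
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_lo = min(errors[inside]),
                 whisker_hi = max(errors[inside]),
                 n = length(errors),
                 outliers = sort(errors[!inside])),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> median %.2f [q25 %.2f, q75 %.2f], whiskers [%.2f, %.2f], n=%d, %d outlier(s)\n",
              x$median, x$q25, x$q75, x$whisker_lo, x$whisker_hi, x$n,
              length(x$outliers)))
  invisible(x)
}

# ----------------------------------------------------------- grid sweeps ----

#' Fit the three-layer model across a flow grid on one photon ensemble
#'
#' For every flow assignment, synthesizes g2 at both detectors from the
#' ensemble and fits the three-layer model. Fits are warm-started from the
#' previous grid point (the grid is ordered), falling back to the cold
#' multi-start whenever a warm-started fit fails to converge or lands at a
#' worse residual.
#'
#' @param ensemble A `photon_ensemble` with two detectors.
#' @param grid List of [flow_assignment()] (e.g. [make_flow_grid()]).
#' @param L1,L2 Assumed layer thicknesses for the fit, cm.
#' @param props List of three [optical_properties()] for the fit.
#' @param bfi2 Fixed middle-layer flow, cm^2/s.
#' @param tau Lag grid, s.
#' @param beta Coherence factor.
#' @param rho_fit Optional length-2 override of the separations used in the
#'   model (e.g. chord distances for a curved surface).
#' @param label Convention label copied into the output.
#' @param curves_list Optional precomputed list of curve pairs (one entry
#'   per grid point, as returned by [dcs_curves()]); lets several
#'   conventions share one synthesis pass.
#' @return `data.frame` with one row per grid point: true flows, fitted
#'   flows, residual, convergence flag.
#' @export
sweep_three_layer <- function(ensemble, grid, L1, L2, props, bfi2 = 0,
                              tau = default_tau(), beta = 0.5,
                              rho_fit = NULL, label = "three_layer",
                              curves_list = NULL) {
  warm <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    curves <- if (is.null(curves_list)) dcs_curves(ensemble, grid[[i]], tau, beta)
              else curves_list[[i]]
    if (!is.null(rho_fit))
      for (d in seq_along(curves)) curves[[d]]$separation <- rho_fit[d]
    fit <- fit_three_layer(curves, L1, L2, props, bfi2 = bfi2, start = warm)
    # periodic cold restarts guard against a warm chain drifting into a
    # secondary minimum; always used when the warm fit fails
    if (!fit$converged || is.null(warm) || (i - 1L) %% 6L == 0L) {
      cold <- fit_three_layer(curves, L1, L2, props, bfi2 = bfi2)
      if (!fit$converged ||
          (cold$converged && cold$residual < fit$residual)) fit <- cold
    }
    warm <- if (fit$converged) c(fit$sbfi, fit$cbfi) else NULL
    rows[[i]] <- data.frame(
      convention = label,
      cbfi_true = attr(grid[[i]], "cbfi"), sbfi_true = attr(grid[[i]], "sbfi"),
      cbfi_est = fit$cbfi, sbfi_est = fit$sbfi,
      residual = fit$residual, converged = fit$converged)
  }
  do.call(rbind, rows)
}

#' Fit the homogeneous model across a flow grid on one photon ensemble
#'
#' @inheritParams sweep_three_layer
#' @param props Bulk [optical_properties()] assumed in the fit.
#' @param detector Which detector's curve to fit (default the long,
#'   brain-sensitive separation).
#' @return `data.frame` as in [sweep_three_layer()] (`sbfi_est` is `NA`).
#' @export
sweep_homogeneous <- function(ensemble, grid, props, tau = default_tau(),
                              beta = 0.5, detector = 2L,
                              label = "homogeneous") {
  warm <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g1 <- g1_from_ensemble(ensemble, grid[[i]], tau, detector)
    curve <- to_g2(g1, tau, ensemble$layout$separations[detector], beta)
    fit <- fit_homogeneous(curve, props, start = warm)
    warm <- if (fit$converged) fit$cbfi else NULL
    rows[[i]] <- data.frame(
      convention = label,
      cbfi_true = attr(grid[[i]], "cbfi"), sbfi_true = attr(grid[[i]], "sbfi"),
      cbfi_est = fit$cbfi, sbfi_est = NA_real_,
      residual = fit$residual, converged = fit$converged)
  }
  do.call(rbind, rows)
}

#' Attach error metrics to a flow-grid sweep
#'
#' Adds the signed CBFi percentage error and, using the fitted value at the
#' baseline grid point as the estimated baseline, the error in estimated
#' rCBFi (percentage points).
#'
#' @param sweep Output of [sweep_three_layer()] or [sweep_homogeneous()].
#' @param baseline The true baseline flows, see [baseline_flow()].
#' @return The sweep with columns `cbfi_error_pct` and `rcbfi_error_pp`.
#' @export
grid_error_table <- function(sweep, baseline = baseline_flow()) {
  near <- function(a, b) abs(a - b) <= 1e-12 + 1e-9 * abs(b)
  out <- lapply(split(sweep, sweep$convention), function(df) {
    ib <- which(near(df$cbfi_true, baseline$cbfi0) &
                near(df$sbfi_true, baseline$sbfi0))
    if (length(ib) != 1L)
      stop("baseline grid point absent from sweep")
    df$cbfi_error_pct <- percent_error(df$cbfi_est, df$cbfi_true)
    df$rcbfi_error_pp <-
      (df$cbfi_est / df$cbfi_est[ib] - df$cbfi_true / df$cbfi_true[ib]) * 100
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ------------------------------------------------------------- run_study ----

#' Run a full simulate-fit-evaluate suite
#'
#' Orchestrates the study end to end for one suite: Monte Carlo transport
#' on each scenario, g2 synthesis for every flow-grid point, three-layer
#' fits under the requested conventions, and error summaries.
#'
#' @param config List with elements:
#'   * `suite`: `"csf"` (four-layer slabs, conventions `csf_layer2` /
#'     `csf_layer3`) or `"sphere"` (three-layer spheres, conventions
#'     `curve` / `line`);
#'   * `csf_thickness_mm` / `radii_cm`: scenarios to run;
#'   * `n_photons`, `seed`: transport budget per scenario;
#'   * optional `tau`, `beta`, `max_store`, `detector_shape`,
#'     `max_path_cm`, `grid`, `conventions`.
#' @return List with `per_point` (one row per scenario x convention x grid
#'   point, including error columns) and `summaries` (one row per scenario
#'   x convention x metric).
#' @export
run_study <- function(config) {
  suite <- match.arg(config$suite, c("csf", "sphere"))
  tau <- config$tau %||% default_tau()
  beta <- config$beta %||% 0.5
  grid <- config$grid %||% make_flow_grid()
  max_store <- config$max_store %||% 150000L
  shape <- config$detector_shape %||% "annulus"
  max_path <- config$max_path_cm %||% DEFAULT_MAX_PATH_CM
  fit_props <- standard_fit_props()
  per_point <- list()

  if (suite == "csf") {
    ths <- config$csf_thickness_mm %||% 1:4
    conventions <- config$conventions %||% c("csf_layer2", "csf_layer3")
    layout <- detector_layout(c(1, 2.5), distance_convention = "line")
    for (t_mm in ths) {
      geom <- make_csf_scenarios(t_mm)[[1]]
      ens <- simulate_slab(geom, layout, config$n_photons, config$seed,
                           max_path_cm = max_path, max_store = max_store,
                           detector_shape = shape)
      for (conv in conventions) {
        L2 <- if (conv == "csf_layer2") 0.6 + t_mm / 10 else 0.6
        sw <- sweep_three_layer(ens, grid, L1 = 0.6, L2 = L2, fit_props,
                                tau = tau, beta = beta, label = conv)
        sw <- cbind(scenario = sprintf("csf_%dmm", t_mm), sw)
        per_point[[length(per_point) + 1L]] <- grid_error_table(sw)
      }
    }
  } else {
    radii <- config$radii_cm %||% c(7, 8, 9, 10)
    conventions <- config$conventions %||% c("curve", "line")
    layout <- detector_layout(c(1, 2.5), distance_convention = "curve")
    for (R in radii) {
      geom <- make_sphere_scenarios(R)[[1]]
      ens <- simulate_sphere(geom, layout, config$n_photons, config$seed,
                             max_path_cm = max_path, max_store = max_store,
                             detector_shape = shape)
      for (conv in conventions) {
        rho_fit <- if (conv == "line")
          chord_distance(layout$separations, R) else NULL
        sw <- sweep_three_layer(ens, grid, L1 = 0.6, L2 = 0.6, fit_props,
                                tau = tau, beta = beta, rho_fit = rho_fit,
                                label = conv)
        sw <- cbind(scenario = sprintf("sphere_R%gcm", R), sw)
        per_point[[length(per_point) + 1L]] <- grid_error_table(sw)
      }
    }
  }

  per_point <- do.call(rbind, per_point)
  rownames(per_point) <- NULL
  summaries <- do.call(rbind, lapply(
    split(per_point, list(per_point$scenario, per_point$convention),
          drop = TRUE),
    function(df) {
      rbind(
        data.frame(scenario = df$scenario[1], convention = df$convention[1],
                   metric = "cbfi_error_pct",
                   t(unlist(summarize_errors(df$cbfi_error_pct)[
                     c("median", "q25", "q75", "whisker_lo", "whisker_hi", "n")]))),
        data.frame(scenario = df$scenario[1], convention = df$convention[1],
                   metric = "rcbfi_error_pp",
                   t(unlist(summarize_errors(df$rcbfi_error_pp)[
                     c("median", "q25", "q75", "whisker_lo", "whisker_hi", "n")]))))
    }))
  rownames(summaries) <- NULL
  list(per_point = per_point, summaries = summaries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
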