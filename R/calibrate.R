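# Calibration of the exit-count scaling law and of the chemotactic
# reduction factor beta(K_E), by iterative adjustment against steady-state
# runs.

#' Portal count required for steady state at one population
#'
#' Determines, by iterative adjustment, the (continuous) number of exit
#' portals whose egress flux balances the steady-state influx
#' `N / T_res`. Because the number of available sites always equals the
#' number of cells, the mean site occupancy is pinned at one and the
#' egress flux per portal is nearly independent of both the portal count
#' and transient population drift; measuring that per-portal flux in a
#' short run therefore gives `N_E* = (N / T_res) / flux_per_portal`
#' directly, and the fixed point is reached in two or three iterations.
#' A confirmation run at the rounded count can be requested to verify
#' that the population actually holds steady.
#'
#' @param N Target population.
#' @param trafficking,motility Parameter objects (`P_E`, `T_res_min`, ...).
#' @param K_E Susceptibility applied to *all* cells (0 for the base
#'   calibration; positive values feed [calibrate_beta()]).
#' @param n_iter Flux-matching iterations (default 3).
#' @param run_days Length of each measurement run (default 1).
#' @param burn_in_h Discarded start of each run (default 4).
#' @param confirm Also run a steady-state confirmation at the rounded
#'   count and report the population drift.
#' @param confirm_days Length of the confirmation run.
#' @return A list of class `"exit_count_calibration"`: `N_E` (continuous
#'   requirement), `N_E_rounded`, `flux_per_portal` (cells/min),
#'   `portal_occ` (mean portal-neighbourhood occupancy), and, if
#'   requested, `confirm_drift` (max relative deviation from `N`).
#' @examples
#' \donttest{
#' set.seed(1)
#' cal <- calibrate_exit_count(2000, run_days = 0.5)
#' }
#' @export
calibrate_exit_count <- function(N, trafficking = trafficking_params(),
                                 motility = motility_params(), K_E = 0,
                                 n_iter = 3, run_days = 1, burn_in_h = 4,
                                 confirm = FALSE, confirm_days = 3) {
  dt <- motility$dt_min
  # mean-field seed: flux ~= 27 * P_E * (mean occupancy 1) per portal-step
  ne <- max(1L, as.integer(round(
    N * dt / (trafficking$T_res_min * 27 * trafficking$P_E))))
  ne_star <- NA_real_
  phi <- NA_real_
  pocc <- NA_real_
  for (it in seq_len(n_iter)) {
    cfg <- simulation_config(
      N0 = N, duration_days = run_days, motility = motility,
      trafficking = trafficking, K_E_global = K_E,
      n_portals = ne, record_every_min = 60)
    sim <- run_simulation(cfg)
    win_min <- burn_in_h * 60
    exits <- sum(!is.na(sim$transits$exit_min) &
                   sim$transits$exit_min > win_min)
    dur <- run_days * 1440 - win_min
    phi <- exits / dur / ne
    keep <- sim$population$t_min > win_min
    pocc <- mean(sim$population$portal_occ[keep], na.rm = TRUE)
    ne_star <- (N / trafficking$T_res_min) / phi
    ne_new <- max(1L, as.integer(round(ne_star)))
    if (ne_new == ne && it > 1) break
    ne <- ne_new
  }
  out <- list(N = N, K_E = K_E, N_E = ne_star,
              N_E_rounded = max(1L, as.integer(round(ne_star))),
              flux_per_portal = phi, portal_occ = pocc,
              P_E = trafficking$P_E, T_res_min = trafficking$T_res_min)
  if (confirm) {
    cfg <- simulation_config(
      N0 = N, duration_days = confirm_days, motility = motility,
      trafficking = trafficking, K_E_global = K_E,
      n_portals = out$N_E_rounded, record_every_min = 60)
    sim <- run_simulation(cfg)
    out$confirm_drift <- max(abs(sim$population$n_cells - N)) / N
  }
  class(out) <- "exit_count_calibration"
  out
}

#' @export
print.exit_count_calibration <- function(x, ...) {
  cat(sprintf("<exit_count_calibration> N = %d, K_E = %g: N_E* = %.2f (round %d), flux/portal = %.4g cells/min\n",
              x$N, x$K_E, x$N_E, x$N_E_rounded, x$flux_per_portal))
  if (!is.null(x$confirm_drift)) {
    cat(sprintf("  confirmation run: max population drift %.1f%%\n",
                100 * x$confirm_drift))
  }
  invisible(x)
}

#' Calibrate the exit-count power law
#'
#' Runs [calibrate_exit_count()] over a span of populations and fits
#' `log(N_E * T_res) = log a + b log N` by least squares, yielding the
#' `(power_a, power_b)` constants of [required_exit_count()] (T_res in
#' minutes). The populations should span at least an order of magnitude;
#' the fitted exponent is close to 1 (a nearly linear law).
#'
#' @param N_values Populations to calibrate at.
#' @param trafficking,motility Parameter objects.
#' @param run_days Measurement-run length per population.
#' @return A list of class `"exit_calibration"`: `power_a`, `power_b`,
#'   `table` (tibble of per-N results with fit residuals), `fit` (the lm).
#' @examples
#' \donttest{
#' set.seed(1)
#' cal <- calibrate_exit_constants(c(1000, 2000, 4000), run_days = 0.5)
#' }
#' @export
calibrate_exit_constants <- function(N_values = c(2500, 5000, 10000, 20000),
                                     trafficking = trafficking_params(),
                                     motility = motility_params(),
                                     run_days = 1) {
  if (max(N_values) / min(N_values) < 4) {
    warning("`N_values` span less than ~an order of magnitude; ",
            "the fitted exponent will be poorly constrained")
  }
  rows <- lapply(N_values, function(N) {
    cal <- calibrate_exit_count(N, trafficking, motility,
                                run_days = run_days)
    tibble::tibble(N = N, N_E = cal$N_E,
                   flux_per_portal = cal$flux_per_portal,
                   portal_occ = cal$portal_occ)
  })
  tab <- dplyr::bind_rows(rows)
  fit <- stats::lm(log(N_E * trafficking$T_res_min) ~ log(N), data = tab)
  tab$residual <- stats::residuals(fit)
  out <- list(power_a = unname(exp(stats::coef(fit)[1L])),
              power_b = unname(stats::coef(fit)[2L]),
              table = tab, fit = fit,
              P_E = trafficking$P_E, T_res_min = trafficking$T_res_min)
  class(out) <- "exit_calibration"
  out
}

#' @export
print.exit_calibration <- function(x, ...) {
  cat(sprintf("<exit_calibration> N_E * T_res = %.5g * N^%.5g  (T_res in min, P_E = %g)\n",
              x$power_a, x$power_b, x$P_E))
  print(x$table)
  invisible(x)
}

#' Calibrate the chemotactic exit-count reduction factor
#'
#' With every cell attracted to the portals the per-portal egress flux
#' rises (cells crowd the neighbourhoods), so steady state needs fewer
#' portals. For each `K_E` the required portal count is calibrated with
#' all cells chemotactic and expressed as a fraction beta of the
#' non-chemotactic requirement; a quadratic is fitted to beta(K_E) and
#' values are clamped at 0.5, the saturation floor reached when portal
#' neighbourhoods are permanently at double occupancy.
#'
#' @param K_E_values Susceptibilities to calibrate at (include 0).
#' @param N Population used for the calibration runs.
#' @param trafficking,motility Parameter objects.
#' @param run_days Measurement-run length.
#' @return A list of class `"beta_calibration"`: `table` (tibble `K_E`,
#'   `N_E`, `beta`, `portal_occ`), `coeffs` (quadratic `(c0, c1, c2)`).
#' @export
calibrate_beta <- function(K_E_values = c(0, 1, 2, 3, 4, 5), N = 10000,
                           trafficking = trafficking_params(),
                           motility = motility_params(), run_days = 1) {
  if (!0 %in% K_E_values) K_E_values <- c(0, K_E_values)
  rows <- lapply(K_E_values, function(k) {
    cal <- calibrate_exit_count(N, trafficking, motility, K_E = k,
                                run_days = run_days)
    tibble::tibble(K_E = k, N_E = cal$N_E, portal_occ = cal$portal_occ)
  })
  tab <- dplyr::bind_rows(rows)
  base <- tab$N_E[tab$K_E == 0][1L]
  tab$beta <- pmax(tab$N_E / base, 0.5)
  fit <- stats::lm(beta ~ K_E + I(K_E^2), data = tab)
  out <- list(table = tab, coeffs = unname(stats::coef(fit)), N = N)
  class(out) <- "beta_calibration"
  out
}

#' @export
print.beta_calibration <- function(x, ...) {
  cat(sprintf("<beta_calibration> beta(K) ~ %.4f %+.4f K %+.4f K^2 (N = %d)\n",
              x$coeffs[1L], x$coeffs[2L], x$coeffs[3L], x$N))
  print(x$table)
  invisible(x)
}
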