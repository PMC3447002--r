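# Orchestration: configuration, the full per-step simulation, and the
# summary statistics derived from a run.

#' Simulation configuration
#'
#' Collects all run parameters. A configuration plus an RNG seed
#' (`set.seed()` before [run_simulation()]) reproduces a run exactly.
#'
#' The per-step composition, in order: (1) vascular/influx update,
#' (2) ingress, (3) motility + chemotaxis moves over cells in freshly
#' shuffled order, (4) forced resolution of doubly occupied sites,
#' (5) egress, (6) blob and portal bookkeeping, (7) recording.
#'
#' @param N0 Initial T cell population.
#' @param duration_days Simulated duration in days.
#' @param motility A [motility_params()] object.
#' @param trafficking A [trafficking_params()] object.
#' @param inflammation An [inflammation_params()] object.
#' @param K_E_global Chemotactic susceptibility of the bulk population.
#' @param tag_fraction Fraction of entrants tagged during the tag window.
#' @param tag_K_E Susceptibility given to tagged entrants.
#' @param tag_window_h Tag window from the start of the run, hours.
#' @param inflammation_level Held inflammation level in `[0, 1]`; 0 runs
#'   the uninflamed steady state with constant influx `N0 / T_res`.
#' @param hold_days,ramp_hours Inflammation schedule shape (see
#'   [inflammation_schedule()]).
#' @param n_portals Portal count: `"auto"` (default; maintained by the
#'   calibrated power law as the population changes) or a fixed integer.
#' @param portal_at_center Place a single portal at the blob centre and
#'   disable portal maintenance (the simplified single-portal scenario).
#' @param F_in Fixed influx override in cells/min, or `NULL`.
#' @param init_tag Optional list `list(n, radius, K_E)`: tag `n` cells
#'   within `radius` lattice units of the centre at time 0.
#' @param record_every_min Sampling interval of the recorded series.
#' @param headroom Lattice allowance for population growth (max cells =
#'   `headroom * N0`).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(N0 = 10000, duration_days = 5,
                              motility = motility_params(),
                              trafficking = trafficking_params(),
                              inflammation = inflammation_params(),
                              K_E_global = 0,
                              tag_fraction = 0, tag_K_E = 0,
                              tag_window_h = 48,
                              inflammation_level = 0,
                              hold_days = 3.5, ramp_hours = 24,
                              n_portals = "auto",
                              portal_at_center = FALSE,
                              F_in = NULL, init_tag = NULL,
                              record_every_min = 15, headroom = NULL) {
  stopifnot(N0 >= 1, duration_days >= 0, K_E_global >= 0,
            tag_fraction >= 0, tag_fraction <= 1)
  if (inflammation_level < 0 || inflammation_level > 1) {
    stop("`inflammation_level` must be in [0, 1]", call. = FALSE)
  }
  if (is.null(headroom)) {
    headroom <- if (inflammation_level > 0) {
      # the population self-limits near (1 + 8 * level) x N0
      1.6 * (1 + 8 * inflammation_level)
    } else 2
  }
  structure(list(
    N0 = as.integer(N0), duration_days = duration_days,
    motility = motility, trafficking = trafficking,
    inflammation = inflammation, K_E_global = K_E_global,
    tag_fraction = tag_fraction, tag_K_E = tag_K_E,
    tag_window_h = tag_window_h,
    inflammation_level = inflammation_level,
    hold_days = hold_days, ramp_hours = ramp_hours,
    n_portals = n_portals, portal_at_center = portal_at_center,
    F_in = F_in, init_tag = init_tag,
    record_every_min = record_every_min, headroom = headroom
  ), class = "simulation_config")
}

#' Run the agent-based simulation
#'
#' Executes the full per-step loop (see [simulation_config()] for the
#' step composition). Deterministic given a configuration and
#' `set.seed()`.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `"paracortex_sim"`: list with
#'   * `population` — tibble `t_min`, `n_cells`, `n_portals`, `V`, `A`,
#'     `F_in`, `portal_occ` (mean occupancy of portal neighbourhoods),
#'     `tagged_alive`;
#'   * `transits` — tibble `cell_id`, `entry_min`, `exit_min` (`NA` while
#'     the cell is still inside), `tagged`, `K_E`;
#'   * `portals` — final portal coordinates;
#'   * `counters` — bookkeeping exception counts;
#'   * `config` — the configuration.
#' @examples
#' set.seed(1)
#' sim <- run_simulation(simulation_config(N0 = 500, duration_days = 0.1))
#' sim
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mp <- config$motility
  tp <- config$trafficking
  ip <- config$inflammation
  dt <- mp$dt_min
  n_steps <- as.integer(round(config$duration_days * 1440 / dt))

  influx_mode <- if (config$inflammation_level > 0) 1L else 0L
  a_signal <- if (influx_mode == 1L && n_steps > 0L) {
    sched <- inflammation_schedule(config$inflammation_level,
                                   config$hold_days, config$ramp_hours)
    sched((seq_len(n_steps) - 1) * dt)
  } else numeric(0)

  portal_mode <- if (identical(config$n_portals, "auto")) 1L else 0L
  n_fixed <- if (portal_mode == 0L) as.integer(config$n_portals) else 0L
  exit_mult <- beta_exit_reduction(config$K_E_global, tp$beta_coeffs)

  it <- config$init_tag
  res <- cpp_run_simulation(
    config$N0, n_steps, dt, tp$T_res_min, tp$P_E,
    mp$p0, mp$kappa, config$K_E_global,
    config$tag_fraction, config$tag_K_E, config$tag_window_h * 60,
    portal_mode, n_fixed, isTRUE(config$portal_at_center),
    tp$power_a, tp$power_b, exit_mult,
    tp$cap_threshold, tp$min_separation, tp$entry_fraction,
    if (is.null(config$F_in)) -1 else config$F_in,
    influx_mode, a_signal,
    c(ip$alpha_G, ip$beta_G, ip$delta_G, ip$alpha_V, ip$beta_V, ip$n_V,
      ip$delta_V),
    config$headroom,
    max(1L, as.integer(round(config$record_every_min / dt))),
    if (is.null(it)) 0L else as.integer(it$n),
    if (is.null(it)) 0 else it$radius,
    if (is.null(it)) 0 else it$K_E,
    0.01)

  exit_min <- ifelse(res$transits$exit_step < 0, NA_real_,
                     res$transits$exit_step * dt)
  out <- list(
    population = tibble::tibble(
      t_min = res$series$t_min, n_cells = res$series$n_cells,
      n_portals = res$series$n_portals, V = res$series$V,
      A = res$series$A, F_in = res$series$F_in,
      portal_occ = res$series$portal_occ,
      tagged_alive = res$series$tagged_alive),
    transits = tibble::tibble(
      cell_id = res$transits$id,
      entry_min = res$transits$entry_step * dt,
      exit_min = exit_min,
      tagged = res$transits$tagged == 1L,
      K_E = res$transits$K_E),
    portals = tibble::tibble(x = res$portals$x, y = res$portals$y,
                             z = res$portals$z),
    counters = res$counters,
    config = config
  )
  class(out) <- "paracortex_sim"
  out
}

#' @export
print.paracortex_sim <- function(x, ...) {
  p <- x$population
  cat(sprintf("<paracortex_sim> N0 = %d, %.2f simulated days\n",
              x$config$N0, x$config$duration_days))
  cat(sprintf("  final population %d (%.1f%% of N0), %d portals\n",
              p$n_cells[nrow(p)], 100 * p$n_cells[nrow(p)] / x$config$N0,
              p$n_portals[nrow(p)]))
  cat(sprintf("  %d entries, %d exits recorded\n",
              as.integer(x$counters$total_entries),
              as.integer(x$counters$total_exits)))
  invisible(x)
}

#' Transit-time statistics
#'
#' Mean transit (residence) time and the transit-time histogram over
#' closed records of cells that entered after a burn-in, from a
#' steady-state run. Open records (cells still inside at the end) are
#' excluded and counted.
#'
#' @param transits A transit tibble (from a `"paracortex_sim"` or
#'   [run_simulation()]'s `$transits`), or a `"paracortex_sim"` itself.
#' @param burn_in_h Entries before this time are ignored (default 24).
#' @param entry_before_h Optionally also ignore entries after this time
#'   (limits right-censoring bias near the end of the run).
#' @param tagged_only Restrict to tagged cells.
#' @param bin_h Histogram bin width in hours (default 1).
#' @param min_records Error if fewer closed records remain.
#' @return A list of class `"transit_stats"`: `mean_min`, `mean_h`,
#'   `n_closed`, `n_open`, and `histogram` (tibble `bin_left_h`,
#'   `count`, `probability`).
#' @export
transit_statistics <- function(transits, burn_in_h = 24,
                               entry_before_h = Inf, tagged_only = FALSE,
                               bin_h = 1, min_records = 50) {
  if (inherits(transits, "paracortex_sim")) transits <- transits$transits
  sel <- transits$entry_min > burn_in_h * 60 &
    transits$entry_min <= entry_before_h * 60
  if (tagged_only) sel <- sel & transits$tagged
  rec <- transits[sel, , drop = FALSE]
  open <- sum(is.na(rec$exit_min))
  rec <- rec[!is.na(rec$exit_min), , drop = FALSE]
  if (nrow(rec) < min_records) {
    stop(sprintf("insufficient transit records: %d closed (need %d)",
                 nrow(rec), min_records), call. = FALSE)
  }
  tt_min <- rec$exit_min - rec$entry_min
  breaks <- seq(0, max(tt_min / 60, bin_h) + bin_h, by = bin_h)
  h <- graphics::hist(tt_min / 60, breaks = breaks, plot = FALSE)
  structure(list(
    mean_min = mean(tt_min), mean_h = mean(tt_min) / 60,
    n_closed = nrow(rec), n_open = open,
    histogram = tibble::tibble(bin_left_h = h$breaks[-length(h$breaks)],
                               count = h$counts,
                               probability = h$counts / sum(h$counts))
  ), class = "transit_stats")
}

#' @export
print.transit_stats <- function(x, ...) {
  cat(sprintf("<transit_stats> mean transit %.2f h over %d closed records (%d still inside)\n",
              x$mean_h, x$n_closed, x$n_open))
  invisible(x)
}

#' Single-portal retention scenario
#'
#' The simplified setting used to visualise chemotactic egress: a
#' steady-state blob with one exit portal at the centre; `n_tagged` cells
#' initially within `D` lattice units of the portal are given
#' susceptibility `K_E` while all other cells are non-chemotactic. The
#' influx is pinned at the single portal's mean-field egress capacity
#' (`27 * P_E` cells per step) so the population holds steady. Returns
#' the retention curve: tagged cells remaining against time.
#'
#' @param K_E Susceptibility of the tagged cells.
#' @param n_tagged Number of tagged cells (default 100).
#' @param D Initial tagging radius, lattice units (default 7).
#' @param duration_h Simulated hours (default 6).
#' @param N0 Blob size (default 10000).
#' @param trafficking,motility Parameter objects.
#' @return A tibble `t_min`, `t_h`, `tagged_remaining`, `K_E`.
#' @examples
#' \donttest{
#' set.seed(1)
#' ret <- single_portal_scenario(2, N0 = 2000, duration_h = 2)
#' }
#' @export
single_portal_scenario <- function(K_E, n_tagged = 100, D = 7,
                                   duration_h = 6, N0 = 10000,
                                   trafficking = trafficking_params(),
                                   motility = motility_params()) {
  f_in <- 27 * trafficking$P_E / motility$dt_min
  cfg <- simulation_config(
    N0 = N0, duration_days = duration_h / 24,
    motility = motility, trafficking = trafficking,
    portal_at_center = TRUE, F_in = f_in,
    init_tag = list(n = n_tagged, radius = D, K_E = K_E),
    record_every_min = 15)
  sim <- run_simulation(cfg)
  tibble::tibble(t_min = sim$population$t_min,
                 t_h = sim$population$t_min / 60,
                 tagged_remaining = sim$population$tagged_alive,
                 K_E = K_E)
}

#' Tagged-subset residence-time experiment
#'
#' Steady-state trafficking in which a randomly selected fraction of the
#' cells entering during an initial window is tagged and given chemotactic
#' susceptibility `K_E`, while the bulk population stays non-chemotactic.
#' Reports the tagged subset's mean transit time and distribution.
#'
#' @param K_E_subset Susceptibility of the tagged entrants.
#' @param fraction Tagged fraction of entrants (default 0.1).
#' @param window_h Tagging window from the start, hours (default 48).
#' @param N0 Population (default 10000).
#' @param duration_days Run length (default 10).
#' @param trafficking,motility Parameter objects.
#' @param burn_in_h Entries before this are excluded from statistics.
#' @return A list of class `"subset_experiment"`: `stats` (the tagged
#'   subset's `"transit_stats"`), `untagged_stats`, `sim`.
#' @export
tagged_subset_experiment <- function(K_E_subset, fraction = 0.1,
                                     window_h = 48, N0 = 10000,
                                     duration_days = 10,
                                     trafficking = trafficking_params(),
                                     motility = motility_params(),
                                     burn_in_h = 24) {
  cfg <- simulation_config(
    N0 = N0, duration_days = duration_days,
    motility = motility, trafficking = trafficking,
    tag_fraction = fraction, tag_K_E = K_E_subset,
    tag_window_h = window_h)
  sim <- run_simulation(cfg)
  tagged <- transit_statistics(sim, burn_in_h = burn_in_h,
                               entry_before_h = window_h,
                               tagged_only = TRUE, min_records = 30)
  untag <- sim$transits[!sim$transits$tagged, , drop = FALSE]
  untagged <- transit_statistics(untag, burn_in_h = burn_in_h,
                                 entry_before_h = window_h,
                                 min_records = 30)
  structure(list(K_E = K_E_subset, stats = tagged,
                 untagged_stats = untagged, sim = sim),
            class = "subset_experiment")
}

#' @export
print.subset_experiment <- function(x, ...) {
  cat(sprintf("<subset_experiment> K_E = %g: tagged subset mean transit %.2f h (untagged %.2f h)\n",
              x$K_E, x$stats$mean_h, x$untagged_stats$mean_h))
  invisible(x)
}
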