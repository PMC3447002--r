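# Inflammation -> growth factor -> vascularity -> T cell influx coupling,
# plus the deterministic mean-field population model used as a cross-check
# on the agent-based runs.

#' Growth-factor production rate
#'
#' Production of the generic growth factor G is a baseline rate
#' proportional to the initial population plus an inflammation-driven rate
#' proportional to the product of the initial population and the current
#' inflammation signal: `beta_G * N0 + alpha_G * N0 * A`.
#'
#' @param N0 Initial T cell population.
#' @param A Inflammation signal in `[0, 1]`.
#' @param params An [inflammation_params()] object.
#' @return Production rate in gfu/min.
#' @examples
#' production_rate(1e5, 0)   # baseline 5e-3 gfu/min
#' production_rate(1e5, 1)   # 9x baseline
#' @export
production_rate <- function(N0, A, params = inflammation_params()) {
  if (any(A < 0 | A > 1)) stop("`A` must lie in [0, 1]", call. = FALSE)
  params$beta_G * N0 + params$alpha_G * N0 * A
}

#' Hill saturation of the growth-factor concentration
#'
#' The vascularity growth rate saturates with the G concentration through
#' a Hill function. Concentrations are expressed relative to the
#' uninflamed equilibrium `C_G_eq = beta_G / delta_G`, so the
#' half-saturation constant `beta_V` is dimensionless:
#' `H = x^n / (x^n + beta_V^n)` with `x = C_G / C_G_eq`, `n = n_V`.
#'
#' @param C_G Growth-factor concentration, gfu/cell (`>= 0`).
#' @param params An [inflammation_params()] object.
#' @return H in `[0, 1)`.
#' @examples
#' p <- inflammation_params()
#' hill(p$beta_G / p$delta_G, p)  # at equilibrium concentration: 0.2
#' @export
hill <- function(C_G, params = inflammation_params()) {
  if (any(C_G < 0)) stop("`C_G` must be >= 0", call. = FALSE)
  cg_eq <- params$beta_G / params$delta_G
  x <- (C_G / cg_eq)^params$n_V
  x / (x + params$beta_V^params$n_V)
}

#' Vascularity decay rate from the equilibrium condition
#'
#' `delta_V` is not free: requiring `dV/dt = 0` at `V = 1` in the
#' uninflamed equilibrium (where `C_G = C_G_eq`) gives
#' `delta_V = alpha_V * H(C_G_eq)`.
#'
#' @param params A list with the inflammation parameters (before
#'   `delta_V` is attached).
#' @return Decay rate in 1/min.
#' @examples
#' derive_delta_V(inflammation_params())  # 2e-4
#' @export
derive_delta_V <- function(params) {
  cg_eq <- params$beta_G / params$delta_G
  x <- 1  # C_G_eq relative to itself
  H_eq <- x^params$n_V / (x^params$n_V + params$beta_V^params$n_V)
  params$alpha_V * H_eq
}

#' Initial vascular state
#'
#' The uninflamed equilibrium: `M_G = beta_G * N0 / delta_G`, `V = 1`.
#'
#' @inheritParams production_rate
#' @return A list with `M_G` (gfu) and `V`.
#' @export
vascular_state <- function(N0, params = inflammation_params()) {
  list(M_G = params$beta_G * N0 / params$delta_G, V = 1)
}

#' One Euler step of the vascular sub-model
#'
#' Explicit Euler at the lattice time step (all rates are at most 2e-3 per
#' minute, so stiffness is negligible; agreement with an adaptive
#' integrator is property-tested):
#' `M_G += dt (production - delta_G M_G)`; `C_G = M_G / N`;
#' `V += dt (alpha_V H(C_G) - delta_V) V`.
#'
#' @param state List with `M_G`, `V` (see [vascular_state()]).
#' @param N Current population (sets the fluid volume, hence `C_G`).
#' @param N0 Initial population (sets production).
#' @param A Inflammation signal in `[0, 1]`.
#' @param params An [inflammation_params()] object.
#' @param dt_min Step in minutes (default 0.25).
#' @return The updated state.
#' @export
step_vascular <- function(state, N, N0, A, params = inflammation_params(),
                          dt_min = 0.25) {
  if (state$V <= 0) stop("integration failure: V must stay positive",
                         call. = FALSE)
  state$M_G <- state$M_G +
    dt_min * (production_rate(N0, A, params) - params$delta_G * state$M_G)
  C_G <- state$M_G / N
  state$V <- state$V +
    dt_min * (params$alpha_V * hill(C_G, params) - params$delta_V) * state$V
  state
}

#' T cell influx rate from vascularity
#'
#' The relative vascularity scales the steady-state influx rate:
#' `F_in = V * N0 / T_res`.
#'
#' @param V Relative vascularity (`> 0`).
#' @param N0 Initial population.
#' @param T_res_min Residence time in minutes.
#' @return Influx rate, cells/min.
#' @examples
#' influx_rate(1, 1e5, 720)  # ~138.9 cells/min
#' @export
influx_rate <- function(V, N0, T_res_min) {
  if (any(V <= 0)) stop("`V` must be positive", call. = FALSE)
  V * N0 / T_res_min
}

#' Inflammation signal schedule
#'
#' The standard pulse: hold the signal at `level` for `hold_days`, ramp
#' linearly to zero over `ramp_hours`, zero afterwards. Returns a function
#' of time (minutes) vectorised over its argument.
#'
#' @param level Held level, in `[0, 1]`.
#' @param hold_days Days at the held level (default 3.5).
#' @param ramp_hours Ramp-down duration, hours (default 24).
#' @return A function `A(t_min)`.
#' @examples
#' A <- inflammation_schedule(1)
#' A(c(3, 4, 5) * 1440)  # 1.0, 0.5, 0
#' @export
inflammation_schedule <- function(level, hold_days = 3.5, ramp_hours = 24) {
  if (level < 0 || level > 1) stop("`level` must be in [0, 1]", call. = FALSE)
  hold_min <- hold_days * 1440
  ramp_min <- ramp_hours * 60
  function(t_min) {
    out <- ifelse(
      t_min < hold_min, level,
      ifelse(t_min < hold_min + ramp_min,
             level * (1 - (t_min - hold_min) / ramp_min), 0))
    as.numeric(out)
  }
}

#' Deterministic mean-field population trajectory
#'
#' Integrates the coupled ODE system — growth factor, vascularity and the
#' population balance `dN/dt = F_in(t) - N / T_res` — with an adaptive
#' high-accuracy integrator. This is the deterministic counterpart of an
#' agent-based run and is used as a cross-model check.
#'
#' @param N0 Initial population.
#' @param T_res_min Residence time, minutes.
#' @param schedule A function `A(t_min)`, e.g. from
#'   [inflammation_schedule()].
#' @param duration_days Length of the trajectory.
#' @param params An [inflammation_params()] object.
#' @param out_step_min Output sampling interval, minutes.
#' @return A tibble with columns `t_min`, `A`, `M_G`, `V`, `F_in`, `N`.
#' @examples
#' po <- population_ode(1e4, 720, inflammation_schedule(0.5), 10)
#' max(po$N) / 1e4
#' @export
population_ode <- function(N0, T_res_min, schedule = function(t) 0,
                           duration_days = 10,
                           params = inflammation_params(),
                           out_step_min = 60) {
  st <- vascular_state(N0, params)
  rhs <- function(t, y, parms) {
    A <- schedule(t)
    dM <- production_rate(N0, A, params) - params$delta_G * y[["M_G"]]
    C_G <- y[["M_G"]] / y[["N"]]
    dV <- (params$alpha_V * hill(C_G, params) - params$delta_V) * y[["V"]]
    F_in <- influx_rate(y[["V"]], N0, T_res_min)
    dN <- F_in - y[["N"]] / T_res_min
    list(c(dM, dV, dN))
  }
  times <- seq(0, duration_days * 1440, by = out_step_min)
  sol <- deSolve::ode(y = c(M_G = st$M_G, V = st$V, N = N0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  tibble::tibble(
    t_min = sol[, "time"], A = schedule(sol[, "time"]),
    M_G = sol[, "M_G"], V = sol[, "V"],
    F_in = influx_rate(sol[, "V"], N0, T_res_min), N = sol[, "N"]
  )
}

#' Euler time series of the vascular sub-model
#'
#' Fixed-step Euler integration of the growth-factor and vascularity
#' equations at the lattice time step, with the population held by the
#' caller-supplied function (defaults to constant `N0`). This mirrors
#' exactly what the agent-based engine computes internally.
#'
#' @inheritParams population_ode
#' @param N_of_t Function giving the population at time `t_min`.
#' @param dt_min Euler step, minutes.
#' @return A tibble with `t_min`, `A`, `M_G`, `V`, `F_in`.
#' @export
simulate_vascular <- function(N0, T_res_min, schedule = function(t) 0,
                              duration_days = 10,
                              params = inflammation_params(),
                              N_of_t = function(t) N0, dt_min = 0.25,
                              out_step_min = 60) {
  n_steps <- round(duration_days * 1440 / dt_min)
  st <- vascular_state(N0, params)
  keep_every <- max(1L, round(out_step_min / dt_min))
  n_out <- floor(n_steps / keep_every) + 1L
  out <- matrix(NA_real_, n_out, 4L)
  k <- 1L
  out[1L, ] <- c(0, schedule(0), st$M_G, st$V)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt_min
    st <- step_vascular(st, N_of_t(t), N0, schedule(t), params, dt_min)
    if (s %% keep_every == 0L) {
      k <- k + 1L
      out[k, ] <- c(s * dt_min, schedule(s * dt_min), st$M_G, st$V)
    }
  }
  tibble::tibble(t_min = out[, 1L], A = out[, 2L], M_G = out[, 3L],
                 V = out[, 4L],
                 F_in = influx_rate(out[, 4L], N0, T_res_min))
}
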