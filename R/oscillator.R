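#' Tissue length at time t
#'
#' Linear growth law `L(t) = L0 + g * t`. With the defaults (`L0 = 2`,
#' `g = 1`) this is the uniform-proliferation reference law `L(t) = t + 2`.
#'
#' @param t time (>= 0); vectorised.
#' @param params a [model_params()] object.
#' @return tissue length(s), same shape as `t`.
#' @examples
#' domain_length(0, model_params())  # 2
#' @export
domain_length <- function(t, params) {
  if (any(t < 0)) stop("domain_length: t must be non-negative")
  params$L0 + params$g * t
}

#' Relative proliferation rate at time t
#'
#' Under uniform (space-constant) proliferation the per-length growth rate
#' is `r(t) = L'(t) / L(t)`; for the linear law this is `g / (L0 + g*t)`,
#' i.e. `1 / (t + 2)` at the defaults, decreasing monotonically to zero.
#'
#' @inheritParams domain_length
#' @return relative growth rate(s).
#' @export
growth_rate <- function(t, params) {
  if (any(t < 0)) stop("growth_rate: t must be non-negative")
  params$g / (params$L0 + params$g * t)
}

#' Initial tissue state
#'
#' Builds the Lagrangian cell array at `t = 0`: `n_cells` material cells
#' spanning `[0, L0]`, all in phase at `phi0` (anterior at `x = 0`,
#' posterior at `x = L0`). In the distributed variant each cell carries a
#' conserved relative coordinate `rho = x / L(t)`; in the localized variant
#' cells are fixed in lab coordinates and carry their (deterministic)
#' progress-zone exit time.
#'
#' @param params a [model_params()] object.
#' @return an object of class `tissue_state`.
#' @export
init_tissue <- function(params) {
  n <- params$n_cells
  if (params$variant == "distributed_distance") {
    rho <- seq(0, 1, length.out = n)
    st <- list(
      t = 0, variant = params$variant,
      rho = rho, x = rho * params$L0,
      phi = rep(params$phi0, n),
      frozen = rep(FALSE, n), z_frozen = rep(NA_real_, n),
      freeze_time = rep(Inf, n),
      birth = rep(0, n)
    )
  } else {
    x <- seq(0, params$L0, length.out = n)
    # exit time of a fixed cell: L(t) - x > pz_width, exact for linear L;
    # cells nominally outside the zone at t = 0 are treated as exiting at 0
    # (every cell starts in phase at phi0)
    te <- if (params$g > 0) {
      pmax(0, (x + params$pz_width - params$L0) / params$g)
    } else {
      ifelse(params$L0 - x > params$pz_width, 0, Inf)
    }
    st <- list(
      t = 0, variant = params$variant,
      rho = x / params$L0, x = x,
      phi = rep(params$phi0, n),
      frozen = rep(FALSE, n), z_frozen = rep(NA_real_, n),
      freeze_time = rep(Inf, n),
      birth = rep(0, n),
      exit_time = te,
      exit_phase = params$phi0 + 2 * pi * te / params$T0
    )
  }
  structure(st, class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue_state (%s): %d cells at t = %g, %d frozen\n",
              x$variant, length(x$phi), x$t, sum(x$frozen)))
  invisible(x)
}

#' Advect cells on the uniformly growing tissue
#'
#' Advances time by `dt` and moves every cell so that its relative
#' coordinate `rho = x / L(t)` is exactly conserved (`x_new =
#' rho * L(t + dt)`), with the anterior end fixed at `x = 0`. Only defined
#' for the distributed-proliferation variant, where uniform growth makes
#' `rho` a material (Lagrangian) coordinate. Cell order and count are
#' preserved.
#'
#' @param state a `tissue_state`.
#' @param dt timestep.
#' @param params a [model_params()] object.
#' @return the updated `tissue_state` at `t + dt`.
#' @export
advect <- function(state, dt, params) {
  if (state$variant != "distributed_distance")
    stop("advect: only defined for the distributed_distance variant")
  state$t <- state$t + dt
  state$x <- state$rho * domain_length(state$t, params)
  state
}

#' Oscillation period of cells in the distributed-proliferation model
#'
#' `T(d) = T0 * (1 + A * d)` with `d = L(t) - x` the distance from the
#' posterior end: fastest oscillation (`T = T0`) at the posterior, slowest
#' at the anterior.
#'
#' @param state a `tissue_state` of the `distributed_distance` variant.
#' @param params a [model_params()] object.
#' @param cell_index optional single cell index. If supplied the period of
#'   that cell is returned and asking for a frozen cell is an error; if
#'   `NULL` the full per-cell vector is returned with `NA` at frozen cells.
#' @return period(s) in time units.
#' @export
oscillation_period <- function(state, params, cell_index = NULL) {
  if (state$variant != "distributed_distance")
    stop("oscillation_period: distance rule applies to the distributed_distance variant")
  d <- domain_length(state$t, params) - state$x
  per <- params$T0 * (1 + params$A * d)
  if (is.null(cell_index)) {
    per[state$frozen] <- NA_real_
    return(per)
  }
  if (state$frozen[cell_index])
    stop("oscillation_period: undefined for a frozen cell")
  per[cell_index]
}

#' Oscillation period as a function of cell age (progress-zone model)
#'
#' In the localized (progress-zone) variant, cells oscillate at the base
#' period `T0` while inside the zone and slow down with physiological age
#' `a` (time since zone exit): `T(a) = T0 * (1 + A * a)`.
#'
#' @param age time since leaving the progress zone (>= 0); vectorised.
#' @param params a [model_params()] object.
#' @return period(s) in time units.
#' @export
oscillation_period_age <- function(age, params) {
  if (any(age < 0)) stop("oscillation_period_age: age must be non-negative")
  params$T0 * (1 + params$A * age)
}

#' Cell state from phase
#'
#' `z = z_max * cos(phi)`: bounded by `±z_max`, period `2*pi` in the phase.
#'
#' @param phi phase in radians; vectorised.
#' @param params a [model_params()] object.
#' @return cell state(s) `z`.
#' @export
cell_state <- function(phi, params) params$z_max * cos(phi)

# instantaneous phase speed 2*pi/T along the exact trajectory,
# distributed variant: d(s) = u * L(s) for conserved u = 1 - rho
.rate_dist <- function(s, u, params) {
  2 * pi / (params$T0 * (1 + params$A * u * (params$g * s + params$L0)))
}

# phase speed for an exited progress-zone cell of age a
.rate_age <- function(a, params) {
  2 * pi / (params$T0 * (1 + params$A * a))
}

#' Advance oscillator phases over one timestep
#'
#' Integrates `dphi/dt = 2*pi / T` for every unfrozen cell over
#' `[t, t + dt]` along its exact material trajectory, using a fixed-step
#' 4th-order (Simpson) quadrature — the phase speed depends on time only,
#' since trajectories are exact. A cell whose period reaches the critical
#' value `B` inside the step has its phase advanced only up to the
#' threshold-crossing instant (the period is linear in time under the
#' linear growth law, so the crossing is resolved exactly); [freeze_update()]
#' then freezes it. Frozen cells are untouched. `state$t` is not modified:
#' advance time afterwards with [advect()] (or posterior addition in the
#' localized variant).
#'
#' @inheritParams advect
#' @return the `tissue_state` with updated phases.
#' @export
phase_step <- function(state, dt, params) {
  t0 <- state$t
  if (state$variant == "distributed_distance") {
    u <- 1 - state$rho
    T_now <- params$T0 * (1 + params$A * u * (params$g * t0 + params$L0))
    T_nxt <- params$T0 * (1 + params$A * u * (params$g * (t0 + dt) + params$L0))
    dt_eff <- rep(dt, length(u))
    cross <- !state$frozen & T_now < params$B & T_nxt >= params$B
    dt_eff[cross] <- dt * (params$B - T_now[cross]) /
      (T_nxt[cross] - T_now[cross])
    dt_eff[state$frozen | T_now >= params$B] <- 0
    dphi <- dt_eff / 6 * (.rate_dist(t0, u, params) +
                          4 * .rate_dist(t0 + dt_eff / 2, u, params) +
                          .rate_dist(t0 + dt_eff, u, params))
    state$phi <- state$phi + dphi
  } else {
    state$phi <- state$phi +
      .dphi_localized(t0, dt, state$exit_time, state$frozen, params)
  }
  state
}

# phase increment over [t0, t0+dt] for localized-variant cells: constant
# speed 2*pi/T0 while in the zone, age rule after exit, stop at the freeze
# age a* = (B-T0)/(A*T0)
.dphi_localized <- function(t0, dt, exit_time, frozen, params) {
  t1 <- t0 + dt
  a_star <- .d_star(params)
  zone_len <- pmax(0, pmin(t1, exit_time) - t0)
  dphi <- 2 * pi * zone_len / params$T0
  a_lo <- pmax(0, t0 - exit_time)
  a_hi <- pmax(0, pmin(t1, exit_time + a_star) - exit_time)
  len <- pmax(0, a_hi - a_lo)
  pos <- len > 0
  if (any(pos)) {
    al <- a_lo[pos]; ln <- len[pos]
    dphi[pos] <- dphi[pos] + ln / 6 * (.rate_age(al, params) +
                                       4 * .rate_age(al + ln / 2, params) +
                                       .rate_age(al + ln, params))
  }
  dphi[frozen] <- 0
  dphi
}

#' Freeze cells whose period has reached the critical value
#'
#' Any unfrozen cell whose current period is `>= B` becomes frozen: its
#' state `z_frozen` is fixed at `z_max * cos(phi)` (the phase having been
#' advanced exactly to the crossing instant by [phase_step()]) and never
#' changes afterwards. Re-checking an already frozen cell is a no-op.
#' The recorded `freeze_time` is the exact threshold-crossing time, which
#' is available in closed form because the period is linear in time.
#'
#' @param state a `tissue_state`.
#' @param params a [model_params()] object.
#' @return the updated `tissue_state`.
#' @export
freeze_update <- function(state, params) {
  d_star <- .d_star(params)
  if (state$variant == "distributed_distance") {
    u <- 1 - state$rho
    d <- u * domain_length(state$t, params)
    newly <- !state$frozen & d >= d_star - 1e-12
    if (any(newly)) {
      tc <- if (params$g > 0) {
        pmax(0, (d_star / u[newly] - params$L0) / params$g)
      } else {
        rep(0, sum(newly))
      }
      state$freeze_time[newly] <- pmin(tc, state$t)
    }
  } else {
    age <- state$t - state$exit_time
    newly <- !state$frozen & age >= d_star - 1e-12
    if (any(newly))
      state$freeze_time[newly] <-
        pmin(state$exit_time[newly] + d_star, state$t)
  }
  if (any(newly)) {
    state$z_frozen[newly] <- cell_state(state$phi[newly], params)
    state$frozen[newly] <- TRUE
  }
  state
}

#' Freeze time of a material cell (closed form, uniform growth)
#'
#' Analytic oracle for the distributed variant under the linear growth law.
#' A cell at conserved relative distance `u = 1 - rho` from the posterior
#' sits at distance `d(t) = u * L(t)` and freezes when `d` reaches
#' `d* = (B - T0) / (A * T0)`, i.e. at `t_f(u) = (d*/u - L0) / g`. The
#' posterior end (`u = 0`) never freezes.
#'
#' @param u relative distance from the posterior end, in `(0, 1]`;
#'   vectorised.
#' @param params a [model_params()] object.
#' @return freeze time(s); `Inf` where the cell never freezes.
#' @export
closed_form_freeze_time <- function(u, params) {
  if (any(u <= 0) || any(u > 1))
    stop("closed_form_freeze_time: u must lie in (0, 1]")
  d_star <- .d_star(params)
  if (params$g == 0) {
    return(ifelse(u * params$L0 >= d_star, 0, Inf))
  }
  pmax(0, (d_star / u - params$L0) / params$g)
}

#' Accumulated cycles at freezing (closed form, uniform growth)
#'
#' Integral of the instantaneous frequency `1/T(d(t))` along the exact
#' trajectory `d(t) = u * (g*t + L0)` up to the freeze time:
#' `N(u) = 1/(T0*A*u*g) * log((1 + A*d*) / (1 + A*L0*u))` cycles, with
#' `d* = (B - T0)/(A*T0)`. At the reference parameters this is
#' `N(u) = (2/u) * log(5 / (1 + u))`, strictly decreasing in `u`.
#'
#' @inheritParams closed_form_freeze_time
#' @return accumulated oscillation cycles at the freezing instant.
#' @export
closed_form_freeze_phase <- function(u, params) {
  if (any(u <= 0) || any(u > 1))
    stop("closed_form_freeze_phase: u must lie in (0, 1]")
  if (params$g == 0)
    stop("closed_form_freeze_phase: undefined for a non-growing tissue")
  d_star <- .d_star(params)
  log((1 + params$A * d_star) / (1 + params$A * params$L0 * u)) /
    (params$T0 * params$A * u * params$g)
}
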