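#' Simulate the oscillator tissue and build its kymograph
#'
#' Runs the full model from `t = 0` to `t_end`: phase integration along
#' exact material trajectories, advection (distributed variant) or
#' posterior cell addition (localized variant), and freezing, sampling the
#' cell-state field onto a fixed space-time grid. Deterministic for fixed
#' parameters.
#'
#' In the localized variant the tissue grows purely by posterior addition:
#' existing cells keep their lab position and a new in-phase cell is
#' appended whenever the gap between the last cell and `L(t)` exceeds the
#' initial cell spacing, so spatial resolution never degrades below the
#' initial spacing.
#'
#' @param params a [model_params()] object.
#' @param record_dt sampling interval of the kymograph rows (time units).
#' @param n_bins number of lab-coordinate bins spanning `[0, L(t_end)]`.
#' @return An object of class `kymograph`: a list with
#' \describe{
#'   \item{times}{sampled times (strictly increasing, starts at 0).}
#'   \item{space_bins}{bin centres of the `n_bins` half-open lab bins.}
#'   \item{z_grid}{`length(times) x n_bins` matrix of cell state `z`;
#'     `NA` marks bins outside the tissue at that time.}
#'   \item{lengths}{`L(t)` at each sampled time.}
#'   \item{frozen_front}{two-column matrix (`lo`, `hi`): lab extent of the
#'     frozen (segmented) region at each sampled time, `NA` when empty.}
#'   \item{cells}{per-cell record: material coordinate `mat` (`rho` for the
#'     distributed variant, lab `x` for the localized one), `birth`,
#'     `freeze_time` (`Inf` if still oscillating at `t_end`),
#'     `freeze_phase` and `z_frozen` (`NA` if unfrozen), plus `exit_time`
#'     for the localized variant.}
#'   \item{params}{the parameters used.}
#' }
#' @examples
#' p <- model_params(t_end = 8, dt = 0.05, n_cells = 100)
#' k <- simulate_tissue(p, record_dt = 0.5, n_bins = 50)
#' range(k$lengths)
#' @export
simulate_tissue <- function(params, record_dt = 0.1, n_bins = 200) {
  stopifnot(record_dt >= params$dt, n_bins >= 10)
  if (params$variant == "distributed_distance") {
    kym <- .simulate_distributed(params, record_dt, n_bins)
  } else {
    kym <- .simulate_localized(params, record_dt, n_bins)
  }
  zmax_seen <- max(abs(kym$z_grid), na.rm = TRUE)
  if (zmax_seen > params$z_max + 1e-6)
    stop("simulate_tissue: internal instability, |z| exceeded z_max")
  kym
}

.kymo_grid <- function(params, record_dt, n_bins) {
  n_steps <- max(1L, round(params$t_end / params$dt))
  k_rec <- max(1L, round(record_dt / params$dt))
  rec_steps <- c(0L, seq(k_rec, n_steps, by = k_rec))
  if (rec_steps[length(rec_steps)] != n_steps)
    rec_steps <- c(rec_steps, n_steps)
  l_max <- domain_length(params$t_end, params)
  list(n_steps = n_steps, rec_steps = rec_steps,
       times = rec_steps * params$dt,
       centers = (seq_len(n_bins) - 0.5) * l_max / n_bins)
}

# sample per-cell z onto the lab bins; NA beyond the tissue
.kymo_row <- function(x, z, centers, L) {
  row <- rep(NA_real_, length(centers))
  inside <- centers <= L
  if (any(inside))
    row[inside] <- stats::approx(x, z, xout = centers[inside], rule = 2)$y
  row
}

.front_of <- function(x, frozen) {
  if (!any(frozen)) c(NA_real_, NA_real_)
  else c(min(x[frozen]), max(x[frozen]))
}

.simulate_distributed <- function(params, record_dt, n_bins) {
  gr <- .kymo_grid(params, record_dt, n_bins)
  state <- init_tissue(params)
  state <- freeze_update(state, params)  # g = 0 tissues may freeze at t = 0
  n_rec <- length(gr$rec_steps)
  z_grid <- matrix(NA_real_, n_rec, n_bins)
  lengths <- numeric(n_rec)
  front <- matrix(NA_real_, n_rec, 2, dimnames = list(NULL, c("lo", "hi")))
  rec <- function(i) {
    z <- ifelse(state$frozen, state$z_frozen, cell_state(state$phi, params))
    z_grid[i, ] <<- .kymo_row(state$x, z, gr$centers,
                              domain_length(state$t, params))
    lengths[i] <<- domain_length(state$t, params)
    front[i, ] <<- .front_of(state$x, state$frozen)
  }
  rec(1L)
  ri <- 2L
  for (s in seq_len(gr$n_steps)) {
    state <- phase_step(state, params$dt, params)
    state <- advect(state, params$dt, params)
    state <- freeze_update(state, params)
    if (ri <= n_rec && s == gr$rec_steps[ri]) {
      rec(ri)
      ri <- ri + 1L
    }
  }
  cells <- data.frame(
    mat = state$rho,
    birth = state$birth,
    freeze_time = state$freeze_time,
    freeze_phase = ifelse(state$frozen, state$phi, NA_real_),
    z_frozen = state$z_frozen
  )
  structure(list(times = gr$times, space_bins = gr$centers, z_grid = z_grid,
                 lengths = lengths, frozen_front = front, cells = cells,
                 params = params),
            class = "kymograph")
}

.simulate_localized <- function(params, record_dt, n_bins) {
  gr <- .kymo_grid(params, record_dt, n_bins)
  spacing <- params$L0 / (params$n_cells - 1)
  cap <- params$n_cells +
    as.integer(ceiling(params$g * params$t_end / spacing)) + 16L
  x <- phi <- z_frozen <- freeze_time <- exit_time <- birth <-
    rep(NA_real_, cap)
  frozen <- rep(FALSE, cap)
  st0 <- init_tissue(params)
  n <- params$n_cells
  idx <- seq_len(n)
  x[idx] <- st0$x; phi[idx] <- st0$phi
  exit_time[idx] <- st0$exit_time
  freeze_time[idx] <- Inf; birth[idx] <- 0
  n_rec <- length(gr$rec_steps)
  z_grid <- matrix(NA_real_, n_rec, n_bins)
  lengths <- numeric(n_rec)
  front <- matrix(NA_real_, n_rec, 2, dimnames = list(NULL, c("lo", "hi")))
  d_star <- .d_star(params)
  t <- 0
  rec <- function(i) {
    j <- seq_len(n)
    z <- ifelse(frozen[j], z_frozen[j], cell_state(phi[j], params))
    z_grid[i, ] <<- .kymo_row(x[j], z, gr$centers, domain_length(t, params))
    lengths[i] <<- domain_length(t, params)
    front[i, ] <<- .front_of(x[j], frozen[j])
  }
  rec(1L)
  ri <- 2L
  for (s in seq_len(gr$n_steps)) {
    j <- seq_len(n)
    phi[j] <- phi[j] +
      .dphi_localized(t, params$dt, exit_time[j], frozen[j], params)
    t <- s * params$dt
    # posterior addition: keep the zone populated at the initial spacing
    L_now <- domain_length(t, params)
    while (L_now - x[n] >= spacing) {
      n <- n + 1L
      x[n] <- x[n - 1L] + spacing
      exit_time[n] <- (x[n] + params$pz_width - params$L0) / params$g
      phi[n] <- params$phi0 + 2 * pi * t / params$T0  # zone common phase
      freeze_time[n] <- Inf
      birth[n] <- t
      frozen[n] <- FALSE
    }
    j <- seq_len(n)
    age <- t - exit_time[j]
    newly <- j[!frozen[j] & age >= d_star - 1e-12]
    if (length(newly)) {
      freeze_time[newly] <- pmin(exit_time[newly] + d_star, t)
      z_frozen[newly] <- cell_state(phi[newly], params)
      frozen[newly] <- TRUE
    }
    if (ri <= n_rec && s == gr$rec_steps[ri]) {
      rec(ri)
      ri <- ri + 1L
    }
  }
  j <- seq_len(n)
  cells <- data.frame(
    mat = x[j],
    birth = birth[j],
    freeze_time = freeze_time[j],
    freeze_phase = ifelse(frozen[j], phi[j], NA_real_),
    z_frozen = z_frozen[j],
    exit_time = exit_time[j]
  )
  structure(list(times = gr$times, space_bins = gr$centers, z_grid = z_grid,
                 lengths = lengths, frozen_front = front, cells = cells,
                 params = params),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  nf <- sum(is.finite(x$cells$freeze_time))
  cat(sprintf("kymograph (%s): %d times x %d bins, L in [%g, %g]\n",
              x$params$variant, length(x$times), length(x$space_bins),
              min(x$lengths), max(x$lengths)))
  cat(sprintf("  %d cells tracked, %d frozen by t = %g\n",
              nrow(x$cells), nf, max(x$times)))
  invisible(x)
}
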