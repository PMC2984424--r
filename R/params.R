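#' Parameters of the cellular-oscillator segmentation model
#'
#' Bundles every constant of the oscillator/growth system into a validated
#' list. The defaults are the reference parameter set for the
#' distributed-proliferation model on a linearly growing tissue:
#' `A = 0.5`, `B = 5`, `T0 = 1`, `L(t) = t + 2` over `0 < t < 50`, with the
#' cell state bounded by `|z| <= 10`.
#'
#' The oscillation period of an unfrozen cell is
#' `T(d) = T0 * (1 + A * d)` in the `distributed_distance` variant, where
#' `d` is the cell's distance from the posterior end, and
#' `T(a) = T0 * (1 + A * a)` in the `localized_age` variant, where `a` is
#' the time since the cell left the posterior progress zone. A cell freezes
#' (segments) when its period reaches the critical value `B`; its state
#' `z = z_max * cos(phi)` then stays constant.
#'
#' @param A period-gradient coefficient (> 0). Per unit tissue length in the
#'   distance variant, per unit time of age in the age variant.
#' @param B critical period at which oscillation arrests (time units,
#'   `B > T0`).
#' @param T0 base oscillation period at the posterior end / inside the
#'   progress zone (time units, > 0).
#' @param z_max cell-state amplitude bound (dimensionless, > 0).
#' @param L0 initial tissue length (length units, > 0).
#' @param g tissue growth speed: `L(t) = L0 + g * t` (>= 0; `g = 0` gives a
#'   non-growing tissue).
#' @param t_end simulation horizon (time units, > 0).
#' @param dt integration timestep (time units; must satisfy
#'   `dt <= T0 / 20`).
#' @param n_cells initial number of material cells (>= 50).
#' @param variant `"distributed_distance"` (uniform proliferation, period
#'   set by distance from the posterior) or `"localized_age"` (posterior
#'   progress zone, period set by cell age after zone exit).
#' @param pz_width progress-zone width (length units; only used by the
#'   `localized_age` variant, defaults to `L0`).
#' @param phi0 initial phase shared by all cells (radians).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' p$A
#' model_params(variant = "localized_age", n_cells = 400)
#' @export
model_params <- function(A = 0.5, B = 5, T0 = 1, z_max = 10, L0 = 2,
                         g = 1, t_end = 50, dt = 0.01, n_cells = 2000,
                         variant = c("distributed_distance", "localized_age"),
                         pz_width = L0, phi0 = 0) {
  variant <- match.arg(variant)
  stopifnot(
    "A must be > 0" = is.numeric(A) && length(A) == 1 && A > 0,
    "T0 must be > 0" = is.numeric(T0) && length(T0) == 1 && T0 > 0,
    "B must exceed T0" = is.numeric(B) && length(B) == 1 && B > T0,
    "z_max must be > 0" = is.numeric(z_max) && length(z_max) == 1 && z_max > 0,
    "L0 must be > 0" = is.numeric(L0) && length(L0) == 1 && L0 > 0,
    "g must be >= 0" = is.numeric(g) && length(g) == 1 && g >= 0,
    "t_end must be > 0" = is.numeric(t_end) && length(t_end) == 1 && t_end > 0,
    "dt must be > 0" = is.numeric(dt) && length(dt) == 1 && dt > 0,
    "dt must be <= T0/20" = dt <= T0 / 20,
    "n_cells must be >= 50" = is.numeric(n_cells) && length(n_cells) == 1 &&
      n_cells >= 50,
    "phi0 must be a number" = is.numeric(phi0) && length(phi0) == 1
  )
  if (variant == "localized_age") {
    stopifnot("pz_width must be > 0" = is.numeric(pz_width) &&
                length(pz_width) == 1 && pz_width > 0)
  }
  structure(
    list(A = A, B = B, T0 = T0, z_max = z_max, L0 = L0, g = g,
         t_end = t_end, dt = dt, n_cells = as.integer(n_cells),
         variant = variant, pz_width = pz_width, phi0 = phi0),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cellular-oscillator model parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  period rule: T = T0*(1 + A*%s), freeze at T >= B\n",
              if (x$variant == "distributed_distance") "d" else "age"))
  cat(sprintf("  A=%g  B=%g  T0=%g  z_max=%g\n", x$A, x$B, x$T0, x$z_max))
  cat(sprintf("  growth: L(t) = %g + %g*t,  t in [0, %g],  dt=%g\n",
              x$L0, x$g, x$t_end, x$dt))
  cat(sprintf("  n_cells=%d  phi0=%g", x$n_cells, x$phi0))
  if (x$variant == "localized_age") cat(sprintf("  pz_width=%g", x$pz_width))
  cat("\n")
  invisible(x)
}

# distance from the posterior end (or age) at which the period reaches B
.d_star <- function(params) (params$B - params$T0) / (params$A * params$T0)
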