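test_that("linear growth law and uniform proliferation rate", {
  p <- ref_params()
  expect_identical(domain_length(0, p), 2)
  expect_identical(domain_length(48, p), 50)
  expect_identical(domain_length(0, model_params(L0 = 5)), 5)
  expect_error(domain_length(-1, p), "non-negative")
  tt <- seq(0, 50, by = 0.5)
  expect_true(all(diff(domain_length(tt, p)) > 0))
  # r(t) = L'(t)/L(t) = 1/(t + 2), monotonically decreasing to 0
  expect_equal(growth_rate(0, p), 0.5)
  expect_equal(growth_rate(8, p), 0.1)
  expect_true(all(diff(growth_rate(tt, p)) < 0))
  expect_lt(growth_rate(1e6, p), 1e-5)
  # non-growing tissue
  p0 <- model_params(g = 0)
  expect_identical(domain_length(c(0, 10, 40), p0), rep(2, 3))
  expect_identical(growth_rate(5, p0), 0)
})

test_that("advection conserves the material coordinate and cell order", {
  p <- ref_params()
  st <- init_tissue(p)
  st2 <- advect(st, 50, p)
  expect_equal(st2$x[st2$rho == 0], 0)              # anterior fixed point
  expect_equal(st2$x[st2$rho == 1], 52)             # rho * L(50)
  expect_identical(st2$rho, st$rho)                 # exactly conserved
  expect_true(all(diff(st2$x) > 0))                 # order preserved
  expect_length(st2$x, p$n_cells)
  st_loc <- init_tissue(model_params(variant = "localized_age"))
  expect_error(advect(st_loc, 1, p), "distributed_distance")
})

test_that("oscillation period follows the distance and age rules", {
  p <- ref_params()
  st <- init_tissue(p)
  # posterior cell: d = 0 => T = T0 = 1; anterior cell of the t=0 tissue:
  # d = L0 = 2 => T = 2
  per <- oscillation_period(st, p)
  expect_equal(per[p$n_cells], 1)
  expect_equal(per[1], 2)
  expect_true(all(diff(per) < 0))  # maximal at the anterior end
  # the freezing threshold sits at d* = (B - T0)/(A*T0) = 8:
  # at t = 6, L = 8 and the anterior cell (x = 0) has period exactly B
  st$t <- 6
  st$x <- st$rho * domain_length(st$t, p)
  expect_equal(oscillation_period(st, p, cell_index = 1), 5)  # = B
  st$frozen[1] <- TRUE
  expect_error(oscillation_period(st, p, cell_index = 1), "frozen")
  expect_true(is.na(oscillation_period(st, p)[1]))
  # age rule
  expect_equal(oscillation_period_age(0, p), 1)
  expect_equal(oscillation_period_age(2, p), 2)
  expect_equal(oscillation_period_age(8, p), 5)     # freeze age a* = 8
  expect_error(oscillation_period_age(-1, p), "non-negative")
})

test_that("cell state is a bounded cosine of the phase", {
  p <- ref_params()
  expect_equal(cell_state(0, p), 10)
  expect_equal(cell_state(pi, p), -10)
  expect_equal(cell_state(pi / 2, p), 0)
  phi <- seq(-20, 20, by = 0.01)
  expect_true(all(abs(cell_state(phi, p)) <= p$z_max))
  expect_equal(cell_state(phi + 2 * pi, p), cell_state(phi, p))
})

test_that("phase advances by one cycle per period and stops when frozen", {
  p <- ref_params()
  st <- init_tissue(p)
  n <- p$n_cells
  st2 <- phase_step(st, p$T0, p)
  # posterior cell (d = 0) oscillates at exactly T0
  expect_equal(st2$phi[n] - st$phi[n], 2 * pi)
  st$frozen[1] <- TRUE
  st3 <- phase_step(st, 1, p)
  expect_identical(st3$phi[1], st$phi[1])
})

test_that("closed-form freeze time and phase match independent quadrature", {
  p <- ref_params()
  # threshold-distance oracle d* = 8: t_f(u) = 8/u - 2
  expect_equal(closed_form_freeze_time(1, p), 6)
  expect_equal(closed_form_freeze_time(0.5, p), 14)
  expect_gt(closed_form_freeze_time(1e-6, p), 7e6)  # posterior never freezes
  expect_error(closed_form_freeze_time(0, p), "\\(0, 1]")
  expect_error(closed_form_freeze_phase(-0.1, p), "\\(0, 1]")
  # N(u) = (2/u) log(5/(1+u)) at the reference constants
  expect_equal(closed_form_freeze_phase(1, p), 2 * log(2.5), tolerance = 1e-12)
  expect_equal(closed_form_freeze_phase(0.5, p), 4 * log(10 / 3),
               tolerance = 1e-12)
  # independent oracle: numerical quadrature of 1/T along d(t) = u*(t + L0)
  for (u in c(1, 0.7, 0.4, 0.2)) {
    nq <- stats::integrate(function(s) 1 / (p$T0 * (1 + p$A * u * (s + p$L0))),
                           0, closed_form_freeze_time(u, p),
                           rel.tol = 1e-10)$value
    expect_equal(closed_form_freeze_phase(u, p), nq, tolerance = 1e-8)
  }
  # strictly decreasing in u
  ug <- seq(0.05, 1, by = 0.01)
  expect_true(all(diff(closed_form_freeze_phase(ug, p)) < 0))
})

test_that("freezing starts only once the tissue outgrows the threshold", {
  p <- ref_params()
  st <- freeze_update(init_tissue(p), p)
  expect_false(any(st$frozen))   # max d = L0 = 2 < d* = 8 at t = 0
  # place the tissue at t = 6 where the anterior cell reaches d* exactly
  st$t <- 6
  st$x <- st$rho * domain_length(st$t, p)
  st2 <- freeze_update(st, p)
  expect_true(st2$frozen[1])
  expect_equal(st2$freeze_time[1], 6)
  expect_equal(st2$z_frozen[1], cell_state(st2$phi[1], p))
  # idempotent on an already frozen cell
  st3 <- freeze_update(st2, p)
  expect_identical(st3$z_frozen[1], st2$z_frozen[1])
  expect_identical(st3$freeze_time[1], st2$freeze_time[1])
})
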