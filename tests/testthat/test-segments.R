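test_that("band detection on prescribed frozen profiles", {
  # fully frozen tissue with constant positive state: a single band
  mat <- seq(0, 4, by = 0.01)
  k1 <- synthetic_kymo(mat, z_frozen = rep(3, length(mat)),
                       freeze_time = seq(0.1, 1, length.out = length(mat)))
  tab1 <- band_labels(k1, 1)
  expect_identical(nrow(tab1), 1L)
  expect_identical(tab1$sign, 1)
  # two complete bands of widths (3, 1) plus the growing posterior run
  z <- ifelse(mat < 3, 1, ifelse(mat < 4, -1, 1))
  mat2 <- c(mat, seq(4.01, 4.5, by = 0.01))
  z2 <- c(z, rep(1, length(mat2) - length(mat)))
  k2 <- synthetic_kymo(mat2, z_frozen = z2,
                       freeze_time = seq(0.1, 1, length.out = length(mat2)))
  tab2 <- band_labels(k2, 1)
  expect_identical(tab2$sign, c(1, -1, 1))
  expect_false(tab2$complete[3])
  w <- establishment_widths(tab2, drop_edge = FALSE)
  expect_equal(unname(w), c(3, 1), tolerance = 0.01)
})

test_that("nothing is called segmented before the anterior freeze time", {
  tab <- band_labels(ref_kymo(), 5)   # anterior freeze-time oracle = 6
  expect_identical(nrow(tab), 0L)
})

test_that("band boundaries match brute force on the closed-form frozen profile", {
  k <- ref_kymo()
  p <- k$params
  tab <- band_labels(k, p$t_end)
  # brute force: sign runs of cos(2*pi*N(u)) on a fine u grid
  u_min <- (p$B - p$T0) / (p$A * p$T0) / domain_length(p$t_end, p)
  ug <- seq(1, u_min, length.out = 200000)
  prof <- cos(2 * pi * closed_form_freeze_phase(ug, p))
  sgn <- ifelse(prof >= 0, 1, -1)
  runs <- rle(sgn)
  expect_identical(nrow(tab), length(runs$lengths))
  expect_identical(tab$sign, runs$values)
  # zero crossings, interpolated on the grid, in rho = 1 - u
  ends <- cumsum(runs$lengths)
  cuts <- vapply(ends[-length(ends)], function(i) {
    w <- prof[i] / (prof[i] - prof[i + 1])
    1 - (ug[i] + w * (ug[i + 1] - ug[i]))
  }, numeric(1))
  bin_rho <- diff(k$space_bins[1:2]) / domain_length(p$t_end, p)
  expect_equal(tab$mat_hi[tab$complete], cuts, tolerance = bin_rho)
})

test_that("segments appear in anterior-to-posterior order, alternate in sign, and tile the frozen prefix", {
  tab <- band_labels(ref_kymo(), 50)
  expect_true(all(diff(tab$t_established) > 0))
  expect_true(all(tab$sign[-1] * tab$sign[-nrow(tab)] == -1))
  expect_equal(tab$mat_lo[-1], tab$mat_hi[-nrow(tab)])
  expect_equal(tab$mat_lo[1], 0)
})

test_that("first segment establishes just before t = 10 under the reference parameters", {
  k <- ref_kymo()
  fs <- first_segment_time(k)
  expect_gt(fs, 6)
  expect_lt(fs, 10)
  # analytic refinement: solve N(u) = N(1) + 1, then t = d*/u - L0
  p <- k$params
  n1 <- closed_form_freeze_phase(1, p)
  u_star <- stats::uniroot(function(u) closed_form_freeze_phase(u, p) - n1 - 1,
                           c(0.2, 1), tol = 1e-12)$root
  expect_equal(fs, closed_form_freeze_time(u_star, p), tolerance = 0.05)
})

test_that("first-segment time is non-increasing in the simulation horizon", {
  t5 <- first_segment_time(simulate_tissue(small_params(t_end = 5),
                                           record_dt = 0.5, n_bins = 20))
  k12 <- simulate_tissue(model_params(t_end = 12, dt = 0.01, n_cells = 500),
                         record_dt = 0.2, n_bins = 50)
  t12 <- first_segment_time(k12)
  t50 <- first_segment_time(ref_kymo())
  expect_identical(t5, Inf)
  expect_true(t5 >= t12)
  # once established, lengthening the horizon does not move the call
  # (up to the cell-grid resolution of the two runs)
  expect_equal(t12, t50, tolerance = 0.05)
})

test_that("establishment widths shrink towards the posterior for interior bands", {
  tab <- band_labels(ref_kymo(), 50)
  w <- establishment_widths(tab)
  expect_gte(length(w), 10)
  expect_true(all(diff(w) < 0))
  # the anterior-most band abuts the tissue edge and spans less than a
  # half-cycle, so it is narrower than band 2 and excluded by default
  w_all <- establishment_widths(tab, drop_edge = FALSE)
  expect_lt(w_all[1], w_all[2])
  # too few bands is an error
  mat <- seq(0, 2, by = 0.01)
  k1 <- synthetic_kymo(mat, rep(1, length(mat)),
                       seq(0.1, 1, length.out = length(mat)))
  expect_error(establishment_widths(band_labels(k1, 1)), "at least 2")
})

test_that("established bands widen with uniform growth and stay fixed without it", {
  k <- ref_kymo()
  p <- k$params
  tab <- band_labels(k, p$t_end)
  for (b in c(2, 5, 10)) {
    ws <- width_growth(k, b)
    expect_true(all(diff(ws$width) > 0))
    expect_gte(min(ws$width), tab$width_at_establishment[b] - 1e-9)
    # uniform-growth scaling: w(t) = w_est * L(t)/L(t_est)
    t_est <- tab$t_established[b]
    expect_equal(ws$width[nrow(ws)] / ws$width[1],
                 domain_length(max(ws$time), p) / domain_length(ws$time[1], p),
                 tolerance = 1e-9)
  }
  expect_error(width_growth(k, 999), "no established band")
  # localized variant: no proliferation outside the zone, constant widths
  ws_loc <- width_growth(localized_kymo(), 3)
  expect_equal(diff(range(ws_loc$width)), 0)
})

test_that("progress-zone variant lays down near-equal bands", {
  w <- establishment_widths(band_labels(localized_kymo(), 50))
  expect_lt((max(w) - min(w)) / mean(w), 0.05)
  expect_equal(mean(w), 0.5, tolerance = 0.01)   # g * T0 / 2
})
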