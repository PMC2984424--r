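#' Segment bands of the frozen region at a given time
#'
#' Partitions the frozen (segmented) anterior prefix of the tissue into
#' maximal constant-sign runs of the frozen cell state — the alternating
#' dark/light bands of the space-time diagram. Band boundaries are the
#' zero crossings of the frozen `z` profile, located by linear
#' interpolation between adjacent cells; a band's establishment time is
#' the freeze time of its posterior boundary.
#'
#' The posterior-most run is still being laid down while the freezing
#' front advances, so it is reported with `complete = FALSE` and no
#' establishment width. The anterior-most band is additionally flagged
#' `edge_truncated`: its anterior limit is the tissue edge, not a sign
#' change, so it spans less than a half-cycle of frozen phase and its
#' width is not comparable to the interior bands'.
#'
#' @param kymo a [simulate_tissue()] kymograph.
#' @param t query time within the simulated range.
#' @return A `data.frame` of class `segment_table` with columns
#'   `band_index`, `sign` (+1/-1), `t_established`, `mat_lo`/`mat_hi`
#'   (material coordinates: `rho` for the distributed variant, lab `x` for
#'   the localized one), `rho_lo`/`rho_hi`, `width_at_establishment`
#'   (lab-length units, `NA` for the incomplete posterior run),
#'   `complete`, and `edge_truncated`. Zero rows when nothing is frozen.
#' @export
band_labels <- function(kymo, t) {
  if (t < min(kymo$times) - 1e-9 || t > max(kymo$times) + 1e-9)
    stop("band_labels: t outside the simulated time range")
  params <- kymo$params
  cells <- kymo$cells[order(kymo$cells$mat), ]
  fr <- which(cells$freeze_time <= t + 1e-12)
  empty <- data.frame(band_index = integer(), sign = numeric(),
                      t_established = numeric(), mat_lo = numeric(),
                      mat_hi = numeric(), rho_lo = numeric(),
                      rho_hi = numeric(),
                      width_at_establishment = numeric(),
                      complete = logical(), edge_truncated = logical())
  if (!length(fr)) return(structure(empty, class = c("segment_table",
                                                     "data.frame")))
  z <- cells$z_frozen[fr]
  m <- cells$mat[fr]
  ft <- cells$freeze_time[fr]
  sgn <- ifelse(z >= 0, 1, -1)
  runs <- rle(sgn)
  k <- length(runs$lengths)
  ends <- cumsum(runs$lengths)          # last cell index of each run
  # interpolated zero crossings at each run boundary
  cut_m <- cut_t <- numeric(max(k - 1, 0))
  for (b in seq_len(k - 1)) {
    i <- ends[b]
    w <- z[i] / (z[i] - z[i + 1])
    cut_m[b] <- m[i] + w * (m[i + 1] - m[i])
    cut_t[b] <- ft[i] + w * (ft[i + 1] - ft[i])
  }
  mat_lo <- c(m[1], cut_m)
  mat_hi <- c(cut_m, m[length(m)])
  t_est <- c(cut_t, max(ft[is.finite(ft)]))
  complete <- c(rep(TRUE, k - 1), FALSE)
  lab_width <- function(lo, hi, te) {
    if (params$variant == "distributed_distance")
      (hi - lo) * domain_length(te, params)
    else hi - lo
  }
  width_est <- ifelse(complete,
                      mapply(lab_width, mat_lo, mat_hi, t_est),
                      NA_real_)
  to_rho <- function(mat, te) {
    if (params$variant == "distributed_distance") mat
    else mat / domain_length(te, params)
  }
  out <- data.frame(
    band_index = seq_len(k),
    sign = runs$values,
    t_established = t_est,
    mat_lo = mat_lo, mat_hi = mat_hi,
    rho_lo = mapply(to_rho, mat_lo, t_est),
    rho_hi = mapply(to_rho, mat_hi, t_est),
    width_at_establishment = width_est,
    complete = complete,
    edge_truncated = c(TRUE, rep(FALSE, k - 1))
  )
  structure(out, class = c("segment_table", "data.frame"))
}

#' Time at which the first complete segment is established
#'
#' The first segment is called established at the smallest time when the
#' frozen region spans one full oscillation cycle of frozen phase (two
#' sign alternations of the frozen state). Accumulated freeze phase grows
#' monotonically towards the posterior, so this is the freeze time of the
#' first cell whose freeze phase exceeds the anterior-most cell's by
#' `2*pi`.
#'
#' @param kymo a [simulate_tissue()] kymograph.
#' @return the establishment time, or `Inf` if the simulation ends before
#'   a full cycle has frozen.
#' @export
first_segment_time <- function(kymo) {
  cells <- kymo$cells[is.finite(kymo$cells$freeze_time), ]
  if (!nrow(cells)) return(Inf)
  o <- order(cells$freeze_time)
  span <- cells$freeze_phase[o] - cells$freeze_phase[o][1]
  hit <- which(span >= 2 * pi)
  if (!length(hit)) return(Inf)
  cells$freeze_time[o][hit[1]]
}

#' Establishment widths of the interior segment bands
#'
#' Returns `width_at_establishment` by band index for the complete bands
#' of a segment table. Under distributed proliferation with the reference
#' parameters these widths decrease strictly from anterior to posterior
#' for all interior bands (the edge-truncated anterior band spans less
#' than a half-cycle and is excluded by default); under the localized
#' progress-zone variant they are near-constant.
#'
#' @param table a [band_labels()] segment table.
#' @param drop_edge drop the edge-truncated anterior band (default TRUE).
#' @return named numeric vector of widths (names = band indices).
#' @export
establishment_widths <- function(table, drop_edge = TRUE) {
  keep <- table$complete & (!drop_edge | !table$edge_truncated)
  if (sum(table$complete) < 2)
    stop("establishment_widths: need at least 2 established bands")
  stats::setNames(table$width_at_establishment[keep],
                  table$band_index[keep])
}

#' Width trajectory of an established band
#'
#' A band's boundaries are material: once frozen they are carried
#' passively by tissue growth. Under uniform (distributed) proliferation
#' the band's lab width therefore scales with the whole tissue,
#' `w(t) = w_est * L(t) / L(t_est)`, strictly increasing while the tissue
#' grows; under the localized variant (no proliferation outside the zone)
#' it stays constant.
#'
#' @param kymo a [simulate_tissue()] kymograph.
#' @param band_index index of an established (complete) band in the final
#'   segment table.
#' @param times sample times (default: kymograph times from establishment
#'   onwards).
#' @return `data.frame` with columns `time` and `width`.
#' @export
width_growth <- function(kymo, band_index, times = NULL) {
  table <- band_labels(kymo, max(kymo$times))
  row <- table[table$band_index == band_index & table$complete, ]
  if (!nrow(row))
    stop("width_growth: no established band with index ", band_index)
  if (is.null(times))
    times <- kymo$times[kymo$times >= row$t_established]
  width <- if (kymo$params$variant == "distributed_distance") {
    (row$mat_hi - row$mat_lo) * domain_length(times, kymo$params)
  } else {
    rep(row$mat_hi - row$mat_lo, length(times))
  }
  data.frame(time = times, width = width)
}
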