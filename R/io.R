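#' Write a kymograph as a tab-delimited matrix
#'
#' Rows are sampled times, columns the lab-coordinate bins; the first
#' column holds the time. Bins outside the tissue carry the sentinel
#' `NA`. Deterministic: identical kymographs give byte-identical files.
#'
#' @param kymo a [simulate_tissue()] kymograph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kymograph_tsv <- function(kymo, path) {
  m <- cbind(time = kymo$times, kymo$z_grid)
  colnames(m) <- c("time", sprintf("bin%03d", seq_along(kymo$space_bins)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.10g", r)), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read back a kymograph TSV matrix
#'
#' @param path a file written by [write_kymograph_tsv()].
#' @return list with `times` and `z_grid`.
#' @export
read_kymograph_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  list(times = d[[1]], z_grid = as.matrix(d[, -1, drop = FALSE]))
}

#' Export a kymograph as a plain (ASCII) PGM image
#'
#' 8-bit grayscale portable graymap, `P2` format: one pixel row per
#' sampled time, one column per space bin, black = `-z_max`, white =
#' `+z_max`. The out-of-tissue sentinel has no grayscale channel and is
#' rendered as 0.
#'
#' @inheritParams write_kymograph_tsv
#' @return `path`, invisibly.
#' @export
write_kymograph_pgm <- function(kymo, path) {
  zm <- kymo$params$z_max
  g <- round((kymo$z_grid + zm) / (2 * zm) * 255)
  g[is.na(g)] <- 0
  g[g < 0] <- 0; g[g > 255] <- 255
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2",
               paste(ncol(g), nrow(g)),
               "255",
               apply(g, 1, paste, collapse = " ")), con)
  invisible(path)
}

#' Write the length and frozen-front series of a kymograph
#'
#' CSV with header: `time`, `length` (`L(t)`), `front_lo`, `front_hi`
#' (lab extent of the frozen region, empty fields when nothing is
#' frozen).
#'
#' @inheritParams write_kymograph_tsv
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(kymo, path) {
  d <- data.frame(time = kymo$times, length = kymo$lengths,
                  front_lo = kymo$frozen_front[, "lo"],
                  front_hi = kymo$frozen_front[, "hi"])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a segment table as CSV
#'
#' Columns `band_index`, `sign`, `t_established`, `rho_lo`, `rho_hi`,
#' `width_at_establishment`, `complete`, `edge_truncated`.
#'
#' @param table a [band_labels()] segment table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(table, path) {
  cols <- c("band_index", "sign", "t_established", "rho_lo", "rho_hi",
            "width_at_establishment", "complete", "edge_truncated")
  utils::write.csv(as.data.frame(table)[, cols], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a nuclei point pattern as CSV (with sidecar metadata)
#'
#' Columns `ap`, `lat` (full `%.17g` precision, so the round trip through
#' [read_point_pattern()] is exact) and `mitotic` (0/1). Scenario,
#' generator parameters and seed go to a `<path>.meta` key=value sidecar.
#'
#' @param pattern a [generate_embryo()] point pattern.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  con <- file(path, "wb")
  writeLines(c("ap,lat,mitotic",
               sprintf("%.17g,%.17g,%d", pattern$ap, pattern$lat,
                       as.integer(pattern$mitotic))), con)
  close(con)
  gp <- attr(pattern, "gen_params")
  meta <- c(paste0("scenario=", attr(pattern, "scenario")),
            paste0("seed=", attr(pattern, "seed")),
            paste0("n_nuclei=", nrow(pattern)))
  if (!is.null(gp))
    meta <- c(meta, vapply(names(gp), function(k)
      paste0(k, "=", paste(gp[[k]], collapse = ",")), character(1)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a nuclei point pattern CSV
#'
#' Restores the pattern written by [write_point_pattern()], including the
#' sidecar metadata when present.
#'
#' @param path CSV path.
#' @return a `point_pattern` data frame.
#' @export
read_point_pattern <- function(path) {
  d <- utils::read.csv(path, colClasses = c("numeric", "numeric", "integer"))
  pat <- data.frame(ap = d$ap, lat = d$lat, mitotic = d$mitotic == 1L)
  meta_path <- paste0(path, ".meta")
  scenario <- NA_character_; seed <- NA_integer_
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    if (!is.na(meta["scenario"])) scenario <- meta[["scenario"]]
    if (!is.na(meta["seed"])) seed <- as.integer(meta[["seed"]])
  }
  structure(pat, scenario = scenario, seed = seed,
            class = c("point_pattern", "data.frame"))
}

#' Write a zone-test result as key=value text and a CSV row
#'
#' @param result a [posterior_test()] result.
#' @param path output path for the key=value file; a one-row CSV is
#'   written next to it at `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_zone_test <- function(result, path) {
  num <- function(v) sprintf("%.10g", v)
  writeLines(c(
    paste0("K=", result$K),
    paste0("posterior_bin_index=", result$posterior_bin_index),
    paste0("n_nuclei=", result$n_nuclei),
    paste0("n_mitoses=", result$n_mitoses),
    paste0("nuclei_per_bin=", paste(result$nuclei_per_bin, collapse = ",")),
    paste0("mitoses_per_bin=", paste(result$mitoses_per_bin, collapse = ",")),
    paste0("enrichment=", num(result$enrichment)),
    paste0("p_binomial=", num(result$p_binomial)),
    paste0("p_permutation=", num(result$p_permutation)),
    paste0("n_permutations=", result$n_permutations),
    paste0("alpha=", num(result$alpha)),
    paste0("reject=", as.integer(result$reject))
  ), path)
  d <- data.frame(K = result$K, posterior_bin = result$posterior_bin_index,
                  n_nuclei = result$n_nuclei, n_mitoses = result$n_mitoses,
                  enrichment = result$enrichment,
                  p_binomial = result$p_binomial,
                  p_permutation = result$p_permutation,
                  n_permutations = result$n_permutations,
                  alpha = result$alpha, reject = result$reject)
  utils::write.csv(d, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

# flat key=value manifest; keys sorted so output is deterministic
.write_manifest <- function(config, path) {
  flat <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ","), character(1))
  writeLines(paste0(names(flat)[order(names(flat))], "=",
                    flat[order(names(flat))]), path)
  invisible(path)
}
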