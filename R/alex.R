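# ALEX burst pipeline: burst search, ratiometric observables, crosstalk and
# gamma calibration, accurate FRET efficiency.
#
# Conventions (standard ALEX):
#   E_raw = F_Dex_Aem / (F_Dex_Aem + F_Dex_Dem)                (proximity ratio)
#   S_raw = (F_Dex_Aem + F_Dex_Dem) / (F_Dex_Aem + F_Dex_Dem + F_Aex_Aem)
#   F_fret = F_Dex_Aem - Lk * F_Dex_Dem - Dir * F_Aex_Aem      (crosstalk)
#   1/S_corr = Omega + Sigma * E_corr across FRET standards; gamma derived as
#   gamma = (Omega - 1) / (Omega + Sigma - 1)
#   E_acc = F_fret / (F_fret + gamma * F_Dex_Dem)

.burst_cols <- c("F_Dex_Dem", "F_Dex_Aem", "F_Aex_Aem", "F_Aex_Dem")

new_burst_table <- function(df, factors = NULL) {
  stopifnot(is.data.frame(df))
  structure(df, class = c("burst_table", "data.frame"), factors = factors)
}

#' @export
print.burst_table <- function(x, ...) {
  cat(sprintf("Burst table: %d bursts\n", nrow(x)))
  if (nrow(x)) {
    cols <- intersect(c("E_raw", "S_raw", "E_corr", "S_corr", "E_acc"), names(x))
    if (length(cols)) {
      m <- vapply(cols, function(cc) mean(x[[cc]], na.rm = TRUE), numeric(1))
      cat("  population means:",
          paste(sprintf("%s = %.3f", cols, m), collapse = ", "), "\n")
    }
  }
  f <- attr(x, "factors")
  if (!is.null(f)) print(f)
  invisible(x)
}

#' Correction factors for ALEX FRET
#'
#' Calibration state applied to all bursts of an experiment: donor-leakage
#' fraction `Lk`, acceptor direct-excitation fraction `Dir`, the calibration
#' line slope `Sigma` and intercept `Omega` (of `1/S_corr` versus `E_corr`
#' across FRET standards), and the detection-correction factor `gamma`
#' derived from them.
#'
#' @param Lk donor-leakage fraction (>= 0).
#' @param Dir direct-excitation fraction (>= 0).
#' @param gamma detection-correction factor (> 0).
#' @param Sigma,Omega calibration slope and intercept (NA until calibrated).
#' @return an object of class `correction_factors`.
#' @export
correction_factors <- function(Lk = 0, Dir = 0, gamma = 1,
                               Sigma = NA_real_, Omega = NA_real_) {
  .assert(.is_number(Lk) && Lk >= 0, "Lk must be a non-negative number")
  .assert(.is_number(Dir) && Dir >= 0, "Dir must be a non-negative number")
  .assert(.is_number(gamma) && gamma > 0, "gamma must be a positive number")
  structure(list(Lk = Lk, Dir = Dir, gamma = gamma,
                 Sigma = as.numeric(Sigma), Omega = as.numeric(Omega)),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("Correction factors: Lk = %.4f, Dir = %.4f, gamma = %.4f",
              x$Lk, x$Dir, x$gamma))
  if (is.finite(x$Sigma)) cat(sprintf(" (Sigma = %.4f, Omega = %.4f)", x$Sigma, x$Omega))
  cat("\n")
  invisible(x)
}

#' Burst search on a photon stream
#'
#' Bins all photons into contiguous smoothing windows and defines a burst as a
#' maximal run of windows whose all-photon rate exceeds `rate_threshold_khz`.
#' Bursts with fewer than `min_photons` total photons are discarded to remove
#' false positives from background. The four excitation/emission stream counts
#' are accumulated per burst; guard-gap (`off_window`) photons count toward
#' the rate and photon floor but not toward any stream.
#'
#' @param stream a [photon_stream()].
#' @param rate_threshold_khz burst selection rate threshold (default 3 kHz).
#' @param min_photons minimum photons per burst (default 40, midpoint of the
#'   conventional 35-50 range).
#' @param smoothing_window_ms rate smoothing window (default 1 ms).
#' @return a `burst_table` with per-burst times and stream counts.
#' @export
find_bursts <- function(stream, rate_threshold_khz = 3.0, min_photons = 40,
                        smoothing_window_ms = 1.0) {
  .assert(inherits(stream, "photon_stream"), "stream must be a photon_stream")
  .assert(.is_number(rate_threshold_khz) && rate_threshold_khz > 0,
          "rate_threshold_khz must be positive")
  .assert(.is_number(smoothing_window_ms) && smoothing_window_ms > 0,
          "smoothing_window_ms must be positive")
  .assert(.is_count(min_photons) && min_photons >= 1, "min_photons must be a positive count")

  empty <- new_burst_table(data.frame(
    t_start = numeric(0), t_end = numeric(0),
    F_Dex_Dem = integer(0), F_Dex_Aem = integer(0),
    F_Aex_Aem = integer(0), F_Aex_Dem = integer(0),
    n_photons = integer(0)))
  n <- length(stream$timestamps)
  if (n == 0L) return(empty)

  w_us <- smoothing_window_ms * 1000
  bin <- floor(stream$timestamps / w_us) + 1L
  counts <- tabulate(bin, nbins = max(bin))
  above <- counts > rate_threshold_khz * smoothing_window_ms

  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)

  # map each bin to a candidate burst id (NA below threshold)
  bin2burst <- rep(NA_integer_, length(counts))
  for (i in seq_along(keep)) {
    bin2burst[run_start[keep[i]]:run_end[keep[i]]] <- i
  }
  bid <- bin2burst[bin]
  lab <- split_streams(stream)

  in_burst <- !is.na(bid)
  tot <- tabulate(bid[in_burst], nbins = length(keep))
  ok <- tot >= min_photons
  if (!any(ok)) return(empty)

  tb <- table(factor(bid[in_burst], levels = seq_along(keep)), lab[in_burst])
  cnt <- matrix(as.integer(tb[, c("Dex_Dem", "Dex_Aem", "Aex_Aem", "Aex_Dem"),
                              drop = FALSE]),
                nrow = length(keep), dimnames = list(NULL, .burst_cols))

  df <- data.frame(
    t_start = (run_start[keep[ok]] - 1L) * w_us,
    t_end = run_end[keep[ok]] * w_us,
    F_Dex_Dem = cnt[ok, "F_Dex_Dem"],
    F_Dex_Aem = cnt[ok, "F_Dex_Aem"],
    F_Aex_Aem = cnt[ok, "F_Aex_Aem"],
    F_Aex_Dem = cnt[ok, "F_Aex_Dem"],
    n_photons = tot[ok]
  )
  new_burst_table(df)
}

#' Raw ratiometric observables E and S
#'
#' Computes the uncorrected proximity ratio
#' `E_raw = F_Dex_Aem / (F_Dex_Aem + F_Dex_Dem)` and stoichiometry
#' `S_raw = (F_Dex_Aem + F_Dex_Dem) / (F_Dex_Aem + F_Dex_Dem + F_Aex_Aem)`.
#' Bursts with a zero denominator are flagged undefined (`NA`) and excluded
#' from downstream histograms but retained in the table.
#'
#' @param x a `burst_table`, or the `F_Dex_Dem` counts (with `fda`, `faa`).
#' @param fda,faa `F_Dex_Aem` and `F_Aex_Aem` counts when `x` is numeric.
#' @return for a `burst_table`, the table with `E_raw`/`S_raw` columns added;
#'   for numeric input, a data.frame with columns `E_raw`, `S_raw`.
#' @examples
#' raw_es(10, 30, 40)  # E_raw 0.75, S_raw 0.5
#' @export
raw_es <- function(x, fda = NULL, faa = NULL) {
  if (inherits(x, "burst_table") || (is.data.frame(x) && all(.burst_cols[1:3] %in% names(x)))) {
    r <- .raw_es_num(x$F_Dex_Dem, x$F_Dex_Aem, x$F_Aex_Aem)
    x$E_raw <- r$E_raw
    x$S_raw <- r$S_raw
    return(if (inherits(x, "burst_table")) x else new_burst_table(x))
  }
  .raw_es_num(x, fda, faa)
}

.raw_es_num <- function(fdd, fda, faa) {
  .assert(all(c(fdd, fda, faa) >= 0, na.rm = TRUE), "photon counts must be non-negative")
  dex <- fda + fdd
  E <- ifelse(dex > 0, fda / dex, NA_real_)
  S <- ifelse(dex + faa > 0, dex / (dex + faa), NA_real_)
  data.frame(E_raw = E, S_raw = S)
}

#' Estimate crosstalk factors from calibration subpopulations
#'
#' The donor-leakage fraction `Lk` is the median of
#' `F_Dex_Aem / F_Dex_Dem` over donor-only bursts (selected by
#' `S_raw > donor_only_S_min`); the direct-excitation fraction `Dir` is the
#' median of `F_Dex_Aem / F_Aex_Aem` over acceptor-only bursts
#' (`S_raw < acceptor_only_S_max`). Medians are used because per-burst count
#' ratios are heavy-tailed at low counts.
#'
#' @param table a `burst_table` (raw E/S are computed if absent).
#' @param donor_only_S_min stoichiometry threshold selecting donor-only bursts.
#' @param acceptor_only_S_max threshold selecting acceptor-only bursts.
#' @param min_bursts minimum bursts required in each subpopulation.
#' @return a [correction_factors()] with `Lk` and `Dir` set (`gamma = 1`).
#' @export
estimate_crosstalk <- function(table, donor_only_S_min = 0.85,
                               acceptor_only_S_max = 0.15, min_bursts = 20) {
  if (!"S_raw" %in% names(table)) table <- raw_es(table)
  s <- table$S_raw
  don <- which(!is.na(s) & s > donor_only_S_min & table$F_Dex_Dem > 0)
  acc <- which(!is.na(s) & s < acceptor_only_S_max & table$F_Aex_Aem > 0)
  if (length(don) < min_bursts || length(acc) < min_bursts) {
    stop(sprintf(paste0(
      "calibration error: need >= %d bursts in each calibration subpopulation ",
      "(donor-only: %d, acceptor-only: %d); supply correction factors externally"),
      min_bursts, length(don), length(acc)), call. = FALSE)
  }
  Lk <- median(table$F_Dex_Aem[don] / table$F_Dex_Dem[don])
  Dir <- median(table$F_Dex_Aem[acc] / table$F_Aex_Aem[acc])
  correction_factors(Lk = Lk, Dir = Dir, gamma = 1)
}

#' Apply crosstalk corrections to burst counts
#'
#' Subtracts donor-leakage and direct-excitation contributions from the
#' FRET-channel count, `F_fret = F_Dex_Aem - Lk*F_Dex_Dem - Dir*F_Aex_Aem`
#' (floored at 0), and recomputes the ratiometric observables with `F_fret`
#' in place of `F_Dex_Aem`.
#'
#' @param table a `burst_table`.
#' @param factors a [correction_factors()].
#' @return the table with `F_fret_corr`, `E_corr`, `S_corr` columns added.
#' @export
correct_counts <- function(table, factors) {
  .assert(inherits(factors, "correction_factors"), "factors must be correction_factors")
  ff <- pmax(0, table$F_Dex_Aem - factors$Lk * table$F_Dex_Dem -
               factors$Dir * table$F_Aex_Aem)
  dex <- ff + table$F_Dex_Dem
  table$F_fret_corr <- ff
  table$E_corr <- ifelse(dex > 0, ff / dex, NA_real_)
  table$S_corr <- ifelse(dex + table$F_Aex_Aem > 0,
                         dex / (dex + table$F_Aex_Aem), NA_real_)
  attr(table, "factors") <- factors
  table
}

#' Calibrate the gamma detection-correction factor from FRET standards
#'
#' Fits the linear relation `1/S_corr = Omega + Sigma * E_corr` through the
#' population means of two or more FRET standards of distinct efficiency
#' (e.g. short and long polyproline rulers) and derives
#' `gamma = (Omega - 1) / (Omega + Sigma - 1)`. Calibration uses
#' crosstalk-corrected, gamma-uncorrected observables.
#'
#' @param standard_tables list of >= 2 `burst_table`s, one per standard, each
#'   already crosstalk-corrected (or supply `factors` to correct here).
#' @param factors optional [correction_factors()] applied to any table lacking
#'   corrected columns; also the source of `Lk`/`Dir` carried into the result.
#' @param min_delta_E minimum spread in mean corrected E across standards.
#' @return a [correction_factors()] with `Sigma`, `Omega`, `gamma` filled in.
#' @export
calibrate_gamma <- function(standard_tables, factors = NULL, min_delta_E = 0.1) {
  .assert(is.list(standard_tables) && length(standard_tables) >= 2,
          "need at least 2 FRET standards of distinct mean efficiency")
  tabs <- lapply(standard_tables, function(tb) {
    if (!"E_corr" %in% names(tb)) {
      .assert(!is.null(factors),
              "standard tables lack corrected counts and no factors were supplied")
      tb <- correct_counts(if ("S_raw" %in% names(tb)) tb else raw_es(tb), factors)
    }
    tb
  })
  mE <- vapply(tabs, function(tb) mean(tb$E_corr, na.rm = TRUE), numeric(1))
  mS <- vapply(tabs, function(tb) mean(tb$S_corr, na.rm = TRUE), numeric(1))
  .assert(all(is.finite(mE)) && all(is.finite(mS) & mS > 0),
          "standards must yield finite mean E_corr and positive mean S_corr")
  if (diff(range(mE)) < min_delta_E) {
    stop(sprintf(
      "degenerate calibration: standard mean efficiencies span %.3f < %.3f",
      diff(range(mE)), min_delta_E), call. = FALSE)
  }
  fit <- lm(y ~ x, data = data.frame(x = mE, y = 1 / mS))
  Omega <- unname(coef(fit)[1])
  Sigma <- unname(coef(fit)[2])
  gamma <- (Omega - 1) / (Omega + Sigma - 1)
  .assert(is.finite(gamma) && gamma > 0,
          "calibration produced non-positive gamma; check standards")
  base <- if (is.null(factors)) {
    f0 <- attr(tabs[[1]], "factors")
    if (is.null(f0)) correction_factors() else f0
  } else factors
  correction_factors(Lk = base$Lk, Dir = base$Dir, gamma = gamma,
                     Sigma = Sigma, Omega = Omega)
}

#' Accurate FRET efficiency
#'
#' Gamma-corrected FRET efficiency
#' `E_acc = F_fret / (F_fret + gamma * F_Dex_Dem)`. Bursts with a zero
#' denominator are flagged undefined (`NA`). The raw value is stored;
#' histogramming clips to its range at binning time.
#'
#' @param table a `burst_table` (crosstalk correction applied first if absent).
#' @param factors a [correction_factors()] with calibrated `gamma`.
#' @return the table with an `E_acc` column added.
#' @export
accurate_E <- function(table, factors) {
  .assert(inherits(factors, "correction_factors"), "factors must be correction_factors")
  if (!"F_fret_corr" %in% names(table)) table <- correct_counts(table, factors)
  den <- table$F_fret_corr + factors$gamma * table$F_Dex_Dem
  table$E_acc <- ifelse(den > 0, table$F_fret_corr / den, NA_real_)
  attr(table, "factors") <- factors
  table
}

#' Two-dimensional E-S histogram
#'
#' Bins bursts on a uniform efficiency/stoichiometry grid. Values outside the
#' range are clipped into the end bins, so the grid total equals the number of
#' bursts with defined E and S.
#'
#' @param table a `burst_table` with E/S columns.
#' @param bin_E,bin_S bin widths (default 0.025).
#' @param use `"raw"`, `"corrected"` or `"accurate"` observables (accurate
#'   pairs `E_acc` with `S_corr`).
#' @param e_range,s_range histogram ranges.
#' @return list with `E_breaks`, `S_breaks` and a `counts` matrix
#'   (E bins in rows, S bins in columns), class `es_histogram`.
#' @export
es_histogram_2d <- function(table, bin_E = 0.025, bin_S = 0.025,
                            use = c("raw", "corrected", "accurate"),
                            e_range = c(-0.1, 1.1), s_range = c(-0.1, 1.1)) {
  use <- match.arg(use)
  cols <- switch(use,
                 raw = c("E_raw", "S_raw"),
                 corrected = c("E_corr", "S_corr"),
                 accurate = c("E_acc", "S_corr"))
  .assert(all(cols %in% names(table)),
          "table lacks %s/%s; run the corresponding pipeline stage first",
          cols[1], cols[2])
  E <- table[[cols[1]]]
  S <- table[[cols[2]]]
  ok <- is.finite(E) & is.finite(S)
  eb <- seq(e_range[1], e_range[2], by = bin_E)
  sb <- seq(s_range[1], s_range[2], by = bin_S)
  cnt <- matrix(0L, nrow = length(eb) - 1L, ncol = length(sb) - 1L)
  if (any(ok)) {
    ei <- pmin(pmax(findInterval(E[ok], eb, rightmost.closed = TRUE), 1L), nrow(cnt))
    si <- pmin(pmax(findInterval(S[ok], sb, rightmost.closed = TRUE), 1L), ncol(cnt))
    for (k in seq_along(ei)) cnt[ei[k], si[k]] <- cnt[ei[k], si[k]] + 1L
  }
  structure(list(E_breaks = eb, S_breaks = sb, counts = cnt, n_values = sum(ok)),
            class = "es_histogram")
}

#' @export
print.es_histogram <- function(x, ...) {
  cat(sprintf("2D E-S histogram: %d x %d bins, %d bursts\n",
              nrow(x$counts), ncol(x$counts), x$n_values))
  invisible(x)
}

#' Select dual-labeled bursts by stoichiometry
#'
#' Convenience filter keeping bursts in an intermediate stoichiometry band,
#' removing donor-only (S near 1) and acceptor-only (S near 0) molecules.
#'
#' @param table a `burst_table`.
#' @param s_min,s_max stoichiometry band (defaults 0.25-0.85).
#' @param use `"corrected"` (default when available) or `"raw"` stoichiometry.
#' @return the filtered `burst_table`.
#' @export
select_dual <- function(table, s_min = 0.25, s_max = 0.85,
                        use = if ("S_corr" %in% names(table)) "corrected" else "raw") {
  s <- if (use == "corrected") table$S_corr else table$S_raw
  .assert(!is.null(s), "table has no stoichiometry column for use = '%s'", use)
  keep <- !is.na(s) & s > s_min & s < s_max
  out <- table[keep, , drop = FALSE]
  new_burst_table(out, factors = attr(table, "factors"))
}

#' Run the full ALEX analysis chain on a photon stream
#'
#' Burst search, raw ratios, crosstalk estimation (or externally supplied
#' factors), optional gamma calibration against standard streams, and
#' accurate FRET efficiency.
#'
#' @param stream a [photon_stream()].
#' @param rate_threshold_khz,min_photons,smoothing_window_ms burst-search
#'   parameters, see [find_bursts()].
#' @param factors `"auto"` to estimate `Lk`/`Dir` from the stream's own
#'   donor-only and acceptor-only subpopulations, or a [correction_factors()].
#' @param standards optional list of >= 2 photon streams of FRET standards
#'   used to calibrate gamma (each analyzed with the same burst parameters).
#' @return a `burst_table` with raw, corrected and accurate observables and
#'   the applied [correction_factors()] attached as attribute `"factors"`.
#' @export
analyze_alex <- function(stream, rate_threshold_khz = 3.0, min_photons = 40,
                         smoothing_window_ms = 1.0, factors = "auto",
                         standards = NULL) {
  tb <- raw_es(find_bursts(stream, rate_threshold_khz, min_photons,
                           smoothing_window_ms))
  f <- if (identical(factors, "auto")) estimate_crosstalk(tb) else factors
  .assert(inherits(f, "correction_factors"),
          "factors must be 'auto' or a correction_factors object")
  if (!is.null(standards)) {
    std_tabs <- lapply(standards, function(s) {
      correct_counts(raw_es(find_bursts(s, rate_threshold_khz, min_photons,
                                        smoothing_window_ms)), f)
    })
    f <- calibrate_gamma(std_tabs, factors = f)
  }
  accurate_E(correct_counts(tb, f), f)
}
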