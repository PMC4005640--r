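# Alternation scheme and photon stream containers.
#
# Timestamps are integer-valued microseconds on a shared clock so that window
# assignment at period boundaries is exact; excitation windows are half-open
# [start, end) within the alternation period.

#' Laser alternation scheme
#'
#' Describes the period of donor/acceptor laser alternation and the half-open
#' excitation windows within it. Defaults follow a 100 microsecond period with
#' a 40% duty cycle per laser: donor excitation in \[0, 40) and acceptor
#' excitation in \[50, 90), leaving symmetric 10 microsecond guard gaps.
#'
#' @param period_us alternation period in microseconds.
#' @param dex_window length-2 numeric, half-open donor-excitation window
#'   within the period.
#' @param aex_window length-2 numeric, half-open acceptor-excitation window.
#' @return an object of class `alternation_scheme`.
#' @examples
#' alternation_scheme()
#' @export
alternation_scheme <- function(period_us = 100,
                               dex_window = c(0, 40),
                               aex_window = c(50, 90)) {
  .assert(.is_number(period_us) && period_us > 0, "period_us must be positive")
  for (w in list(dex_window, aex_window)) {
    .assert(is.numeric(w) && length(w) == 2L && w[1] < w[2],
            "excitation windows must be increasing length-2 numerics")
    .assert(w[1] >= 0 && w[2] <= period_us,
            "excitation windows must lie within [0, period)")
  }
  .assert(dex_window[2] <= aex_window[1] || aex_window[2] <= dex_window[1],
          "dex_window and aex_window must be disjoint")
  len_d <- diff(dex_window)
  len_a <- diff(aex_window)
  .assert(abs(len_d - len_a) < 1e-9,
          "both excitation windows must have equal length (one duty fraction)")
  structure(
    list(period_us = period_us,
         dex_window = as.numeric(dex_window),
         aex_window = as.numeric(aex_window),
         duty_fraction = len_d / period_us),
    class = "alternation_scheme"
  )
}

#' @export
print.alternation_scheme <- function(x, ...) {
  cat(sprintf(
    "Alternation scheme: period %g us, duty %.0f%%\n  Dex [%g, %g) us, Aex [%g, %g) us\n",
    x$period_us, 100 * x$duty_fraction,
    x$dex_window[1], x$dex_window[2], x$aex_window[1], x$aex_window[2]))
  invisible(x)
}

#' Photon arrival stream
#'
#' A two-detector photon stream: strictly increasing arrival timestamps
#' (microseconds) with a detector label per photon, plus the alternation
#' scheme used to partition photons into excitation/emission streams.
#'
#' @param timestamps numeric vector of strictly increasing arrival times
#'   (integer microseconds).
#' @param detectors character vector, one of `"donor"`/`"acceptor"` per photon.
#' @param scheme an [alternation_scheme()].
#' @return an object of class `photon_stream`.
#' @export
photon_stream <- function(timestamps, detectors, scheme = alternation_scheme()) {
  .assert(inherits(scheme, "alternation_scheme"), "scheme must be an alternation_scheme")
  .assert(length(timestamps) == length(detectors),
          "timestamps and detectors must have equal length")
  if (length(timestamps)) {
    .assert(is.numeric(timestamps) && all(is.finite(timestamps)),
            "timestamps must be finite numbers")
    d <- diff(timestamps)
    if (length(d) && any(d <= 0)) {
      stop(sprintf("timestamps must be strictly increasing (violated at photon %d)",
                   which(d <= 0)[1] + 1L), call. = FALSE)
    }
    .assert(all(detectors %in% c("donor", "acceptor")),
            "detector labels must be 'donor' or 'acceptor'")
  }
  structure(
    list(timestamps = as.numeric(timestamps),
         detectors = as.character(detectors),
         scheme = scheme),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- length(x$timestamps)
  span <- if (n) diff(range(x$timestamps)) / 1e6 else 0
  cat(sprintf("Photon stream: %d photons over %.3f s\n", n, span))
  print(x$scheme)
  invisible(x)
}

#' Split a photon stream into excitation/emission streams
#'
#' Assigns every photon to one of the four ALEX streams by combining the
#' excitation window containing its timestamp (modulo the alternation period)
#' with its detector. Photons arriving in neither excitation window (guard
#' gaps) are labeled `off_window` and excluded from all burst counts.
#'
#' @param stream a [photon_stream()].
#' @return factor with levels `Dex_Dem`, `Dex_Aem`, `Aex_Aem`, `Aex_Dem`,
#'   `off_window`, one per photon.
#' @examples
#' s <- photon_stream(c(10, 155), c("donor", "acceptor"))
#' split_streams(s)  # Dex_Dem, Aex_Aem
#' @export
split_streams <- function(stream) {
  .assert(inherits(stream, "photon_stream"), "stream must be a photon_stream")
  sch <- stream$scheme
  phase <- stream$timestamps %% sch$period_us
  in_dex <- phase >= sch$dex_window[1] & phase < sch$dex_window[2]
  in_aex <- phase >= sch$aex_window[1] & phase < sch$aex_window[2]
  donor <- stream$detectors == "donor"
  lab <- rep("off_window", length(phase))
  lab[in_dex & donor] <- "Dex_Dem"
  lab[in_dex & !donor] <- "Dex_Aem"
  lab[in_aex & !donor] <- "Aex_Aem"
  lab[in_aex & donor] <- "Aex_Dem"
  factor(lab, levels = c("Dex_Dem", "Dex_Aem", "Aex_Aem", "Aex_Dem", "off_window"))
}
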