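# Donor-bleaching FRET from two-channel TIRF trajectories.
#
# Per-molecule efficiency from the donor intensity before (I_da) and after
# (I_d) single-step acceptor photobleaching: E = (I_d - I_da) / I_d. Only
# traces showing the useful bleaching sequence (one downward acceptor step,
# then one downward donor step to background) are analyzed.

#' Subtract trajectory backgrounds
#'
#' Background levels `B_d`/`B_a` are the channel means over the last
#' `tail_frames` frames (after both dyes have bleached in a usable trace);
#' both channels are shifted down by their background.
#'
#' @param traj a [fret_trajectory()].
#' @param tail_frames frames averaged at the trace end (default 30, i.e.
#'   3 s at 100 ms frames).
#' @return the background-corrected trajectory with attributes `B_d`, `B_a`
#'   and `background_corrected = TRUE`.
#' @export
subtract_background <- function(traj, tail_frames = 30) {
  .assert(inherits(traj, "fret_trajectory"), "traj must be a fret_trajectory")
  .assert(.is_count(tail_frames) && tail_frames >= 1, "tail_frames must be >= 1")
  n <- length(traj$I_d)
  .assert(n > tail_frames, "trajectory (%d frames) must be longer than tail_frames (%d)",
          n, tail_frames)
  idx <- (n - tail_frames + 1L):n
  B_d <- mean(traj$I_d[idx])
  B_a <- mean(traj$I_a[idx])
  traj$I_d <- traj$I_d - B_d
  traj$I_a <- traj$I_a - B_a
  attr(traj, "B_d") <- B_d
  attr(traj, "B_a") <- B_a
  attr(traj, "background_corrected") <- TRUE
  traj
}

# least-squares binary segmentation for piecewise-constant mean, with a
# BIC-style penalty per accepted change point. Returns 1-based indices of the
# first frame of each new segment.
.binseg <- function(x, max_cp = 4, pen_mult = 10) {
  n <- length(x)
  if (n < 4) return(integer(0))
  sigma2 <- (mad(diff(x)) / sqrt(2))^2
  # noiseless traces: accept any split with a real RSS reduction
  pen <- max(pen_mult * log(n) * sigma2, 1e-9 * max(var(x), .Machine$double.eps))

  best_split <- function(a, b) {
    m <- b - a + 1L
    if (m < 4L) return(NULL)
    seg <- x[a:b]
    cs <- cumsum(seg)
    tot <- cs[m]
    i <- seq_len(m - 1L)
    # RSS reduction of splitting after position i (within-segment means)
    red <- cs[i]^2 / i + (tot - cs[i])^2 / (m - i) - tot^2 / m
    # keep at least 2 frames per side for stable means
    red[c(1L, m - 1L)] <- -Inf
    j <- which.max(red)
    list(pos = a + j, gain = red[j])  # pos = first index of the right segment
  }

  cps <- integer(0)
  segs <- list(c(1L, n))
  while (length(cps) < max_cp) {
    cand <- lapply(segs, function(s) best_split(s[1], s[2]))
    gains <- vapply(cand, function(cc) if (is.null(cc)) -Inf else cc$gain, numeric(1))
    k <- which.max(gains)
    if (!length(gains) || gains[k] <= pen) break
    pos <- cand[[k]]$pos
    s <- segs[[k]]
    segs[[k]] <- c(s[1], pos - 1L)
    segs[[length(segs) + 1L]] <- c(pos, s[2])
    cps <- sort(c(cps, pos))
  }
  cps
}

.segment_means <- function(x, cps) {
  bounds <- c(1L, cps, length(x) + 1L)
  vapply(seq_len(length(bounds) - 1L),
         function(i) mean(x[bounds[i]:(bounds[i + 1L] - 1L)]), numeric(1))
}

#' Detect photobleaching steps in a TIRF trajectory
#'
#' Locates intensity change points in each channel by binary-segmentation
#' least-squares step fitting with a BIC-style penalty, then tests the useful
#' bleaching sequence: the acceptor channel must show exactly one downward
#' step, the donor channel exactly one downward step landing at background,
#' and the acceptor step must strictly precede the donor step. (The donor's
#' upward step on acceptor bleach is expected and permitted.)
#' Non-conforming traces are returned with `usable = FALSE`.
#'
#' @param traj a background-corrected [fret_trajectory()]
#'   (see [subtract_background()]).
#' @param max_cp maximum change points searched per channel.
#' @return an object of class `bleach_analysis`: a list with
#'   `acceptor_bleach_frame`, `donor_bleach_frame` (first frame at the
#'   bleached level, `NA` when absent), `usable`, and the per-channel change
#'   points and segment means.
#' @export
detect_bleach_steps <- function(traj, max_cp = 4) {
  .assert(inherits(traj, "fret_trajectory"), "traj must be a fret_trajectory")
  if (!isTRUE(attr(traj, "background_corrected"))) {
    warning("trajectory does not appear background-corrected; run subtract_background() first")
  }
  cps_a <- .binseg(traj$I_a, max_cp = max_cp)
  cps_d <- .binseg(traj$I_d, max_cp = max_cp)
  mu_a <- .segment_means(traj$I_a, cps_a)
  mu_d <- .segment_means(traj$I_d, cps_d)

  res <- list(acceptor_bleach_frame = NA_integer_, donor_bleach_frame = NA_integer_,
              usable = FALSE, cps_acceptor = cps_a, cps_donor = cps_d,
              means_acceptor = mu_a, means_donor = mu_d,
              molecule_id = traj$molecule_id)

  acc_ok <- length(cps_a) == 1L && diff(mu_a)[1] < 0
  steps_d <- diff(mu_d)
  down_d <- which(steps_d < 0)
  don_ok <- FALSE
  d_frame <- NA_integer_
  if (length(down_d) == 1L && length(cps_d) <= 2L) {
    d_frame <- cps_d[down_d]
    final_mean <- mu_d[length(mu_d)]
    top_mean <- max(mu_d)
    # the downward step must land at background and be the last change
    don_ok <- down_d == length(steps_d) &&
      top_mean > 0 && abs(final_mean) < 0.2 * top_mean
    # any extra change must be the upward recovery preceding the bleach
    if (length(cps_d) == 2L && don_ok) don_ok <- steps_d[1] > 0
  }
  if (acc_ok && don_ok && cps_a[1] < d_frame) {
    res$acceptor_bleach_frame <- cps_a[1]
    res$donor_bleach_frame <- d_frame
    res$usable <- TRUE
  }
  structure(res, class = "bleach_analysis")
}

#' @export
print.bleach_analysis <- function(x, ...) {
  if (x$usable) {
    cat(sprintf("Bleach analysis '%s': usable (acceptor @ %d, donor @ %d)",
                x$molecule_id, x$acceptor_bleach_frame, x$donor_bleach_frame))
    if (!is.null(x$E)) cat(sprintf(", E = %.3f", x$E))
    cat("\n")
  } else {
    cat(sprintf("Bleach analysis '%s': not usable (%d acceptor / %d donor change points)\n",
                x$molecule_id, length(x$cps_acceptor), length(x$cps_donor)))
  }
  invisible(x)
}

#' Donor-bleaching FRET efficiency
#'
#' Averages the background-corrected donor channel over the acceptor-present
#' region (`I_da`, frames before the acceptor bleach) and the acceptor-absent
#' region (`I_d_alone`, frames between the two bleaches), and returns
#' `E = (I_d_alone - I_da) / I_d_alone`. Averaging over many frames
#' suppresses shot noise, so the estimator is effectively limited by
#' calibration rather than counting statistics.
#'
#' @param traj a background-corrected [fret_trajectory()].
#' @param steps a [detect_bleach_steps()] result with `usable = TRUE`.
#' @param min_region_frames minimum frames required in each averaging region
#'   (default 5); smaller regions flag the result undefined.
#' @return the `bleach_analysis` augmented with `I_da`, `I_d_alone` and `E`
#'   (`E = NA` with `usable = FALSE` when a region is degenerate).
#' @export
donor_bleach_fret <- function(traj, steps, min_region_frames = 5) {
  .assert(inherits(traj, "fret_trajectory"), "traj must be a fret_trajectory")
  .assert(inherits(steps, "bleach_analysis"), "steps must be a bleach_analysis")
  .assert(isTRUE(steps$usable), "trace is not usable (bleaching sequence not met)")
  a <- steps$acceptor_bleach_frame
  d <- steps$donor_bleach_frame
  if ((a - 1L) < min_region_frames || (d - a) < min_region_frames) {
    steps$I_da <- NA_real_
    steps$I_d_alone <- NA_real_
    steps$E <- NA_real_
    steps$usable <- FALSE
    warning("averaging region shorter than min_region_frames; E undefined")
    return(steps)
  }
  steps$I_da <- mean(traj$I_d[1:(a - 1L)])
  steps$I_d_alone <- mean(traj$I_d[a:(d - 1L)])
  steps$E <- (steps$I_d_alone - steps$I_da) / steps$I_d_alone
  steps$B_d <- attr(traj, "B_d")
  steps$B_a <- attr(traj, "B_a")
  steps
}

#' Analyze an ensemble of TIRF trajectories
#'
#' Applies background subtraction, bleach-step detection and the
#' donor-bleaching FRET estimator to each trajectory.
#'
#' @param trajs list of [fret_trajectory()].
#' @param tail_frames background tail length, see [subtract_background()].
#' @return data.frame with one row per molecule: `molecule_id`, `usable`,
#'   bleach frames, `I_da`, `I_d_alone`, `E`.
#' @export
analyze_tirf <- function(trajs, tail_frames = 30) {
  if (inherits(trajs, "fret_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    trc <- subtract_background(tr, tail_frames)
    st <- detect_bleach_steps(trc)
    if (st$usable) st <- donor_bleach_fret(trc, st)
    data.frame(molecule_id = tr$molecule_id,
               usable = st$usable,
               acceptor_bleach_frame = st$acceptor_bleach_frame,
               donor_bleach_frame = st$donor_bleach_frame,
               I_da = if (is.null(st$I_da)) NA_real_ else st$I_da,
               I_d_alone = if (is.null(st$I_d_alone)) NA_real_ else st$I_d_alone,
               E = if (is.null(st$E)) NA_real_ else st$E,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
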