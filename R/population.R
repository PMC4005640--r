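# FRET-efficiency histograms and Gaussian population decomposition.
#
# Histograms are fitted (nonlinear least squares on bin counts) to
#   y(x) = y0 + sum_i area_i * Normal(x; mean_i, width_i)
# with n in {1, 2} components; components are parameterized by area
# (integral), so population fractions are area_i / sum(area). Model order is
# chosen by the least-squares Akaike criterion
#   AIC = N * ln(RSS / N) + 2k,  k = 3n + 1,
# with ties resolved toward the single component.

#' FRET efficiency histogram
#'
#' Bins efficiencies on a uniform grid (default bin width 0.025 over
#' \[-0.1, 1.1\]). Out-of-range values are counted in the end bins, so counts
#' always sum to the number of events.
#'
#' @param E_values finite numeric efficiencies.
#' @param bin_width bin width (default 0.025).
#' @param range histogram range (default `c(-0.1, 1.1)`).
#' @return an object of class `fret_histogram`: `bin_edges`, `mids`,
#'   `counts`, `n_values`, `bin_width`.
#' @export
fret_histogram <- function(E_values, bin_width = 0.025, range = c(-0.1, 1.1)) {
  .assert(length(E_values) > 0, "E_values must be non-empty")
  .assert(all(is.finite(E_values)), "E_values must be finite")
  .assert(.is_number(bin_width) && bin_width > 0, "bin_width must be positive")
  .assert(is.numeric(range) && length(range) == 2L && range[1] < range[2],
          "range must be increasing length-2 numeric")
  edges <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  idx <- findInterval(E_values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_values = length(E_values),
                 bin_width = bin_width),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("FRET histogram: %d events in %d bins of width %g over [%g, %g]\n",
              x$n_values, length(x$counts), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

.mix_predict <- function(x, pars, n) {
  y <- rep(pars[["y0"]], length(x))
  for (i in seq_len(n)) {
    y <- y + pars[[paste0("a", i)]] *
      dnorm(x, pars[[paste0("m", i)]], pars[[paste0("w", i)]])
  }
  y
}

# starting points for the mixture fit: histogram peaks plus deterministic
# jittered restarts for robustness
.mix_starts <- function(h, n) {
  x <- h$mids
  y <- h$counts
  bw <- h$bin_width
  tot_area <- sum(y) * bw
  y0_0 <- max(min(y), 0)
  top <- order(y, decreasing = TRUE)
  m1 <- x[top[1]]
  w0 <- max(2 * bw, sqrt(max(weighted.mean((x - weighted.mean(x, y))^2, y), bw^2)))
  if (n == 1) {
    starts <- list(
      list(m1 = m1, w1 = w0 / 2, a1 = tot_area, y0 = y0_0),
      list(m1 = m1, w1 = w0, a1 = tot_area * 0.8, y0 = y0_0),
      list(m1 = weighted.mean(x, y), w1 = w0, a1 = tot_area, y0 = 0))
    return(starts)
  }
  # second start mean: highest bin at least 3 bins away from the first peak
  far <- top[abs(x[top] - m1) >= 3 * bw]
  m2 <- if (length(far)) x[far[1]] else m1 + 4 * bw
  list(
    list(m1 = m1, w1 = 2 * bw, m2 = m2, w2 = 2 * bw,
         a1 = tot_area * 0.6, a2 = tot_area * 0.4, y0 = y0_0),
    list(m1 = m1, w1 = 3 * bw, m2 = m2, w2 = 3 * bw,
         a1 = tot_area * 0.5, a2 = tot_area * 0.5, y0 = 0),
    list(m1 = m1, w1 = 4 * bw, m2 = m2, w2 = 4 * bw,
         a1 = tot_area * 0.7, a2 = tot_area * 0.3, y0 = y0_0))
}

#' Fit a sum-of-Gaussians model to a FRET histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `y0 + sum_i area_i * Normal(x; mean_i, width_i)` against bin centers,
#' with `n` = 1 or 2 components. Bounds keep means inside the histogram
#' range, widths in `[bin_width/2, range width]` and areas/baseline
#' non-negative. Multiple deterministic starting points (seeded from the two
#' highest distinct histogram peaks for `n = 2`) guard against local minima;
#' the best converged fit by residual sum of squares is kept. Degenerate
#' two-component solutions (coincident means or a vanishing component) are
#' rejected as fit failures.
#'
#' @param hist a [fret_histogram()] (>= 5 occupied bins for `n = 1`,
#'   >= 8 for `n = 2`).
#' @param n number of Gaussian components, 1 or 2.
#' @param init optional named list of starting values
#'   (`m1, w1, a1[, m2, w2, a2], y0`) tried before the built-in starts.
#' @param weights `"poisson"` (default; weights `1/max(count, 1)` so that
#'   residuals are on the counting-noise scale) or `"none"` (plain least
#'   squares).
#' @param aicc use the small-sample corrected Akaike criterion.
#' @return an object of class `fret_mixture`: components (mean, width, area),
#'   `y0`, `n`, `rss`, `aic`, `fractions`, and the histogram.
#' @export
fit_mixture <- function(hist, n = 1, init = NULL,
                        weights = c("poisson", "none"), aicc = FALSE) {
  .assert(inherits(hist, "fret_histogram"), "hist must be a fret_histogram")
  .assert(n %in% c(1, 2), "n must be 1 or 2")
  weights <- match.arg(weights)
  occ <- sum(hist$counts > 0)
  .assert(occ >= if (n == 1) 5 else 8,
          "histogram has %d occupied bins; need >= %d for n = %d",
          occ, if (n == 1) 5 else 8, n)

  x <- hist$mids
  y <- hist$counts
  bw <- hist$bin_width
  rng <- range(hist$bin_edges)
  wts <- if (weights == "poisson") 1 / pmax(y, 1) else rep(1, length(y))

  lower <- c(m = rng[1], w = bw / 2, a = 0)
  upper <- c(m = rng[2], w = diff(rng), a = sum(y) * bw * 10)
  nm <- if (n == 1) c("m1", "w1", "a1", "y0") else c("m1", "w1", "m2", "w2", "a1", "a2", "y0")
  lo <- setNames(c(rep(lower["m"], n), rep(lower["w"], n), rep(0, n), 0),
                 c(paste0("m", 1:n), paste0("w", 1:n), paste0("a", 1:n), "y0"))
  hi <- setNames(c(rep(upper["m"], n), rep(upper["w"], n), rep(upper["a"], n), max(y) + 1),
                 names(lo))

  form <- if (n == 1) {
    y ~ y0 + a1 * dnorm(x, m1, w1)
  } else {
    y ~ y0 + a1 * dnorm(x, m1, w1) + a2 * dnorm(x, m2, w2)
  }
  dat <- data.frame(x = x, y = y)

  starts <- .mix_starts(hist, n)
  if (!is.null(init)) starts <- c(list(init), starts)
  best <- NULL
  diag_msgs <- character(0)
  for (s in starts) {
    s <- s[names(lo)]
    fit <- tryCatch(
      nlsLM(form, data = dat, start = s, weights = wts,
            lower = lo[names(s)], upper = hi[names(s)],
            control = list(maxiter = 300)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    rss <- sum(wts * (y - predict(fit))^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop(sprintf("mixture fit failed to converge after %d starts: %s",
                 length(starts), paste(unique(diag_msgs), collapse = "; ")),
         call. = FALSE)
  }

  p <- as.list(coef(best$fit))
  areas <- unlist(p[paste0("a", 1:n)])
  means <- unlist(p[paste0("m", 1:n)])
  widths <- unlist(p[paste0("w", 1:n)])
  if (n == 2) {
    # a genuine second population must be resolved (means separated by more
    # than the sum of the widths -- closer components are indistinguishable
    # from one skewed population), broader than one bin (sub-bin structure
    # cannot be measured at this binning; such components are noise spikes),
    # statistically supported (area exceeding 3x its standard error) and
    # non-negligible (>= 2% of the total area; smaller components are
    # outlier tails, not populations)
    se <- tryCatch(summary(best$fit)$coefficients[, 2], error = function(e) NULL)
    area_se <- if (is.null(se)) c(0, 0) else se[paste0("a", 1:2)]
    if (abs(diff(means)) < max(sum(widths), bw) ||
        any(widths < bw) ||
        any(areas < 3 * area_se) ||
        min(areas) / sum(areas) < 0.02) {
      stop(sprintf(paste0(
        "degenerate two-component fit (means %.3f/%.3f, widths %.4f/%.4f, ",
        "area fractions %.4f/%.4f); no second population supported by the histogram"),
        means[1], means[2], widths[1], widths[2],
        areas[1] / sum(areas), areas[2] / sum(areas)),
        call. = FALSE)
    }
  }
  o <- order(means)
  comps <- data.frame(mean = means[o], width = widths[o], area = areas[o])
  N <- length(y)
  k <- 3 * n + 1
  aic <- N * log(best$rss / N) + 2 * k
  if (aicc) aic <- aic + 2 * k * (k + 1) / max(N - k - 1, 1)
  structure(list(components = comps, y0 = p$y0, n = n, rss = best$rss,
                 aic = aic, fractions = comps$area / sum(comps$area),
                 hist = hist, weights = weights, aicc = aicc),
            class = "fret_mixture")
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: n = %d, AIC = %.2f, RSS = %.2f, y0 = %.2f\n",
              x$n, x$aic, x$rss, x$y0))
  df <- cbind(x$components, fraction = x$fractions)
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fret_mixture <- function(object, ...) {
  print(object)
  cat(sprintf("Histogram: %d events, %d bins\n",
              object$hist$n_values, length(object$hist$counts)))
  invisible(object)
}

#' @export
coef.fret_mixture <- function(object, ...) {
  cmp <- object$components
  out <- c(rbind(cmp$mean, cmp$width, cmp$area))
  names(out) <- as.vector(vapply(seq_len(object$n), function(i)
    paste0(c("mean", "width", "area"), i), character(3)))
  c(out, y0 = object$y0)
}

#' @export
predict.fret_mixture <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$hist$mids else
    (if (is.data.frame(newdata)) newdata$x else newdata)
  pars <- as.list(coef(object))
  y <- rep(pars$y0, length(x))
  for (i in seq_len(object$n)) {
    y <- y + pars[[paste0("area", i)]] *
      dnorm(x, pars[[paste0("mean", i)]], pars[[paste0("width", i)]])
  }
  y
}

#' @export
residuals.fret_mixture <- function(object, ...) {
  object$hist$counts - predict(object)
}

#' @export
plot.fret_mixture <- function(x, main = "FRET population fit", ...) {
  h <- x$hist
  barplot(h$counts, names.arg = round(h$mids, 2), space = 0, border = NA,
          col = "grey80", xlab = "FRET efficiency", ylab = "events",
          main = main, ...)
  xs <- seq(h$bin_edges[1], h$bin_edges[length(h$bin_edges)], length.out = 400)
  # barplot x-units: bins are unit-width starting at 0
  to_bar <- function(e) (e - h$bin_edges[1]) / h$bin_width
  lines(to_bar(xs), predict(x, xs), col = "red3", lwd = 2)
  invisible(x)
}

#' Choose the number of Gaussian populations by AIC
#'
#' Applies the least-squares Akaike criterion
#' `AIC = N_bins * ln(RSS/N_bins) + 2k`, `k = 3n + 1`, to two fits of the
#' same histogram and returns the lower-AIC fit; ties go to the
#' single-component model.
#'
#' @param fit1,fit2 [fit_mixture()] results on the same histogram (`fit2`
#'   may be `NULL`, e.g. when the two-component fit failed as degenerate).
#' @return the chosen `fret_mixture`.
#' @export
select_model_aic <- function(fit1, fit2) {
  .assert(inherits(fit1, "fret_mixture"), "fit1 must be a fret_mixture")
  if (is.null(fit2)) return(fit1)
  .assert(inherits(fit2, "fret_mixture"), "fit2 must be a fret_mixture")
  .assert(identical(fit1$hist$counts, fit2$hist$counts),
          "fits must be on the same histogram")
  if (fit2$aic < fit1$aic) fit2 else fit1
}

#' Population fractions from a mixture fit
#'
#' @param fit a `fret_mixture`.
#' @return numeric vector `area_i / sum(area)`, one per component
#'   (ordered by component mean).
#' @export
population_fractions <- function(fit) {
  .assert(inherits(fit, "fret_mixture"), "fit must be a fret_mixture")
  tot <- sum(fit$components$area)
  .assert(tot > 0, "total fitted area is zero")
  fit$components$area / tot
}

#' Histogram, fit and model-select FRET populations
#'
#' Convenience wrapper: builds the efficiency histogram, fits 1- and (when
#' requested) 2-component Gaussian models, and selects the model order by
#' AIC. A degenerate or non-convergent two-component fit falls back to the
#' single component.
#'
#' @param E_values finite efficiencies.
#' @param bin_width,range histogram parameters, see [fret_histogram()].
#' @param max_n maximum components tried (1 or 2).
#' @param aicc use the small-sample corrected criterion.
#' @return the selected `fret_mixture`.
#' @export
fit_populations <- function(E_values, bin_width = 0.025, range = c(-0.1, 1.1),
                            max_n = 2, aicc = FALSE) {
  h <- fret_histogram(E_values, bin_width, range)
  f1 <- fit_mixture(h, 1, aicc = aicc)
  f2 <- if (max_n >= 2) {
    tryCatch(fit_mixture(h, 2, aicc = aicc), error = function(e) NULL)
  } else NULL
  select_model_aic(f1, f2)
}
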