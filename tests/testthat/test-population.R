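# efficiency histograms, Gaussian mixture fits, AIC model selection

test_that("histogram binning conserves counts and clips into end bins", {
  h <- fret_histogram(rep(0.512, 100))
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1)
  h2 <- fret_histogram(c(rep(0.2125, 5), rep(0.7125, 7)))
  expect_equal(sum(h2$counts > 0), 2)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(5, 7))
  # out-of-range values land in the end bins
  h3 <- fret_histogram(c(-0.5, 0.5, 2.3))
  expect_equal(h3$counts[1], 1)
  expect_equal(h3$counts[length(h3$counts)], 1)
  expect_equal(sum(h3$counts), 3)
  expect_error(fret_histogram(numeric(0)), "non-empty")
  expect_error(fret_histogram(c(0.1, NA)), "finite")
})

test_that("histogram counts match a brute-force tally", {
  set.seed(13)
  ev <- runif(500, -0.1, 1.1)
  h <- fret_histogram(ev)
  tally <- vapply(seq_along(h$counts), function(i) {
    lo <- h$bin_edges[i]; hi <- h$bin_edges[i + 1]
    if (i == length(h$counts)) sum(ev >= lo & ev <= hi) else sum(ev >= lo & ev < hi)
  }, numeric(1))
  expect_equal(h$counts, as.integer(tally))
})

test_that("single-Gaussian parameters are recovered from histogram fits", {
  ev <- simulate_efficiencies(0.75, 0.06, 1, 2000, seed = 19)
  f <- fit_mixture(fret_histogram(ev), 1)
  expect_lt(abs(f$components$mean - 0.75), 0.01)
  expect_lt(abs(f$components$width - 0.06), 0.01)
  expect_equal(sum(f$fractions), 1)
})

test_that("two-component mixtures are recovered with fractions by area", {
  ev <- simulate_efficiencies(c(0.49, 0.74), c(0.06, 0.06), c(0.27, 0.73),
                              5000, seed = 19)
  f <- fit_mixture(fret_histogram(ev), 2)
  expect_lt(abs(f$components$mean[1] - 0.49), 0.02)
  expect_lt(abs(f$components$mean[2] - 0.74), 0.02)
  expect_lt(abs(max(population_fractions(f)) - 0.73), 0.05)
  # nested models: two components never fit worse than one
  f1 <- fit_mixture(fret_histogram(ev), 1)
  expect_lte(f$rss, f1$rss)
})

test_that("fractions are invariant to rescaling all counts", {
  ev <- simulate_efficiencies(c(0.3, 0.7), c(0.05, 0.05), c(0.35, 0.65),
                              3000, seed = 23)
  h <- fret_histogram(ev)
  h3 <- h
  h3$counts <- h$counts * 3L
  h3$n_values <- h$n_values * 3L
  f <- fit_mixture(h, 2)
  f3 <- fit_mixture(h3, 2)
  # invariance is exact up to the unit-floor in the Poisson weights of
  # empty bins, hence the loose-but-tight tolerance
  expect_equal(population_fractions(f3), population_fractions(f),
               tolerance = 1e-3)
  expect_equal(f3$components$mean, f$components$mean, tolerance = 1e-3)
})

test_that("structureless histograms reject a second component", {
  set.seed(29)
  flat <- fret_histogram(runif(2000, -0.1, 1.1))
  expect_error(fit_mixture(flat, 2), "degenerate|converge")
})

test_that("AIC selection prefers the parsimonious model on ties", {
  ev <- simulate_efficiencies(0.6, 0.06, 1, 1500, seed = 31)
  h <- fret_histogram(ev)
  f1 <- fit_mixture(h, 1)
  fake2 <- f1
  fake2$n <- 2
  N <- length(h$counts)
  fake2$aic <- N * log(f1$rss / N) + 2 * (3 * 2 + 1)  # same rss, larger k
  expect_identical(select_model_aic(f1, fake2)$n, 1)
  # a NULL (failed) two-component fit falls back to one
  expect_identical(select_model_aic(f1, NULL)$n, 1)
})

test_that("model order is chosen correctly on both reference regimes", {
  n1_ok <- sum(vapply(1:12, function(s) {
    fit_populations(simulate_efficiencies(0.75, 0.06, 1, 2000,
                                          seed = 300 + s))$n == 1
  }, logical(1)))
  n2_ok <- sum(vapply(1:12, function(s) {
    fit_populations(simulate_efficiencies(c(0.49, 0.74), c(0.06, 0.06),
                                          c(0.27, 0.73), 5000,
                                          seed = 400 + s))$n == 2
  }, logical(1)))
  expect_gte(n1_ok, 11)
  expect_gte(n2_ok, 11)
})

test_that("population fractions follow the area definition", {
  ev <- simulate_efficiencies(c(0.3, 0.8), c(0.05, 0.05), c(0.27, 0.73),
                              4000, seed = 37)
  f <- fit_mixture(fret_histogram(ev), 2)
  fr <- population_fractions(f)
  expect_equal(fr, f$components$area / sum(f$components$area))
  expect_equal(sum(fr), 1)
  # hand-set areas: 73/27
  f$components$area <- c(27, 73)
  expect_equal(population_fractions(f), c(0.27, 0.73))
})

test_that("mixture fit methods expose coherent coefficients and predictions", {
  ev <- simulate_efficiencies(0.5, 0.07, 1, 1500, seed = 41)
  f <- fit_mixture(fret_histogram(ev), 1)
  cf <- coef(f)
  expect_named(cf, c("mean1", "width1", "area1", "y0"))
  # predicted curve integrates approximately to the event count
  xs <- seq(-0.1, 1.1, by = 0.001)
  integral <- sum(predict(f, xs)) * 0.001 / f$hist$bin_width
  expect_lt(abs(integral / 1500 - 1), 0.1)
  expect_length(residuals(f), length(f$hist$counts))
})
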