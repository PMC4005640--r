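# ALEX pipeline: stream splitting, burst search, ratios, corrections,
# calibration

test_that("stream splitting assigns window x detector labels exactly", {
  s <- photon_stream(c(10, 45, 155), c("donor", "donor", "acceptor"))
  expect_equal(as.character(split_streams(s)),
               c("Dex_Dem", "off_window", "Aex_Aem"))
  # boundary behavior: half-open windows
  s2 <- photon_stream(c(0, 39, 40, 50, 89, 90), rep("acceptor", 6))
  expect_equal(as.character(split_streams(s2)),
               c("Dex_Aem", "Dex_Aem", "off_window", "Aex_Aem", "Aex_Aem",
                 "off_window"))
})

test_that("burst search finds a planted cluster and nothing in background", {
  # 60 photons over 1 ms = 60 kHz against zero background: exactly one burst
  st <- planted_burst_stream(n = 60, span_ms = 1)
  tb <- find_bursts(st)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$n_photons, 60)
  expect_equal(tb$F_Dex_Dem, 60)
  # empty stream: empty table
  expect_equal(nrow(find_bursts(photon_stream(numeric(0), character(0)))), 0)
  # 1 kHz homogeneous background for 10 s: sub-threshold, no bursts
  set.seed(5)
  bg <- background_stream(rate_khz = 1, dur_s = 10)
  expect_equal(nrow(find_bursts(bg)), 0)
  # parameter validation
  expect_error(find_bursts(st, rate_threshold_khz = 0), "rate_threshold")
  expect_error(find_bursts(st, smoothing_window_ms = -1), "smoothing_window")
})

test_that("burst search recall and precision on planted bursts over background", {
  set.seed(17)
  scheme <- alternation_scheme()
  n_planted <- 150
  per_ms <- 40  # bursts every 40 ms
  planted <- lapply(seq_len(n_planted), function(i) {
    t0 <- i * per_ms * 1000
    slots <- as.vector(outer(0:39, t0 + 100 * (0:9), `+`))
    sort(sample(slots, 60))
  })
  bg_n <- rpois(1, 1 * (n_planted + 2) * per_ms)  # 1 kHz background
  bg_t <- sort(sample.int((n_planted + 2) * per_ms * 1000, bg_n)) - 1
  tt <- c(unlist(planted), bg_t)
  tt <- sort(unique(tt))
  st <- photon_stream(tt, rep("donor", length(tt)), scheme)
  tb <- find_bursts(st)
  # recall: every planted burst center must fall inside a detected burst
  centers <- (seq_len(n_planted) * per_ms + 0.5) * 1000
  hit <- vapply(centers, function(ct) any(tb$t_start <= ct & tb$t_end >= ct),
                logical(1))
  expect_gte(mean(hit), 0.99)
  # precision: no detected burst without a planted center
  matched <- vapply(seq_len(nrow(tb)), function(i)
    any(centers >= tb$t_start[i] & centers <= tb$t_end[i]), logical(1))
  expect_gte(mean(matched), 0.99)
})

test_that("raw ratiometric observables follow the stream-count definitions", {
  expect_equal(raw_es(50, 50, 0), data.frame(E_raw = 0.5, S_raw = 1.0))
  expect_equal(raw_es(10, 30, 40), data.frame(E_raw = 0.75, S_raw = 0.5))
  expect_equal(raw_es(80, 0, 40)$E_raw, 0)
  # zero denominators flag the burst undefined
  und <- raw_es(0, 0, 10)
  expect_true(is.na(und$E_raw))
  expect_equal(und$S_raw, 0)
  expect_true(is.na(raw_es(0, 0, 0)$S_raw))
  expect_error(raw_es(-1, 5, 5), "non-negative")
})

test_that("crosstalk estimation recovers the instrument truth", {
  inst <- instrument_model(Lk_true = 0.10, Dir_true = 0.08, gamma_true = 1)
  sim <- simulate_alex_experiment(
    list(species_model(0, "donor_only", 0.55),
         species_model(0, "acceptor_only", 0.45)),
    inst, 1500, seed = 23)
  f <- estimate_crosstalk(raw_es(find_bursts(sim$stream)))
  expect_lt(abs(f$Lk - 0.10), 0.01)
  expect_lt(abs(f$Dir - 0.08), 0.01)
  # ideal instrument: crosstalk consistent with zero within counting noise
  sim0 <- simulate_alex_experiment(
    list(species_model(0, "donor_only", 0.55),
         species_model(0, "acceptor_only", 0.45)),
    instrument_model(), 1000, seed = 29)
  f0 <- estimate_crosstalk(raw_es(find_bursts(sim0$stream)))
  expect_lt(f0$Lk, 0.01)
  expect_lt(f0$Dir, 0.01)
  # missing subpopulation: calibration error pointing at external factors
  simd <- simulate_alex_experiment(species_model(0, "donor_only", 1),
                                   instrument_model(), 200, seed = 31)
  expect_error(estimate_crosstalk(raw_es(find_bursts(simd$stream))),
               "supply correction factors externally")
})

test_that("crosstalk correction reproduces its arithmetic contract", {
  tb <- raw_es(structure(
    data.frame(F_Dex_Dem = c(100, 100, 100), F_Dex_Aem = c(50, 10, 50),
               F_Aex_Aem = c(50, 0, 50), F_Aex_Dem = 0),
    class = c("burst_table", "data.frame")))
  # identity at zero factors
  id <- correct_counts(tb, correction_factors(Lk = 0, Dir = 0))
  expect_equal(id$E_corr, id$E_raw)
  expect_equal(id$S_corr, id$S_raw)
  # exact cancellation of a donor-only burst
  dn <- correct_counts(tb[2, ], correction_factors(Lk = 0.10, Dir = 0))
  expect_equal(dn$F_fret_corr, 0)
  expect_equal(dn$E_corr, 0)
  # plain arithmetic: (100, 50, 50) with Lk = Dir = 0.1
  cc <- correct_counts(tb[3, ], correction_factors(Lk = 0.1, Dir = 0.1))
  expect_equal(cc$F_fret_corr, 35)
  expect_equal(cc$E_corr, 35 / 135)
  # floor at zero
  fl <- correct_counts(tb[2, ], correction_factors(Lk = 0.5, Dir = 0))
  expect_equal(fl$F_fret_corr, 0)
})

test_that("gamma calibration recovers the simulated detection factor", {
  for (g in c(0.75, 1.0)) {
    inst <- instrument_model(Lk_true = 0.05, Dir_true = 0.05, gamma_true = g)
    mix <- simulate_alex_experiment(
      list(species_model(0.5, "dual", 0.5), species_model(0, "donor_only", 0.3),
           species_model(0, "acceptor_only", 0.2)),
      inst, 1000, seed = 41)
    ct <- estimate_crosstalk(raw_es(find_bursts(mix$stream)))
    f <- calibrate_from_standards(inst, ct, seed = 43)
    expect_lt(abs(f$gamma / g - 1), 0.05)
  }
  # single standard: precondition violation
  sim <- simulate_alex_experiment(species_model(0.3, "dual", 1),
                                  instrument_model(), 300, seed = 47)
  tb <- correct_counts(raw_es(find_bursts(sim$stream)), correction_factors())
  expect_error(calibrate_gamma(list(tb)), "at least 2")
  # indistinguishable standards: degenerate regression
  expect_error(calibrate_gamma(list(tb, tb)), "degenerate")
})

test_that("accurate E reduces correctly and is monotone in the FRET count", {
  tb <- raw_es(structure(
    data.frame(F_Dex_Dem = 40, F_Dex_Aem = 60, F_Aex_Aem = 50, F_Aex_Dem = 0),
    class = c("burst_table", "data.frame")))
  # gamma = 1: E_acc equals the corrected proximity ratio
  e1 <- accurate_E(tb, correction_factors(gamma = 1))
  expect_equal(e1$E_acc, e1$E_corr)
  # arithmetic: F_fret 60, F_Dex_Dem 40, gamma 0.75
  e2 <- accurate_E(tb, correction_factors(gamma = 0.75))
  expect_equal(e2$E_acc, 60 / (60 + 0.75 * 40))
  # F_fret = 0 gives E_acc = 0
  tb0 <- raw_es(structure(
    data.frame(F_Dex_Dem = 40, F_Dex_Aem = 0, F_Aex_Aem = 0, F_Aex_Dem = 0),
    class = c("burst_table", "data.frame")))
  expect_equal(accurate_E(tb0, correction_factors(gamma = 1))$E_acc, 0)
  # monotone non-decreasing in F_Dex_Aem with all else fixed
  fda <- 0:120
  tbm <- raw_es(structure(
    data.frame(F_Dex_Dem = 50, F_Dex_Aem = fda, F_Aex_Aem = 40, F_Aex_Dem = 0),
    class = c("burst_table", "data.frame")))
  em <- accurate_E(tbm, correction_factors(Lk = 0.07, Dir = 0.05, gamma = 0.9))
  expect_true(all(diff(em$E_acc) >= 0))
})

test_that("stoichiometry separates the labeling states in simulation", {
  sim <- simulate_alex_experiment(
    list(species_model(0.5, "dual", 0.5), species_model(0, "donor_only", 0.25),
         species_model(0, "acceptor_only", 0.25)),
    instrument_model(Lk_true = 0.08, Dir_true = 0.06, gamma_true = 0.9),
    1200, seed = 53)
  es <- raw_es(sim$truth)
  st <- sim$truth$label_state
  expect_gt(mean(es$S_raw[st == "donor_only"] > 0.85), 0.99)
  expect_gt(mean(es$S_raw[st == "acceptor_only"] < 0.15), 0.99)
  expect_gt(mean(es$S_raw[st == "dual"] > 0.15 & es$S_raw[st == "dual"] < 0.85),
            0.99)
})

test_that("2D E-S histogram conserves bursts and resolves two species", {
  one <- raw_es(structure(
    data.frame(F_Dex_Dem = 50, F_Dex_Aem = 50, F_Aex_Aem = 100, F_Aex_Dem = 0),
    class = c("burst_table", "data.frame")))
  h1 <- es_histogram_2d(one)
  expect_equal(sum(h1$counts), 1)
  expect_equal(sum(h1$counts > 0), 1)
  sim <- simulate_alex_experiment(
    list(species_model(0.75, "dual", 0.5), species_model(0.25, "dual", 0.5)),
    instrument_model(), 800, seed = 59)
  tb <- raw_es(find_bursts(sim$stream))
  h <- es_histogram_2d(tb)
  expect_equal(sum(h$counts), sum(is.finite(tb$E_raw) & is.finite(tb$S_raw)))
  # two modes separated in E within the intermediate-S band
  emarg <- rowSums(h$counts)
  mids <- (h$E_breaks[-1] + h$E_breaks[-length(h$E_breaks)]) / 2
  top2 <- sort(mids[order(emarg, decreasing = TRUE)[1:4]])
  expect_gt(max(top2) - min(top2), 0.3)
})

test_that("full chain recovers the population mean for a distorted instrument", {
  inst <- instrument_model(Lk_true = 0.12, Dir_true = 0.08, gamma_true = 1.15)
  true_E <- 0.65
  sim <- simulate_alex_experiment(
    list(species_model(true_E, "dual", 0.7), species_model(0, "donor_only", 0.2),
         species_model(0, "acceptor_only", 0.1)),
    inst, 2500, seed = 61)
  std1 <- simulate_alex_experiment(species_model(0.3, "dual", 1), inst, 1000,
                                   seed = 62)
  std2 <- simulate_alex_experiment(species_model(0.8, "dual", 1), inst, 1000,
                                   seed = 63)
  tb <- analyze_alex(sim$stream, standards = list(std1$stream, std2$stream))
  dual <- select_dual(tb)
  expect_lt(abs(mean(dual$E_acc, na.rm = TRUE) - true_E), 0.02)
})
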