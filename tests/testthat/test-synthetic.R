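# forward simulators: ground-truth bookkeeping, estimator unbiasedness,
# reproducibility, degenerate inputs

test_that("burst simulation keeps exact photon bookkeeping and valid streams", {
  sim <- simulate_alex_experiment(
    list(species_model(0.6, "dual", 0.7), species_model(0, "donor_only", 0.3)),
    instrument_model(Lk_true = 0.1, Dir_true = 0.05, gamma_true = 0.9),
    200, seed = 11)
  tr <- sim$truth
  # the four stream counts sum to the drawn burst total
  expect_equal(tr$F_Dex_Dem + tr$F_Dex_Aem + tr$F_Aex_Aem + tr$F_Aex_Dem,
               tr$n_photons)
  # strictly increasing timestamps, all photons on a detector
  expect_true(all(diff(sim$stream$timestamps) > 0))
  expect_true(all(sim$stream$detectors %in% c("donor", "acceptor")))
  # every burst window is disjoint from the next
  expect_true(all(tr$t_start[-1] >= tr$t_end[-nrow(tr)]))
})

test_that("per-burst raw E of an ideal dual species is unbiased", {
  true_E <- 0.6
  sim <- simulate_alex_experiment(
    species_model(true_E, "dual", 1),
    instrument_model(Lk_true = 0, Dir_true = 0, gamma_true = 1,
                     bg_rate_donor_khz = 0, bg_rate_acceptor_khz = 0),
    10000, photons_per_burst = list(mean = 130, min = 100), seed = 7)
  es <- raw_es(sim$truth)
  expect_lt(abs(mean(es$E_raw) - true_E), 0.005)
})

test_that("simulations are bit-reproducible by seed and differ across seeds", {
  a <- simulate_alex_experiment(species_model(0.5, "dual", 1),
                                instrument_model(), 50, seed = 3)
  b <- simulate_alex_experiment(species_model(0.5, "dual", 1),
                                instrument_model(), 50, seed = 3)
  c <- simulate_alex_experiment(species_model(0.5, "dual", 1),
                                instrument_model(), 50, seed = 4)
  expect_identical(a$stream$timestamps, b$stream$timestamps)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_false(identical(a$stream$timestamps, c$stream$timestamps))
  # seeded simulators restore the caller's RNG state
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(simulate_alex_experiment(species_model(0.5, "dual", 1),
                                     instrument_model(), 5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("degenerate burst-simulation inputs behave per contract", {
  # n_bursts = 0: empty stream and empty ground truth
  sim0 <- simulate_alex_experiment(species_model(0.5, "dual", 1),
                                   instrument_model(), 0, seed = 1)
  expect_length(sim0$stream$timestamps, 0)
  expect_equal(nrow(sim0$truth), 0)
  # donor-only, no crosstalk, no background: no acceptor pathway at all
  simd <- simulate_alex_experiment(
    species_model(0, "donor_only", 1),
    instrument_model(Lk_true = 0, Dir_true = 0, bg_rate_donor_khz = 0,
                     bg_rate_acceptor_khz = 0),
    100, seed = 2)
  es <- raw_es(simd$truth)
  expect_true(all(simd$truth$F_Dex_Aem == 0))
  expect_true(all(es$S_raw == 1))
  expect_true(all(es$E_raw == 0))
  # invalid inputs rejected
  expect_error(simulate_alex_experiment(species_model(0.5, "dual", 0.5),
                                        instrument_model(), 10),
               "fractions must sum to 1")
  expect_error(instrument_model(Lk_true = -0.1), "Lk_true")
  expect_error(species_model(1.2, "dual"), "true_E")
})

test_that("TIRF trajectory simulation matches its stated level structure", {
  tr <- simulate_tirf_trajectory(
    tirf_ground_truth(0.6, Id_level = 500, bg_d = 50, bg_a = 30,
                      acceptor_bleach_frame = 80, donor_bleach_frame = 200,
                      noise_sd = 0),
    300)
  expect_equal(unique(tr$I_d[1:79]), 500 * 0.4 + 50)
  expect_equal(unique(tr$I_d[80:199]), 550)
  expect_equal(unique(tr$I_d[200:300]), 50)
  expect_equal(unique(tr$I_a[1:79]), 500 * 0.6 + 30)
  expect_equal(unique(tr$I_a[80:300]), 30)
  expect_error(tirf_ground_truth(0.6, acceptor_bleach_frame = 200,
                                 donor_bleach_frame = 100),
               "must precede")
  expect_error(simulate_tirf_trajectory(
    tirf_ground_truth(0.6, acceptor_bleach_frame = 80, donor_bleach_frame = 200),
    150), "n_frames")
})

test_that("FCS curve simulation matches the model amplitude and monotonicity", {
  cv <- simulate_fcs_curve(4, 4e-4, kappa = 6,
                           lags = 10^seq(-9, 0, length.out = 64), noise_sd = 0)
  expect_equal(cv$G[1], 1 / 4, tolerance = 1e-5)  # lag -> 0 limit
  expect_true(all(diff(cv$G) <= 0))               # non-increasing in lag
  expect_error(simulate_fcs_curve(4, -1), "tau_D")
  expect_error(simulate_fcs_curve(4, 1e-3, kappa = 0.5), "kappa")
})

test_that("assay curve simulation honors its closed-form anchors", {
  mm <- simulate_assay_curves("michaelis_menten", list(KM = 1.5, Vmax = 2),
                              x_grid = 1.5)
  expect_equal(mm$rate, 1)  # S = KM gives Vmax/2
  b <- simulate_assay_curves("binding", list(Kd = 0.22), x_grid = 0)
  expect_equal(b$intensity_norm, 1)  # no ligand, no quench
  expect_error(simulate_assay_curves("unknown", list(), 1), "unknown mode")
  expect_error(simulate_assay_curves("binding", list(Kd = -1), 1), "Kd")
})
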