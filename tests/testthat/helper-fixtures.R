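# shared fixtures built in code

# photon stream with one hand-planted burst: n photons packed into the donor
# excitation windows of consecutive periods starting at t0, over optional
# sparse background
planted_burst_stream <- function(n = 60, t0 = 5000, span_ms = 1,
                                 scheme = alternation_scheme()) {
  per <- scheme$period_us
  k <- span_ms * 1000 / per
  slots <- as.vector(outer(seq(scheme$dex_window[1], scheme$dex_window[2] - 1,
                               by = 1),
                           t0 + per * (seq_len(k) - 1), `+`))
  t <- sort(slots)[seq_len(n)]
  photon_stream(t, rep("donor", n), scheme)
}

# sparse homogeneous background stream at `rate_khz` over `dur_s` seconds
background_stream <- function(rate_khz = 1, dur_s = 10, seed = 1,
                              scheme = alternation_scheme()) {
  n <- rpois(1, rate_khz * dur_s * 1000)  # RNG seeding handled by caller
  t <- sort(sample.int(dur_s * 1e6, n)) - 1
  det <- sample(c("donor", "acceptor"), n, replace = TRUE)
  photon_stream(t, det, scheme)
}

# standard two-ruler gamma calibration against a given instrument
calibrate_from_standards <- function(inst, factors, n_bursts = 1000, seed = 1) {
  s1 <- simulate_alex_experiment(species_model(0.3, "dual", 1), inst, n_bursts,
                                 seed = seed)
  s2 <- simulate_alex_experiment(species_model(0.8, "dual", 1), inst, n_bursts,
                                 seed = seed + 1)
  calibrate_gamma(list(
    correct_counts(raw_es(find_bursts(s1$stream)), factors),
    correct_counts(raw_es(find_bursts(s2$stream)), factors)), factors = factors)
}
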