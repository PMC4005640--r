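# Forward simulators for every data type the analysis consumes, each with
# explicit seeds and recorded ground truth so downstream stages are testable
# by parameter recovery.
#
# The ALEX simulator is an effective per-burst model: no diffusion-path or
# optics physics. Each burst draws a total photon count (shifted Poisson,
# floored) and splits it multinomially over the detection streams with weights
#   w_DD = bD * (1 - E)
#   w_DA = bD * (gamma * E + Lk * (1 - E)) + Dir * bA
#   w_AA = bA
# (bD/bA = per-burst brightness under donor/acceptor excitation). This is the
# inverse of the correction order: gamma-weighted partition, then leakage,
# then direct excitation; background photons arrive as an independent
# homogeneous process. Leakage enters as an additive acceptor-channel weight
# proportional to the donor-channel weight, so the donor-only population ratio
# F_Dex_Aem / F_Dex_Dem recovers Lk exactly.

#' FRET species model for burst simulation
#'
#' One molecular species in a simulated ALEX mixture: its true transfer
#' efficiency, labeling state, mixing weight and effective per-burst
#' brightness under each laser.
#'
#' @param true_E true FRET efficiency in \[0, 1\] (ignored for single-label
#'   species).
#' @param label_state `"dual"`, `"donor_only"` or `"acceptor_only"`.
#' @param fraction mixing weight in \[0, 1\]; fractions over a species list
#'   must sum to 1.
#' @param brightness_Dex mean detected photons per burst under donor
#'   excitation (forced to 0 for acceptor-only species).
#' @param brightness_Aex mean detected photons per burst under acceptor
#'   excitation (forced to 0 for donor-only species).
#' @return an object of class `species_model`.
#' @export
species_model <- function(true_E, label_state = c("dual", "donor_only", "acceptor_only"),
                          fraction = 1, brightness_Dex = 100, brightness_Aex = 80) {
  label_state <- match.arg(label_state)
  .assert(.is_number(true_E) && true_E >= 0 && true_E <= 1,
          "true_E must lie in [0, 1]")
  .assert(.is_number(fraction) && fraction >= 0 && fraction <= 1,
          "fraction must lie in [0, 1]")
  .assert(.is_number(brightness_Dex) && brightness_Dex >= 0,
          "brightness_Dex must be >= 0")
  .assert(.is_number(brightness_Aex) && brightness_Aex >= 0,
          "brightness_Aex must be >= 0")
  if (label_state == "donor_only") brightness_Aex <- 0
  if (label_state == "acceptor_only") brightness_Dex <- 0
  structure(list(true_E = true_E, label_state = label_state, fraction = fraction,
                 brightness_Dex = brightness_Dex, brightness_Aex = brightness_Aex),
            class = "species_model")
}

#' Instrument model for burst simulation
#'
#' True distortion parameters of the simulated instrument: donor leakage,
#' acceptor direct excitation, detection-correction factor and background
#' count rates, plus the laser alternation scheme.
#'
#' @param Lk_true,Dir_true dimensionless crosstalk fractions (>= 0).
#' @param gamma_true detection-correction factor (> 0).
#' @param bg_rate_donor_khz,bg_rate_acceptor_khz background count rates per
#'   detector (kHz).
#' @param alternation an [alternation_scheme()].
#' @return an object of class `instrument_model`.
#' @export
instrument_model <- function(Lk_true = 0, Dir_true = 0, gamma_true = 1,
                             bg_rate_donor_khz = 0.3, bg_rate_acceptor_khz = 0.3,
                             alternation = alternation_scheme()) {
  .assert(.is_number(Lk_true) && Lk_true >= 0, "Lk_true must be >= 0")
  .assert(.is_number(Dir_true) && Dir_true >= 0, "Dir_true must be >= 0")
  .assert(.is_number(gamma_true) && gamma_true > 0, "gamma_true must be > 0")
  .assert(.is_number(bg_rate_donor_khz) && bg_rate_donor_khz >= 0,
          "bg_rate_donor_khz must be >= 0")
  .assert(.is_number(bg_rate_acceptor_khz) && bg_rate_acceptor_khz >= 0,
          "bg_rate_acceptor_khz must be >= 0")
  .assert(inherits(alternation, "alternation_scheme"),
          "alternation must be an alternation_scheme")
  structure(list(Lk_true = Lk_true, Dir_true = Dir_true, gamma_true = gamma_true,
                 bg_rate_donor_khz = bg_rate_donor_khz,
                 bg_rate_acceptor_khz = bg_rate_acceptor_khz,
                 alternation = alternation),
            class = "instrument_model")
}

#' Simulate an ALEX single-molecule burst experiment
#'
#' Forward-simulates a photon stream of diffusing-molecule bursts from a
#' species mixture and an instrument model, together with a ground-truth
#' burst table recording each burst's species and true stream counts.
#' Per burst the total photon count is drawn from a shifted Poisson
#' (mean `photons_per_burst$mean`, floored at `photons_per_burst$min`) and
#' split multinomially over the detection streams (see file header for the
#' distortion weights); burst inter-arrival times are exponential; background
#' photons arrive as a homogeneous random process at the instrument rates.
#' Photon timestamps are distinct integer microseconds, so the stream is
#' strictly increasing.
#'
#' @param species a [species_model()] or list of them; fractions must sum to 1.
#' @param instrument an [instrument_model()].
#' @param n_bursts number of bursts (>= 0).
#' @param photons_per_burst list with `mean` and `min` of the shifted-Poisson
#'   burst-size distribution.
#' @param burst_duration_ms nominal burst duration (extended automatically if
#'   a burst draws more photons than its excitation windows can hold).
#' @param interarrival_mean_ms mean exponential gap between bursts (default
#'   250 ms, the single-molecule dilution regime: the chance of two
#'   molecules landing in the same or adjacent 1 ms search windows stays
#'   below ~1%, so multi-molecule bursts are negligible).
#' @param seed integer seed; simulations are bit-reproducible given the seed.
#' @return list with `stream` (a [photon_stream()]) and `truth` (a
#'   ground-truth `burst_table` with species labels and true counts).
#' @export
simulate_alex_experiment <- function(species, instrument = instrument_model(),
                                     n_bursts,
                                     photons_per_burst = list(mean = 100, min = 40),
                                     burst_duration_ms = 1,
                                     interarrival_mean_ms = 250,
                                     seed = NULL) {
  if (inherits(species, "species_model")) species <- list(species)
  .assert(length(species) >= 1 && all(vapply(species, inherits, logical(1), "species_model")),
          "species must be a species_model or list of species_model")
  .assert(inherits(instrument, "instrument_model"), "instrument must be an instrument_model")
  .assert(.is_count(n_bursts), "n_bursts must be a non-negative count")
  fr <- vapply(species, `[[`, numeric(1), "fraction")
  .assert(abs(sum(fr) - 1) < 1e-9, "species fractions must sum to 1 (got %.6f)", sum(fr))
  .assert(is.list(photons_per_burst) && .is_number(photons_per_burst$mean) &&
            .is_number(photons_per_burst$min) &&
            photons_per_burst$mean >= photons_per_burst$min &&
            photons_per_burst$min >= 1,
          "photons_per_burst must give mean >= min >= 1")
  .assert(.is_number(burst_duration_ms) && burst_duration_ms > 0,
          "burst_duration_ms must be positive")
  .assert(.is_number(interarrival_mean_ms) && interarrival_mean_ms > 0,
          "interarrival_mean_ms must be positive")

  sch <- instrument$alternation
  truth_empty <- new_burst_table(data.frame(
    species = integer(0), label_state = character(0), true_E = numeric(0),
    t_start = numeric(0), t_end = numeric(0),
    F_Dex_Dem = integer(0), F_Dex_Aem = integer(0),
    F_Aex_Aem = integer(0), F_Aex_Dem = integer(0), n_photons = integer(0)))
  if (n_bursts == 0L) {
    return(list(stream = photon_stream(numeric(0), character(0), sch),
                truth = truth_empty))
  }

  with_seed(seed, {
    sp <- sample.int(length(species), n_bursts, replace = TRUE, prob = fr)
    st <- vapply(species, `[[`, character(1), "label_state")[sp]
    E <- vapply(species, `[[`, numeric(1), "true_E")[sp]
    E[st == "donor_only"] <- 0
    bD <- vapply(species, `[[`, numeric(1), "brightness_Dex")[sp]
    bA <- vapply(species, `[[`, numeric(1), "brightness_Aex")[sp]

    floor_n <- round(photons_per_burst$min)
    n_tot <- floor_n + rpois(n_bursts, photons_per_burst$mean - floor_n)

    g <- instrument$gamma_true
    wDD <- bD * (1 - E)
    wDA <- bD * (g * E + instrument$Lk_true * (1 - E)) + instrument$Dir_true * bA
    wAA <- bA
    W <- wDD + wDA + wAA
    .assert(all(W > 0), "every species must have positive total brightness")

    nDD <- rbinom(n_bursts, n_tot, wDD / W)
    rem <- n_tot - nDD
    pDA <- ifelse(wDA + wAA > 0, wDA / (wDA + wAA), 0)
    nDA <- rbinom(n_bursts, rem, pDA)
    nAA <- rem - nDA

    # timing: each burst occupies k whole alternation periods starting on a
    # period boundary; photon times are sampled without replacement from the
    # integer-microsecond slots of the matching excitation windows
    period <- sch$period_us
    dex0 <- ceiling(sch$dex_window[1]); dex1 <- ceiling(sch$dex_window[2])
    aex0 <- ceiling(sch$aex_window[1]); aex1 <- ceiling(sch$aex_window[2])
    slots_d <- dex1 - dex0
    slots_a <- aex1 - aex0
    k_def <- max(1, ceiling(burst_duration_ms * 1000 / period))
    k <- pmax(k_def,
              ceiling((nDD + nDA) / (0.8 * slots_d)),
              ceiling(nAA / (0.8 * slots_a)))
    dur <- k * period
    gaps <- rexp(n_bursts, rate = 1 / interarrival_mean_ms) * 1000

    times <- vector("list", n_bursts)
    dets <- vector("list", n_bursts)
    t_start <- numeric(n_bursts)
    t_end <- numeric(n_bursts)
    prev_end <- 0
    dex_off <- dex0:(dex1 - 1)
    aex_off <- aex0:(aex1 - 1)
    for (i in seq_len(n_bursts)) {
      s0 <- ceiling((prev_end + gaps[i]) / period) * period
      ki <- k[i]
      base <- s0 + period * (seq_len(ki) - 1)
      dslots <- as.vector(outer(dex_off, base, `+`))
      aslots <- as.vector(outer(aex_off, base, `+`))
      nd <- nDD[i] + nDA[i]
      td <- if (nd) sort(sample(dslots, nd)) else numeric(0)
      which_da <- if (nd && nDA[i]) sample.int(nd, nDA[i]) else integer(0)
      dd_det <- rep("donor", nd)
      dd_det[which_da] <- "acceptor"
      ta <- if (nAA[i]) sort(sample(aslots, nAA[i])) else numeric(0)
      times[[i]] <- c(td, ta)
      dets[[i]] <- c(dd_det, rep("acceptor", nAA[i]))
      t_start[i] <- s0
      t_end[i] <- s0 + ki * period
      prev_end <- t_end[i]
    }
    burst_t <- unlist(times)
    burst_d <- unlist(dets)

    # homogeneous background over the full record
    T_end <- prev_end + period
    n_bg_d <- rpois(1, instrument$bg_rate_donor_khz * T_end / 1000)
    n_bg_a <- rpois(1, instrument$bg_rate_acceptor_khz * T_end / 1000)
    n_bg <- n_bg_d + n_bg_a
    bg_t <- numeric(0)
    if (n_bg > 0) {
      bg_t <- sample.int(T_end, n_bg) - 1
      # redraw any collision with burst photons (rare; keeps strict ordering)
      for (it in 1:50) {
        clash <- bg_t %in% burst_t | duplicated(bg_t)
        if (!any(clash)) break
        bg_t[clash] <- sample.int(T_end, sum(clash)) - 1
      }
    }
    bg_det <- c(rep("donor", n_bg_d), rep("acceptor", n_bg_a))

    all_t <- c(burst_t, bg_t)
    all_d <- c(burst_d, bg_det)
    o <- order(all_t)
    stream <- photon_stream(all_t[o], all_d[o], sch)

    truth <- new_burst_table(data.frame(
      species = sp, label_state = st,
      true_E = vapply(species, `[[`, numeric(1), "true_E")[sp],
      t_start = t_start, t_end = t_end,
      F_Dex_Dem = nDD, F_Dex_Aem = nDA, F_Aex_Aem = nAA,
      F_Aex_Dem = 0L, n_photons = n_tot))
    list(stream = stream, truth = truth)
  })
}

#' Ground truth for a simulated TIRF trajectory
#'
#' Parameters of one immobilized molecule's two-channel intensity trace with
#' the useful bleaching sequence: acceptor photobleach first, donor second.
#'
#' @param true_E true FRET efficiency.
#' @param Id_level donor intensity with no acceptor present (counts/frame).
#' @param bg_d,bg_a channel backgrounds (counts/frame).
#' @param acceptor_bleach_frame,donor_bleach_frame 1-based indices of the
#'   first frame at the bleached level; acceptor must precede donor.
#' @param noise_sd Gaussian frame noise (counts/frame).
#' @return an object of class `tirf_ground_truth`.
#' @export
tirf_ground_truth <- function(true_E, Id_level = 500, bg_d = 60, bg_a = 40,
                              acceptor_bleach_frame, donor_bleach_frame,
                              noise_sd = 30) {
  .assert(.is_number(true_E) && true_E >= 0 && true_E <= 1, "true_E must be in [0, 1]")
  .assert(all(c(Id_level, bg_d, bg_a) >= 0), "intensity levels must be >= 0")
  .assert(.is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  .assert(.is_count(acceptor_bleach_frame) && .is_count(donor_bleach_frame),
          "bleach frames must be counts")
  .assert(acceptor_bleach_frame < donor_bleach_frame,
          "acceptor_bleach_frame must precede donor_bleach_frame")
  structure(list(true_E = true_E, Id_level = Id_level, bg_d = bg_d, bg_a = bg_a,
                 acceptor_bleach_frame = as.integer(acceptor_bleach_frame),
                 donor_bleach_frame = as.integer(donor_bleach_frame),
                 noise_sd = noise_sd),
            class = "tirf_ground_truth")
}

#' Two-channel TIRF intensity trajectory
#'
#' Frame-indexed donor/acceptor intensities of one immobilized molecule.
#'
#' @param I_d,I_a per-frame donor and acceptor intensities (equal length).
#' @param frame_period_ms camera frame period (default 100 ms exposure).
#' @param molecule_id label.
#' @return an object of class `fret_trajectory`.
#' @export
fret_trajectory <- function(I_d, I_a, frame_period_ms = 100, molecule_id = "mol1") {
  .assert(length(I_d) == length(I_a), "channel lengths must be equal")
  .assert(.is_number(frame_period_ms) && frame_period_ms > 0,
          "frame_period_ms must be positive")
  structure(list(I_d = as.numeric(I_d), I_a = as.numeric(I_a),
                 frame_period_ms = frame_period_ms,
                 molecule_id = as.character(molecule_id)),
            class = "fret_trajectory")
}

#' @export
print.fret_trajectory <- function(x, ...) {
  cat(sprintf("TIRF trajectory '%s': %d frames at %g ms\n",
              x$molecule_id, length(x$I_d), x$frame_period_ms))
  invisible(x)
}

#' Simulate a TIRF bleaching trajectory
#'
#' Generates a two-channel trace with the stated bleaching sequence: before
#' the acceptor bleach the donor runs at `Id_level*(1-true_E) + bg_d` and the
#' acceptor at `Id_level*true_E + bg_a`; between the bleaches the donor
#' recovers to `Id_level + bg_d` while the acceptor sits at background; after
#' the donor bleach both channels are at background. Gaussian frame noise of
#' sd `noise_sd` is added to both channels.
#'
#' @param truth a [tirf_ground_truth()].
#' @param n_frames total frames (> `donor_bleach_frame`).
#' @param seed integer seed.
#' @param molecule_id label for the trajectory.
#' @return a [fret_trajectory()].
#' @export
simulate_tirf_trajectory <- function(truth, n_frames = 300, seed = NULL,
                                     molecule_id = "mol1") {
  .assert(inherits(truth, "tirf_ground_truth"), "truth must be a tirf_ground_truth")
  .assert(.is_count(n_frames) && n_frames > truth$donor_bleach_frame,
          "n_frames must exceed donor_bleach_frame")
  with_seed(seed, {
    f <- seq_len(n_frames)
    a <- truth$acceptor_bleach_frame
    d <- truth$donor_bleach_frame
    mu_d <- ifelse(f < a, truth$Id_level * (1 - truth$true_E) + truth$bg_d,
                   ifelse(f < d, truth$Id_level + truth$bg_d, truth$bg_d))
    mu_a <- ifelse(f < a, truth$Id_level * truth$true_E + truth$bg_a, truth$bg_a)
    fret_trajectory(mu_d + rnorm(n_frames, 0, truth$noise_sd),
                    mu_a + rnorm(n_frames, 0, truth$noise_sd),
                    molecule_id = molecule_id)
  })
}

#' Simulate an ensemble of TIRF trajectories
#'
#' Draws `n_molecules` traces at a common true efficiency with randomized
#' bleach times. A fraction `p_defect` of traces violates the useful
#' bleaching sequence (donor bleaching first, taking the FRET-fed acceptor
#' down with it, or donor blinking producing a second downward step) and
#' should be rejected by [detect_bleach_steps()].
#'
#' @param n_molecules ensemble size.
#' @param true_E true FRET efficiency.
#' @param n_frames frames per trace.
#' @param Id_level,bg_d,bg_a,noise_sd trace levels, see [tirf_ground_truth()].
#' @param p_defect probability of a non-conforming trace (default 0.5,
#'   mirroring the typical yield of useful bleaching sequences).
#' @param seed integer seed.
#' @return list of [fret_trajectory()] with a `truth` data.frame attribute
#'   (per-molecule bleach frames and defect flags).
#' @export
simulate_tirf_ensemble <- function(n_molecules, true_E, n_frames = 300,
                                   Id_level = 500, bg_d = 60, bg_a = 40,
                                   noise_sd = 30, p_defect = 0.5, seed = NULL) {
  .assert(.is_count(n_molecules) && n_molecules >= 1, "n_molecules must be >= 1")
  with_seed(seed, {
    a <- sample(40:120, n_molecules, replace = TRUE)
    d <- pmin(a + sample(60:140, n_molecules, replace = TRUE), n_frames - 40L)
    defect <- runif(n_molecules) < p_defect
    type <- ifelse(defect,
                   sample(c("donor_first", "blink"), n_molecules, replace = TRUE),
                   "none")
    trajs <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      id <- sprintf("mol%03d", i)
      if (type[i] == "none") {
        tr <- simulate_tirf_trajectory(
          tirf_ground_truth(true_E, Id_level, bg_d, bg_a, a[i], d[i], noise_sd),
          n_frames, molecule_id = id)
      } else if (type[i] == "donor_first") {
        # donor dies first; the FRET-fed acceptor goes dark at the same frame
        f <- seq_len(n_frames)
        mu_d <- ifelse(f < d[i], Id_level * (1 - true_E) + bg_d, bg_d)
        mu_a <- ifelse(f < d[i], Id_level * true_E + bg_a, bg_a)
        tr <- fret_trajectory(mu_d + rnorm(n_frames, 0, noise_sd),
                              mu_a + rnorm(n_frames, 0, noise_sd),
                              molecule_id = id)
      } else {
        # donor blinks off for a stretch between the two bleaches
        tr <- simulate_tirf_trajectory(
          tirf_ground_truth(true_E, Id_level, bg_d, bg_a, a[i], d[i], noise_sd),
          n_frames, molecule_id = id)
        off0 <- a[i] + max(5L, (d[i] - a[i]) %/% 3L)
        off1 <- min(off0 + 15L, d[i] - 5L)
        tr$I_d[off0:off1] <- bg_d + rnorm(off1 - off0 + 1L, 0, noise_sd)
      }
      trajs[[i]] <- tr
    }
    attr(trajs, "truth") <- data.frame(
      molecule_id = sprintf("mol%03d", seq_len(n_molecules)),
      true_E = true_E, acceptor_bleach_frame = a, donor_bleach_frame = d,
      defect = type, stringsAsFactors = FALSE)
    trajs
  })
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the single-component 3D-diffusion autocorrelation model on a lag
#' grid and applies multiplicative Gaussian noise.
#'
#' @param n_particles mean focal-volume occupancy N (> 0).
#' @param tau_D diffusion time in seconds (> 0).
#' @param kappa axial-to-lateral focus ratio (> 1).
#' @param lags lag-time grid in seconds (log-spaced by default).
#' @param noise_sd relative (multiplicative) noise level.
#' @param seed integer seed.
#' @return an object of class `fcs_curve` with `lags`, `G`, and the
#'   generating parameters in `$truth`.
#' @export
simulate_fcs_curve <- function(n_particles, tau_D, kappa = 6,
                               lags = 10^seq(-6, 0, length.out = 64),
                               noise_sd = 0, seed = NULL) {
  .assert(.is_number(tau_D) && tau_D > 0, "tau_D must be positive")
  .assert(.is_number(kappa) && kappa > 1, "kappa must exceed 1")
  .assert(.is_number(n_particles) && n_particles > 0, "n_particles must be positive")
  .assert(is.numeric(lags) && all(lags > 0) && !is.unsorted(lags, strictly = TRUE),
          "lags must be strictly increasing and positive")
  with_seed(seed, {
    G0 <- fcs_model(lags, n_particles, tau_D, kappa)
    G <- G0 * (1 + rnorm(length(lags), 0, noise_sd))
    structure(list(lags = lags, G = G,
                   truth = list(n_particles = n_particles, tau_D = tau_D,
                                kappa = kappa, noise_sd = noise_sd)),
              class = "fcs_curve")
  })
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("FCS curve: %d lags, G(0+) ~ %.4f\n", length(x$lags), x$G[1]))
  invisible(x)
}

#' Simulate bulk assay curves
#'
#' Generates a noisy titration (tight-binding donor quench) or
#' Michaelis-Menten rate curve.
#'
#' For `mode = "binding"`, `params` needs `Kd` (nM) and optionally
#' `labeled_total` (nM, default 10) and `amplitude` (default 0.7); the
#' normalized donor intensity declines as `1 - amplitude * fraction_bound`
#' with the exact ligand-depletion (quadratic) bound fraction, plus additive
#' Gaussian noise of sd `noise_sd`. For `mode = "michaelis_menten"`, `params`
#' needs `KM` (mM) and `Vmax`; rates follow `v = Vmax*S/(KM + S)` with
#' multiplicative Gaussian noise of relative sd `noise_sd`.
#'
#' @param mode `"binding"` or `"michaelis_menten"`.
#' @param params named list of model parameters (see Details).
#' @param x_grid ligand (nM) or substrate (mM) grid.
#' @param noise_sd noise level (absolute for binding, relative for MM).
#' @param seed integer seed.
#' @return a data.frame: `ligand_nM`/`intensity_norm` or `substrate_mM`/`rate`.
#' @export
simulate_assay_curves <- function(mode, params, x_grid, noise_sd = 0, seed = NULL) {
  .assert(is.character(mode) && length(mode) == 1L &&
            mode %in% c("binding", "michaelis_menten"),
          "unknown mode '%s': use 'binding' or 'michaelis_menten'", as.character(mode)[1])
  .assert(is.numeric(x_grid) && all(x_grid >= 0), "x_grid must be non-negative")
  with_seed(seed, {
    if (mode == "binding") {
      .assert(.is_number(params$Kd) && params$Kd > 0, "binding mode needs Kd > 0")
      P <- if (is.null(params$labeled_total)) 10 else params$labeled_total
      A <- if (is.null(params$amplitude)) 0.7 else params$amplitude
      fb <- fraction_bound(x_grid, P, params$Kd)
      data.frame(ligand_nM = x_grid,
                 intensity_norm = 1 - A * fb + rnorm(length(x_grid), 0, noise_sd))
    } else {
      .assert(.is_number(params$KM) && params$KM > 0, "michaelis_menten mode needs KM > 0")
      .assert(.is_number(params$Vmax) && params$Vmax > 0, "michaelis_menten mode needs Vmax > 0")
      v <- params$Vmax * x_grid / (params$KM + x_grid)
      data.frame(substrate_mM = x_grid,
                 rate = v * (1 + rnorm(length(x_grid), 0, noise_sd)))
    }
  })
}

#' Draw FRET efficiencies from a Gaussian mixture
#'
#' Ground-truth event generator for population-analysis tests: samples
#' per-molecule efficiencies from a 1- or 2-component Gaussian mixture.
#'
#' @param means,widths,fractions component parameters (equal lengths;
#'   fractions sum to 1).
#' @param n number of events.
#' @param seed integer seed.
#' @return numeric vector of `n` efficiencies.
#' @export
simulate_efficiencies <- function(means, widths, fractions, n, seed = NULL) {
  .assert(length(means) == length(widths) && length(means) == length(fractions),
          "means, widths and fractions must have equal length")
  .assert(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  .assert(all(widths > 0), "widths must be positive")
  .assert(.is_count(n) && n >= 1, "n must be a positive count")
  with_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = fractions)
    rnorm(n, means[comp], widths[comp])
  })
}

#' Experimental-scenario presets for the ALEX simulator
#'
#' Species mixtures encoding the study's promoter-complex scenarios, with the
#' reported population means and fractions as generator parameters. Each
#' preset mixes the dual-labeled conformer populations (75% of bursts,
#' split by the reported fractions) with donor-only (15%) and acceptor-only
#' (10%) contaminants so that crosstalk calibration is exercised.
#'
#' Available presets: `"free-sigma54"` (two conformers, E 0.74/0.49,
#' 73%/27%), `"holoenzyme"` (E 0.71), `"rpc"` (closed complex, E 0.75),
#' `"late-melted"` (E 0.29/0.73, 43%/57%), `"late-melted-pspf"`
#' (E 0.27/0.73, 78%/22%), `"rpo-atp"` (post-hydrolysis, E 0.22), and
#' `"standards"` (two polyproline-like FRET rulers at E 0.3/0.8, dual-label
#' only, used for gamma calibration).
#'
#' @param name preset name.
#' @return list with `name`, `species` (list of [species_model()]) and
#'   `description`.
#' @export
alex_preset <- function(name = c("free-sigma54", "holoenzyme", "rpc",
                                 "late-melted", "late-melted-pspf", "rpo-atp",
                                 "standards")) {
  name <- match.arg(name)
  duals <- switch(name,
    "free-sigma54" = list(E = c(0.74, 0.49), f = c(0.73, 0.27)),
    "holoenzyme" = list(E = 0.71, f = 1),
    "rpc" = list(E = 0.75, f = 1),
    "late-melted" = list(E = c(0.29, 0.73), f = c(0.43, 0.57)),
    "late-melted-pspf" = list(E = c(0.27, 0.73), f = c(0.78, 0.22)),
    "rpo-atp" = list(E = 0.22, f = 1),
    "standards" = list(E = c(0.3, 0.8), f = c(0.5, 0.5)))
  desc <- switch(name,
    "free-sigma54" = "free dual-labeled sigma54: two conformers 0.74 (73%) / 0.49 (27%)",
    "holoenzyme" = "sigma54-RNAP holoenzyme: single population E = 0.71",
    "rpc" = "closed promoter complex on the early-melted promoter: E = 0.75",
    "late-melted" = "holoenzyme on the late-melted promoter: E 0.29 (43%) / 0.73 (57%)",
    "late-melted-pspf" = "late-melted complex plus apo-PspF: E 0.27 (78%) / 0.73 (22%)",
    "rpo-atp" = "heparin-resistant open complex after ATP hydrolysis: E = 0.22",
    "standards" = "two polyproline-like FRET rulers (E 0.3 / 0.8) for gamma calibration")
  if (name == "standards") {
    species <- mapply(function(e, f) species_model(e, "dual", f),
                      duals$E, duals$f, SIMPLIFY = FALSE)
  } else {
    species <- c(
      mapply(function(e, f) species_model(e, "dual", 0.75 * f),
             duals$E, duals$f, SIMPLIFY = FALSE),
      list(species_model(0, "donor_only", 0.15),
           species_model(0, "acceptor_only", 0.10)))
  }
  list(name = name, species = species, description = desc)
}
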