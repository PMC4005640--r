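---
title: "Models and methods behind smfret"
author: "smfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfret)
```

This vignette explains the models the package implements, the assumptions
they make, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices taken
where the design was genuinely open. Every empirical statement here is one
the test suite or the acceptance script computes.

## 1. ALEX burst spectroscopy

### Observables

In alternating laser excitation, a diffusing dual-labeled molecule crossing
the confocal volume produces a photon burst that is split into four streams
by excitation window (donor `Dex` / acceptor `Aex`, taken modulo the
alternation period) and detector (`Dem`/`Aem`). The alternation period
defaults to 100 µs with a 40% duty cycle per laser; the window placement
within the period is not physically constrained, so the package uses
`Dex = [0, 40)` µs and `Aex = [50, 90)` µs with symmetric 10 µs guard gaps.
Photons in the gaps are labeled `off_window` and excluded from stream
counts (they still count toward burst detection, since detection is
spectroscopy-agnostic). Timestamps are integer microseconds so window
assignment at boundaries is exact; windows are half-open.

The uncorrected proximity ratio and stoichiometry are

$$E_{raw} = \frac{F^{Dex}_{Aem}}{F^{Dex}_{Aem} + F^{Dex}_{Dem}},\qquad
S_{raw} = \frac{F^{Dex}_{Aem} + F^{Dex}_{Dem}}
               {F^{Dex}_{Aem} + F^{Dex}_{Dem} + F^{Aex}_{Aem}}.$$

$S$ separates donor-only molecules ($S \approx 1$), acceptor-only
($S \approx 0$) and dual-labeled molecules (intermediate $S$). Bursts with
an undefined ratio (zero denominator) are flagged `NA` and retained in the
table but excluded from histograms.

### Burst search

A burst is a maximal run of contiguous 1 ms smoothing windows whose
all-photon rate exceeds 3 kHz; bursts with fewer than `min_photons = 40`
photons (the midpoint of the conventional 35–50 range) are discarded. The
binned-rate search was chosen over a sliding Lee/Seidel-style search
because the method is specified only by a rate threshold and a photon
floor; at the default 3 kHz threshold and 40-photon floor, sub-threshold
background produces essentially no false bursts, and planted bursts at ten
times the threshold rate are recovered with ≥ 99% recall and precision
(property-tested). The smoothing window (1 ms) matches the typical transit
time; both are user parameters.

### Crosstalk and γ corrections

Two crosstalk terms contaminate the FRET channel: donor emission leaking
into the acceptor detector (*Lk*) and direct excitation of the acceptor by
the donor laser (*Dir*). They are estimated from the calibration
subpopulations of the same measurement — *Lk* as the median of
$F^{Dex}_{Aem}/F^{Dex}_{Dem}$ over donor-only bursts
($S_{raw} > 0.85$), *Dir* as the median of
$F^{Dex}_{Aem}/F^{Aex}_{Aem}$ over acceptor-only bursts
($S_{raw} < 0.15$). Medians are used because per-burst count ratios are
heavy-tailed at low counts. At least 20 bursts per subpopulation are
required; otherwise the estimator refuses and asks for externally supplied
factors. The corrected FRET count is
$F_{fret} = F^{Dex}_{Aem} - Lk\,F^{Dex}_{Dem} - Dir\,F^{Aex}_{Aem}$,
floored at zero.

The detection-correction factor γ absorbs the donor/acceptor difference in
detection efficiency and quantum yield. It is calibrated from two (or
more) FRET standards of distinct efficiency — polyproline-type rulers —
by fitting the linear relation

$$1/S_{corr} = \Omega + \Sigma\, E_{corr}$$

through the standards' population means and taking
$\gamma = (\Omega - 1)/(\Omega + \Sigma - 1)$. Calibration uses
crosstalk-corrected, γ-uncorrected observables; whether the stoichiometry
entering the calibration plot should itself be γ-corrected is not uniquely
fixed by the published material, and this choice is validated end to end:
with simulated instruments at γ between 0.75 and 1.2 (the experimentally
observed range) the full chain recovers γ within 5%. Standards whose mean
efficiencies differ by less than 0.1 raise a degenerate-regression error.
The accurate efficiency is
$E = F_{fret}/(F_{fret} + \gamma F^{Dex}_{Dem})$.

## 2. TIRF donor-bleaching FRET

Immobilized complexes are recorded as two-channel frame trajectories
(100 ms frames). Backgrounds $B_d$, $B_a$ are the channel means over the
last `tail_frames = 30` frames (3 s, honoring the several-seconds
convention) and are subtracted. Change points are located per channel by
least-squares binary segmentation: the best single split of a segment is
accepted when its residual-sum-of-squares reduction exceeds a BIC-style
penalty ($10\,\hat\sigma^2 \ln n$, with $\hat\sigma$ from the median
absolute deviation of first differences, which is robust to the steps
themselves); splitting recurses to at most four change points. On
noise-free traces any true step is accepted (the penalty floor is tiny),
so synthetic staircases are localized exactly.

A trace is **usable** when the acceptor channel shows exactly one downward
step, the donor channel exactly one downward step landing at background
(an upward donor step at the acceptor bleach is expected and permitted),
and the acceptor step strictly precedes the donor step. The estimator then
averages the donor channel before the acceptor bleach ($I_{DA}$) and
between the two bleaches ($I_D$) and returns
$E = (I_D - I_{DA})/I_D$ — the standard donor-bleaching form, which is
insensitive to γ and to leakage because only the donor channel enters.
Averaging regions shorter than 5 frames flag the molecule undefined.
Frame averaging makes the per-molecule estimator noise small
(scaling as $1/\sqrt{\text{region length}}$, property-tested), so ensemble
histograms at realistic camera noise are dominated by binning rather than
shot noise; ensemble modes are therefore read from the peak histogram bin.

The ensemble simulator emulates the practical yield of useful bleaching
sequences: a configurable fraction of traces (default 50%) is generated
defective, either with the donor bleaching first (which silences the
FRET-fed acceptor in the same frame) or with donor blinking; the analysis
must reject these, and tests verify that it does.

## 3. Population analysis

Efficiency histograms use bin width 0.025 over $[-0.1, 1.1]$; out-of-range
values are counted into the end bins so events are conserved. Histograms
are fitted with a baseline plus one or two Gaussians parameterized by
**area** (not amplitude), so population fractions are directly
$area_i/\sum_j area_j$. Bounds keep means inside the histogram range,
widths in $[\text{bin}/2, \text{range width}]$, areas and baseline
non-negative. Starting points come from the two highest distinct histogram
peaks, with width-varied restarts; the best converged fit by residual is
kept.

**Weighting.** The fit minimizes Poisson-weighted least squares
(weights $1/\max(y_i, 1)$) by default. With unweighted least squares the
high-count bins dominate the residual, and a narrow spurious component
that absorbs the counting noise of two or three peak bins can halve the
RSS; combined with the least-squares Akaike criterion this selects a
phantom second population in more than half of single-population
replicates. Poisson weighting puts residuals on the counting-noise scale
and restores calibrated model selection; plain least squares remains
available via `weights = "none"`.

**Model order.** The number of components ($n$ = 1 or 2; larger mixtures
are out of scope) is chosen by the least-squares information criterion
$AIC = N \ln(RSS/N) + 2k$ with $k = 3n + 1$ parameters and $N$ the number
of bins, ties resolved toward $n = 1$; a small-sample corrected variant
(AICc) is available behind a flag. Because a second component is a
boundary hypothesis, the criterion alone is liberal; a candidate second
population must additionally be *credible*:

- resolved — means separated by more than the sum of the two widths
  (closer components cannot be distinguished from a single skewed
  population by a histogram);
- measurable — width at least one bin (sub-bin structure is invisible at
  the chosen binning; such components are single-bin noise spikes);
- supported — area exceeding three times its standard error;
- non-negligible — at least 2% of the total area (smaller components are
  outlier tails, not populations).

Fits violating these are rejected as degenerate and the analysis falls
back to one component. Under the reference regimes (a single population of
2000 events; a 73/27 two-population mixture of 5000 events separated by
about four widths) this selects the correct order in well over 95% of
seeded replicates, verified in the acceptance tests.

**Accuracy.** On the full simulated ALEX chain the recovered component
means are accurate to about ±0.01 and the major-population fraction to a
few percentage points. The residual fraction bias (the wider component
absorbs some overlap mass, since per-burst efficiencies are
binomial-ratio distributed, not exactly Gaussian) is intrinsic to
histogram Gaussian fitting and applies equally to the experimental
procedure the package mirrors.

## 4. Förster distances

Mean efficiencies convert to inter-dye distances by
$R = R_0 (1/E - 1)^{1/6}$ with $R_0$ a configuration parameter defaulting
to 60 Å, the standard literature value for the AF488/AF594 pair; the value
is validated by requiring all reported (E, R) worked examples to agree
within 1.5 Å, with the E = 0.75 → 50.0 Å pair exact. No orientation-factor
or accessible-volume modeling is attempted; distances are "relative dye
separations" in the same sense the underlying experiments report them.
Outputs are rounded to 0.1 Å.

## 5. FCS and hydrodynamics

Autocorrelation curves follow the single-component 3D Gaussian-focus
diffusion model
$G(\tau) = N^{-1}(1 + \tau/\tau_D)^{-1}(1 + \tau/(\kappa^2\tau_D))^{-1/2}$
with the axial ratio fixed at $\kappa = 6$ (typical confocal value,
fittable behind a flag). Fits require at least 20 lag points and warn when
the fitted $\tau_D$ exceeds the largest lag (no decay information). The
diffusion time converts to a diffusion coefficient through the calibrated
lateral focal radius, $D = w_0^2/(4\tau_D)$, and to a hydrodynamic radius
by Stokes–Einstein, $R_h = k_B T/(6\pi\eta D)$, with defaults
$T = 303.15$ K and $\eta = 7.972\times10^{-4}$ Pa·s (water at 30 °C).
$w_0$ must come from a free-dye calibration; no instrument constants are
assumed. Triplet kinetics and multi-component diffusion are out of scope.

## 6. Bulk assays

- **Anisotropy**: $r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$ with the
  G factor from horizontal-polarization excitation; scale-invariant by
  construction.
- **Binding titrations**: normalized donor intensity
  $1 - A\,f_b(L; P, K_d)$ where $f_b$ is the exact ligand-depletion
  (quadratic) bound fraction. The quadratic is the default because the
  labeled species (10 nM) exceeds the sub-nanomolar $K_d$ roughly 50-fold,
  where the simple hyperbola is badly biased; the hyperbolic model is kept
  for the dilute regime and the two agree within 1% when
  $P \ll K_d$ (property-tested). Note that in the tight-binding regime the
  titration shape pins $K_d$ only through the curvature near the
  stoichiometric point, so noiseless curves identify it exactly while even
  sub-percent noise degrades it quickly — a property of the experiment,
  not of the optimizer.
- **ATPase**: the NADH-coupled assay converts the A340 slope with
  $\varepsilon_{NADH} = 6220\ \mathrm{M^{-1}cm^{-1}}$ (standard value,
  held as a named constant) and normalizes by enzyme concentration;
  Michaelis–Menten parameters come from nonlinear least squares of
  $v = V_{max} S/(K_M + S)$ over the assayed 0.1–5 mM substrate range.

## 7. The synthetic-data layer

The ALEX generator is an *effective per-burst* model: each burst draws a
total photon count from a shifted Poisson (mean 100, floored at the
40-photon search minimum) and splits it multinomially over the detection
streams with weights

$$w_{DD} = b_D(1-E),\quad
  w_{DA} = b_D\,[\gamma E + Lk(1-E)] + Dir\,b_A,\quad
  w_{AA} = b_A,$$

where $b_D, b_A$ are the species' brightnesses under each laser (defaults
100/80, giving dual-species stoichiometries near 0.55). This applies the
distortions in the inverse order of the corrections (γ-weighted partition,
leakage, direct excitation, background) and makes the calibration
estimators exactly consistent: the donor-only ratio recovers *Lk*, the
acceptor-only ratio recovers *Dir*, and the two-standard regression
recovers γ. Leakage is realized as an acceptor-channel weight proportional
to the donor-channel weight — an equivalent reformulation of
photon-by-photon misdirection that keeps the count bookkeeping exact
(the four stream counts always sum to the drawn total; an invariant test
asserts this). Burst timestamps occupy whole alternation periods starting
on period boundaries, sampled without replacement from the integer
microsecond slots of the matching excitation windows; background photons
arrive homogeneously at 0.3 kHz per detector.

Inter-arrival times are exponential with a 250 ms mean by default. This
is the single-molecule dilution regime: with 1 ms bursts and a 1 ms search
window, the probability that two molecules fall into the same or adjacent
windows (and are merged into one artifactual intermediate-efficiency
burst) stays below about 1%. At substantially shorter spacings merged
bursts become a measurable contaminant of the population fractions, which
is why dilution to ~100 pM is standard experimental practice.

What the generator does **not** emulate: diffusion paths through a
Gaussian point-spread function (brightness is an effective per-burst
quantity, so burst-size and burst-duration statistics are conventional
choices, not fitted to any instrument); within-burst dynamics;
photophysics beyond single-step bleaching and simple blinking in the TIRF
ensemble; camera gain statistics (TIRF noise is Gaussian per frame);
triplet shoulders in FCS curves. Passing recovery tests on this generator
therefore demonstrates correctness of the analysis algebra and estimator
calibration under realistic counting statistics — not robustness to every
instrumental artifact of real data.

All simulators take an explicit integer seed, run under a temporarily
seeded RNG (the caller's random state is restored), and are
bit-reproducible given the seed.

## 8. Validation problem sizes

The test suite exercises the chain at the scale of the study conditions:
5000-burst mixtures with 1200-burst calibration standards for the
end-to-end ALEX recovery; three γ values × five seeds for calibration;
200-molecule TIRF ensembles; 40 seeded replicates per regime for model
selection; 64-point FCS curves; and 7–14-point assay curves. These sizes
keep the full suite under a minute of compute while leaving Monte Carlo
margins well clear of the tested tolerances.

## 9. Known limitations

- Burst search is binned, not sliding-window; bursts separated by less
  than one smoothing window merge (mitigated by the dilution-regime
  default spacing, but real high-concentration data would need a finer
  search or dual-channel burst filters, which are out of scope).
- The Gaussian population model inherits the small overlap-assignment
  bias discussed in §3 whenever components are closer than ~4 widths.
- Donor-bleaching FRET is reported uncorrected for γ or leakage, as is
  standard for the method; absolute distances from TIRF efficiencies
  carry the same caveat as the underlying experiments.
- No lifetime, polarization-resolved, burst-variance or within-burst
  dynamic analyses.
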