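# smfret

Single-molecule FRET analysis for mapping protein conformational change,
built around two complementary measurement modes and the bulk assays that
support them:

- **ALEX burst spectroscopy** of freely diffusing dual-labeled molecules:
  photon streams from alternating donor/acceptor excitation are split into
  the four excitation/emission streams, bursts are found by a rate
  threshold, and each burst yields a FRET efficiency *E* and stoichiometry
  *S* after crosstalk and detection-factor corrections.
- **TIRF donor-bleaching FRET** of surface-immobilized complexes:
  per-molecule efficiencies from the donor intensity step when the acceptor
  photobleaches.
- **Population analysis**: efficiency histograms decomposed into one or two
  Gaussian populations with Akaike model selection and area-based fractions.
- **Förster conversion** of mean efficiencies to inter-dye distances, and
  **FCS** diffusion fits with Stokes–Einstein hydrodynamic radii.
- **Assay fits**: fluorescence anisotropy, tight-binding titrations
  (ligand-depletion quadratic) and NADH-coupled ATPase Michaelis–Menten
  kinetics.

A seeded forward simulator generates every data type the analysis consumes
(photon streams, bleaching trajectories, FCS curves, assay curves) with
known ground truth, so the entire chain is testable by parameter recovery.
The package is aimed at single-molecule biophysicists who want a scripted,
reproducible version of this analysis chain, and at method developers who
need a ground-truth generator to validate burst analysis code.

## The model

For each diffusing-molecule burst the four photon-stream counts
F<sup>Dex</sup><sub>Dem</sub>, F<sup>Dex</sup><sub>Aem</sub>,
F<sup>Aex</sup><sub>Aem</sub>, F<sup>Aex</sup><sub>Dem</sub> give the raw
ratiometric observables

    E_raw = F_Dex_Aem / (F_Dex_Aem + F_Dex_Dem)
    S_raw = (F_Dex_Aem + F_Dex_Dem) / (F_Dex_Aem + F_Dex_Dem + F_Aex_Aem)

Donor leakage *Lk* (from the donor-only population, S ≈ 1) and acceptor
direct excitation *Dir* (from the acceptor-only population, S ≈ 0) are
subtracted,

    F_fret = F_Dex_Aem − Lk·F_Dex_Dem − Dir·F_Aex_Aem

and the detection-correction factor γ is calibrated by fitting
1/S<sub>corr</sub> = Ω + Σ·E<sub>corr</sub> across FRET standards of
distinct efficiency, γ = (Ω − 1)/(Ω + Σ − 1). The accurate efficiency is

    E = F_fret / (F_fret + γ·F_Dex_Dem)

Efficiency histograms (bin 0.025) are fitted with
y<sub>0</sub> + Σ<sub>i</sub> area<sub>i</sub>·N(x; mean<sub>i</sub>,
width<sub>i</sub>), n ∈ {1, 2}, the order chosen by
AIC = N·ln(RSS/N) + 2k, and mean efficiencies convert to distances through
the Förster relation R = R<sub>0</sub>(1/E − 1)<sup>1/6</sup>
(R<sub>0</sub> = 60 Å for the AF488/AF594 pair).

For immobilized molecules the donor-bleaching estimator uses the donor
intensity before (I<sub>DA</sub>) and after (I<sub>D</sub>) single-step
acceptor photobleaching: E = (I<sub>D</sub> − I<sub>DA</sub>)/I<sub>D</sub>.

## Worked example

Simulate the two-conformer mixture (E 0.74/0.49, fractions 73%/27%, with
donor-only and acceptor-only contaminants) on a distorted instrument
(γ = 0.9, Lk = 0.08, Dir = 0.06), then run the full analysis chain:

```r
library(smfret)

inst <- instrument_model(Lk_true = 0.08, Dir_true = 0.06, gamma_true = 0.9)
sim  <- simulate_alex_experiment(alex_preset("free-sigma54")$species, inst,
                                 n_bursts = 5000, seed = 1)
std1 <- simulate_alex_experiment(species_model(0.3, "dual", 1), inst, 1200, seed = 2)
std2 <- simulate_alex_experiment(species_model(0.8, "dual", 1), inst, 1200, seed = 3)

bursts <- analyze_alex(sim$stream, standards = list(std1$stream, std2$stream))
attr(bursts, "factors")
#> Correction factors: Lk = 0.0795, Dir = 0.0606, gamma = 0.8733 (Sigma = 0.1140, Omega = 1.7860)

dual <- select_dual(bursts)                 # keep intermediate-S bursts
fit  <- fit_populations(dual$E_acc[is.finite(dual$E_acc)])
fit
#> Gaussian mixture fit: n = 2, AIC = 7.27, RSS = 41.72, y0 = 0.06
#>    mean   width  area fraction
#>  0.5043 0.08451 23.70   0.2617
#>  0.7459 0.05763 66.86   0.7383

E <- fit$components$mean
distance_from_E(max(E))                     # 50.1 Angstrom
delta_distance(min(E), max(E))              # 9.7 Angstrom domain opening
```

The estimated correction factors (Lk 0.0795, Dir 0.0606, γ 0.873) recover
the instrument truth; the mixture fit selects two populations and returns
means 0.746/0.504 with a 74% major fraction, within shot-noise scatter of
the generating parameters. Converting the means gives inter-dye distances
of 50.1 Å and 59.8 Å.

A command-line wrapper over the same functions is installed at
`inst/scripts/smfret` (subcommands `simulate-alex`, `analyze-alex`,
`analyze-tirf`, `fit-populations`, `distances`, `fcs`, `assays`, ...); see
`?smfret_cli`.

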