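# peristroma

Spatial dissection of stroma-mediated drug resistance in tumor tissue.

Targeted therapies (for example ALK inhibitors in ALK+ non-small-cell lung
cancer) induce deep tumor regressions but rarely eradicate the disease.
Part of the surviving residual population owes its persistence not to
cell-intrinsic mutations but to *environment-mediated drug resistance*
(EMDR): paracrine protection supplied by cancer-associated fibroblasts,
which acts only within a narrow peristromal band a few cell diameters wide.
`peristroma` is a toolkit for quantifying this spatially restricted
protection and for asking, in silico, which of its aspects — magnitude,
distance, abundance or spatial dispersal of the protective stroma — most
strongly controls the size of residual disease.

The package covers the full analysis loop:

1. **Rate inference** (`fit_exponential()`, `proliferation_from_brdu()`,
   `death_rate()`). Tumor volume series are treated as exponential,
   `V(t) = V0 e^{rt}`; the net rate decomposes as `r = p − d`. The
   proliferation rate per day is the BrdU labeling index scaled by
   `24 h / S-phase duration` (a factor 3 for an 8 h S phase), and the death
   rate follows as `d = p − r`.
2. **Spatial statistics** (`rdf()`, `csr_envelope()`, `gmax()`). A radial
   distribution function of marker-positive tumor cells measured in 5 μm
   annuli around every 15 μm stroma pixel, normalized per pixel by the
   complete-spatial-randomness (CSR) expectation obtained from marker-label
   shuffles that preserve all positions and label counts. A min–max
   envelope of 39 shuffled curves gives a pointwise 95% band. The curve
   maximum `g_max` measures the magnitude of peristromal enrichment and its
   radius the characteristic distance of the EMDR effect.
3. **On-lattice simulation** (`abm_params()`, `run_abm()`,
   `calibrate_abm()`). A 100 × 100 cell grid (15 μm/cell, 24 h steps) on
   which tumor cells divide, die and migrate around a fixed stromal
   topology. Therapy reduces division and raises death everywhere except
   inside the peristromal niche (within 3 cells of active stroma), where
   division stays high enough to hold a protected equilibrium.
   `calibrate_abm()` maps experimentally inferred per-day rates onto
   per-step probabilities, absorbing the lattice's space-limitation bias.
4. **Perturbation experiments** (`sweep_emdr()`, `fit_decay()`,
   `compare_topologies()`). Sweeps of EMDR magnitude, distance and producer
   fraction across stromal topologies, summarised by residual population
   size and by the exponential decay rate of residual disease per unit of
   EMDR reduction.
5. **Synthetic tissue** (`gen_stroma_topology()`, `gen_labeled_pattern()`,
   `gen_volume_series()`). Generators with controlled stroma abundance and
   dispersal, peristromal marker enrichment, and noisy volume series; they
   make every module testable without animal data and define the reference
   conditions for calibration.

## Worked example

```r
library(peristroma)
set.seed(1)

## 1. rates: regressing tumor under therapy (volumes in mm^3, weekly)
v <- gen_volume_series(V0 = 120, r = -0.113, times = seq(0, 28, by = 7))
rates <- rate_estimates(r = as.numeric(fit_exponential(v$day, v$volume_mm3)),
                        p = proliferation_from_brdu(0.0087))
rates
#> rates per day: net growth r = -0.113, proliferation p = 0.026, death d = 0.139 (S phase 8 h)

## 2. spatial statistics on a synthetic treated-tissue section
topo <- gen_stroma_topology(abundance = 0.06, dispersal = 0.9)
pat  <- gen_labeled_pattern(topo, n_cells = 5000, base_positive = 0.05,
                            enrichment = 5, niche_width = 3)
env  <- csr_envelope(pat, marker = "pos", n_shuffles = 39)
gmax(env)
#> $g_max           2.56
#> $r_at_max_um     47.5
#> $r_at_max_cells  3.17

## 3. simulate therapy on that topology and perturb the EMDR producers
params <- abm_params()          # calibrated defaults (see vignette)
ens <- run_abm_reps(topo, params, n_reps = 20, seed = 1)
ens
#> abm_ensemble: 20 reps | baseline 8019.4 +/- 6.5 | residual 3820.5 +/- 42.5 (0 extinct)

sw <- sweep_emdr(topo, params, "producer", levels = c(0, 0.5, 1),
                 n_reps = 10, seed = 2)
as.data.frame(sw)[1:6]
#>     aspect level residual_mean residual_sd n_reps extinct
#> 1 producer   0.0         0.000      0.0000     10      10
#> 2 producer   0.5         0.444      0.0066     10       0
#> 3 producer   1.0         0.476      0.0038     10       0
attr(sw, "decay_rate")
#> 8.94  (per unit reduction in producer fraction)
```

Reading the numbers: the fitted net rate −0.113/day with a BrdU-derived
proliferation of 0.026/day implies a death rate of 0.139/day — therapy
kills faster than the residual cells divide, yet the tumor persists. The
RDF peaks at ~3 cell diameters from the stroma (`r_at_max_cells`), the
width of the protective niche. Under simulated therapy the population
settles at ~48% of its baseline inside this niche; removing all EMDR
producers (level 0) eradicates every replicate, and the fitted decay rate
quantifies how fast residual disease collapses as producers are withdrawn.

A command-line front end mirroring these steps is installed as `exec/emdr`
(`emdr topology | pattern | volumes | rdf | calibrate | simulate | sweep`).

## Package layout

- `R/tissue.R` — lattice grids, label masks, stroma pixelation, niche maps
- `R/pattern.R` — marked point patterns and the CSV exchange format
- `R/rates.R` — growth/proliferation/death rate inference
- `R/rdf.R` — radial distribution function and CSR envelopes
- `R/abm.R`, `src/abm.cpp` — the on-lattice simulator and its calibration
- `R/synth.R` — synthetic-tissue generators
- `R/experiments.R` — EMDR perturbation sweeps and decay-rate fits
- `vignettes/peristroma-methods.Rmd` — model assumptions, estimator
  choices, calibration details and known limitations
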