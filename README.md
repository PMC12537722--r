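# smtz

Porewater geochemistry and microbial community analysis around the
sediment **sulfate–methane transition zone (SMTZ)**, built for two-bay
warming comparisons: a chronically heated coastal bay against an adjacent
control bay, sampled in summer and winter.

In anoxic coastal sediments, downward-diffusing sulfate meets
upward-diffusing methane at the SMTZ, where anaerobic oxidation of methane
(AOM) consumes both. Warming accelerates sulfate consumption, thins the
sulfate reduction zone, and lets methane accumulate closer to the
seafloor — raising the risk of methane release to the water column. `smtz`
implements the quantitative chain needed to measure that:

* **Headspace equilibration**: jar GC readings (ppm CH₄) →
  total porewater methane (mM), partitioning moles between the gas
  headspace (ideal gas) and the aqueous phase (Henry's law with van 't
  Hoff temperature correction).
* **Sulfate fluxes**: per-core linear sulfate gradients, the depth of no
  sulfate (DNS) as the regression x-intercept, a linearity exclusion rule
  (R² ≥ 0.90), and Fick's-first-law diffusive fluxes
  `J = −φ·Ds·dC/dx` with the logarithmic tortuosity correction
  `Ds = D0 / (1 − ln φ²)`, in mmol m⁻² d⁻¹.
* **Season/bay comparisons**: windowed temperature summaries, Welch
  t-tests, and methane fold changes at matched depths with a detection
  floor.
* **Community analysis** (written from first principles, cross-checked
  against independent implementations in the tests): family-level
  aggregation of ASV counts, relative abundance with top-k pooling,
  Bray–Curtis dissimilarity `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`, classical PCoA, and
  sequential-SS PERMANOVA with free permutations.
* **Synthetic data**: generators for porewater profiles, temperature
  logger series, headspace jars and Dirichlet-multinomial count tables
  with known ground truth, so the full chain runs and is tested without
  any external data.

## Worked example

```r
library(smtz)

# A 1 % CH4 headspace reading in the standard jar (600 mL jar, 133 mL
# sediment at 0.8 porosity, 200 mL water, 200 mL headspace):
total_porewater_methane(10000)
#> [1] 0.8223265          # mM total porewater methane

# Fick's-law flux for a sulfate gradient of -1 mM/cm at 0.8 porosity:
diffusive_flux(-1, ds = 5e-6, porosity = 0.8)
#> [1] 3.456              # mmol m-2 d-1, positive = downward into sediment

# A noiseless synthetic core: 28 mM surface sulfate depleted at 25 cm
truth <- profile_truth("A", "control", "summer",
                       sulfate_surface = 28, dns_true = 25, noise_sd = 0)
core  <- generate_porewater_profiles(list(truth), seq(1, 31, 2), seed = 1)
res   <- core_flux(core$profiles[[1]], temperature_c = 19.9)
res
#> <flux_result> site A (control, summer): DNS 25.0 cm, J 5.083 mmol m-2 d-1, R2 1.000, included
```

The DNS comes back at exactly the planted 25 cm; the flux follows from the
−1.12 mM/cm gradient, the 19.9 °C diffusion coefficient and the tortuosity
correction. Running the whole synthetic study (12 cores, a year of hourly
two-bay temperature data, 60 community samples):

```r
run_pipeline(pipeline_config(seed = 1L), out_dir = "results/study")
#> [flux] 12 cores, 11 included
#> [community] PERMANOVA bay: F = 23.67, p = 0.001
```

yields group fluxes of ≈1.0 (control summer) and ≈0.44 (control winter)
mmol m⁻² d⁻¹ with mean DNS ≈25.6 and ≈36.9 cm — summer consumes sulfate
faster and shallower — and the heated bay shallower than the control in
both seasons, with the community PERMANOVA attributing significant
variation to bay, depth and their interaction.

The same stages can be run as a narrated workflow:

```sh
Rscript analysis/01_simulate.R     # synthetic study data + ground truth
Rscript analysis/02_methane.R      # headspace -> porewater CH4
Rscript analysis/03_flux.R         # gradients, DNS, fluxes, exclusions
Rscript analysis/04_compare.R      # temperatures, Welch test, fold changes
Rscript analysis/05_community.R    # Bray-Curtis, PCoA, PERMANOVA
```

All tables land under `results/study/` with provenance headers (config
fingerprint, seed, version). Real data in the same CSV/TSV schemas are
interchangeable with the simulated files.

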