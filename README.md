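# mpsoilrisk

Probabilistic risk assessment of microplastics (MPs) reaching agricultural
soils through land application of stabilized sewage sludge.

Sewage sludge captures most of the microplastics removed from wastewater;
spreading it on fields as fertilizer returns those particles to soil, where
they can chronically affect earthworms, plants, soil bacteria and fungi.
`mpsoilrisk` implements the full quantitative chain needed to ask *what
fraction of soil species is at risk* from this practice:

1. **Effect-descriptor harmonization.** Published chronic toxicity results
   arrive as heterogeneous descriptors — NOEC (no observed effect
   concentration), LOEC (lowest observed effect concentration), HONEC
   (highest tested concentration with no effect at all). Each is reduced to
   a chronic no-effect equivalent
   `NOEC_eq = descriptor / (UF_T x UF_D x UF_C)`, with three uncertainty
   factors on the ladder {1, 2, 4} penalizing short exposure, imprecise
   descriptors and severe endpoints (survival > growth/reproduction >
   sub-organismal). Mass-based concentrations (mg/kg dw) are converted to
   particle numbers from particle geometry and polymer density.
2. **SSD.** Per-species geometric means feed a species sensitivity
   distribution: log-normal, log-logistic and Burr XII candidates fitted by
   maximum likelihood, selected by lowest AIC. The 5th percentile is the
   hazard concentration for 5% of species, HC5; a parametric bootstrap
   (1001 refits) gives its two-sided 95% interval, whose upper limit serves
   as the optimistic safety threshold.
3. **EED.** Environmental exposure distributions for stabilized sludge,
   sludge-amended soil (SAS) and control soils (five candidate families,
   AIC-selected), with per-plant averaging and a percentile collapse for
   surveys that would otherwise dominate the data set. The sludge-to-SAS
   median ratio defines the realistic dilution factor; dilution acts
   exactly on the scale parameter of the fitted family.
4. **Two-dimensional Monte Carlo risk.** For each of 1001 uncertainty
   iterations (one bootstrap parameter draw per distribution), 1001
   simulated species with independently drawn exposures give a proportion
   of affected species `mean(C > S)`; the 1001 proportions yield a point
   estimate (median) and an empirical 95% uncertainty interval per dilution
   scenario, plus an exceedance verdict against the 5% protection goal.

A synthetic-data module generates complete study bundles with known ground
truth (species means, true HC5, closed-form true proportions), so the
whole pipeline is testable end to end without any external data.

## Worked example

```r
library(mpsoilrisk)

config <- risk_config(seed = 42L)        # 1001 bootstrap, 1001 x 1001 MC2D
bundle <- gen_full_study(config)         # synthetic study, known truth
run    <- run_pipeline(bundle$toxicity, bundle$exposure, config)
print(run)
```

```
<mp_run>
  SSD: lognormal on 25 species; HC5 = 64.03 [4.484; 764.4]
  dilution ratio 17.59 (factor 18)
           scenario factor proportion_point    unc_low  unc_high    verdict
  worst_case_sludge      1       0.41958042 0.28171828 0.5634366    exceeds
 sludge_dilution_17     17       0.21978022 0.10689311 0.3516484    exceeds
                sas      1       0.19280719 0.09090909 0.3186813    exceeds
            control      1       0.09090909 0.02597403 0.1858142 intersects
```

Reading: the fitted SSD puts the concentration harming 5% of species (HC5)
at 64 particles/kg dw (bootstrap median; 95% CI 4.5–764). Undiluted sludge
concentrations would affect ~42% of soil species [28%; 56%]; after the
realistic ~17-fold environmental dilution, ~22%; sludge-amended soils sit
at ~19% and control fields at ~9%, whose interval is the only one touching
the 5% protection goal ("intersects"). Numbers vary with the seed — both
data generation and the two simulation layers are stochastic by design.

`run$tables` holds every reported table (`percentiles`, `risk`, `fits`,
`compliance`, `harmonized`, `species_sensitivity`); passing
`out_dir = "somewhere"` writes them as CSV together with a JSON run
summary, a curation log and the overlay/sweep figures as PDF.

A command-line wrapper is installed at `inst/cli/mprisk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mprisk.R", package="mpsoilrisk"))')" \
    run-all --simulate --seed 1 --out out_dir
```

## Input formats

CSV, UTF-8, header row mandatory, empty cells for absent values.

* `toxicity.csv` — one row per study x species x particle entry:
  `entry_id, study_id, species_label, taxon_group, endpoint_name,
  endpoint_category (A/B/C), descriptor_kind (HONEC/NOEC/LOEC),
  noec_value, loec_value, honec_value, exposure_days,
  concentration_unit (nb_per_kg_dw/mg_per_kg_dw), particle_shape,
  particle_diameter_um, particle_length_um, particle_thickness_um,
  particle_density_g_cm3, particle_polymer, particle_size_basis`
* `exposure_<matrix>.csv` — `sample_id, study_id, site_id,
  concentration_nb_per_kg_dw` for matrices `sludge`, `sas`, `control`.
* `inst/extdata/densities.csv` — editable polymer density defaults
  (standard literature values, not measurements).

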