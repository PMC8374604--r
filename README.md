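# cueflux

Transcriptomic markers of fungal growth, respiration and carbon-use
efficiency.

## What it does

Fungal carbon-use efficiency (CUE) — the fraction of metabolized carbon
allocated to biomass rather than respired,

    CUE = mu / (mu + qCO2)

with relative growth rate `mu = ln(Bt/B0)/t` (day⁻¹) and metabolic
quotient `qCO2` (respiration per unit biomass carbon, day⁻¹) — is central
to biogeochemical modelling but hard to measure directly. `cueflux`
implements the derivation of *gene-expression markers* for these fluxes
from liquid-culture experiments, for microbial ecologists who want to
assess growth, respiration and CUE indirectly, e.g. in natural communities
via metatranscriptomics or RT-qPCR.

The pipeline:

1. **Carbon fluxes** — biomass measurements and a closed-loop CO₂ rise
   become `mu`, respiration (ideal gas law; 1 atm, 20 °C, 274 cm³ loop,
   2.5 min read, all configurable), `qCO2` and CUE, with QC flags for
   negative growth and invalid records.
2. **Expression** — RNA-seq counts are RPKM-normalized, summed within
   Enzyme Commission (EC) classes for cross-species comparability, and
   filtered to classes with ≥ 10 RPKM in every sample.
3. **Marker models** — power-law fits on the natural-log scale,
   `ln mu = a1 + b1 ln GT48`, `ln qCO2 = a2 + b2 ln KGD`
   (GT48 = 1,3-β-glucan synthase, EC 2.4.1.34; KGD = 2-oxoglutarate
   dehydrogenase, EC 1.2.4.2), plus a genome-wide Pearson-correlation
   screen ranking every enzyme class against each flux.
4. **CUE index** — the fitted models combine into
   `CUE_gene = (1 + C · KGD^b2 / GT48^b1)^-1` with `C = e^(a2-a1)`,
   evaluated against measured CUE by untransformed linear regression.
5. **Group statistics** — two-way ANOVA (sequential SS), Tukey HSD with
   compact letters, and per-isolate Welch t-tests for medium effects.
6. **Synthetic studies** — `generate_study()` simulates the full
   experiment (4 isolates × 2 media × 9 replicates, 62 usable samples,
   planted marker laws with realistic noise) with known ground truth, so
   the whole pipeline is testable without external data.

## Worked example

```r
library(cueflux)

st  <- generate_study(study_config(seed = 1))
res <- run_pipeline(st$phenotypes, st$counts, st$gene_lengths,
                    st$annotation, metadata = st$metadata, quiet = TRUE)
print(res)
```

```
CUE marker pipeline run
  samples: 72 total, 10 unsequenced, 0 flagged, 62 usable
  enzyme classes: 450 aggregated, 435 pass the 10-RPKM filter
  candidate models:
 response   marker alpha  beta     r2
       mu 2.4.1.34 -9.84 1.420 0.7657
       mu 2.4.1.16 -3.61 0.550 0.0747
     qco2  1.2.4.2 -6.77 1.041 0.6020
     qco2 1.1.1.41 -3.17 0.489 0.0574
     qco2 1.1.1.42 -5.80 0.978 0.1892
  selected markers: growth 2.4.1.34 (screen rank 1), respiration 1.2.4.2 (rank 1)
  compact constant: 21.55
  index vs measured CUE: intercept 0.030, slope 0.943, R2 0.749
```

Reading this: of 72 simulated cultures, 62 enter the fits (10 lost to
sequencing/QC, none flagged for negative growth). The planted growth
marker GT48 is recovered with slope 1.42 (truth 1.4) and tops the
genome-wide screen; the chitin-synthase alternative explains far less
variance (R² 0.07 vs 0.77), reproducing the a-priori-candidate selection
logic. The CUE index built from the two fitted models tracks measured CUE
with slope ≈ 0.94 and R² 0.75 on this seed.

Working with published coefficients:

```r
ref <- reference_models()
ix  <- build_index(ref$growth, ref$resp)
ix$compact_constant            # 26.31
zero_crossing(ref$growth)      # 6.886 — basal ln GT48 expression
cue_gene(ix, gt48 = exp(8), kgd = exp(7))  # 0.745
```

A thin command-line front end with per-stage subcommands (`simulate`,
`fluxes`, `normalize`, `screen`, `fit`, `index`, `stats`, `run`,
`fixtures`) is installed at `inst/cli/cueflux.R`; configuration is YAML
(`read_pipeline_config()`), tables are TSV, models JSON.

## Documentation

The methods vignette (`vignettes/cueflux-methods.Rmd`) describes the
model and its assumptions, the tunable parameters and their defaults, the
synthetic-data generator's design and limitations, and the numerical
choices (tie-breaking, degenerate inputs, tolerances).
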