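# cellulosim

Stochastic molecular simulation of enzymatic cellulose hydrolysis in R.

Enzymatic saccharification of cellulose — the rate-limiting, cost-dominating
step of cellulosic ethanol production — is carried out by a synergistic
enzyme system: endoglucanases (EG) cut accessible internal β-1,4 bonds,
preferentially in amorphous regions; cellobiohydrolases attack chain ends
(CBH I from the reducing end, CBH II from the non-reducing end) and
processively release cellobiose; β-glucosidase (BG) hydrolyzes soluble
oligomers to glucose. Classical lumped kinetic models struggle with exactly
the features that control this process: dynamic substrate morphology,
per-enzyme accessibility, and endo–exo and exo–BG synergism.

`cellulosim` takes the opposite approach and simulates every hydrolysis
event discretely. Cellulose is built explicitly — microfibrils of 36-chain
elementary fibrils, each glucose unit carrying end-state, surface,
crystallinity and solubility attributes, with crystalline regions laid out
as ~200-unit bands — and hydrolysis proceeds in one-minute Monte Carlo
steps. Each enzyme *i* gets a per-minute event budget from its loading
*E<sub>i</sub>* (mg/g glucan), specific activity *U<sub>i</sub>* (IU/mg) and
stability *S<sub>i</sub>*,

> N<sup>max</sup><sub>h,i</sub> = E·U·S · 162×10⁻⁶ · G<sub>sim</sub>,

allocated over microfibrils by their current census of attackable material
(surface units, reducing/non-reducing ends, or soluble molecules). Budgets
are spent on uniformly drawn targets under class-specific rules — binding
footprints, a 25% accessibility penalty off the microfibril surface, reduced
endoglucanase acceptance in crystalline regions, processive runs with
desorption, DP ≤ 6 solubilization that exposes the chain layer beneath —
and a counter scheme in which encounters with free glucose/cellobiose waste
budget, reproducing product inhibition. Observables include soluble sugar
concentrations (g/L), cellulose conversion, hydrolysis rates, chain-length
distributions, crystallinity trajectories and degrees of synergism
(DS = mixture conversion ÷ sum of individual conversions).

See `vignettes/stochastic-cellulose-hydrolysis.Rmd` for the full model
description, parameter table and calibration rationale.

## Worked example

A 48-h hydrolysis of Avicel (100 g/L) by the natural *T. reesei* protein
ratio (12% EG I, 60% CBH I, 20% CBH II; 20 mg protein/g glucan) with excess
β-glucosidase:

```r
library(cellulosim)

avicel <- buildSubstrate("avicel", seed = 1)
avicel
#> CelluloseAssembly: 5 microfibril(s), 124 elementary fibrils, 1,205,352 glucose units
#>   DP range: 250-288  realized CrI: 0.5513

mix <- treeseiMixture(20, bgIuPerG = 100)
res <- runHydrolysis(avicel, mix, durationMin = 48 * 60, seed = 1)

rxn <- standardReaction(100)   # 100 g glucan / L
cp  <- concentrationProfiles(res, rxn)
cp[cp$hours %in% c(6, 12, 24, 48), c("hours", "cGlu", "cG2", "cG6plus", "conversion")]
#>    hours   cGlu   cG2 cG6plus conversion
#> 7      6 17.981 0.376  83.367     16.633
#> 13    12 32.021 0.554  70.481     29.519
#> 25    24 51.964 0.594  52.423     47.577
#> 49    48 76.428 0.483  30.530     69.470
```

Glucose (`cGlu`) is the dominant product because excess BG converts the
cellobiose released by the cellobiohydrolases; the insoluble DP 6+ fraction
(`cG6plus`) falls from 100 to 30.5 g/L, i.e. 69.5% conversion. Without BG
the same mixture stalls near 31% — cellobiose inhibition throttles the CBHs.

Endo–exo synergism on the same substrate:

```r
eg   <- celluloseConversion(runHydrolysis(avicel, enzymePreset("EGI", 10),  2880, seed = 1))
cbh  <- celluloseConversion(runHydrolysis(avicel, enzymePreset("CBHI", 10), 2880, seed = 1))
both <- celluloseConversion(runHydrolysis(avicel,
          enzymeSystem(enzymePreset("EGI", 10), enzymePreset("CBHI", 10)), 2880, seed = 1))
c(EG = eg, CBHI = cbh, mixture = both)
#>        EG      CBHI   mixture
#>  5.815646 11.733670 25.885300
degreeOfSynergism(both, c(eg, cbh))
#> [1] 1.475004
```

The mixture converts ~1.5× more than the sum of its parts: endoglucanase
creates fresh reducing ends for CBH I, and CBH I clears the pulverized
surface fragments that stall EG, exposing fresh layers. Synergism grows
with substrate DP and crystallinity (≈4.9 on cotton) because CBH alone is
then starved of chain ends.

A command-line entry point wraps the same functions:

```sh
Rscript inst/scripts/hydrolysis_sim.R --substrate avicel --enzyme CBHI:10 \
    --solid-loading 100 --hours 48 --seed 7 --replicates 3 --out runs/cbh1
```

writing trajectory CSVs, a final chain-length histogram, `summary.json`,
the resolved YAML configuration and a run log.

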