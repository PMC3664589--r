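---
title: "A stochastic molecular model of enzymatic cellulose hydrolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic molecular model of enzymatic cellulose hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`cellulosim` simulates the enzymatic depolymerization of cellulose one
hydrolysis event at a time. Instead of fitting lumped rate expressions, the
substrate is represented explicitly — every glucose unit carries its own
attributes — and enzyme action is a per-minute Monte Carlo process whose
elementary moves follow the known modes of action of cellulases. The payoff
of this resolution is that phenomena that are hard to encode in ordinary
differential-equation kinetics emerge from the bookkeeping itself: surface
erosion and the exposure of buried chains, endo–exo synergism, product
inhibition, chain-length distributions, and the dependence of hydrolysis on
crystallinity and degree of polymerization (DP).

```{r, eval = FALSE}
library(cellulosim)
avicel <- buildSubstrate("avicel", seed = 1)
mix <- treeseiMixture(20, bgIuPerG = 100)   # 12% EG I, 60% CBH I, 20% CBH II
res <- runHydrolysis(avicel, mix, durationMin = 48 * 60, seed = 1)
celluloseConversion(res)
```

# The substrate model

Cellulose I-beta is built hierarchically:

* an **elementary fibril (EF)** is 36 parallel glucose chains of equal DP on
  a 6 x 6 cross-section lattice. The 20 perimeter chains are the EF surface;
  the 12 chains of the next ring and the 4 core chains are buried at depths
  1 and 2.
* a **microfibril (MF)** is a 2-D bundle of EFs, 4–6 per row and column,
  drawn uniformly at build time. All EFs of one MF share one DP, drawn
  uniformly from the substrate's DP range.
* an assembly is a set of MFs. The shipped presets describe the classic
  model substrates: Avicel (DP 250–300, CrI 0.5–0.6, 5 MFs), filter paper
  (DP 700–800, CrI 0.4–0.5, 4 MFs), bacterial cellulose (DP 1800–2000,
  CrI 0.85–0.95, 2 MFs) and cotton (DP 2500–3000, CrI 0.85–0.95, 2 MFs),
  each realized with at least $10^6$ glucose units.

All chains are parallel (cellulose I-beta), with axial position 0 the
reducing end. Each glucose unit has a serial number and carries: end state
(reducing/non-reducing/interior), EF-surface and MF-surface flags,
crystallinity, solubility and its distance to the chain's non-reducing end
(`substrateSnapshot()` exports the full table).

**Crystalline banding.** Crystalline and amorphous regions occur as
transverse bands shared by all 36 chains of an EF. Bands are nominally 200
units long and placed so that both chain ends always lie inside crystalline
bands. These two conventions cannot both hold exactly on short or weakly
crystalline chains (a single 200-band on a DP-275 chain would already give
CrI 0.73), so the band count is `round(K/200)` with a minimum of two end
bands, and band lengths are rebalanced to sum to the drawn crystalline
target `K` — effectively the end bands are truncated. The realized
crystallinity index,

$$\mathrm{CrI} = \frac{\text{crystalline insoluble units}}
                      {\text{total insoluble units}},$$

then always falls inside the preset's range, without rejection loops. The
amorphous remainder is split uniformly at random among the gaps, which is
the only randomness in band placement.

**Layer exposure.** Each buried chain is assigned the lattice neighbor one
ring closer to the surface as its *cover*. When a cover unit is solubilized,
the unit directly beneath it (same axial position) becomes EF surface. This
per-position rule reproduces progressive surface erosion: an enzyme peeling
a surface chain gradually uncovers the chain below it. The cover assignment
is injective, so each buried position has a well-defined exposure trigger;
the four corner chains cover nobody.

# Enzymes and event budgets

Eight mechanistic classes are supported (non-processive EG with and without
a carbohydrate-binding module, processive EG, processive/non-processive
CBH I and CBH II, and beta-glucosidase). The shipped presets carry the
*T. reesei* specific activities of 0.4, 0.8 and 1.6 IU/mg for EG I, CBH I
and CBH II; beta-glucosidase is dosed directly in IU per g glucan, as is
conventional for supplementation.

An enzyme's per-minute event budget is its catalytic capacity on the
simulated substrate. The simulated cellulose mass is
$G_{sim} \cdot 162 / 6.023\times10^{23}$ grams (162 g/mol per anhydroglucose
unit), and one IU liberates one micromole ($6.023\times10^{17}$ molecules)
of product per minute, so

$$N^{max}_{h,i} = E_i \, U_i \, S_i \cdot 162\times10^{-6} \cdot G_{sim},$$

with $E_i$ the loading (mg/g cellulose), $U_i$ the specific activity
(IU/mg) and $S_i \in [0,1]$ a stability hook (fixed at 1, i.e. optimal
temperature and pH; the slot exists so empirical stability models can be
plugged in). We note that the dimensional form above (162 in the numerator)
is the only reading under which realistic loadings produce non-degenerate
hydrolysis; see `maxBondsPerMinute()`. At 10 mg/g and 0.4 IU/mg on $10^6$
units this gives 648 bonds/min. Fractional budgets are carried by stochastic
rounding (floor plus a Bernoulli trial on the remainder) so long-run rates
match the real-valued budget.

Each minute the budget is split across microfibrils in proportion to the
material the enzyme can act on: EF-surface glucose units for EG, reducing
ends for CBH I, non-reducing ends for CBH II, soluble molecules for BG
(`allocateEvents()`). The resulting (enzyme, MF) work units are processed in
randomized order so no class systematically preempts another.

# The per-minute Monte Carlo step

Within a work unit, targets are drawn uniformly from the microfibril's
current candidate list: EF-surface units plus the microfibril's soluble
products for EG/CBH, soluble molecules only for BG. A **minute counter**
limits the work: a productive cleavage costs 1, a failed binding costs
`nNb`, a non-productive binding `nNp`, and drawing a free glucose or
cellobiose molecule costs `nInhibG` or `nInhibG2`. The last rule is the
inhibition mechanism: as products accumulate the enzyme wastes more and more
of its budget on inhibitor encounters, so hydrolysis is progressively
throttled — exactly the cellobiose/glucose product inhibition observed for
cellulases, with its strength set by the counter increments.

Class-specific rules:

* **Endoglucanase** binds anywhere on a surface chain if a `footprint` of
  contiguous, unblocked surface units is available, with acceptance reduced
  to `pBuried = 0.75` on EF-surface chains that are not on the MF surface.
  The bond at the target is cut with acceptance `pCrystalline` in
  crystalline regions (amorphous preference) and `pGlucoseEnd = 0.9` for
  terminal, glucose-producing cuts. EG acts on soluble oligomers down to
  DP 4 (a uniformly chosen bond) and is inhibited by free glucose and
  cellobiose.
* **Cellobiohydrolase I** binds only at reducing ends of surface chains
  (CBH II: non-reducing ends), threads the chain and cleaves every alternate
  bond, releasing cellobiose, until the remainder falls below DP 5, the
  minute budget is exhausted, or it desorbs (probability 0.05 per cleavage
  in amorphous regions, 0.025 in crystalline ones). Non-processive variants
  release a single cellobiose per binding. Above the preferred chain length
  of 300 units, CBH binding acceptance falls off inversely with chain
  length (`pLongChain * 300 / DP`); a step function cannot reproduce the
  relative conversions of bacterial cellulose versus cotton, whose DPs
  differ only by ~1.4-fold, whereas the inverse law does. CBH acts on
  soluble DP 5–6 oligomers with reduced acceptance `pSoluble` and is
  inhibited by cellobiose (strongly) and glucose.
* **Beta-glucosidase** acts on the soluble pool only: cellobiose to two
  glucose (acceptance `pBgG2 = 1`, its preferred substrate), DP 3–6
  oligomers lose one glucose per cut (`pBgOligo = 0.5`), and free glucose
  inhibits.

After every productive cut, chain-end properties are reassigned, fragments
of DP 6 and below leave the lattice for the soluble pool (vacating their
positions and exposing the layer beneath), and all censuses are updated.
Enzyme binding does not persist across minute boundaries: processive runs
finish or desorb within the minute they start, and footprint blocking —
which models crowding among enzymes acting simultaneously — is cleared at
the minute's end. Cross-minute bound-enzyme state is deliberately out of
scope.

All randomness flows from R's RNG, so a (substrate, system, duration, seed)
quadruple reproduces a trajectory bit-for-bit.

# Observables

Counts convert to laboratory scale through the reaction specification
($W_{sample}$ g solution, solids fraction $S$, cellulose fraction $C$,
volume $V$ mL):

$$G_{actual} = \frac{W_{sample}\, S\, C \cdot 6.023\times10^{23}}{162},
\qquad
C_X = N_X \cdot \frac{G_{actual}}{G_{sim}} \cdot
      \frac{MW_X}{6.023\times10^{23}} \cdot \frac{1000}{V}.$$

Molecular weights are 180 for glucose, 342 for cellobiose, $162n + 18$ for
soluble oligomers of DP $n$ (hydrated ends, following the glucose and
cellobiose pattern) and 162 per anhydroglucose unit for the insoluble DP 6+
fraction. Conversion is the solubilized fraction of glucose units,
$100\,(1 - \text{insoluble}/G_{sim})$ — an anhydro-unit fraction; defining
it on hydrated masses would differ by under 1.2% relative. The hydrolysis
rate is the windowed loss of insoluble cellulose, $-\Delta C_{G6+} \cdot
V/1000$ per hour. The degree of synergism for an enzyme mixture is

$$DS = \frac{\Delta C_{mixed}}{\sum_i \Delta C_i},$$

the mixture conversion over the sum of the conversions of its components
acting alone. Anhydro-mass closure — insoluble units plus
$\sum_n n \cdot$ (soluble count at DP $n$) equal to $G_{sim}$ — holds
exactly after every recorded interval and is asserted in the test suite.

# Parameters: fixed constants and calibrated defaults

Fixed model constants, taken as given: desorption probabilities 0.05/0.025
(amorphous/crystalline), the 25% accessibility penalty for EF-only surface
chains, the 90% terminal-cut acceptance for EG, the DP ≤ 6 solubility
threshold, the CBH I preferred chain length of 300, and the specific
activities above.

The remaining parameters — binding footprints, the counter increments, the
EG crystalline-region factor, the long-chain acceptance scale and the CBH
acceptance on soluble oligomers — are not fixed by first principles. They
were calibrated **once**, by a coarse grid search, against the published
simulated behaviour of the *T. reesei* system on model cellulosic
substrates (48-h conversions of Avicel by individual enzymes and mixtures
with and without excess beta-glucosidase, degrees of synergism in the
ranges reported for Avicel through cotton, and the relative conversions of
high-DP substrates), and then frozen as the shipped defaults of
`hydrolysisParams()`:

| parameter | EG | CBH I | CBH II | BG |
|---|---|---|---|---|
| footprint (units) | 20 | 6 | 6 | — |
| minimum substrate DP | 4 | 5 | 5 | 2 |
| `pCrystalline` | 0.08 | — | — | — |
| `prefChainDp` / `pLongChain` | — | 300 / 0.8 | 300 / 0.8 | — |
| `nNb` / `nNp` | 1 / 5 | 1 / 1 | 1 / 1 | 1 / 1 |
| `nInhibG` / `nInhibG2` | 2 / 10 | 3.5 / 115 | 3.5 / 70 | 1 / — |

Why these shapes: the large EG footprint makes endoglucanase stall once a
surface layer is pulverized into short fragments, which is what gives
endo–exo synergism its strength — in a mixture, cellobiohydrolases clear
those fragments and expose fresh layers that keep EG productive. The high
EG non-productive cost couples the EG rate tightly to crystallinity, which
carries the difference between amorphous-rich Avicel and highly crystalline
cotton. Cellobiose is a far stronger CBH inhibitor than glucose
(`nInhibG2 >> nInhibG`), which is what beta-glucosidase supplementation
relieves. The CBH footprint is smaller than EG's so that DP 7–9 fragments
remain degradable; with both footprints large they would be permanently
inert to every enzyme.

EG's minimum substrate length is 4, not 5: with a DP-5 floor, cellotetraose
could never be consumed in EG-only hydrolysis, while the characteristic
oligomer dynamics (G4–G6 rising over the first hours and then declining,
with cellobiose and cellotriose only accumulating) require it.

# What the generator does and does not emulate

The substrate builder *is* the data generator for this package: its presets
define the study conditions (DP ranges, crystallinity ranges, microfibril
counts, ≥ $10^6$ units), and all reported numbers are simulated at 100 g/L
glucan for 48 h (2880 minute-steps), as means of three replicate seeds.
High-DP substrates (cotton, bacterial cellulose) are also run as a single
microfibril at full chain length where noted; because budgets, censuses and
inhibition all scale with the simulated unit count, the dynamics are nearly
size-invariant and the scaled-down runs track the full presets.

Real cellulosic substrates differ in ways the model does not represent:
cellulose I-alpha antiparallel packing, hemicellulose and lignin occupying
inter-fibril space, enzyme adsorption equilibria and diffusion, thermal
deactivation (the stability hook is fixed at 1), cellulosomes and
GH61/LPMO accessory activity are all out of scope. Passing tests therefore
demonstrate internal consistency and agreement with reference *simulation*
behaviour of pure model substrates, not predictive accuracy for
lignocellulosic biomass.

# Numerical choices and degenerate inputs

* Time step: 1 minute, the natural unit of the IU-based budgets; 48 h =
  2880 steps.
* Fractional budgets: stochastic rounding per (enzyme, MF, minute).
* Candidate draws are uniform with replacement over the current list; the
  within-minute state updates (cleavage, solubilization, blocking) apply
  immediately.
* Tie-breaks: an EG target at a fragment's non-reducing end cuts the bond
  to its left; processive EG chooses its direction by a fair coin.
* Degenerate inputs: an all-solubilized substrate makes the crystallinity
  index undefined (`NA` with a warning); an empty enzyme system yields a
  warned no-op trajectory; a crystallinity target below 2 units per chain
  is rejected because both chain ends must be crystalline; budgets with an
  all-zero census are zero.
* R integer seeds must stay below $2^{31}$; replicate runs use seed,
  seed + 1, seed + 2.

# Known limitations

Counter increments are dimensionless calibration constants, not binding
affinities; they reproduce inhibition qualitatively and the calibrated
endpoints quantitatively, but are not transferable to enzymes with
different kinetics without recalibration. Solid loading affects reported
concentrations only — inhibition operates on simulated molecule counts, so
conversion trajectories are loading-independent, a known simplification of
the counter scheme. Within-minute enzyme crowding is modeled only through
footprint blocking; explicit enzyme copy numbers are not tracked. The
oligomer molecular-weight convention ($162n+18$) slightly overstates the
mass of reported soluble sugars relative to an anhydro convention.
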