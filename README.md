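# chaforge

Simulation-assisted design and analysis of enzyme-free DNA biosensor
circuits built on aptamer recognition and **catalytic hairpin assembly
(CHA)**.

The package targets the in-silico half of a label-free thrombin sensor: an
aptamer:initiator (Aptamer:S) probe releases the initiator strand S when the
target binds; S catalytically opens hairpin H1, which recruits H2 into an
H1:H2 product duplex carrying G-quadruplex-forming tails at both ends, and S
is released for another cycle. The quadruplexes light up a fluorogenic dye
(or form a peroxidase-mimicking DNAzyme for a colorimetric readout). Before
any wet-lab work, every stage of this design can — and should — be checked
computationally. `chaforge` provides those checks as a reusable toolkit,
plus the downstream assay statistics.

It is intended for DNA-nanotechnology practitioners designing
strand-displacement circuits, and ships the four-oligo thrombin sensor panel
as a built-in fixture.

## What it computes

**Secondary-structure thermodynamics** (`partition_function`, `mfe`,
`structure_free_energy`, `enumerate_structures`). Pseudoknot-free structures
are scored loop-wise, `ΔG(s) = Σ_loop ΔG(loop)`, with a documented DNA
nearest-neighbor stack table and size-dependent loop penalties. The
partition function `Q = Σ_{s∈Γ} exp(−ΔG(s)/kT)` and equilibrium
probabilities `p(s) = exp(−ΔG(s)/kT)/Q` are computed by interval dynamic
programming (compiled), and — the package's core correctness claim — verified
against exhaustive enumeration of the ensemble `Γ` on short strands.

**Test-tube equilibrium** (`enumerate_complexes`,
`complex_partition_function`, `solve_equilibrium`, `analyze_tube`). Strand
sets form multi-strand complexes (rotation-distinct orderings up to size
`L`); each complex gets a connected-structure partition function `Q_j` from
a nick-aware extension of the same DP, and equilibrium concentrations solve
the convex program

```
min_x  Σ_j x_j (log x_j − log Q_j − 1)   s.t.  A x = x⁰,  x ≥ 0
```

(mass conservation; `A` the strand-by-complex stoichiometry matrix), via
Newton iterations on the dual so that the law of mass action holds exactly
at every iterate.

**Circuit kinetics** (`build_network`, `simulate_cha`,
`amplification_ratio`). A domain-level mass-action model of the triggered
circuit — trigger release, reversible hairpin opening, catalytic turnover,
and the target-independent H1+H2 leak — integrated with stiff ODE methods,
with the four strand-moiety conservation laws as built-in invariants.

**Assay analytics** (`fit_log_linear`, `predict_signal`, `lod_3sigma`,
`delta_f`, `f_over_f0`). Log-linear calibration `Y = a·lg[X] + b` on
replicate means, and the limit of detection `LOD = 3σ/S` from blank spread
and slope, in both its literal (decades) and calibration-inverted
(concentration) forms. Seeded generators (`generate_calibration_readouts`,
`generate_blank_readouts`, `random_hairpin_panel`) emulate readout tables so
the whole path is testable without instrument data.

## Worked example

```r
library(chaforge)
panel <- load_panel("builtin")
model <- energy_model()          # 37 C DNA loop model

# 1. Do the hairpins fold as designed?
h1 <- mfe(panel$H1, model)
cat(h1$dotbracket, sprintf(" (dG = %.2f kcal/mol)\n", h1$energy))
#> ..........((((((((((............))))))))))..........  (dG = -9.11 kcal/mol)
find_g_tracts(panel$H1, 3)       # 4 G-tracts: quadruplex-capable
#>   start length
#> 1     1      3
#> 2    41      3
#> 3    45      3
#> 4    50      3

# 2. What does the assembled tube look like at equilibrium?
eq <- analyze_tube(panel, tube(c(S = 50, H1 = 300, H2 = 300), max_size = 4))
print(eq)
#> equilibrium_state: 44 complexes, 7 iterations, residual 5.50e-13, kkt 1.42e-14
#>        complex size         x_nM
#> 1        H1.H2    2 2.999896e+02
#> 2            S    1 4.999298e+01
#> 3      H1.S.H2    3 6.246065e-03
#> 4  H1.H2.H1.H2    4 8.253690e-04
#> ...

# 3. How much product does 1 nM of target generate in 2 h?
ar <- amplification_ratio(rate_config(), cha_initial_state(1), t_end = 7200)
cat(sprintf("Duplex: %.1f nM with target, %.2f nM leak-only (ratio %.1f)\n",
            ar$duplex_with, ar$duplex_without, ar$ratio))
#> Duplex: 291.1 nM with target, 6.34 nM leak-only (ratio 45.9)

# 4. Calibrate synthetic readouts and estimate the detection limit
tab <- generate_calibration_readouts(calibration_design(seed = 7))
fit <- fit_log_linear(tab, range = c(0.01, 1))
print(fit)
#> Y = 747.23 lg[X] + 3480.78  (r = 0.9964, residual sd = 58.8, 5 levels)
lod <- lod_3sigma(blank_stats(tab$signal[tab$concentration_nM == 0]), fit)
```

Reading the numbers: the H1 minimum-free-energy structure is a single
hairpin whose stem sequesters the S-recognition segment while the toehold
stays open — the metastable fuel a CHA circuit needs. At thermodynamic
equilibrium the designed H1:H2 product dominates every by-product complex
(S·H1·H2, (H1·H2)₂, ...) by four orders of magnitude, so the sequence design
is sound. Kinetically, 1 nM of target yields ~291 nM of product in two hours
(~291 turnovers per target) against a ~6 nM leak, a 46-fold with/without
contrast. The synthetic calibration recovers its generating line within
noise, and the blank spread plus slope give the 3σ/S detection limit.

A command-line wrapper over the same functions ships as `exec/chaforge`
(subcommands `fixtures`, `structure`, `tube`, `simulate`, `calibrate`,
`synth`, `demo`); `chaforge demo --seed 7 --out DIR` runs the whole pipeline
above and writes CSV/JSON reports.

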