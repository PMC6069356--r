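---
title: "chaforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chaforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaforge)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The sensor it models is an enzyme-free,
label-free thrombin assay: an aptamer:initiator probe (Aptamer:S) releases
the initiator S on target binding; S catalytically assembles two metastable
hairpins H1 and H2 into an H1:H2 duplex whose ends carry
G-quadruplex-forming tails; the quadruplexes transduce to fluorescence (dye
binding) or color (DNAzyme). The package covers four layers: single-strand
structure thermodynamics, multi-strand tube equilibrium, circuit kinetics,
and assay statistics, plus seeded synthetic data so all of it is testable
offline.

## 1. Secondary-structure thermodynamics

### Ensemble and energy model

A secondary structure `s` is a set of non-crossing Watson–Crick pairs
(A:T, G:C only — the sensor's design logic is exact complementarity, so
wobble pairs are deliberately excluded) over one or more ordered strands.
Its free energy is a sum over the loops of its base-pairing graph:

\[ \Delta G(s) = \sum_{\mathrm{loop} \in s} \Delta G(\mathrm{loop}), \qquad
   Q = \sum_{s \in \Gamma} e^{-\Delta G(s)/kT}, \qquad
   p(s) = \tfrac{1}{Q} e^{-\Delta G(s)/kT}. \]

`decompose_loops()` performs the partition into hairpin, stack, bulge,
interior, multiloop and exterior loops; every base belongs to exactly one
loop (pairs are owned by the loop they close), and the all-unpaired
structure scores exactly zero.

The loop parameters (an `energy_model()` object) are a documented constant
block:

* **Stacks**: the unified DNA nearest-neighbor ΔG°37 table, indexed by the
  top-strand dinucleotide (e.g. `GC/GC` −2.24, `AT/AT` −0.88 kcal/mol).
* **Hairpin / bulge / interior penalties**: size-dependent tables to 30 nt
  (anchor values, linearly interpolated), with Jacobson–Stockmayer
  logarithmic extrapolation `ΔG(n) = ΔG(30) + 1.75·RT·ln(n/30)` beyond.
  Single-nucleotide bulges retain the flanking stack.
* **Multiloop**: affine `a + b·(bordering pairs) + c·(unpaired)` with
  a = 3.4, b = 0.4, c = 0.1 kcal/mol. `c` is kept (small but) nonzero so
  that unpaired-base bookkeeping in the dynamic programs is exercised by the
  oracle tests rather than silently multiplied by zero.
* **Temperature**: 310.15 K default — the assay runs at 37 °C — entering
  through `kT` (R = 1.9872 × 10⁻³ kcal/mol/K). The stack/loop tables are the
  37 °C values regardless of the temperature argument; an enthalpy/entropy
  split is out of scope.
* **Minimum hairpin loop**: 3 unpaired bases (the universal convention).
* **Simplifications**: no coaxial stacking, no dangles, no terminal-AT
  terms. These keep the dynamic program and the enumeration oracle in exact
  agreement, which is the correctness surface that matters here: *every
  ensemble-level test is parameter-agnostic*, so the table values set the
  scale of the answers but cannot hide an algorithmic bug.

Two further ensemble conventions: bulge/interior loops larger than 30
unpaired nucleotides are excluded from Γ (the standard two-loop cap; at the
oracle lengths it can never bind, since a 22-nt strand caps two-loops at 18
nt), while `structure_free_energy()` still scores any structure it is handed
finitely by extrapolation — an oversized loop is an extrapolation case,
never an exception. Pseudoknots and G-quadruplexes are outside Γ;
quadruplex-forming capability is assessed at the sequence level
(`find_g_tracts()`: ≥ 4 maximal G-runs of ≥ 3), because a nested-structure
ensemble cannot represent a tetrad.

### Two routes, one answer

`enumerate_structures()` exhaustively lists Γ for total length ≤ 22 and
scores each structure through the loop-decomposition route.
`partition_function()` and `mfe()` compute `Q` and the ensemble minimum by
interval dynamic programming (compiled, O(N³) with the two-loop cap). The
test suite and the acceptance script drive both routes over random strands
of length 8–18 and require agreement to 1 × 10⁻⁹ relative for `Q` (observed:
~10⁻¹⁵) and exact minima for MFE. Enumerated probabilities must sum to 1
within 10⁻¹².

MFE ties are resolved by a deterministic traceback: unpaired before paired,
smaller partner index first, hairpin before two-loop before multiloop
closure. (A global "lexicographically smallest pair set" rule is not
well-defined operationally — the empty set is a prefix of everything — so
the package specifies determinism through the traceback order instead; the
choice only affects which co-optimal structure is printed, never the
energy.)

### Numerical notes

Boltzmann weights of stable 200-nt complexes overflow doubles
(`exp(-ΔG/kT)` with ΔG ≈ −160 kcal/mol), so the engine rescales every weight
by `exp(g₀/kT)` per nucleotide with g₀ = −0.75 kcal/mol and removes the
factor from the returned logarithm exactly. Equilibrium code consumes
`log Q` throughout.

## 2. Multi-strand complexes and tube equilibrium

A complex is a rotation-distinct ordered multiset of strands (a necklace);
`enumerate_complexes()` lists all of them up to size `L`. The default
`L = 4` tracks the largest by-product the tube analysis follows (the
(H1·H2)₂ tetramer). Each ordering gets a partition function `Q_j` from a
nick-aware extension of the same DP:

* a loop containing a strand break (nick) is an exterior loop with zero
  energy;
* only **connected** structures count (every nick spanned by at least one
  pair) — structures that fall apart at a nick belong to smaller complexes.
  Connectedness is enforced by a first-unspanned-nick subtraction over
  prefix orderings, done in log space;
* `Q_j` is divided by the rotational symmetry order of the ordering (the
  standard indistinguishability correction; exercised by the homodimer
  tests), and carries an association penalty of 1.96 kcal/mol per strand
  beyond the first (1 M standard state, duplex-initiation scale);
* a single-strand "complex" reduces exactly to `partition_function()`.

The multi-strand DP is verified against exhaustive enumeration of connected
structures on small systems (e.g. `GGG+CCC`, homodimers, trimers), again to
~10⁻¹⁵.

Equilibrium concentrations minimize `Σ_j x_j(log x_j − log Q_j − 1)` under
`A x = x⁰, x ≥ 0` (concentrations molar, 1 M reference). The solver works
on the dual: one potential λ_i per strand, `log x_j = log Q_j + Σ_i A_ij
λ_i` — the law of mass action — holds *exactly* at every iterate, and
Newton steps (Jacobi-preconditioned, Armijo line search relaxed to the
floating-point resolution of the objective) drive the mass-balance residual
below 10⁻¹⁰ relative, typically in well under 20 iterations with no
randomness (initialization: ideal monomer distribution, uniformly shifted
until the largest complex sits below the total mass scale). The returned
diagnostics report the residual, the mass-action certificate (`kkt`, zero by
construction up to rounding), and the line-searched objective trace, which
the tests assert is monotone non-increasing. Against the closed-form
A + B ⇌ AB solution the solver agrees to better than 10⁻⁹ relative over a
100-point grid of bond strengths and totals.

For the sensor tube (S 50 nM, H1 300 nM, H2 300 nM, L = 4, 44 complexes)
the analysis reproduces the designed outcome: H1·H2 at ~300 nM dominates
every by-product by ~4–5 orders of magnitude. This is a statement about the
*thermodynamic* landscape — the hairpins are only kinetically metastable,
which is exactly what makes the circuit work.

## 3. Circuit kinetics

The kinetic layer is a domain-level (species, not base-pair) mass-action
model, matching the abstraction level of strand-displacement simulators.
The target protein is represented as a single strand fully complementary to
the aptamer — the recognition step is treated as strand displacement, and
protein–aptamer biophysics is out of scope. Eight species, five elementary
reactions:

| reaction | rate | default |
|---|---|---|
| Thrombin + AptamerS → AptamerThrombin + S | `k_trigger` | 10⁻³ /nM/s |
| S + H1 ⇌ S_H1 | `k_open`, `k_open_rev` | 10⁻³ /nM/s, 10⁻³ /s |
| S_H1 + H2 → DuplexH1H2 + S | `k_cat` | 10⁻³ /nM/s |
| H1 + H2 → DuplexH1H2 (leak) | `k_leak` | 10⁻⁸ /nM/s |

The bimolecular defaults (≈10⁶ /M/s) are typical of long-toehold
displacement; the leak is set 4–5 orders slower, the designed metastability
regime. They are configuration, not correctness: the structural properties
(four conservation laws — thrombin, S-moiety, H1, H2 — non-negativity,
monotone product growth, zero product without trigger and leak) hold for
any non-negative rates and are what the tests pin down quantitatively
(conservation drift ≤ 10⁻⁶ relative with `lsoda` at rtol 10⁻¹⁰/atol 10⁻¹²).

Under the assay concentrations (1 nM target, 50 nM probe, 300 nM each
hairpin, 2 h) the defaults give ~291 product copies per target and a
with/without-target ratio of ~46. The published simulation of this circuit
reports a ratio of "about 30×", but its rate constants are not printed, so
the package treats the regime — catalytic turnover ≥ 100×, ratio ≥ 10 — as
the reproducible claim rather than any exact number. Deterministic ODEs
only: at nM × µL scales, stochastic effects are irrelevant and the
published trajectories are smooth.

## 4. Assay statistics

* Transduction is affine (`signal_from_species`): 2 signaling quadruplexes
  per product duplex ("at both ends"), optional per-hairpin leak weight and
  background. Colorimetric readouts use the same form with their own
  gain/background; TMB/H₂O₂ enzyme kinetics are not modeled.
* `ΔF = F − F₀` and `F/F₀` follow their definitions (`F₀ > 0` required for
  the ratio).
* Calibration (`fit_log_linear`) is OLS of *replicate-mean* signal on
  `lg X`, matching how replicate error bars are presented; a per-replicate
  fit is available. `r` is the Pearson correlation of `(lg X, mean Y)` —
  the published "correlation coefficient of 0.985" does not state whether
  it is r or R², so the fit object reports both `r` and `r_squared`.
* `lod_3sigma` applies the literal `3σ/S` rule. Applied to a log-linear
  slope this is in *decades* of concentration, not molarity, so the
  calibration-inverted concentration form (signal `F₀ + 3σ` mapped through
  the line) is always reported alongside. The assay's published 2.4 pM
  cannot be recomputed here: it requires the raw blank spread, which exists
  only in figure form. What the package pins down instead is the
  arithmetic (exact on hand-computable inputs) and the scaling laws
  (linear in σ, inverse in |S|).

## 5. Synthetic data

`generate_calibration_readouts()` draws
`Y = 721.64·lg X + 3432.27 + N(0, σ²)` over the assay's standard series
(0, 0.01, 0.05, 0.1, 0.5, 1, 10, 50 nM; 3 replicates) — the published
calibration coefficients are the generator defaults, which makes the
fitting path self-validating. Choices a user should know:

* **Noise**: homoscedastic Gaussian, σ = 50 signal units by default. The
  true replicate noise is unpublished; σ = 50 is a few percent of the
  dynamic range, consistent with the size of the reported three-replicate
  error bars. Symmetric error bars justify the Gaussian; nothing richer is
  claimed.
* **Blanks**: drawn around `blank_mean = 1800`, a background below the
  lowest calibration point (the line itself diverges to −∞ as X → 0, so a
  blank level is a separate physical parameter). The serum option adds a
  positive offset only — elevated background from potassium-induced
  quadruplexes — leaving the spread unchanged.
* **Recovery study**: 200 seeded fits at σ = 50 recover the generator slope
  within 3 standard errors in ≥ 99 % of runs. The SE used is the *exact
  sampling* standard error of the slope under the known generator noise
  (σ/√3 over 5 log-spaced means), so the 3-SE band is a z-band with nominal
  99.73 % coverage; a per-fit estimated SE with 3 residual degrees of
  freedom would make it a t-band with ~94 % coverage and would test the
  t-distribution, not the recovery.

What the generators deliberately do **not** emulate: raw emission spectra,
photobleaching, plate effects, heteroscedasticity, outliers. Green tests on
synthetic data therefore demonstrate correctness of the estimators and the
pipeline, not robustness to instrument pathology.

`random_hairpin_panel()` builds `stem + loop + rc(stem)` strands with G/C
stems and A/C/T loops; the strand then contains exactly `stem_len` possible
pairs, all used by the designed contiguous stem, so for stems ≥ 3 the
designed hairpin attains the ensemble minimum by construction — a seeded
corpus with a known answer for the folding engine.

## 6. Problem sizes and budgets

The shipped tests run the enumeration oracle on 50 random 8–18-mers,
exhaustive multi-strand checks on ≤ 12-nt complexes, the 100-point dimer
grid, the full 44-complex sensor tube, four 2-h kinetic integrations and a
200-fit recovery study — a few minutes end to end on one core. These sizes
were chosen so the exhaustive oracles stay exact and fast; the DP engine
itself handles the 224-nt tetramer complexes in under a second each.

## 7. Known limitations

* The energy model is a fixed 37 °C table; no salt correction, no
  enthalpy/entropy split, no dangles/coaxial terms. Absolute free energies
  are therefore approximate; ensemble-level *consistency* is what is
  guaranteed.
* The rotational-symmetry division for palindromic complex orderings is the
  standard distinguishability approximation, not an exact symmetry-class
  sum.
* Complex enumeration is exhaustive in necklaces; for many-strand panels at
  large L it grows quickly (fine at the sensor's 3 strands, L = 4).
* The kinetic model tracks the eight designed species only — no spurious
  sequence-level side reactions, no fuel degradation.
* Signal transduction is linear; saturation of dye or DNAzyme is not
  modeled.
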