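---
title: "Modelling fructan biosynthesis: kinetics, steady states and DP profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fructan biosynthesis: kinetics, steady states and DP profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fructansim)
```

## The biological problem

Temperate grasses store carbon as fructans: fructose chains grown on a
sucrose primer by fructosyltransferases (FTs). 1-SST condenses two
sucrose molecules into the trisaccharide 1-kestose; 1-FFT and its
relatives (6-SFT, 6G-FFT) then shuttle single fructose units between
fructan donors and acceptors. Kinetically all of these transfers are the
same event — move one fructose from a donor oligomer to an acceptor — so
the package collapses them into one reaction family over a single linear
series `gf1..gf10` (glucose plus *n* fructose units) and ignores the
distinction between inulin, levan and neoseries bond types. What
distinguishes hypotheses about the enzymology is then *which* donors and
acceptors are allowed and how fast each transfer runs; those choices
reshape the steady-state polymer-length (DP) profile, which is what an
ion-trap LC-MS measurement of tissue extracts sees.

## Model structure and assumptions

The network (`fructanNetwork()`) has 14 species and 22 reactions.
Assumptions inherited from the underlying biochemical scheme:

* glucose is supplied at a constant concentration (clamped state, 0.1
  mol L⁻¹ by default) — the model describes synthesis in a tissue with
  ample carbon supply;
* glucose/fructose interconversion is reversible, implemented as two
  independent irreversible Michaelis–Menten reactions;
* sucrose synthesis is irreversible; its ATP requirement is not modelled,
  and invertase/sucrase hydrolysis of sucrose is ignored;
* no degradation: fructan exohydrolases are absent, so the model applies
  to tissue states where polymerization dominates (e.g. mid-regrowth
  leaf blades);
* the chain is programmed up to `gf10`, which is a pure sink — produced
  by the ninth transfer, never consumed. This truncation is immaterial
  for the DP3–10 window the MS data cover.

A consequence of the sink is worth stating explicitly: at "steady state"
every pool is stationary *except* `gf10`, which grows linearly as the
chain's outflow. All convergence criteria in the package therefore range
over the unclamped, non-sink species. Without that exclusion no scheme
would ever satisfy a max-derivative criterion.

## Rate laws and the "mol reactant" convention

Velocities are expressed as moles of reactant consumed per litre per day.
The three rate forms are:

* unary `S -> P`: rate `v[S]/(K+[S])`, K in mol L⁻¹;
* hetero binary `A + B -> ...`: event rate `v[A][B]/(K+[A][B])`, K in
  (mol L⁻¹)²; each substrate is consumed, and each product formed, at the
  event rate;
* homodimeric `2S -> C + D`: S is consumed at `v[S]²/(K+[S]²)` and each
  product forms at half that rate.

The binary product form `[A][B]` (rather than, say, sequential-binding
kinetics) and the homodimer half-rate convention were adopted because
they are the simplest forms consistent with the published steady states:
at the basic scheme's steady state the fructose balance closes exactly
(supply 0.5 = 0.25 back-conversion + 0.25 into sucrose, mol L⁻¹ d⁻¹), and
production balances consumption for every pool of all five published
schemes to within the 2-significant-figure rounding of those published
concentrations (< 5 % relative residual; mostly < 1 %). The test suite
pins this down with a flux-balance oracle evaluated at the published
states, which is the strongest validation available for a reconstructed
rate law. Under the alternative convention (homodimer products at the
full event rate) the gf4 balance of the gf3-donor scheme misses by an
order of magnitude more.

Default parameters: K = 0.1 mol L⁻¹ for the glc/fru pair, K = 0.01
(mol L⁻¹)² for every binary reaction, applied uniformly to the gf3-donor
family for all n = 3…9; v = 1 mol L⁻¹ d⁻¹ for the basic pathway, v = 0
for the optional reactions.

## Schemes as velocity presets

One fixed topology carries all five published schemes; presets
(`schemePresets()`) override only maximum velocities. This mirrors the
parameter table's structure (optional reactions are listed with v = 0
rather than omitted) and keeps scheme comparisons free of structural
confounds. Scheme (a) is the classic 1-SST/1-FFT model; (b) adds gf3 as
donor; (c) makes one of those transfers fast (v = 10), carving a gap at
the consumed acceptor gf4; (d) cuts gf3 synthesis and routes fructose
into glucose-free oligomers f2/f3; (e) re-weights the elongation chain
(v = 2 for most transfers, 10 towards gf9, 4 towards gf10) to reproduce
the bimodal DP profile measured in ryegrass blades.

## Numerical choices

* **Integration** (`simulateNetwork()`, `findSteadyState()`):
  `deSolve::lsoda` with rtol 1e-8, atol 1e-12. The system is only mildly
  stiff (K = 0.01 against concentrations of 1e-3–1e-1), but lsoda's
  automatic stiff/non-stiff switching makes the choice safe for arbitrary
  velocity overrides. Time is in days; the default horizon is 1e4 d with
  checkpoints at 10, 100 and 1000 d, and the steady-state criterion is
  max |d[X]/dt| < 1e-9 mol L⁻¹ d⁻¹ over the settling species. All schemes
  converge near t = 100 d in well under a second.
* **Negative excursions**: concentrations below zero by less than ~100×
  atol are clipped to zero; anything larger aborts — it would indicate a
  genuine solver failure, not round-off.
* **Root solving** (`steadyStateRoot()`): a damped Newton iteration on a
  forward-difference Jacobian over the settling species, seeded from an
  integration endpoint. Step halving enforces monotone residual decrease
  and non-negativity. Species whose every reaction is switched off are
  excluded from the unknowns (their residual rows are identically zero
  and would make the Jacobian singular); they keep their seed value. The
  root and integration routes agree to < 0.1 % on every scheme, which the
  tests assert as an oracle-equivalence property.
* **Degenerate inputs**: an all-zero-velocity network returns its initial
  conditions as the (trivial) steady state; all-zero fructan pools make
  sum/max normalization an error rather than NaN.

## MS annotation conventions

Fructan oligomers DP3–10 ionize predominantly as singly charged [M−H]⁻
ions. The package models the m/z series as an anchor (503.3 Th at DP3)
plus a constant 162.0 Th per fructose residue — the spacing of the
reported series itself. The increment is deliberately *not* derived from
atomic masses: the one-decimal instrument values sit between monoisotopic
and average-mass predictions, and reproducing the instrument's reported
series exactly matters more here than mass-spectrometric first
principles. Matching uses a ±0.5 Th tolerance (unit-resolution trap),
configurable on `dpSeries()`.

Peak aggregation sums all isomeric peaks per DP (1-/6-/6G-kestose are
indistinguishable by mass) and excludes known non-fructan contaminants —
the sucrosyl-galactosides raffinose and loliose at the DP3 m/z — by their
identity label. Chromatographic identity is information a bare peak table
does not carry, so exclusion is label-based, and unlabeled DP3 peaks are
kept with a warning.

## The synthetic peak-table generator

`synthesizePeakTable()` emulates what the annotation layer consumes: per
DP class it splits the total intensity across the observed isomer
multiplicities (3 fructan + 2 contaminant peaks at DP3; 4 each at DP4–7;
3, 1 and 2 at DP8–10) with a seeded Dirichlet draw, jitters m/z within
half the match tolerance, and applies multiplicative log-normal intensity
noise. At zero noise the table aggregates back to its source distribution
exactly, which gives the annotation pipeline a conservation-style
round-trip test.

What it does *not* emulate: chromatographic peak shape and co-elution,
detector saturation, charge-state mixtures, in-source fragmentation, or
the actual relative response factors of different DP classes. Passing
round-trip tests therefore validates the bookkeeping of annotation, not
instrument realism; measured intensity profiles remain external data.

## Fitting velocities to a measured profile

`fitVelocities()` automates the velocity-tuning exercise: choose a set of
free velocity parameters, and minimize the sum of squared differences
between the sum-normalized model and target DP distributions. Design
decisions, since the original adjustment was manual and no objective was
ever published:

* the objective compares *relative* DP profiles (glucose, fructose and
  sucrose pools are ignored) — absolute MS intensities are not on the
  model's concentration scale;
* derivative-free Nelder-Mead inside a [0, 20] velocity box (covering the
  largest published velocity, 10, with headroom), with penalty values for
  out-of-box or steady-state-failing trial points;
* Nelder-Mead's simplex tends to collapse early on this smooth, flat
  landscape, so each start is polished by re-expanding the simplex from
  the incumbent until the objective stops improving; with three seeded
  random restarts (plus the default start) the seven-velocity
  self-recovery problem reaches objectives below 1e-12 in a few seconds;
* one-dimensional fits use Brent's method instead;
* fitted parameter sets are reported but should not be over-interpreted:
  different velocity sets can produce indistinguishable profiles, and
  only the distribution match is asserted anywhere in the package.

## Problem sizes and runtime

The steady-state computations are 14-dimensional ODE/root problems and
run in milliseconds; the full test suite (around 300 assertions,
including five steady-state reproductions, dual-route agreement and a
seven-parameter fit recovery) completes in about ten seconds on a single
CPU. These sizes are the package's natural scale — the model is a
desk-scale instrument, chosen so that every published number can be
re-derived from scratch on any machine.

## Known limitations

* One linear fructan series: no branch-type resolution (β2–1 vs β2–6
  bonds, terminal vs internal glucose), so isomer-level biology is out of
  reach by construction.
* No degradation pathway: the model cannot describe tissues where
  exohydrolase activity matters (e.g. shortly after defoliation).
* The glucose clamp abstracts the whole upstream carbon supply; diurnal
  dynamics of supply are not represented.
* The chain truncation at gf10 biases nothing within DP3–10 but forbids
  conclusions about longer polymers, which in planta reach DP ≫ 10.
* Deterministic ODEs only: no stochastic effects, no spatial or
  vacuolar compartmentalization.
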