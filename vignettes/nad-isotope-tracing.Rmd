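---
title: "Tracing NAD+ synthesis in colitis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing NAD+ synthesis in colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadflux)
```

# The problem

NAD+ is maintained by three biosynthetic routes: de novo synthesis from
tryptophan through the kynurenine pathway, salvage of nicotinamide (NAM)
through NAMPT, and the Preiss-Handler route from nicotinic acid (NA) —
the latter fed in the gut largely by microbial deamidation of
host-derived NAM. In inflammatory bowel disease the colonic NAD+ pool
falls, and the question this package's pipeline answers is *where the
remaining NAD+ comes from*: how much of each compartment's pool is
salvage-derived versus tryptophan-derived, and how that partition shifts
between the early flare-up (mild colitis, days 4-5 of DSS treatment) and
the active flare (days 7-11).

The measurement design is a 20-h constant-rate intravenous infusion of
one of two tracers per animal — uniformly ¹³C-labeled tryptophan
(1.25 nmol/g/min, i.e. a 50 mM solution at 0.5 µl per 20 g per min) or
2,4,5,6-ring-deuterated nicotinamide (0.1 nmol/g/min, 4 mM) — with serum
sampled at 0, 15, 30 min, 1, 2, 6, 15 and 20 h and tissues and luminal
contents collected terminally. The 20-h duration exists to put serum
enrichment on its plateau, because the contribution formulas divide by
serum precursor enrichment *at steady state*.

# Atom mapping

The atlas (`default_atlas()`) stores metabolites with their molecular
formulas (standard chemistry: Trp C₁₁H₁₂N₂O₂, Kyn C₁₀H₁₂N₂O₃, QUIN
C₇H₅NO₄, NAM C₆H₆N₂O, ...) and atom transitions annotated with how many
tracer-element atoms each carries through. Expected isotopologue shifts
follow by walking the graph from the tracer's entry metabolite:

```{r shifts}
map <- default_atlas()
sapply(c("tryptophan", "kynurenine", "quinolinic_acid", "NAD", "NAM"),
       function(m) expected_shift(tracer_trp13c(), m, map)[1])
expected_shift(tracer_nam_d4(), "NAM", map)
```

Three modeling choices deserve explanation:

* **Route-resolved shifts.** Free NAM under the deuterated tracer exists
  as the intact M+4 infusate *and* as M+3 released by NAD+ breakdown;
  the two species carry different information (delivery vs turnover), so
  `expected_shift()` returns the per-route set and callers select by
  route label rather than receiving a silently collapsed value.
* **Redox-site loss.** The 4-position deuterium sits on the redox-active
  carbon of the nicotinamide ring and is lost when the molecule is
  incorporated into NAD+. We model this as a deterministic −1 applied at
  the NAM→NMN incorporation edge, but *only* to the intact infusate
  species (shift = 4): a recycled M+3 molecule has already shed that
  atom and re-incorporates unchanged. This conditioning is what makes
  "apply the loss exactly once along any path" automatic, including
  around the salvage/consumption cycle.
* **Luminal NA.** Structurally, deamidation of NAM M+4 would give NA
  M+4; the monitored set for NA is nonetheless {0, 3} because the
  microbial deamidation edge is conditioned on its substrate arriving
  via the recycling route — luminal NAM is host-recycled M+3, and the
  intact infusate is not observed in the lumen. This is an empirical
  constraint of the system encoded as an edge predicate, not an atom
  bookkeeping rule.

3-hydroxyanthranilic acid is shipped with its structural retention of
7 tracer carbons. Reported-label conventions sometimes quote M+6 for it;
`default_atlas(shift_overrides = c("3-hydroxyanthranilic_acid" = 6))`
installs that reading without touching the atom map.

# Natural-abundance and purity correction

A measured MID is the true tracer-derived MID blurred by naturally
occurring heavy isotopes and by incomplete tracer enrichment. Column
*j* of the correction matrix is the convolution of two binomials: the
*j* intended-heavy positions each actually heavy with probability
`purity` (default 0.99, applied per position independently), and the
remaining *n − j* tracer-element positions each picking up a natural
heavy isotope (defaults ¹³C 0.0107, ²H 1.15·10⁻⁴ — standard reference
values; the instrument-facing side of the study does not determine
them). In the default **high-resolution** mode only the tracer element
is convolved, appropriate for Orbitrap-class resolution where e.g. ¹³C
and ²H isotopologues are mass-resolved; a **nominal** mode convolving
all elements (including ¹⁸O at +2) is provided for completeness.

Correction solves `M x = raw` by non-negative least squares and
renormalizes, guaranteeing non-negative fractions rather than clamping
the negatives a direct inversion can produce. Numerical notes:

* The raw vector is sum-normalized before solving. Corrected fractions
  are scale-invariant by construction, and the NNLS active-set
  tolerance is absolute, so solving at ion-count magnitudes (~10⁷) can
  exhaust the iteration budget that the normalized problem solves
  cleanly.
* The relative residual is recorded on every corrected MID and the
  record flagged above 10⁻³; flagged rows propagate as flags, never as
  silent drops.
* An all-zero raw vector is an error ("empty measurement"); a formula
  with zero tracer-element atoms yields the 1×1 identity, not an error.
* The forward model (`forward_convolve()`) is the brute-force matrix
  product and doubles as the independent oracle: round-tripping 200
  random MIDs on molecules up to C₁₂ recovers the truth to better than
  10⁻⁸ in the test suite.

# The synthetic-data generator

`build_default_model()` + `simulate_infusion()` + `measure()` stand in
for the study's animals. The kinetic model is linear first-order
mass-isotopomer balance: pools are constant (validated: total influx
equals total efflux for every pool), and each pool's isotopologue
fractions relax toward the flux-weighted mixture of its inflows, with
shift transformation along conversion edges taken from the atlas. This
is justified for trace-level doses where no enzyme approaches
saturation and the interpretable quantity is the steady-state fraction.
The ODE system (`deSolve::lsoda`, absolute tolerance 10⁻¹⁰, relative
10⁻⁸) is solved on the study's sampling grid; an unbalanced config is
refused, not repaired.

The default compartment set is minimal — serum, liver, colon, colon
lumen — which keeps a full cohort simulation well under a second while
retaining every qualitative feature the estimators probe: a de novo
liver, a salvage-dominated colon, a lumen fed by host NAM through
microbial NA. Host→lumen NAM transfer and microbial deamidation are
single lumped first-order steps (one "microbiome" per luminal
compartment).

Scenario presets fix the study conditions: relative to control, the
active flare halves the colonic NAD+ pool (20 → 10 nmol/g), raises
colonic salvage flux and NAD+ consumption, raises hepatic de novo flux,
and raises the circulating kynurenine pool; the early flare-up sits in
between. The colonic salvage share of NAD+ synthesis is 80 / 75 / 70 %
in control / early / active. No pool sizes or flux magnitudes are
reported by the animal study itself; these magnitudes are free model
parameters chosen once to give plasma-like turnover ordering (serum
pools minutes, tissue NAD+ tens of minutes) and plateaus comfortably
inside the 15-20 h window, and only the *directions* of the scenario
differences are anchored to the biology.

The measurement forward model applies tracer impurity and
natural-abundance convolution (the same matrix the corrector inverts),
scales by pool size to an ion-count scale, and multiplies by mean-one
log-normal noise with configurable CV (LC-MS-like multiplicative
error); all randomness flows from the config seed, and a fixed seed
reproduces the table byte-for-byte.

**What passing tests do and do not show.** The generator emulates
compartmental dilution, recycling topology, natural-abundance blur,
impurity and multiplicative noise. It does not emulate chromatographic
interference, detector saturation, extraction variation between
animals, diurnal intake, enzyme saturation, or microbial community
structure. Parameter-recovery results on it therefore validate the
*estimator arithmetic and its propagation through correction*, not the
biological accuracy of any particular animal's numbers.

# Contribution estimates

The estimator divides a tissue NAD+ isotopologue fraction by the
animal's own serum precursor enrichment at plateau:

* NAM arm: `100 · NAD+(M+3) / (NAM(M+3) + NAM(M+4))_serum` — both serum
  species are labeled precursor available for salvage, so both enter
  the denominator; fractions (not concentrations) are summed, keeping
  the formula homogeneous and consistent with the tryptophan arm.
* Trp arm: `100 · NAD+(M+6) / Trp(M+11)_serum`.

The plateau is the per-animal mean of serum points at ≥ 900 min
(configurable), i.e. the 15-h and 20-h samples on the study grid; the
steadiness flag compares the last two points against an absolute 0.05
tolerance. Per-animal ratios are computed first and then summarized as
mean ± SEM — aggregating before the ratio would discard the pairing of
each animal's numerator with its own denominator.

Two documented behaviors are features, not bugs. First, the estimator
carries a small downward *precursor-dilution* bias: tissue NAM is
slightly less enriched than serum NAM because local recycling dilutes
it, so a colon configured at 70 % salvage reads a little below 70 even
noise-free (the acceptance suite bounds the end-to-end estimate within
±5 points at 5 % noise, n = 10). Second, a compartment with *zero*
local de novo flux still shows a nonzero "Trp contribution" whenever it
salvages hepatically recycled M+6 NAM — the workflow drivers reproduce
this on the tryptophan arm, and it mirrors the interpretation that
colonic tryptophan-derived NAD+ arises through the liver-NAM relay
rather than local synthesis. Contributions above 100 % (denominator
underestimation) are reported as-is.

# DAI scoring

The index sums six components, each 0-5: binned percent weight loss and
five observed ordinals (stool, bleeding, posture, activity, fur), total
0-30. The printed weight bins are integer-edged (1-5, 6-10, 11-19,
20-25, > 25 %), leaving non-integer losses unassigned; we round half-up
to an integer first, which covers every value with no gaps and keeps
the map monotone (verified exhaustively over the full component grid in
the tests). The combined score is the plain sum — no division by the
number of parameters — and the verbal anchors of the ordinal scales are
documentation for the observer, not computed quantities.

# Statistics

Two-group comparisons use the Mann-Whitney U test, two-sided (the
sidedness is a package decision; nothing in the design implies a
one-sided alternative), exact when both n ≤ 8 without ties and
normal-approximated with tie correction otherwise; the implementation
is checked against a full-enumeration permutation oracle for all
layouts with n ≤ 5 and holds its nominal size at α = 0.05 in a seeded
null simulation. Multi-group comparisons use tie-corrected
Kruskal-Wallis followed by Dunn's z-tests on mean ranks. Dunn p-values
are emitted both raw and BH-adjusted — post hoc software defaults
differ on this, so both are reported and labeled. Significance bands
include the § < 0.1 trend band used throughout the figures. qPCR fold
changes use 2^−ΔΔCt against a reference gene (TBP in the study).

# Problem sizes

The shipped drivers and tests run everything at desk scale: cohorts of
10 animals per arm and scenario, the 8-point serum grid, the 4-compartment
network (≈ 60-130 ODE states per arm), 200-case correction round-trips,
and a 10,000-replicate null calibration — sizes chosen so a full rebuild
of every table stays in the minutes range on one core while keeping
every estimator's sampling error well inside the tolerances asserted.

# Known limitations

* Nominal mass shifts only: no position-specific isotopomer modeling,
  so e.g. intramolecular deuterium scrambling is out of scope.
* No absolute quantification (the study has no calibration curves);
  pool sizes are relative TIC, normalized to the control-group mean.
* The simulator's rate constants are not physiologically calibrated;
  only effect directions across scenarios are meaningful.
* The correction does not reproduce any specific external tool's code
  paths (resolution handling is a binary high/nominal switch; no ¹⁵N
  tracers).
* Indole-branch and serotonin metabolites are monitored as shifts only;
  no quantitative flux model is attached to them.
* Metagenomic profiling, network integration with taxa, histology and
  immunoassays that surround the tracing results in the original study
  are out of scope here.
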