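# nadflux

Stable-isotope tracing analysis of NAD+ metabolism in DSS-induced murine
colitis: from raw mass-isotopomer intensity tables (or a built-in
compartmental infusion simulator) through natural-abundance correction,
fractional labeling, and precursor-contribution estimates that partition
each tissue's NAD+ pool between nicotinamide (NAM) salvage and de novo
synthesis from tryptophan (Trp), plus the disease-activity scoring and
group statistics used alongside.

## Who this is for

Researchers analysing in vivo tracer infusions of NAD+ precursors —
[U-¹³C₁₁]-tryptophan (infused at 1.25 nmol/g/min) or
[2,4,5,6-²H]-nicotinamide (0.1 nmol/g/min) — over a 20-h constant-rate
protocol with serum sampling at 0, 15, 30 min, 1, 2, 6, 15 and 20 h, and
terminal tissue/luminal dissection.

## The core calculations

**Atom mapping.** A pathway atlas encodes the de novo (kynurenine)
pathway, NAM salvage, the Preiss-Handler route from nicotinic acid (NA),
NAD+ consumption/recycling, NAM methylation, and microbial deamidation of
host-derived luminal NAM. From it, the expected nominal shift of any
product is derived: Trp M+11 → Kyn M+10 (formate lost) → QUIN M+7
(alanine lost) → NAD+ M+6 (CO₂ lost at QPRT) → recycled NAM M+6; and for
the ring-deuterated tracer, NAM M+4 → NAD+ M+3 (the redox-active 4-²H is
lost on incorporation) → recycled NAM M+3.

**Natural-abundance correction.** Measured MIDs are deblurred by
non-negative least squares against the binomial forward model

    raw = M · x,   M[·, j] = Binom(j, purity) ⊛ Binom(n − j, p_nat)

with ¹³C natural abundance 0.0107, ²H 1.15·10⁻⁴, per-position tracer
purity 0.99, and (default) high-resolution mode in which only the tracer
element is convolved.

**Precursor contributions.** With serum denominators taken at the
steady-state plateau (mean of ≥ 15 h samples, per animal):

    NAM contribution (%) = 100 · NAD⁺(M+3)_tissue / [NAM(M+3) + NAM(M+4)]_serum
    Trp contribution (%) = 100 · NAD⁺(M+6)_tissue / Trp(M+11)_serum

Values above 100 % are reported, never clipped. The two arms come from
separate animals and are never forced to sum to 100 %.

**DAI.** The disease activity index is the sum (0–30) of six 0–5
components: binned percent weight loss, stool consistency, bleeding,
posture, activity and fur.

**Statistics.** Mann-Whitney U for two groups (exact when both n ≤ 8
without ties), Kruskal-Wallis with Dunn's post hoc z-tests for more,
Benjamini-Hochberg adjustment, significance bands down to the § < 0.1
trend band, and 2^−ΔΔCt qPCR fold changes.

## Worked example

Simulate an active-flare nicotinamide-arm cohort (10 animals, 5 %
multiplicative measurement noise), forward-model the LC-MS readout, and
run the full correction → labeling → contribution pipeline:

```r
library(nadflux)
map <- default_atlas()

expected_shift(tracer_trp13c(), "NAD", map)
#> de_novo salvage
#>       6       6

cfg <- build_default_model("active_flare", tracer_nam_d4(),
                           seed = 1, noise_cv = 0.05)
sim <- simulate_infusion(cfg, map)
obs <- measure(sim, map, n_reps = 10)
est <- estimate_contributions(obs$peaks, obs$metadata, map)
est$summary[, c("compartment", "precursor", "n_animals",
                "mean_percent", "sem")]
#>   compartment precursor n_animals mean_percent  sem
#> 1       colon       NAM        10         68.5 1.20
#> 2 colon_lumen       NAM        10         76.4 1.15
#> 3       liver       NAM        10         49.0 1.23
```

The active-flare preset sources the colonic NAD+ pool 70 % from salvage;
the pipeline recovers 68.5 ± 1.2 % — the small deficit is the
precursor-dilution bias inherent to the serum-referenced estimator. The
high luminal value reflects that most microbial NAD+ also traces back to
host NAM through microbial NA.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the whole study on synthetic
cohorts and write their tables under `results/`:

1. `01_simulate.R` — both tracer arms × {control, early flare-up, active
   flare}, raw peak tables + metadata + configured ground truth.
2. `02_correct_label.R` — correction, fractional labeling, serum plateau
   estimates.
3. `03_contributions.R` — per-animal contribution records and
   compartment summaries vs ground truth.
4. `04_dai_stats.R` — DAI time course on a synthetic clinical table,
   Mann-Whitney and Kruskal-Wallis + Dunn comparisons, a 2^−ΔΔCt example.

Run them in order from the repository root with `Rscript`.

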