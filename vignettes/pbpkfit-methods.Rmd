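---
title: "Methods: the pbpkfit whole-body model, partition equations, and fitting machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pbpkfit whole-body model, partition equations, and fitting machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpkfit)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The whole-body model

`simulate_pbpk()` solves a 14-compartment perfusion-limited mass balance.
Each organ is a well-mixed volume `V_t` perfused at blood flow `Q_t`;
venous blood passes through the lung in series to arterial blood, which
feeds the remaining eleven tissues; gut and spleen drain through the
portal vein into the liver. For a non-eliminating tissue, in amounts
(µg),

$$V_t \frac{dC_t}{dt} = Q_t\left(C_{in} - \frac{C_t}{K_{pu,t}\,f_{up}}
B\!:\!P\right), \qquad K_{pu,t}\,f_{up} = K_{p,t},$$

so the term `C_t · B:P / Kp_t` is the *blood-side* concentration leaving
the tissue. Liver and kidney additionally lose drug at rate
`CL_organ · C_out,blood`. Writing elimination as a separate flux (rather
than inside the flow parentheses) keeps units consistent and gives the
textbook identity `Dose = ΣCL · AUC_blood` in the low-extraction limit,
which the test suite verifies to 1%. Hepatic metabolism and biliary loss
are one lumped `cl_hepatic`; renal loss is `cl_renal`.

Dosing is linear throughout: IV boluses are initial-condition additions to
venous blood, infusions constant-rate venous inputs, and oral doses enter
a gut-lumen depot emptying at `ka` (1/h), of which a fraction `f_oral`
reaches gut tissue. First-pass hepatic extraction is *not* folded into
`f_oral`; it emerges from the portal topology, so `f_oral` means fraction
absorbed × gut escape only.

**Assumptions**: perfusion-limited (instantaneous tissue equilibration at
`Kp`), linear clearance, no enterohepatic recirculation, no
permeability-limited sub-compartments, no transporters.

### Solver

Between dose events the system is linear and time-invariant, so the
default solver propagates the state with matrix exponentials — the exact
solution, not an approximation. An eigendecomposition fast path (used when
a reconstruction check passes at 1e-9 relative) makes each simulation a
few milliseconds, which is what allows a full coarse-grid + simplex fit in
seconds; a Padé `Matrix::expm()` fallback covers defective rate matrices
(e.g. deliberately degenerate all-equal-Kp configurations). Mass balance
is exact to machine precision by construction (the rate matrix has zero
column sums once the elimination and unabsorbed sinks are included), and
the conservation tests require `< 1e-6` relative error. A fixed-step RK4
mode (`solver = "fixed_step"`, default step 1e-4 h) is retained for parity
with fixed-step engines and is tested to agree with the exact propagator
to 1e-8; it is never the default because it is strictly slower and less
accurate. Amounts a hair below zero from floating-point cancellation are
clamped at a `−1e-9 × dose` floor; anything below that raises a solver
error.

## 2. Tissue:plasma partitioning

`build_partition_set()` supplies per-tissue `Kp` under three
configurations:

* `rodgers_fixed`: composition-based prediction from the measured logP;
* `rodgers_logp_optimized`: the same equations with logP replaced by an
  optimized value — the hybrid configuration;
* `kp_optimized`: a single effective `Kp` applied to all twelve tissue
  compartments (eliminating organs included; a documented toggle of the
  build, since whether they were included in the original design is not
  stated anywhere we can check).

The mechanistic equations follow the Rodgers–Rowland treatment of
ionization. With `P = 10^logP`, `X` and `Y` the intracellular and plasma
ionized:neutral ratios, and tissue volume fractions `f_ew` (extracellular
water), `f_iw` (intracellular water), `f_nl` (neutral lipid), `f_np`
(neutral phospholipid):

**Class 1** (monoprotic bases with pKa ≥ 7, the "moderate-to-strong"
cutoff of the standard classification): intracellular binding is to
acidic phospholipids,

$$K_{pu} = f_{ew} + \frac{1+X}{1+Y} f_{iw}
 + \frac{K_{a,AP}\,[AP]\,X}{1+Y}
 + \frac{P f_{nl} + (0.3P + 0.7) f_{np}}{1+Y},$$

with the affinity constant `K_a,AP` back-calculated from the measured
blood:plasma ratio: `Kpu_BC = (B:P − (1 − Hct)) / (Hct · fup)` is the
red-cell partition coefficient, and inverting the same equation on the
red-cell composition yields `K_a,AP` (clamped at zero; a `B:P` at or below
`1 − Hct` means no cell partitioning and is an error).

**Class 2** (acids, weak bases, neutrals, zwitterions): extracellular
binding is to tissue proteins, with the association back-calculated from
`fup` net of plasma-lipid partitioning and scaled by the tissue:plasma
binding-protein ratio, clamped at zero.

For adipose only, the neutral-lipid term uses the vegetable-oil scale
`log10 P_vo:w = 1.115 logP − 1.35` in place of octanol — octanol
over-predicts partitioning into storage fat; the `f_np` term keeps the
octanol scale.

**A monotonicity subtlety.** `Kp` is non-decreasing in logP at fixed
binding constants (every coefficient of `P` is non-negative), and the
tests assert this for the class-2 build on every bundled tissue and for
the class-1 equation at fixed `K_a,AP`. It is *not* globally true for
class-1 bases when `K_a,AP` is re-derived from a fixed `B:P` at each logP:
as lipids explain more of the red-cell partitioning the derived affinity
falls, and tissues rich in acidic phospholipid relative to lipid (kidney,
liver) can see `Kp` decrease. This is a real property of the
blood-constrained calibration, not a bug.

**Cap rule.** Implausibly large predictions are truncated at a cap
recorded per tissue: `kp_cap = max(50, 5 · Vdss_obs / V_body)` when an
observed NCA Vdss exists, else 50. The formula keeps the model's total
distribution volume within about five times the observed one; truncation
(replacing the value by the cap itself) is the least-surprise default. The
cap is applied inside every optimizer evaluation.

### Physiology data

One human-adult table ships under `inst/extdata/` (CSV per tissue plus a
JSON sidecar of whole-body quantities); other species are additional
tables, not code. Volumes and flows are ICRP-style reference values
(cardiac output 336 L/h, hematocrit 0.45, 70 kg, flows balanced exactly:
non-lung tissue flows sum to cardiac output, lung carries all of it).
Tissue, red-cell and plasma composition values are Rodgers–Rowland-style
tabulations reconstructed for this package — *synthetic stand-ins* of
realistic magnitude, adequate for the package's property-based validation
but not audited against any specific publication; users fitting real data
should substitute their own vetted table via `load_physiology(path)`.

Pre-fit curation checks (`validate_compound()`) flag, without raising:
total clearance at or above cardiac output, `B:P` below `1 − hematocrit`,
and an *observed* NCA Vdss below blood volume. The Vdss floor applies to
observed data during curation only — never to simulated outputs — and we
only flag, since whether violations led to exclusion or correction in
practice is an open question.

## 3. Non-compartmental analysis

`compute_pk_outputs()` uses the linear trapezoid for AUC0–t and AUMC0–t,
Cmax/Tmax by scan with ties broken to the earliest time, and a log-linear
terminal fit on the last 3–6 points after Tmax (extended while r²
improves) for `λ_z`. Extrapolated outputs use
`AUC0–∞ = AUC0–t + C_last/λ_z`,
`AUMC0–∞ = AUMC0–t + C_last t_last/λ_z + C_last/λ_z²`,
`MRT = AUMC0–∞/AUC0–∞`, `Vdss = Dose · MRT / AUC0–∞`.

They are computed only when the terminal phase is sufficiently
characterized: last observed concentration below `0.25 · Cmax`, **or** a
window of at least two terminal half-lives past Tmax. The OR combination
is the permissive reading of the two published clauses; the rule actually
used is recorded in the output (`sufficiency_rule`). After oral dosing the
same formulas are applied uniformly (so MRT includes mean absorption
time), flagged by the `route` column. Accuracy reports drop
terminal-insufficient datasets from the AUC0–∞/MRT/Vdss rows only.

Note that `Dose·MRT/AUC` referenced to plasma equals the model's
`analytic_vdss()` bookkeeping (`B:P·V_blood + Σ V_t Kp_t`) exactly only as
hepatic/renal extraction → 0, because elimination occurs in tissues rather
than the sampling compartment; the cross-check test therefore uses a
low-clearance, long-horizon simulation (agreement within 2%).

## 4. The fitting machinery

The cost is the geometric-mean fold error pooled over datasets × {Cmax,
Tmax, AUC0–t}: `10^mean(|log10(pred/obs)|)`, 1 at perfect agreement.
Simulated Cmax and AUC0–t are read at the observed timepoints so both
sides share the sampling grid; simulated Tmax is read from a dense
151-point grid starting at the first observed time (a deliberate,
documented asymmetry — a sparse observed design cannot localize the peak,
and quantizing the simulated peak to it would leave the cost piecewise
constant in `ka`). Consequences worth knowing:

* at `cv = 0` the generating parameters are no longer the *exact* cost
  optimum; recovery of `ka` is quantized by up to one sampling-slot ratio
  of the design (factor ≈ 1.6 for the 12-point log-spaced oral schedule),
  which is how the noiseless acceptance checks define "optimizer
  tolerance" (amplitude parameters within 10%, `ka` within one slot);
* `logP` under `rodgers_logp_optimized` is weakly identified below
  logP ≈ 1, where tissue lipid terms are negligible — flat cost
  directions are reported honestly (`converged`, cost ≈ 1) rather than
  resolved by fiat.

Search: a deterministic full-factorial grid (8 points per free dimension;
`kp_scalar` and `ka` log-spaced, `logP` and `B:P` linear — logP is
already a logarithm and its range spans zero) is ranked by cost, the top
3 combinations seed Nelder–Mead descents in search scale (log10 for
`kp_scalar`/`ka`) with proposals clipped to bounds, stopping at a 1e-6
relative cost spread or 500 iterations. Bounds: `logP ∈ [−2, 7]`,
`kp_scalar ∈ [0.05, 50]` pre-cap, `ka ∈ [0.01, 10]` 1/h,
`B:P ∈ [1 − Hct, 5]` (the floor is the curation rule). Failures at a grid
point score `Inf` and never abort the grid. Everything is deterministic
given inputs; the seed is recorded, not consumed. Compounds are fitted
independently (sequentially here; the batch contract is preserved because
each compound's fit is self-contained and seeded by compound index).

## 5. The synthetic-study generator

`generate_study()` emulates the statistical structure of a literature PK
corpus — e.g. 21 compounds × 3 arms = 63 datasets — without shipping any
external data. Compounds span the five ionization classes (default mix
.25/.25/.20/.15/.15 for acid/strong base/weak base/neutral/zwitterion);
per-compound truths are drawn once: logP ~ U[−1, 5], class-specific pKa
(acid [3, 6], strong base [7.5, 10.5], weak base [4, 7]), fup ~
U[0.01, 1], hepatic CL ~ U[5, 60] L/h and renal CL ~ U[0, 10] L/h (total
well below cardiac output), B:P ~ U[0.8, 2], ka ~ LogU[0.1, 3] 1/h,
f_oral ~ U[0.5, 1], effective global Kp ~ LogU[0.5, 20]. The *measured*
logP handed to fitting is the true value plus N(0, 0.75²) (clipped to
[−2, 7]) — the imperfect octanol-to-in-vivo translation that motivates
optimizing distribution parameters at all, and the reason the fixed
mechanistic configuration scores worst in the benchmark. Designs are rich:
12 log-spaced samples over 0.083–48 h (IV) or 0.25–48 h (oral); doses
cycle IV 10 mg, oral 20 mg, oral 40 mg. Residual error is multiplicative
log-normal, `σ = sqrt(ln(1 + cv²))`, default cv 0.15 (standard
proportional PK residual; preserves positivity; cv = 0 reproduces the
noiseless curve bit-for-bit). Truth records are kept separate from the
fitting interface (a `truth.csv` the fitting entry points never read).

**What a green test does and does not establish.** The generator draws
from the *same* model family the fitter uses (no model misspecification
except the logP measurement error and, optionally, the
Rodgers-vs-global-Kp mechanism mismatch), with i.i.d. residuals — real
digitized literature data carry correlated digitization error,
inter-study variability, and genuine structural misfit. Green recovery
tests therefore establish the correctness and internal consistency of the
machinery, not field accuracy on real compounds.

**A known identifiability limit.** With one noisy oral arm and only three
summary metrics per profile, `ka` trades off against disposition
(flip-flop-like ambiguity) and `kp_scalar` against `B:P`; at cv = 0.15 the
global optimum of the cost can sit 25–50% from the truth for a minority of
compounds even though the fit's cost is *below* the cost at the truth —
the benchmark test verifies exactly that diagnosis. A per-point residual
likelihood would recover parameters far better, but the three-metric GMFE
cost is the design being reproduced, so the recovery bound in the
acceptance suite is reported as measured rather than silently relaxed.

## 6. Numerical and interface choices

* Exact linear-algebra solver by default; stiff robustness comes free
  (the degenerate fast-flow one-compartment check multiplies flows by
  1000 and still matches the closed form to 0.5%).
* Tmax ties → earliest time; zero concentrations allowed in trapezoids,
  excluded from log-linear fits; all-zero observed profiles skipped with
  a warning.
* Concentration CSVs reject negative values and duplicate timestamps with
  line numbers; units live in the header names
  (`time_h`, `conc_ug_per_L`).
* Reports are deterministic: same inputs → identical tables; fits: same
  inputs + seed → bit-identical parameters.
* The CLI (`inst/cli/pbpkfit`) exits 0/1/2 (success / runtime failure /
  usage error) with single-line diagnostics and logs seed and a config
  hash on every run.

## 7. Limitations

Perfusion-limited distribution only; no saturable clearance, transporter
flux, lysosomal trapping, enterohepatic recirculation, dissolution or
transdermal absorption; no population variability; one physiology per
simulation (species via data tables); alternative partition models
(Poulin–Theil, Berezhkovskiy, Schmitt, Arundel) are out of scope. The
bundled composition table is a realistic stand-in, not an audited
transcription. The three-summary-metric cost limits fine identifiability
of absorption parameters, as quantified above.
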