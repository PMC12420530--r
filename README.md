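# cobraplan

Desk-scale dosimetric evaluation of **Cobalt-60 high-dose-rate (HDR)
intracavitary brachytherapy** for cervical cancer, in R. The package is
aimed at medical physicists and methodologists who want a reproducible,
scriptable stand-in for the evaluation chain of a clinical treatment
planning system: a TG-43 dose engine over tandem-and-ovoids applicator
geometry, DVH metric extraction, plan-quality indices, EQD2 constraint
accounting, and a rigid-body uncertainty framework — exercised on
synthetic pelvic phantom cohorts in place of patient CT data.

## The models at its core

**Dose.** Dose rate around each dwell follows the AAPM TG-43 formalism

> Ḋ(r, θ) = S_K · Λ · G(r, θ)/G(r₀, θ₀) · g(r) · F(r, θ)

with the line-source geometry factor, generic Co-60 tables shipped as
CSV configuration (Λ = 1.087 cGy·h⁻¹·U⁻¹, L = 3.5 mm), and plan dose as
the dwell-time-weighted superposition. Plans use Manchester-style fixed
loading normalized so the mean dose at the two **Point A** positions
(20 mm superior + 20 mm lateral from the cervical os) equals the
prescription — 7 Gy × 4 fractions in the default protocol, after
45 Gy / 25 fx external beam.

**Metrics.** Cumulative/differential DVHs; D90/D80 (minimum dose to the
hottest 90/80% of the HR-CTV); D2cc per organ at risk; V100/V150/V200;
CI = V100_CTV/CTV; COIN = CI × selectivity; DHI = (V100 − V150)/V100;
DNR = V150/V100 (so DHI + DNR = 1 identically); ODI = V200/CTV.
EQD2 = D·(d + α/β)/(2 + α/β) accumulates the external-beam course plus
each brachytherapy fraction (α/β = 3 Gy for organs at risk) against the
clinical aims bladder < 80 Gy, rectum < 75 Gy.

**Uncertainty.** ±1 mm cardinal applicator translations, ±2° per-axis
rotations about the os, and ±2% multiplicative TPS variability; the
perturbed plan is *not* renormalized (the delivered plan is fixed, the
error moves it). Cohort tables report mean / SD / SE / 95% CI with
per-fraction observation counting.

## Worked example

```r
library(cobraplan)

src <- co60_source()                                  # generic Co-60 source
ph  <- make_phantom(phantom_spec(), voxel_size = c(1, 1, 1))
ev  <- evaluate_phantom(ph, src)                      # plan -> dose -> metrics
print(ev$metrics)
print(eqd2_audit(ev$metrics$d2cc))
```

```
HR-CTV D90 7.00 Gy (99.9% Rx), D80 7.83 Gy
  bladder  D2cc 5.73 Gy (81.9% Rx)
  rectum   D2cc 4.73 Gy (67.5% Rx)
  sigmoid  D2cc 3.26 Gy (46.6% Rx)
  bowel    D2cc 2.95 Gy (42.1% Rx)
  V100(CTV) 89.9% | CI 0.90 COIN 0.644 DHI 0.480 DNR 0.520 ODI 0.389
    organ d2cc_fx_gy  eqd2_gy limit_gy within_limit
1 bladder   5.731952 83.24091       80        FALSE
2  rectum   4.727056 72.42098       75         TRUE
3 sigmoid   3.260732 59.53166       75         TRUE
4   bowel   2.946698 57.21850       75         TRUE
```

Reading it: the plan delivers the prescription to the target (D90 at
~100% of 7 Gy, 90% of the HR-CTV inside the prescription isodose) with
the expected organ-dose ordering bladder > rectum > sigmoid > bowel.
The EQD2 audit accumulates 45 Gy/25 fx external beam plus four
brachytherapy fractions at each organ's D2cc: at 5.73 Gy per fraction
the bladder accumulates 83.2 Gy EQD2 and is flagged against the 80 Gy
aim (at 5.40 Gy per fraction it would accumulate 79.49 Gy and pass) —
the audit is strict around exactly that clinical boundary.

Cohort-level analysis, uncertainty report and CSV/JSON bundle:

```r
res <- run_pipeline(run_config(n = 30, master_seed = 17), out_dir = "results/")
summary(res)
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/cobraplan.R all --out results/ --seed 17 --n 30
```

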