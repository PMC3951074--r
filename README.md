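# protonCEA

Cost-utility analysis of proton beam therapy versus conventional X-ray
radiotherapy for childhood medulloblastoma, built around the late effect
that dominates survivors' quality of life: severe (Grade 3–4) hearing loss
from radiation to the cochlea on top of cisplatin chemotherapy.

Proton craniospinal irradiation delivers the same target dose as X-rays
with a far lower cochlear dose — and a far higher price (about $26,944 vs
$3,082 per course). `protonCEA` is for health-economics and radiation-
oncology researchers who want to reproduce, stress-test or extend the
payer-perspective answer to "is that worth it?".

## The model

A deterministic three-state Markov cohort model (alive without hearing
loss, alive with hearing loss, dead) in annual cycles from treatment at
age 6 to age 100. The cohort splits 70/30 into average-/high-risk groups
with 5-year overall survival 85%/70%; deaths in years 1–5 follow a
constant hazard *q* with (1 − *q*)⁵ = OS₅, afterwards a life table
supplies background mortality (a bundled synthetic Gompertz–Makeham table
calibrated to life expectancy ≈ 82 y). Hearing loss emerges one year
after treatment and plateaus at the lifetime risk from year three
(X-ray 39.00%/47.11%, proton 15.55%/26.53% by risk group).

Discounted (3%/y) lifetime costs and QALYs per arm give the incremental
cost-effectiveness ratio

ICER = (C_PT − C_XRT) / (Q_PT − Q_XRT),

evaluated under three utility indexes for the aided hearing-loss state
(EQ-5D 0.807, HUI3 0.644, SF-6D 0.792) and judged against a
willingness-to-pay threshold λ = $46,729/QALY through the net monetary
benefit λ·ΔQALY − ΔCost. Uncertainty is handled by one-way (tornado)
analysis over the studied ranges and by Monte Carlo PSA with independent
triangular distributions, summarised as cost-effectiveness acceptability
curves (CEAC): P(NMB > 0) as a function of λ.

## Worked example

```r
library(protonCEA)

fit <- cea()          # default parameters + bundled life table
summary(fit)
```

```
 index arm     cost   qaly delta_cost delta_qaly  icer
 EQ-5D  PT 28912.24 23.122    21442.9      1.009 21252
 EQ-5D XRT  7469.34 22.113    21442.9      1.009 21252
  HUI3  PT 28912.24 22.430    21442.9      1.861 11521
  HUI3 XRT  7469.34 20.569    21442.9      1.861 11521
 SF-6D  PT 28912.24 23.059    21442.9      1.087 19719
 SF-6D XRT  7469.34 21.971    21442.9      1.087 19719

Net monetary benefit at WTP $46,729/QALY:
  EQ-5D  $25707 (cost-effective)
  HUI3   $65527 (cost-effective)
  SF-6D  $29371 (cost-effective)
Undiscounted expected life years after treatment: 60.5
```

Reading this: proton therapy costs an extra ~$21,443 per patient and buys
1.01 extra discounted QALYs under EQ-5D (1.86 under HUI3, whose hearing
attribute makes it most sensitive to the outcome), for ICERs of
$11,500–21,300/QALY — all well below the $46,729/QALY threshold, so the
net monetary benefit is positive under every index.

Which inputs matter most, and how sure is the verdict:

```r
tor <- one_way(default_params(), synthetic_lifetable(), "EQ-5D")
head(as.data.frame(tor), 4)
#>        parameter icer_at_low icer_at_high   spread
#> 1  discount_rate      6881.6      47726.9 40845.30
#> 2 hl_risk_pt_avg     15204.3      33615.8 18411.55
#> 3    c_pt_course     14575.7      27927.6 13351.84
#> 4      u_hl_eq5d     18988.7      24126.9  5138.13

psa <- run_psa(default_params(), synthetic_lifetable(), n = 10000, seed = 1)
cv  <- ceac(psa)
ceac_at(cv, "integrated")   # P(cost-effective) at $46,729/QALY: 0.9801
plot(cv)
```

The discount rate dominates (the QALY gains arrive decades after the cost
is paid), followed by the proton-arm hearing-loss risk and the proton
course price; the ICER stays below the threshold across every single
parameter range except the extreme of the discount span.

Configuration files (YAML, keys mirroring `default_params()`), custom life
tables (`age,qx` CSV), file-writing orchestration (`run_base_case()`,
`run_sensitivity()`) and a CLI wrapper (`inst/cli/cea.R`) are documented
in the function reference; the methods vignette
(`vignettes/cost-utility-model.Rmd`) explains every modelling convention.

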