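# vakinetics

Model-based compartmental analysis of whole-body vitamin A kinetics from
plasma tracer data.

After an oral dose of isotope-labelled vitamin A, the fraction of the dose
in plasma retinol (FDp) over time carries information about absorption,
plasma/tissue exchange, and the turnover of the large hepatic storage pool.
This package is for researchers in nutrition and tracer kinetics who fit
such curves to estimate vitamin A **total body stores** (TBS, µmol),
**disposal rate** (DR, µmol/d), **days of stores** (TBS/DR) and implied
**liver vitamin A concentration** — and in particular for studies whose
duration is too short to define the terminal slope of the tracer curve, where
a dietary-intake observation can be added to the regression to stabilise the
estimates.

## The model

A linear compartmental system with a pure absorption delay. Compartment 1
receives the dose and the dietary input U(1); material moves 1 → 2 →
(delay, DT(3) days) → 4 → plasma compartment 5, which exchanges with one
(`1EV`) or two (`2EV`) extravascular pools; pool 6 is the storage pool and
the site of irreversible loss. Transfers are fractional coefficients L(I,J)
per day (I = 10 denotes loss to the outside). At steady state, with the
measured plasma pool M(5):

    M(6) = M(5) · L(6,5) / (L(5,6) + L(10,6))      M(7) = M(5) · L(7,5) / L(5,7)
    DR   = M(6) · L(10,6)                          U(1) = DR / 0.75
    TBS  = M(6) + M(7)                             days of stores = TBS / DR

Fitting is weighted nonlinear least squares on FDp with fractional SD 0.05
(and, for the diet-constrained `2EV_DI` treatment, an intake observation —
2.8 µmol/d, the adult RDA — with fractional SD 0.1). Nested models are
compared with an F statistic on the weighted sums of squares.

## Worked example

Simulate a US-like study group (7 subjects, 19 samples from 3 h to 52 d, 5%
multiplicative noise), then analyse the composite geometric-mean curve under
three treatments:

```r
library(vakinetics)

group <- generate_group(generator_config(n_subjects = 7, seed = 42))
cfg   <- run_config(treatments = c("1EV", "2EV", "2EV_DI"))
ga    <- run_group(group, cfg, label = "US-like synthetic", per_subject = FALSE)
print(ga)
#> Group analysis: US-like synthetic ( 7 subjects )
#>   composite M(5): 5.053 umol; geometric-mean liver weight: 1346 g
#>   1EV     U1= 12.514  TBS=   383.6  DR= 9.385  days=   40.9  liverVA=0.256
#>   2EV     U1=  0.794  TBS=  2637.4  DR= 0.596  days= 4428.4  liverVA=1.76
#>   2EV_DI  U1=  2.800  TBS=  1912.3  DR= 2.100  days=  910.6  liverVA=1.28
#>   F-test 1EV_vs_2EV: F=35.398 (df 2,10), p=2.904e-05
#>   F-test 1EV_vs_2EV_DI: F=1633.285 (df 2,11), p=2.467e-14

exp(mean(log(sapply(group, function(s) s$truth$steady$TBS))))   # ground truth
#> [1] 2354.128
```

The one-pool fit misreads the short study: its disposal rate (9.4 µmol/d)
implies an implausible intake of 12.5 µmol/d, and stores come out four-fold
too low against the generator's ground truth (2354 µmol). The unconstrained
two-pool fit is statistically better but unstable in the opposite
direction. Adding the intake observation (`2EV_DI`) pins U(1) at the RDA and
recovers stores (1912 µmol) and DR (2.1 µmol/d) close to truth. The printed
liver concentration uses 90% of TBS over the group's geometric-mean liver
weight.

Steady-state and tracer-theory summaries for any parameter set:

```r
p  <- template_params("US_LIKE")
sp <- model_spec("TWO_EV")
solve_steady_state(p, sp, M5 = 5)     # masses, TBS, DR, days of stores
derived_kinetics(p, sp)               # transit/residence/recycling times
```

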