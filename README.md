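# plk4osc

Receptor-kinetics models and analysis of the Plk4 oscillation that times
centriole biogenesis.

## The problem

Centrioles duplicate once per cell cycle: in S-phase a daughter grows from
the side of each mother. In syncytial fly embryos the master regulator of
this process, Polo-like kinase 4 (Plk4), does not sit at a constant level on
the mother centriole — it *pulses*, once per nuclear cycle, and the
amplitude, timing and area of the pulse predict when daughter centrioles
start growing, how fast, and when they stop. The oscillation is normally
entrained to the cell-cycle oscillator, but it can free-run: in embryos
arrested with dsRNA against the mitotic cyclins, individual centrioles keep
producing small stochastic Plk4 pulses, and those pulses predict individual
duplication events.

`plk4osc` is an R package for everyone who wants to work with this system
quantitatively: it implements the oscillator models, the pulse/kinetic
fitting, the peak-calling and event-matching statistics, the spatial
homogeneity tests, and the two concentration-measurement methods (FCS and
peak counting spectroscopy), together with seeded synthetic-data generators
that emulate every input — so the complete pipeline runs and is tested
without any imaging data.

## The model at its core

Plk4 binds unphosphorylated Asl receptors on the mother centriole at
effective rate k1 = k[P]; bound Plk4 phosphorylates the receptor N times at
rate k2 (states A0\* → A1\* → … → AN\*); from the fully phosphorylated,
low-affinity state it is released at rate k3. This time-delayed negative
feedback — Plk4 destroys its own docking sites — produces one asymmetric
S-phase pulse of total bound Plk4, `scale · Σᵢ [Aᵢ*](t)`:

    d[A0*]/dt = k1[A0] − k2[A0*]
    d[Ai*]/dt = k2[Ai−1*] − k2[Ai*]      (i = 1..N−1)
    d[AN*]/dt = k2[AN−1*] − k3[AN*]
    d[A0]/dt  = −k1[A0]

A mitotic phosphatase (rate k4, active in the last 30% of each cycle) resets
receptors and sustains the oscillation over all 14 embryonic cycles
(`model2_simulate()`, with a conserved-total-Plk4 variant in which the
centriole count doubles each cycle and late-cycle amplitudes decline). A
stochastic per-receptor Markov-chain version (`model3_simulate()`)
reproduces the noisy, desynchronised oscillations of non-cycling embryos.

## Worked example

Generate a synthetic embryo cycle, aggregate the tracks into the mean ± SD
pulse, and fit the candidate pulse shapes:

```r
library(plk4osc)

gen <- gen_cycling_embryo(cycling_embryo_spec(n_cycles = 1, seed = 42))
seg <- segment_and_aggregate(gen$dataset, 11)   # rebased so CS = 0
fit_pulse(seg)
#> <pulse_fit> model=Lorentzian R2=0.9993 A=1.002 center=226.6 s Omega=240.3
gen$truth$cycles[, c("amplitude", "center_rel")]
#>   amplitude center_rel
#> 1         1      226.8
```

The Lorentzian is selected over the Gaussian and the generating amplitude
(1 a.u.) and centre (226.8 s after centrosome separation) are recovered;
`Omega` is the area under the baseline-subtracted pulse from CS to NEB, the
proxy for total Plk4 recruited that cycle.

Fit the kinetic model to a pulse produced by the model itself (1% noise) and
explore the parameter space:

```r
set.seed(3)
tt <- seq(0, 500, 30)
truth <- model1_params()   # k1 = 0.005, k2 = 0.04, k3 = 0.06906, N = 9
y <- model1_analytic(truth, tt)$bound
seg <- pulse_segment(tt, y + rnorm(length(y), 0, 0.01 * max(y)), neb_rel = 500)

fit_model1(seg)
#> <model1_fit> R2=0.99931 k1=0.005029 k2=0.04039 k3=0.06906 A0=1.009

mc <- mcmc_explore(seg, steps = 500, seed = 1)
round(mc$spread, 3)
#>      k1      k2      k3 A0_init
#>   0.041   0.030   0.190   0.036
```

The generating rates are recovered to well under 1%, and the retained MCMC
cloud is an order of magnitude wider along k3 than along the other
parameters — the fit constrains binding, phosphorylation and the receptor
pool tightly but is largely insensitive to the release rate.

Peak-to-event statistics use the same formulas as the embryo analysis; with
49 called peaks, 52 duplication events and 40 unique matches inside a ±5 min
window they give precision 40/49 ≈ 81.6%, recall 40/52 ≈ 76.9%, and a
no-correlation baseline average precision of 52/101 ≈ 51.5%
(`score_matches()`).

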