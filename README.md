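# ivtwin

A kinetic digital twin for mRNA **in vitro transcription (IVT)** and its
continuous, segmented-flow operation — for process engineers and modellers
who calibrate T7 RNA polymerase kinetics from initial-rate experiments,
predict batch progress curves with uncertainty bands, schedule
high-throughput candidate screening in a plug flow reactor, and optimize
reaction conditions with a response-surface design.

## The model

mRNA production follows an extended Michaelis–Menten rate law in the four
NTP concentrations, the template/promoter and pyrophosphate:

$$
v = v_{max}\;
\frac{c_D}{c_D + K_{M,D}\!\left[1 + \tfrac{K_{d,GTP}}{c_{GTP}}\right]}\;
\prod_{i \in \{A,C,G,U\}}
\frac{c_i}{c_i + K_{M,i}\left(1 + \sum_{j \neq i}\tfrac{c_j}{K_{I,j}}
 + \tfrac{c_{PPi}}{K_{I,PPi}}\right)}
$$

coupled to the runoff-transcription mass balances
$dc_{mRNA}/dt = v$, $dc_{NTP,i}/dt = -f_i\,n_{mRNA}\,v$,
$dc_{PPi}/dt = n_{mRNA}\,v - v_{PPiase}$ (pyrophosphatase itself is simple
Michaelis–Menten) with transcript length $n_{mRNA}$ and base fractions
$f_i$. With three NTPs in excess and PPi removed the law reduces to
$v = v_{max}\,c/(K_{M,app}+c)$, the basis of the four bundled estimators
(Lineweaver–Burk, Hanes–Woolf, Eadie–Hofstee, nonlinear least squares).
Calibration precision is propagated into prediction envelopes by Monte Carlo
(30 draws by default, nominal trajectory always included). Segmented-flow
throughput is $\lfloor (T-\tau)/\Delta t \rfloor$ slugs per horizon $T$ at
residence time $\tau$ and injection interval $\Delta t$, versus
$\lfloor T/\tau \rfloor$ sequential batches. Screening uses a 15-run
Box–Behnken design (3 center points), backward stepwise reduction at
α = 0.05 and Derringer–Suich desirability optimization.

The methods vignette (`vignettes/ivt-digital-twin.Rmd`) documents the
assumptions, parameter defaults, numerical choices and limitations.

## A worked example

Simulate the reference batch (10 mM of each NTP, 4284-nt construct,
calibrated constants $v_{max}$ = 0.358 µM/min, $K_{M}$ = 140.4/71.5/165.5/
101.5 µM for A/C/G/U):

```r
library(ivtwin)
ref <- ivt_reference_params()
ts  <- fixture_transcript("bnt-like")
pp  <- ppiase_params(quiet = TRUE)

traj <- simulate_batch(c(A = 10000, C = 10000, G = 10000, U = 10000),
                       ref$params, pp, ts, t_grid = seq(0, 600, by = 60))
tail(traj, 1)
#>   t_min c_ATP_uM c_CTP_uM c_GTP_uM c_UTP_uM c_PPi_uM c_mRNA_uM
#>     600     1034    344.8        0     4138        0     8.049
molar_to_mass(max(traj$c_mRNA_uM), ts)
#> [1] 11.15
```

GTP is the limiting substrate for this GC-rich construct: the batch plateaus
at 8.05 µM mRNA (11.15 g/L) when GTP is exhausted, with pyrophosphate held
near zero by the pyrophosphatase. Estimation from a noisy synthetic
initial-rate experiment (2% cv, 3 replicates at 2.5/5/7.5/10 mM):

```r
d   <- gen_initial_rate_dataset("ref-ATP", replicates = 3,
                                noise = noise_spec(cv = 0.02), seed = 1)
fit_nonlinear(d)
#> <mm_fit:nonlinear> km = 185.6 +/- 45 uM, vmax = 0.3632 +/- 0.0036 uM/min, adj R2 = 0.6201
```

$v_{max}$ comes back to 1.5%; the wide $K_M$ standard error is real — at
substrate levels 18–70× $K_M$ the curvature that identifies $K_M$ is barely
sampled (see the vignette's identifiability note). And the scheduling
arithmetic of continuous operation:

```r
cfg <- reactor_config(tau = 135, dt = 6.6, horizon = 270)
n_produced(build_schedule(cfg))   #> 20
productivity_factor(cfg)          #> 10
```

Twenty candidate slugs complete within the 270-minute window that fits two
sequential batches: a tenfold productivity gain.

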