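---
title: "The concealed voter model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The concealed voter model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvoter)
```

## The model

The basic voter model (BVM) is the classic null model of opinion spreading:
`N` individuals each hold one of two opinions (red or blue), and at rate `c`
per individual a randomly chosen *focal* individual copies the opinion of a
uniformly random neighbour. On a complete graph the red count performs
neutral drift until one opinion takes over.

The concealed voter model (CVM) gives each individual a second, *private*
opinion that nobody else can see. The public layer evolves by copying as in
the BVM; inside each individual two further Poisson processes couple the
layers:

* **externalization**, rate `e`: the private opinion overwrites the public
  one (`Rb -> Bb`, `Br -> Rr`);
* **internalization**, rate `i`: the public opinion overwrites the private
  one (`Rb -> Rr`, `Br -> Bb`).

An individual whose layers disagree (state `Rb` or `Br`) is a *hypocrite*;
one whose layers agree (`Rr`, `Bb`) is *frank*. Consensus is the absorbing
state in which one opinion occupies both layers of everyone; the consensus
time is the first-passage time to it. The complete graph includes a
reflexive self-link: copying one's own public opinion is a null event. The
variant without self-links is the same model with a rescaled copy rate
`c' = c N / (N - 1)`, so no separate code path is provided.

Because the group is well mixed, the full state is the integer count vector
`(n_Rb, n_Br, n_Rr)` (with `n_Bb` implied), and the process is a
continuous-time Markov chain on `choose(N + 3, 3)` states whose channel
rates are listed in `?transition_rates`. Red is the tracked opinion
throughout; all blue quantities are derived.

## Closed-form theory

Write `rho_R` for the public and `rho_r` for the private abundance of red.
The *strength*

\[ m = \frac{i\,\rho_R + e\,\rho_r}{e + i} \]

is a martingale of the dynamics, so its initial value equals the
probability of a red consensus. It involves neither `c` nor `N`, and the
hypocrite abundances enter only through `rho_R` and `rho_r`.

The mean consensus time of the BVM from red fraction `rho` is the entropy
form `-(N/c) [rho ln rho + (1 - rho) ln(1 - rho)]`; the CVM mean consensus
time in the large-`N` regime is the same expression evaluated at `rho = m`
and multiplied by the slowdown factor

\[ \tau(c, e, i) = \frac{(c + e + i)(e + i)^2}{i\,[(e + i)^2 + c\,i]}, \]

which exceeds 1 whenever `e > 0`: concealed opinions always delay
consensus. As `i -> infinity` the private layer shadows the public one and
`tau -> 1`; as `i -> 0` the private layer freezes and the consensus time
diverges, which is why every time formula (and the exact solver) refuses
`i = 0`. The strength `m` itself stays well defined at `i = 0`.

Consensus formation proceeds in two stages. In the fast first stage the
mean gap between the two hypocrite types, `D = rho_Rb - rho_Br`
(identically equal to `rho_R - rho_r`), decays exponentially at rate
`e + i`; its e-folding time is the *equalization time*
`T_equal = 1 / (e + i)`, independent of `N`, `c` and the initial state. The
deterministic large-`N` flow (see `?mean_field_drift`) meanwhile carries
the composition onto an arch-shaped attractor along which
`rho_Rb = rho_Br`, parameterized by the frank-red fraction
(`?attractor_hypocrite_fraction`). The slow second stage is a random walk
along that curve that ends at one of the two consensus corners.

## Parameters and defaults

The benchmark conditions used throughout the package are `N = 400`,
`c = 1`, `e = 1/4`, `i = 1/16` (preset `"main"`), with four reference
initial conditions `(rho_Rb, rho_Br, rho_Rr)`:
`(0, 1, 0)`, `(0.25, 0.75, 0)`, `(0.5, 0.25, 0.25)`, `(0.75, 0, 0)`.
Under these conditions `tau` is about 12.8 and `T_equal = 3.2`, so
consensus takes roughly three orders of magnitude longer than
equalization. The swapped-rate preset `"s2"` (`e = 1/16`, `i = 1/4`) probes
the opposite regime: same `e + i` (hence the same `T_equal`) but
`tau` about 1.47. Rates are in events per individual per unit time; all
times are in the same units.

`reproduce_table2()` defaults to 1000 replicates per initial condition,
the replicate count under which the benchmark observed values (and their
95% confidence half-widths) were defined. Ensemble gap series default to a
grid spacing of 0.25 time units covering four e-folding times.

## Simulation engines

The production engine is a count-based Gillespie sampler (in C++): each
step draws one of at most six state-changing channels proportionally to
its rate and advances time by an exponential variate with the total-rate
mean, so one event costs O(1) regardless of `N`. Null events — copying
one's own colour, or externalizing/internalizing a frank individual — are
excluded from the channel list; they spend no probability and the waiting
times to state changes are distributionally unchanged. The literal
per-agent algorithm (focal choice, `u ~ U(0, c+e+i)` case split, null
events included) is retained as `run_cvm_agent()` purely as a reference:
the test suite checks that the two produce Kolmogorov–Smirnov-
indistinguishable consensus-time distributions. Per-event traces of the
two engines are *not* comparable (the reference logs null events), only
their state paths and timing laws are.

Reproducibility: an ensemble draws one per-replicate integer seed stream
up front from the master seed (`sample.int` under `set.seed(master)`), so
replicate `k` is reproducible in isolation and results do not depend on
execution order. Trajectories store the full event log only for
`N <= 200` by default (`record_events`); above that, or when a `grid` is
given, they store grid samples — the piecewise-constant state at the
requested times — which is what the equalization analysis needs and keeps
memory flat at benchmark scale.

When `i = 0` and the private layer is mixed, consensus is unreachable:
`run_cvm()` then demands a finite `t_max`, and the exact solver refuses
outright (the transient system is singular). We do not implement the
reduced solve on the uniform-private-layer communicating class: that
degenerate case is a single-layer chain already covered by `run_bvm()` and
the BVM formulas.

## Exact small-group oracle

For verification the package solves the absorbing chain exactly:
`build_generator()` assembles the sparse rate matrix over all states,
and `exact_solution()` solves the two standard linear systems on the
transient block (absorption probabilities with red-consensus boundary 1,
mean absorption times with unit source). Sizes grow as `N^3/6`
(1771 states at `N = 20`), so a sparse direct solve is comfortable for the
verification sizes used (`N <= 40` in tests).

Two facts make this a sharp oracle. First, the martingale property is
exact at every finite `N`: the solved absorption probability equals
`strength_m()` state by state to solver precision (the suite asserts
`<= 1e-10` across rate sets). Second, the closed-form consensus time is a
large-`N` result: the exact mean time *exceeds* it at small `N`. Under the
main preset, the ratio of exact to closed-form time from the all-`Br`
state is 1.063, 1.079, 1.073, 1.066, 1.060, 1.055 at
`N = 10, 20, 30, 40, 50, 60` — a finite-size margin of a few percent that
shrinks steadily beyond `N = 20` but is *not* monotone below it. The tests
assert the measured behaviour (margin under 10%, decreasing from `N = 20`
on) rather than a stricter idealization.

## Estimating the equalization time

The observed `T_equal` is recovered from an ensemble as follows: record
the per-replicate gap `D(t)` on a grid, average to `D-bar(t)`, and fit
`log |D-bar(t)|` against `t` by ordinary least squares; minus the inverse
slope is the estimate. Late grid points are dominated by the noise floor
(the ensemble mean of an increasingly sign-mixed quantity), so the fit
window keeps only points with
`|D-bar(t)| > max(3 SE(D-bar(t)), |D0| e^{-3})` — at least three e-folds
above zero and clear of its own standard error. Confidence intervals come
from a replicate-level bootstrap (resample replicate rows, refit; 1000
resamples by default). On a noiseless exponential input the estimator is
exact to numerical precision; the choice of an unweighted fit and of the
two-part floor is deliberately simple and is validated by recovering
`1/(e + i)` within CI for both presets in the test suite.

Confidence intervals elsewhere are standard choices: normal-approximation
binomial for the red-win fraction `F`, t-distribution for mean consensus
times. These reproduce the order of magnitude of the benchmark
half-widths.

## What the generator emulates — and what it does not

Synthetic ensembles generated by `run_ensemble()` are realizations of the
model itself, at the benchmark parameters. Passing tests therefore
establish internal consistency: the stochastic engines, the exact solver
and the closed forms agree with one another at the stated tolerances. They
cannot establish that real opinion dynamics satisfy the model's
assumptions — binary opinions, pairwise public interaction, homogeneous
rates, neutral competition, complete mixing — and no empirical claim about
social systems should be read into a green suite.

## Numerical choices

* `0 ln 0 = 0` in the entropy term (removable singularity), so consensus
  times are exactly 0 at `m` 0 or 1.
* Fractions are realized as counts by largest-remainder rounding with the
  deterministic tie-break order `Rb, Br, Rr, Bb`; exact whenever
  `rho * N` is integral, as in all benchmark initial conditions.
* All formulas are evaluated in double precision; the attractor endpoint
  values are exact in floating point because the discriminants are perfect
  squares there.
* Problem sizes in the test suite are chosen to make each statistical
  check sharp but cheap: win-fraction checks run at `N = 50` (valid
  because `F` depends only on `m`, not `N`), consensus-time checks at
  `N = 400` with 100 replicates and correspondingly wider intervals,
  oracle comparisons at `N <= 10` with 5000 replicates, and equalization
  at `N = 400` with runs truncated at `t = 10` (the gap analysis needs no
  absorption).

## Known limitations

* Complete graphs only; no other topology, no heterogeneous or biased
  rates, and exactly two opinions.
* The closed-form consensus time inherits its large-`N` character: expect
  a few-percent overshoot of simulated means at `N` in the tens (see the
  oracle section), shrinking at benchmark size.
* `estimate_tequal()` needs a nonzero initial gap; initial conditions with
  `rho_Rb = rho_Br` start on the attractor and have nothing to fit.
* The exact solver's dense state space limits it to small groups; it is a
  verification tool, not a production analysis path.
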