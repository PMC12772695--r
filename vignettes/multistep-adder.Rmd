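---
title: "Multi-step adder size homeostasis under a saturating growth law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-step adder size homeostasis under a saturating growth law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adderSHS)
```

## The model

`adderSHS` implements a stochastic hybrid system (SHS) for the size of a
cycling cell. Between discrete events, size $s$ grows deterministically
under a Hill-type saturating growth law,

$$\frac{ds}{dt} = f(s) = \frac{\mu s}{1 + \alpha s},$$

where $\mu > 0$ is the growth constant (1/time) and $\alpha \ge 0$ the
saturation coefficient (1/size). Small cells ($\alpha s \ll 1$) grow
exponentially at rate $\mu$; very large cells grow nearly linearly at the
plateau rate $\mu/\alpha$. This captures the finite biosynthetic capacity
of animal cells, for which unconstrained exponential growth is a poor
assumption; $\alpha = 0$ recovers the classical exponential regime exactly.

Cell-cycle progression is a chain of $M$ stochastic stages. A newborn cell
occupies stage 1 and advances $i \to i+1$ with the size-dependent hazard

$$h(s) = \frac{k s}{1 + \alpha s},$$

identical for every stage (transition rate constant $k > 0$). Division
fires from stage $M$: the tracked daughter keeps a fraction $\beta$ of the
mother's size ($s \to \beta s$) and the stage resets to 1. $\beta$ is
either deterministic (symmetric halving, $\beta = 1/2$) or drawn from a
beta distribution specified by its first two moments
$\langle\beta\rangle$, $\langle\beta^2\rangle$.

The crucial structural assumption is that the hazard is *proportional to
the growth law*, $h(s) = (k/\mu)\,f(s)$. Mechanistically this corresponds
to a division licensing factor synthesized in proportion to growth;
phenomenologically it makes the model an **adder**: the size added between
birth and division is independent of the size at birth, for every
$\alpha$. The regression slope of added size $\Delta_d$ on birth size
$s_b$ — the standard discriminator between adder (0), sizer ($-1$) and
timer ($+1$) strategies — is zero here, and `adder_slope()` verifies this
on simulated cycles.

## Exact simulation by time change

Because $h = (k/\mu) f$, the hazard accumulated while the cell grows from
$s_0$ to $s$ is

$$\int h\,dt = \frac{k}{\mu}\int ds = \frac{k}{\mu}(s - s_0),$$

so the *size increment* to the next stage transition is exponentially
distributed with rate $k/\mu$ — independent of the current size and of
$\alpha$. `simulate_lineage()` exploits this: it draws i.i.d.
Exponential($k/\mu$) increments, converts them to waiting times with the
closed-form flow $t = [\log(s_1/s_0) + \alpha(s_1 - s_0)]/\mu$
(`flow_time()`), and applies the partition reset every $M$-th event. The
added size per cycle is therefore exactly Erlang($M$, $k/\mu$), with mean
$M\mu/k$ (equal to 1 under the usual calibration $k = \mu M$). There is no
time discretization anywhere, so the simulator is exact in distribution.

The inverse flow (`flow_size()`) solves the monotone equation
$\log s + \alpha s = \log s_0 + \alpha s_0 + \mu t$ by Newton iteration
started from an upper bound (the smaller of the exponential envelope
$s_0 e^{\mu t}$ and the linear envelope $s_0 + \mu t/\alpha$). The
residual is concave in $s$, so iterates decrease monotonically to the
root; we stop at relative residual $10^{-13}$, and the round trip
`flow_time(s0, flow_size(s0, t))` reproduces `t` to better than
$10^{-9}$.

As a guard against errors in this reasoning, `oracle_simulate()`
implements the same SHS by Ogata-style thinning — candidate events from a
dominating constant rate ($k/\alpha$ when $\alpha > 0$; an adaptive
look-ahead bound when $\alpha = 0$, where $h(s) = ks$ is unbounded),
accepted with probability $h(s)/\text{bound}$. It shares no code path with
the time-change sampler beyond the deterministic flow, and the test suite
checks distributional equivalence of the two (two-sample
Kolmogorov–Smirnov on division sizes and cycle durations).

## Closed-form steady-state moments

Steady-state lineage moments follow from the extended generator: for any
$F$,

$$\frac{d\langle F\rangle}{dt} = \langle f(s) F'(s)\rangle +
  \sum_{\text{events}} \langle \text{rate} \times \Delta F\rangle ,$$

evaluated at stationarity. Fractions are cleared with the identity
$\langle s^n/(1+\alpha s)\rangle = (\langle s^{n-1}\rangle -
\langle s^{n-1}/(1+\alpha s)\rangle)/\alpha$. With stage indicators $g_i$
and $A_i = \langle g_i s/(1+\alpha s)\rangle$,
$B_i = \langle g_i s^2/(1+\alpha s)\rangle$,
$C_i = \langle g_i s^3/(1+\alpha s)\rangle$, the stationary system is
linear and solves in closed form:

* $\langle 1/(1+\alpha s)\rangle = kL/(kL - M\alpha\mu)$ with
  $L = \langle\log\beta\rangle$;
* all $A_i$ are equal, $A = \mu/(M\alpha\mu - kL)$;
* $B_i = (\mu/k)\,i\,A + \langle\beta\rangle B_M$ with
  $B_M = \mu M A / (k(1-\langle\beta\rangle))$;
* $C_i = (2\mu/k)\sum_{j\le i} B_j + \langle\beta^2\rangle C_M$ with
  $C_M = 2\mu \sum_j B_j / (k(1-\langle\beta^2\rangle))$;

and $\langle s\rangle = \sum_i (A_i + \alpha B_i)$,
$\langle s^2\rangle = \sum_i (B_i + \alpha C_i)$. These sums are evaluated
directly by `moments_multi_step()`; every quantity is polynomial in
$\alpha$, so the $\alpha \to 0$ limit needs no special branch and is exact
at machine precision. `moments_single_step()` is an independent
transcription of the $M = 1$ case; the test suite requires the two to
agree to machine precision at $M = 1$, and requires both to agree with
time-averaged simulation estimates over the grid
$\alpha \in \{0,1,5,10\} \times M \in \{1,2,5,10\}$ within three
batch-means standard errors. The simulator is defined unambiguously by the
growth law, hazard and reset map, so it arbitrates the algebra.

Two analytic landmarks used as fixed references: at $\alpha = 0$,
$\mu = k = \log 2$, $\beta = 1/2$ the mean size is $1/\log 2 \approx
1.4427$ and $CV^2_s = 2\log 2 - 1 \approx 0.3863$; and for $k = \mu M$,
$\beta = 1/2$ the saturation expectation is
$\langle 1/(1+\alpha s)\rangle = \log 2/(\log 2 + \alpha)$.

A note on $\beta$ moments: the exact generator calculation involves
$\langle\log\beta\rangle$. For deterministic $\beta$ this equals
$\log\langle\beta\rangle$, the form in which the result is usually
quoted; for the beta-distributed kind the package uses the exact
$\langle\log\beta\rangle = \psi(a) - \psi(a+b)$ of the moment-matched
shapes. No reference values exist for the random-$\beta$ case, so it is
exercised only through the reduction and simulation cross-checks.

## Lineage statistics and their standard errors

The SHS moment equations describe *time-weighted* lineage expectations, so
`time_averaged_moments()` computes $(1/T)\int s\,dt$, $(1/T)\int s^2 dt$
and $(1/T)\int dt/(1+\alpha s)$ exactly per deterministic flow segment,
using $dt = (1+\alpha s)/(\mu s)\,ds$:

$$\int s\,dt = \frac{(s_1-s_0) + \alpha(s_1^2-s_0^2)/2}{\mu},\qquad
  \int s^2 dt = \frac{(s_1^2-s_0^2)/2 + \alpha(s_1^3-s_0^3)/3}{\mu},$$

and $\int dt/(1+\alpha s) = \log(s_1/s_0)/\mu$ — no quadrature error.
(Published simulation protocols rarely state whether "statistics of 2000
cells" are time-weighted or per-cycle; this package computes the
time-weighted quantity, which is what the moment equations predict, and
documents that convention.)

Defaults chosen once and kept:

* **Burn-in**: 50 cycles discarded before computing steady-state
  statistics. Relaxation from any reasonable `s_init` is much faster (the
  birth-size recursion contracts by $\beta$ per generation); doubling the
  burn-in does not change results beyond noise.
* **Standard errors**: batch means over 100 contiguous blocks of cycles,
  which respects the serial correlation of cycles along a lineage
  (adjacent cycles share the birth size through the reset map).
* **Seeding**: every stochastic entry point takes one root seed and
  derives per-purpose substreams (stage increments, partition draws)
  deterministically, so runs are reproducible and noise sources
  independent.

## Colony simulations

A colony is the set of descendants of one progenitor born at $t = 0$;
both daughters are retained at division (sizes $\beta s$ and
$(1-\beta)s$, both restarting at stage 1, with no stage inheritance).
Stage transitions leave size unchanged, so a cell's division size and
time are fully determined at birth — the colony simulator draws each
cell's Erlang added size at birth and processes generations in vectorized
waves, with no event queue and no time stepping. Cell count $N(t)$ and
biomass $B(t)$ (total size of live cells) are evaluated exactly at
arbitrary sample times. With symmetric deterministic division, $B$ is
continuous across division events.

The generator emulates the published colony protocol:

* **Progenitors**: size drawn with mean 1 and $CV^2 = 1/(3M)$ — the
  steady-state newborn statistics of the exponential-growth model with
  $k = \mu M$ (fixed point of $s' = (s+\Gamma)/2$, giving variance
  $\mathrm{Var}(\Gamma)/3$). The distribution family is not specified by
  the newborn law's two moments alone; the package uses a **gamma**
  (positive support, two parameters). The same progenitor statistics are
  applied for all $\alpha$, as an approximation when $\alpha > 0$.
* **Growth-constant calibration**: population noise is compared across
  $\alpha$ at a matched ensemble-mean population size, by choosing $\mu$
  so that mean $N$ doubles once per unit time. For $\alpha = 0$ the
  Malthusian rate equals $\mu$ exactly, so $\mu = \log 2$; for
  $\alpha > 0$, `calibrate_growth_constant()` estimates the rate by
  regressing $\log \bar N(t)$ on $t$ over the late half of the run and
  bisects on $\mu$ (common random numbers across evaluations keep the
  estimated rate monotone in $\mu$; relative tolerance 1%). The published
  protocol does not state how this calibration was done; bisection on
  simulated rates is this package's documented choice.
* **Scale**: the reference protocol uses $10^4$ colonies; the default
  test scale is 1000–2000 colonies (and 200 per calibration step) to keep
  the suite within a desktop run-time budget. A population cap (default
  $10^6$ cells per colony) guards against runaway exponential growth;
  capped colonies are flagged as truncated.

What a green colony test establishes — and what it does not: across-colony
$CV^2_N(t)$ and $CV^2_B(t)$ start at 0 and $1/(3M)$ respectively, biomass
noise is flat in time when growth is exponential, steady-window population
noise increases with $\alpha$, and $|CV^2_N - CV^2_B|$ shrinks at late
times. These are ensemble properties of the model under the stated
progenitor distribution; they say nothing about real lineage-tracking
data, mother-daughter correlations beyond the adder regression, cell
death, or resource competition, none of which are modeled.

## Worked example

```{r example, eval = FALSE}
library(adderSHS)

p <- model_params(mu = log(2), alpha = 5, k = 10 * log(2), M = 10)
moments_multi_step(p)

traj <- simulate_lineage(p, n_divisions = 20050, seed = 1)
time_averaged_moments(traj, burn_in = 50)

fit <- adder_slope(traj$cycles[traj$cycles$generation > 50, ])
c(slope = fit$slope, se = fit$se)
```

The same computations are available from a shell via the `adder-shs`
script installed under `exec/` (subcommands `moments`,
`simulate-lineage`, `simulate-population`, `validate`).

## Known limitations

* Transition rates are identical across stages by construction; the
  parameter type deliberately reserves no per-stage rates.
* Only the Hill-form growth law is supported; other saturating laws would
  change both the flow closed forms and the increment distribution.
* Analytic moments are steady-state only; no transient moment dynamics.
* The closed forms can in principle leave the valid regime (e.g. negative
  variance) for extreme parameter combinations; this is surfaced as a
  runtime validity error rather than a documented parameter domain, since
  no closed-form positivity condition is available.
* Colony statistics track only $N$ and $B$; no snapshot size
  distributions, lineage trees, or export of tree formats.
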