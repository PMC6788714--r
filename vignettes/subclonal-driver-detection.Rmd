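---
title: "Detection probability of subclonal drivers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection probability of subclonal drivers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subdriver)
```

## The scientific question

Neutrality tests for cancer evolution ask whether the mutation-frequency
spectrum of a tumor deviates from the 1/f power law expected under neutral
growth. A subclonal driver mutation can only distort that spectrum while its
cancer-cell frequency sits at intermediate values — here taken as the window
[0.2, 0.8], much wider than the [0.24, 0.48] CCF range of the original 1/f
test. `subdriver` computes how likely a driver is to be caught inside such a
window at all, under a two-type branching-process model of tumor growth, and
validates the analytics with three independent stochastic simulators.

## The two-type branching model

Growth starts from one wild-type (type-0) cell. Type-0 cells divide at rate
$b$, die at rate $d$ (per day), and acquire a driver at rate $u$ per cell
per day; driver (type-1) cells divide at $b_1$ and die at $d_1$. Net rates
are $r = b - d$ and $r_1 = b_1 - d_1$, the growth-rate ratio is
$c = r_1/r > 1$, and $g = c - 1$ is the driver's relative advantage.
`branching_params()` accepts either the four raw rates or the
$(b, r, g)$ convention with $b_1 = b$ and checks that both types are
supercritical and death rates nonnegative.

With $X_0$ the wild-type population size when the first driver lineage
destined to survive drift appears — exponentially distributed with rate
$(c/b_1)u$ — the distribution of the driver's frequency $f_{sub}$ at total
size $M$ has the cumulative form

$$F[\alpha] = \int_0^M \frac{cu}{b_1} e^{-\frac{cu}{b_1}X_0}
  \left[1 - \exp\!\left(-\frac{cr}{b_1}\,
  \frac{\alpha}{(1-\alpha)^{c}}\,X_0^{c}\,M^{1-c}\right)\right]\,dX_0 ,$$

implemented by `cdf_subclonal_frequency()`. Its $\alpha \to 1$ limit,
$1 - e^{-(cu/b_1)M}$, is the probability that any surviving driver lineage
arises at all (`cdf_upper_limit()`); the deficit from one is the atom of
driverless tumors. The density (`pdf_subclonal_frequency()`) is the
$\alpha$-derivative of the integrand, integrated over $X_0$. Detection
probability is the window mass $F[hi] - F[lo]$
(`detection_probability()`), and `driver_mutation_rate_bounds()` reproduces
the order-of-magnitude bracket $u \in [10^{-7}, 10^{-3}]$ per day from
genomic driver-gene counts and per-base-pair mutation rates.

The key analytic approximations are (i) a continuous, exponential $X_0$
(valid because $X_0 \sim b_1/(cu)$ is typically $10^3$–$10^5$ cells),
(ii) deterministic exponential growth of both populations after the driver
lineage is established, and (iii) bookkeeping that follows a single
surviving driver clone. The simulators below share convention (iii), which
is also how the validation experiments are scored.

## Numerical evaluation

All quadratures run through `stats::integrate` (adaptive Gauss–Kronrod)
with tolerances from `quad_spec()` (defaults: relative $10^{-9}$, absolute
$10^{-14}$, 200 subdivisions).

* The CDF integral uses the substitution $s = (cu/b_1)X_0$, making the
  outer weight $e^{-s}$; the inner exponent is assembled in log space
  ($\exp(c\ln X_0 + (1-c)\ln M)$ etc.), so nothing under- or overflows for
  $M$ up to $10^{12}$ and $c$ up to 3. The upper limit is truncated at
  $s = 45$ ($e^{-45} < 3\cdot10^{-20}$).
* The density integrand can be a spike orders of magnitude narrower than
  the integration range (its mode sits near $B^{-1/c}$ when the coefficient
  $B(\alpha)$ of the $s^c$ term is large). It is therefore maximized first
  (derivative-free search in $\ln s$), rescaled by its peak value, and
  integrated in $\ln s$ split at the peak, where the spike has width of
  order one. A one-piece adaptive rule on the raw scale silently misses
  such spikes; the unit tests pin this with a finite-difference derivative
  oracle and a piecewise normalization check.
* Probabilities are clipped to $[0,1]$ only within $10^{-10}$ of the
  boundary; larger excursions raise an error rather than being hidden.

## Two sequential drivers

For a second driver arising inside the first clone with the same absolute
growth increment $\Delta r = g\,r$, the probability that the second driver
is detectable while the first is already above the window is

$$P_2 \approx \int_{hi}^{1} f_1(\alpha_1)\,
 \bigl[F_2(hi/\alpha_1) - F_2(lo/\alpha_1)\bigr]\, d\alpha_1 ,$$

with $f_1$ the first driver's density and $F_2$ the frequency CDF of the
second driver *within* the first clone. The parameterization of $F_2$ is
genuinely open; this package resolves it as: background net rate $r_1 =
c\,r$, ratio $c_2 = (r_1 + \Delta r)/r_1$, the same $b_1$ and $u$, and
population size $M_2 = \alpha_1 M$ — the second driver competes inside the
first-driver clone, whose size is $\alpha_1 M$ when the tumor has $M$
cells. The outer integral is evaluated in $w = \ln(1-\alpha_1)$, where the
near-fixation concentration of $f_1$ is smooth, with a composite
Gauss–Legendre rule refined toward the window edge (64 nodes by default;
`outer_nodes = NULL` switches to adaptive quadrature, and the test suite
checks the two agree). The integral starts at $\alpha_1 = hi$: if the first
driver sits below the window, the second is necessarily lower still and
contributes nothing.

`two_driver_sweep()` and `average_detection()` evaluate $P_1$, $P_2$ and
their sum over 3 growth regimes $\times$ 3 selection strengths $\times$ 25
log-spaced sizes from $10^6$ to $10^{11}$ cells. Neither the density nor
the *range* of the size grid is pinned by the model, and the grand averages
are sensitive to the range, so `n_M` and `M_range` are exposed and the
sensitivity is worth stating plainly. On the default $10^6$–$10^{11}$
window the package computes a mean total detection probability of 0.391
for the [0.2, 0.8] window and 0.169 for [0.24, 0.48] (density matters
little: 5 vs 25 sizes shifts the wide-window mean by about one point).
Moving the size window to $10^7$–$10^{12}$ cells gives 0.436 and 0.183 —
almost exactly the published averages of 43% and 18% — which suggests that
is the size range the published sweep actually displayed; but over that
window the maximum of $P_1 + P_2$ reaches 0.711, above the published 69%
bound, so no single size window reproduces all three published summary
numbers under this package's $P_2$. The package keeps $10^6$–$10^{11}$ as
the default and reports the discrepancy rather than tuning the window.

## The well-mixed Gillespie simulator

`run_branching()` is an exact stochastic simulation over aggregated counts
(no per-cell state): type-0 count plus one count per nascent driver clone,
kept in founding order. When the *oldest surviving* clone reaches a size
$n$ with $(d_1/b_1)^n <$ `survivor_threshold_prob` (default $10^{-6}$; the
closed-form extinction probability of a birth–death clone), it is declared
the first surviving lineage; from then on only it is tracked, other driver
clones leave the accounting, and the mutation channel is dropped — new
clones would not be tracked anyway, which mirrors the analytic one-clone
convention. That the *front* clone and not "whichever clone first reaches
the threshold" is designated matters: the race winner among many nascent
clones is biased toward atypically fast growers, and at high mutation
rates (many surviving foundings, e.g. $u = 10^{-4}$) that race-designation
variant visibly overshoots the analytic frequencies. Designating the front
clone is unbiased, and once it has passed the threshold no other clone can
ever become the first surviving lineage, so dropping them is exact for
this observable (clones in a branching process do not interact). An
ordered full-simulation cross-check without any designation shortcut
(`branching_sim_eq1_cpp`) is kept in the package and compared against the
production path in the test suite. Runs whose whole population dies out
are rejected, restarted, and counted. If no clone ever reaches the
threshold, the reported fraction sums all living driver clones.

Each attempt draws from its own counter-based RNG stream (xoshiro256++
seeded by a splitmix64 hash of the master seed and the attempt index), so a
sample is reproducible and independent of scheduling. Internally the
post-designation phase — which carries almost all events — runs branchless
and interleaved across several replicates to hide each run's serial
dependency chain; because streams are per-attempt, the interleaving cannot
change any result.

`empirical_cdf()` scores a sample at chosen frequencies with bootstrap
standard errors (joint resampling of runs, 1000 resamples by default).
The analytic-versus-simulation validation runs the three standard panel
parameter sets ($b = b_1 = 0.14$, $d = 0.13$; $c$, $u$ as in each panel) at
$M = 10^6$ cells with 1000 surviving runs per panel, and requires agreement
at every decile within three bootstrap standard errors. $M = 10^6$ is a
deliberate choice: the formula depends on $M$ explicitly, so agreement
there is as informative as at $10^8$ while keeping the exact simulation
affordable. A fourth published panel lists $d > b$ (a subcritical wild
type, presumably a caption slip); the constructor rejects it and the
validation uses the three consistent panels.

`run_three_type()` extends the same machinery with a second driver stage
(net rate increment $\Delta r$, mutation rate $u$ within the tracked first
clone, the same survivor bookkeeping per stage) and serves as the
brute-force oracle for $P_2$. The published parameter regime for this
cross-check is far beyond desk scale, so the test uses a fast-growth point
($b = b_1 = 0.25$, $r = 0.07$, $g = 0.7$, $u = 3\cdot10^{-4}$,
$M = 10^5$, 1500 runs) where the formula's validity conditions
$1 \ll b_1/(cu) \ll M$ still hold, and checks both $P_1$ and $P_2$ within
three binomial standard errors.

## The 3d lattice simulator

`run_spatial()` grows a tumor on a simple cubic lattice: every cell
replicates at rate $b$ times its empty-neighbor fraction (a fully
surrounded cell cannot replicate) and dies at rate $d$ or $d_1$; a
replication of a wild-type cell yields a driver daughter with probability
$u_{site}/b$, after which further mutations are forbidden, so at most one
driver clone exists. One lattice site represents `cells_per_site` cells
(default 100) with $u_{site} = u \times$ `cells_per_site`; results are
reported in cells. Scheduling is exact and event-driven (no time step):
death by uniform choice within a type, replication by rejection sampling
proportional to cached empty-neighbor counts, daughter placed on a uniform
empty neighbor.

The neighborhood is Moore (26 sites) by default. This is a deliberate
choice with a sharp reason: the model is a contact process, and on the
6-neighbor lattice the slow growth regime ($b = 1$, $d = 0.9$) sits
*below* the 3d contact-process critical point (per-neighbor birth-to-death
ratio $\approx 0.185$ against a threshold near $0.22$), so that tumor never
grows at all, while $d = 0.7$ grows as a barely supercritical sparse cloud.
With 26 neighbors all three standard regimes ($d = 0.7, 0.5, 0.9$) are
supercritical. The 6-neighbor variant remains available via
`neighborhood = 6`.

Even above threshold, a near-critical tumor is a low-density cloud whose
radius cannot be predicted from its cell count, so the bounding box is
adaptive: an attempt that outgrows its box is re-run from its own RNG
stream in a larger box, reproducing the identical trajectory — results are
independent of the initial box size.

Rejection policy: extinct runs are rejected and counted; runs that never
produced a driver are rejected (`require_driver = FALSE` lifts this for
null experiments); a run whose driver clone was produced but died out is
*accepted* with driver fraction 0 — producing a driver is what the standard
policy requires — and `reject_driver_extinct = TRUE` applies the stricter
reading instead.

`spatial_screen()` estimates detection probability over 3 regimes
$\times$ 3 selection strengths $\times$ 4 tumor sizes, recording fractions
along single runs so each replicate serves every size. The exact size grids
are not pinned by the model; this package uses, in sites, 500–32 000
(log-spaced) for the moderate and fast regimes and 250–2 000 for the slow
regime, whose near-critical dynamics make larger sizes disproportionately
expensive while the driver there typically sweeps to fixation early (so
detection is already past its peak at these sizes).

## The sigmoidal (late-stage) model

Past the avascular stage, growth is modeled deterministically by two clones
sharing a carrying capacity $K$:
$dx/dt = r\,x\,(1 - (x+y)/K)$ and $dy/dt = c\,r\,y\,(1 - (x+y)/K)$.
Dividing the equations gives the exact first integral
$y = y_0\,(x/x_0)^c$, so the terminal composition needs no integration:
the limiting wild-type size solves $x^* + y_0 (x^*/x_0)^c = K$, found by
bisection in $\log x^*$ (`final_driver_fraction()`), and the final driver
fraction is $1 - x^*/K$. `solve_sigmoidal()` integrates the system with
`deSolve::lsodar` (relative tolerance $10^{-11}$, absolute tolerance scaled
to the initial population, root-stop at total size $(1-10^{-6})K$) and is
held to the first integral within $10^{-6}$ relative by the tests; the
closed form and the ODE terminal fraction agree to the same tolerance on
randomized inputs. Because fractions freeze as growth stops, the
first-integral root is the $t\to\infty$ limit and is used as "the" final
frequency.

`sigmoidal_detection()` chains the two phases per run: the 3d lattice to
the handoff size ($10^6$ cells by default, about the lower edge of clinical
detectability), populations converted from sites to cells, then the
logistic phase to $K$. The spatial rejection policy carries over unchanged.
`sigmoidal_screen()` pairs each lattice regime with its exponential-phase
growth rate ($r = 0.01, 0.07, 0.0013$ — note the terminal fraction depends
only on the handoff composition, $c$ and $K$, so $r$ affects timing only)
and scores the final fractions against the window at $K = 10^{11}$ cells.

## What the simulators do and do not emulate

The generators produce exactly the study conditions of the model: constant
rates, at most one (or two sequential) driver subclones, no cell migration,
no spatial sampling bias, and cancer-cell frequencies observed without
noise. Real tumors add measurement layers that are deliberately out of
scope here: variant-allele-frequency conversion (ploidy, purity), sequencing
noise and depth limits, biopsy sampling of spatially heterogeneous tumors,
and passenger hitchhiking. Passing tests therefore validate the
probability theory and its implementation, not the full chain from reads to
CCF in a clinical sample.

## Problem sizes and determinism

The test suite runs the validation panels at $M = 10^6$ with 1000 surviving
runs each; the grid scan at 12 points per axis ($\approx 2.3\cdot10^5$
evaluated tuples); the lattice screen and the combined-model screen at 200
accepted runs per combination. The acceptance script
(`scripts/acceptance.R`) recomputes the deterministic quantities with fixed
quadrature settings — identical across seeds — and the stochastic screen
from the seed it is given. All stochastic components consume counter-based
per-attempt streams, so any result is reproducible from its manifest.

## Known limitations

* The analytics inherit the one-surviving-clone convention; at mutation
  rates high enough that many surviving clones coexist
  ($(cu/b_1)M \gg 1$), the formula describes the first surviving clone
  rather than the aggregate driver fraction, and the simulators score the
  same observable by construction.
* The two-driver $P_2$ ignores configurations where the *first* driver is
  below the window while the second is inside it; the printed lower
  integration limit encodes that convention and it is kept.
* The lattice model's quantitative detection curves depend on the
  neighborhood and on the site-scaling factor; both are exposed as
  parameters rather than hidden constants.
* Near the contact-process threshold the lattice simulator is exact but
  slow, which is why the slow regime's screen sizes are smaller.
* The grand averages of two-driver detection depend on the tumor-size
  window being averaged over (see the two-driver section); only window
  choices, never per-point probabilities, are affected.
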