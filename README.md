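# subdriver

Detection probability of subclonal driver mutations in growing tumors.

## The problem

Neutrality tests for cancer evolution (the 1/f mutation-frequency-spectrum
test and its relatives) assume that a driver mutation arising after tumor
initiation will be found at a *macroscopic but clearly subclonal*
cancer-cell frequency — conventionally somewhere inside [0.2, 0.8] — where
it can bend the spectrum away from the neutral 1/f shape. `subdriver`
quantifies how often that assumption holds. It implements a two-type
branching-process model of tumor growth and computes, analytically, the
probability distribution of a subclonal driver's cancer-cell frequency when
the tumor reaches a given size, together with the probability that the
driver (or a second, sequential driver) falls inside a detection window.
Three independent stochastic simulators — an exact Gillespie simulation of
the well-mixed process, a 3d lattice tumor-growth model, and a combined
3d + logistic (sigmoidal) late-stage model — validate the analytics and
extend the conclusions to non-exponential growth.

The package is for researchers in cancer population genetics and anyone
evaluating selection inference from subclonal mutation frequencies.

## The model

Wild-type cells divide at rate *b* and die at rate *d* (per day); cells
carrying the driver divide at *b*₁ and die at *d*₁. With net rates
*r* = *b* − *d*, *r*₁ = *b*₁ − *d*₁, ratio *c* = *r*₁/*r* > 1 and driver
mutation rate *u* per cell per day, the cumulative distribution of the
driver frequency at tumor size *M* is

    F[α] = ∫₀^M (cu/b₁) e^(−(cu/b₁)X₀) [1 − exp(−(cr/b₁) α (1−α)^(−c) X₀^c M^(1−c))] dX₀

where *X*₀ is the (exponentially distributed) wild-type population size at
the appearance of the first surviving driver lineage. The probability that
the driver is detectable is the window mass `P_det = F[0.8] − F[0.2]`.
The central scientific result the package reproduces: this density is
convex, so the driver's frequency is biased toward 0 and 1 — across the
entire biologically plausible parameter range the detection probability
never exceeds ~60%, and absence of an intermediate-frequency driver is
therefore weak evidence of neutral evolution.

## Worked example

```r
library(subdriver)

p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
p
#> Two-type branching process parameters (rates per day)
#>   type-0: b = 0.14, d = 0.13 (r = 0.01)
#>   type-1: b1 = 0.14, d1 = 0.123 (r1 = 0.017, c = 1.7, g = 70%)
#>   driver mutation rate u = 1e-05, final size M = 1e+08 cells

cdf_subclonal_frequency(p, c(0.2, 0.5, 0.8))
#> [1] 0.3047225 0.6047803 0.8495248

detection_probability(p)          # F[0.8] - F[0.2]
#> [1] 0.5448023

two_driver_detection(p, delta_r = p$g * p$r)
#> [1] 0.01916375

driver_mutation_rate_bounds()
#> # A tibble: 2 x 5
#>   bound n_driver_genes positions_per_gene   per_bp_rate        rate
#>   <chr>          <dbl>              <dbl>         <dbl>       <dbl>
#> 1 lower             20                 90 0.00000000004 0.000000072
#> 2 upper            600                 90 0.00000006    0.00324
```

So a driver with a 70% growth advantage in a moderately growing tumor of
10⁸ cells has a 54% chance of sitting in the detectable range — this is
close to the best case; sweeping tumor size and selection strength
(`detection_vs_size()`, `scan_detection()`) shows the probability stays
below 60% everywhere. A second sequential driver adds about 2 percentage
points here (`two_driver_detection()`), and the mutation-rate bounds bracket
*u* between ~10⁻⁷ and ~10⁻³ per day.

Simulation cross-checks follow the same grammar and return tidy objects:

```r
sim <- run_branching(p, n_runs = 1000, seed = 1)   # exact Gillespie
empirical_cdf(sim, alphas = seq(0.1, 0.9, 0.1))    # with bootstrap sem
autoplot(sim)                                      # ECDF plot
```

A thin command-line wrapper over these functions is installed at
`inst/cli/subdriver.R` (`Rscript subdriver.R detect-prob --g 0.7 --M 1e8`).

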