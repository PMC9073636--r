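# gkequate

Gaussian kernel equipercentile equating for the equivalent-groups (EG)
design, with analytic standard errors of equating that account for the
sampling variability of the penalty-selected bandwidth.

## The problem

When alternate forms of a standardized test are administered, raw
number-correct scores on form *X* must be mapped onto the scale of form *Y*
so that results are interchangeable. Kernel equating does this in five
steps: presmooth each form's score data with a parametric model, derive the
discrete score probabilities *r* and *s*, continuize the discrete
distributions with a Gaussian kernel, equate through the equipercentile
function, and attach standard errors of equating (SEEs).

The continuized CDF of form *X* is

    F_h(x) = Σ_j r_j Φ( (x − a x_j − (1 − a) μ) / (a h) ),
    a = sqrt(σ² / (σ² + h²)),

where the shrinkage coefficient `a` makes the continuous distribution keep
the discrete mean μ and variance σ² for every bandwidth `h`. The bandwidth
is chosen to minimize the penalty

    PEN1(h) = Σ_j ( r_j − f_h(x_j) )²,

the squared distance between the score probabilities and the continuized
density at the score points. The equating function is
`e_Y(x) = G_h⁻¹(F_h(x))`.

The classical delta-method SEE treats the selected bandwidths as constants.
But `ĥ` is itself a function of the estimated probabilities. This package's
distinctive feature is the propagation of that extra variability: the
first-order condition `∂PEN1/∂h = 0` defines `h(r)` implicitly, the
implicit function theorem gives

    ∂h/∂r = −(∂²PEN1/∂h²)⁻¹ · ∂²PEN1/∂h∂rᵀ,

so `Var(ĥ) = (∂h/∂r) Σ_r (∂h/∂r)ᵀ`, and the modified SEE adds a second
quadratic form to the classical one:

    Var(ê_Y) = A Σ Aᵀ + B Σ Bᵀ,
    A = ∂e_Y/∂(r, s),   B = ∂e_Y/∂(h_X, h_Y) · ∂(h_X, h_Y)/∂(r, s),

with Σ the block-diagonal covariance of the independently estimated score
probabilities. The modified SEE is by construction at least the classical
one at every score.

Presmoothing is either raw multinomial (relative frequencies with the
standard multinomial covariance) or a two-parameter logistic IRT model
fitted by marginal maximum likelihood (EM), with the model-implied score
distribution obtained by the Lord–Wingersky recursion and its covariance by
the delta method through the item parameters.

## Worked example

Two simulated 20-item EG samples (N = 1000 each):

```r
library(gkequate)
x_counts <- c(4, 14, 30, 41, 56, 65, 68, 86, 100, 74, 86, 81,
              80, 71, 42, 47, 25, 18, 7, 4, 1)
y_counts <- c(17, 29, 62, 51, 58, 77, 69, 86, 67, 67, 75, 65,
              62, 50, 56, 34, 28, 24, 13, 7, 3)
dist_x <- multinomial_distribution(0:20, x_counts)
dist_y <- multinomial_distribution(0:20, y_counts)
res <- kernel_equate(dist_x, dist_y)
res
#> Kernel equipercentile equating (equivalent groups)
#>   h_X = 0.48933 (SE 0.01697), h_Y = 0.47974 (SE 0.01457)
as.data.frame(res)[6:9, ]
#>    x equated_y see_original see_modified
#> 6  5    3.8103       0.2786       0.2787
#> 7  6    4.8488       0.2448       0.2448
#> 8  7    5.8993       0.2734       0.2734
#> 9  8    7.0911       0.2477       0.2477
```

A raw score of 5 on form X corresponds to about 3.81 on the form-Y scale,
with a standard error of about 0.28 score points; `see_modified` carries
the additional bandwidth-estimation variance on top of `see_original`
(here, as is typical, a very small addition). The PEN1-selected bandwidths
(≈ 0.49 score points) come with their own standard errors (≈ 0.015–0.017).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/gkequate.R equate --freq-x x.csv --freq-y y.csv --out results/
Rscript inst/cli/gkequate.R simulate --reps 500 --n 1000 --items 20 --seed 1
Rscript inst/cli/gkequate.R selftest
```

and `run_study()` / `cmd_simulate()` run the full Monte Carlo harness:
per replication it samples EG data, presmooths, selects bandwidths,
equates, and computes the analytic SEs; aggregates compare mean analytic
SEs with the Monte Carlo SDs across replications and report 95% CI
coverage against the population equating function.

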