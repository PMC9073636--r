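---
title: "Kernel equating with bandwidth-aware standard errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel equating with bandwidth-aware standard errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkequate)
```

## The model

Kernel equating makes number-correct scores on two test forms
interchangeable under the equivalent-groups (EG) design: two independent
random samples from one population, one taking form X, the other form Y.
Because the groups are exchangeable, the design function is the identity —
the estimated score probability vectors $r$ and $s$ enter the equating
machinery unchanged, and their joint covariance is block-diagonal.

The discrete score distribution of X (scores $x_j$, probabilities $r_j$)
is continuized with a Gaussian kernel,

$$F_h(x) = \sum_j r_j \, \Phi\!\left(\frac{x - a x_j - (1-a)\mu}{a h}\right),
\qquad a = \sqrt{\frac{\sigma^2}{\sigma^2 + h^2}},$$

where $\mu$ and $\sigma^2$ are the mean and variance of the discrete
distribution. The coefficient $a$ shrinks the score points toward the mean
by exactly the amount needed for the continuous distribution to keep
$(\mu, \sigma^2)$ at every bandwidth $h$ — this moment preservation is an
identity, and the test suite verifies it by numerical integration to 1e-7
over random distributions and bandwidths. A useful consequence worth
keeping in mind: as $h \to \infty$ the continuized density does **not**
flatten toward zero but converges to the $N(\mu, \sigma^2)$ density, since
the variance is pinned.

The bandwidth minimizes the penalty
$\mathrm{PEN}_1(h) = \sum_j (r_j - f_h(x_j))^2$, the squared distance
between the probabilities and the continuized density at the score points.
Only this smooth, single-minimum penalty is supported; the additional
smoothness penalty sometimes combined with it is non-differentiable and can
have multiple local minima, which breaks the implicit-function argument
below, so it is deliberately out of scope. The equating function is
$e_Y(x) = G_{h_Y}^{-1}(F_{h_X}(x))$.

## Standard errors

Writing $\partial e_Y = [\partial e_Y/\partial r,\ \partial e_Y/\partial s]$,
the classical delta-method SEE with bandwidths held fixed is
$\sqrt{\partial e_Y \, \Sigma \, \partial e_Y'}$. The $r$-derivative of the
continuized CDF is a *total* derivative: $\mu$, $\sigma^2$ and $a$ are all
functions of $r$, giving entry $j$ the closed form
$\Phi(R_j(x)) - M_j(x) f_h(x)$ with
$M_j = \tfrac12 (x-\mu)(1-a^2) z_j^2 + (1-a) x_j$ and
$z_j = (x_j-\mu)/\sigma$. Derivatives are taken with $r$ as a free vector;
the sum-to-one constraint is absorbed by the rank-deficient probability
covariance, whose rows sum to zero.

The selected bandwidth is an estimator too. At an interior minimum the
first-order condition $\partial \mathrm{PEN}_1/\partial h = 0$ defines
$h(r)$ implicitly, and the implicit function theorem gives

$$\frac{\partial h}{\partial r} =
-\left(\frac{\partial^2 \mathrm{PEN}_1}{\partial h^2}\right)^{-1}
\frac{\partial^2 \mathrm{PEN}_1}{\partial h\, \partial r'},
\qquad
\mathrm{Var}(\hat h) = \frac{\partial h}{\partial r}\, \Sigma_r\,
\frac{\partial h}{\partial r}'.$$

The modified SEE adds the bandwidth pathway as a second quadratic form,

$$\mathrm{Var}(\hat e_Y) = A \Sigma A' + B \Sigma B', \qquad
A = \frac{\partial e_Y}{\partial (r,s)}, \quad
B = \frac{\partial e_Y}{\partial (h_X, h_Y)}
    \frac{\partial (h_X, h_Y)}{\partial (r,s)},$$

with no cross term between the two pathways; the bandwidth-derivative
factor is block-diagonal because $h_X$ depends only on $r$ and $h_Y$ only
on $s$. Two consequences are tested structurally: the modified SEE
dominates the classical SEE at every score, and both vanish together as
$\Sigma \to 0$ and scale as $1/\sqrt{N}$ under multinomial covariance. A
cross-covariance term between the direct and bandwidth pathways could be
entertained; the two-term form is implemented as specified, and since the
bandwidth contribution itself is small the distinction is immaterial in
practice.

All expressions are evaluated at the estimates $(\hat r, \hat s, \hat h_X,
\hat h_Y)$, as is standard for plug-in delta methods.

## Numerical choices

* **Derivatives.** $\partial \mathrm{PEN}_1/\partial h$,
  $\partial F_h/\partial h$ and $\partial F_h/\partial r$ are implemented
  in closed form (the bandwidth enters through both $a(h)$ and the kernel
  scale $a h$). The second derivatives needed by the implicit-function
  gradient are Richardson-extrapolated central differences *of the analytic
  first derivative* — one differentiation order is done exactly, which
  keeps the numerical order benign. Every analytic derivative is checked
  in the suite against an independent Richardson differentiator, and the
  implicit gradient additionally against explicit re-minimization of the
  penalty under simplex-preserving perturbations.
* **Bandwidth search.** `stats::optimize` — golden-section search with
  successive parabolic interpolation — at tolerance 1.5e-8, on the default
  interval $[10^{-3}, 2\sigma]$. No published choice of interval exists;
  penalty-optimal bandwidths sit well below $\sigma$ in practice, and a
  minimum found at (or within $10^{-4}$ of the width of) an endpoint raises
  a boundary flag rather than passing silently.
* **Equating inversion.** `uniroot` on a bracket $\mu_Y \pm 8(\sigma_Y +
  h_Y)$, doubled up to four times, then safeguarded Newton polishing until
  the CDF gap is below 1e-10 — an x-tolerance alone does not bound the
  percentile gap where the density is small.
* **Degenerate cases.** Zero-probability score points are retained
  everywhere (in the penalty sum and in the covariance); a zero-variance
  distribution is an error. Variances in $(-10^{-12}, 0)$ arising from
  floating point are clamped to zero; anything more negative is an error.
  At extreme scores the target density $G'$ can be numerically zero; such
  points are flagged (`g_prime_small`) instead of erroring.
* **IRT presmoothing.** The 2-PL is fitted by EM on 61 equally spaced
  quadrature nodes on $[-6, 6]$ with normalized N(0,1) weights (the latent
  distribution is fixed by the EG design; no latent parameters are
  estimated). Convergence is a maximum absolute parameter change below
  1e-4 within 500 iterations, with per-item damped Newton M-steps. The
  item-parameter covariance uses the empirical (cross-product) Fisher
  information assembled from per-person marginal scores via Fisher's
  identity: it needs a single E-step pass, whereas a finite-difference
  Hessian of the marginal likelihood costs thousands of likelihood sweeps
  per fit — prohibitive inside a Monte Carlo harness — and the two agree
  asymptotically. The score-probability covariance is the delta method
  through the Lord–Wingersky map, with a central-difference Jacobian
  (step $10^{-5}\max(1,|\theta_k|)$; the map is smooth and cheap).

## The synthetic-data generator

The generator emulates realistic standardized-test conditions: item
discriminations $U(0.5, 2)$, difficulties $N(-0.25, 1)$ for form X and
$N(+0.25, 1)$ for form Y (X the slightly easier form), latent trait
$N(0,1)$, equivalent-groups sampling, test lengths 20/40/80 and sample
sizes 1000/4000/16000 as the canonical grid. Item parameters are drawn
once per study and held fixed across replications; all randomness flows
from a master seed through pre-drawn per-replication seeds, so studies are
exactly reproducible and failed replications are recorded and excluded
rather than silently dropped.

What the generator does *not* emulate: local item dependence, guessing
(no 3-PL lower asymptote), multidimensional traits, speededness, or group
non-equivalence. Passing Monte Carlo checks therefore demonstrate the
correctness of the asymptotic derivations under a well-specified 2-PL EG
world, not robustness to violations of it.

The "true" equated function used for coverage is the population analogue:
the equating of the model-implied population score distributions using
their own penalty-optimal bandwidths. Coverage is averaged over interior
scores (excluding the two extreme score points at each end, where $G'$ is
near zero and the CDFs are dominated by tail behavior); whole-range
averages are reported alongside.

## Scale of the validation runs

The Monte Carlo validation in the test suite uses desk-scale versions of
the canonical design, chosen to make the Monte Carlo error small relative
to the 10–15% comparison bands: 500 replications at N = 1000 (20 items,
IRT presmoothing) for the bandwidth-SE and SEE comparisons, 500
replications at N = 4000 (multinomial presmoothing) for CI coverage, and
200 replications for the acceptance script's convergence figure. With 500
replications the Monte Carlo SD of a SD estimate is about 3%, comfortably
inside the bands.

## Known limitations

* The implicit-function variance is a first-order (delta-method)
  approximation around the realized probability vector. Its quality
  depends on how smooth that vector is. Under parametric presmoothing the
  estimated probabilities are smooth in the score index and the
  linearization tracks the actual re-minimized bandwidth closely. Under
  *raw multinomial* probabilities at moderate N, the argmin map is
  evaluated at a jagged point and responds nonlinearly to the
  multinomial noise: the linearized dispersion then overstates the actual
  Monte Carlo dispersion of $\hat h$, and the analytic bandwidth SE should
  be read as conservative. Presmoothing before equating — standard
  practice in any case — is what the bandwidth-SE validation here assumes.
* The modified and classical SEEs are typically nearly identical: the
  bandwidth pathway contributes little variance. The modified form is
  preferred on principle (it accounts for a real source of variability),
  not because it moves the numbers much.
* Only the EG design and the Gaussian kernel are implemented; chained or
  post-stratification equating for non-equivalent groups, log-linear
  presmoothing, and alternative kernels are out of scope.
* Equated values and SEEs at the extreme score points depend on tail
  behavior of the continuized distributions and should be interpreted with
  the `g_prime_small` flag in hand.
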