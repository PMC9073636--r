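#' Derivative of the continuized CDF with respect to the score probabilities
#'
#' Total derivative of `F_h(x)` in the probability vector treated as a free
#' vector, accounting for the dependence of `mu`, `sigma^2` and the
#' shrinkage coefficient `a` on the probabilities:
#' entry `j` is `Phi(R_j(x)) - M_j(x) f_h(x)` with
#' `M_j = (1/2)(x - mu)(1 - a^2) z_j^2 + (1 - a) x_j` and
#' `z_j = (x_j - mu)/sigma`. The rank-deficient probability covariance
#' (rows summing to zero) absorbs the sum-to-one constraint in the
#' delta-method quadratic form.
#'
#' @param cont A [continuize]d distribution.
#' @param x Scalar evaluation point.
#' @return Length-`J` gradient vector.
#' @export
cdf_prob_gradient <- function(cont, x) {
  sc <- cont$base$scores
  sig <- sqrt(cont$sigma2)
  R <- drop(kernel_R(cont, x))
  z <- (sc - cont$mu) / sig
  M <- 0.5 * (x - cont$mu) * (1 - cont$a^2) * z^2 + (1 - cont$a) * sc
  stats::pnorm(R) - M * kernel_pdf(cont, x)
}

# components of the delta-method SEE at one evaluation point
see_components <- function(cont_x, cont_y, x) {
  e <- equate_score(cont_x, cont_y, x)
  g_prime <- kernel_pdf(cont_y, e)
  list(
    e = e,
    g_prime = g_prime,
    d_e_d_r = cdf_prob_gradient(cont_x, x) / g_prime,
    d_e_d_s = -cdf_prob_gradient(cont_y, e) / g_prime,
    d_e_d_hx = kernel_cdf_dh(cont_x, x) / g_prime,
    d_e_d_hy = -kernel_cdf_dh(cont_y, e) / g_prime
  )
}

quad_form_sqrt <- function(v, Sigma) {
  q <- drop(v %*% Sigma %*% v)
  if (q < -1e-12) stop("negative variance in delta-method quadratic form: ", q)
  sqrt(max(q, 0))
}

#' Classical standard error of equating (bandwidths fixed)
#'
#' Delta-method SEE treating the bandwidths as constants: `SEE(x) =
#' sqrt(d_e Sigma d_e')` with `d_e = [d e/d r, d e/d s]`, the r-block
#' `(1/G') dF/dr` and the s-block `-(1/G') dG/ds` evaluated at the equated
#' value, and `Sigma` the block-diagonal covariance of the independently
#' estimated score probabilities.
#'
#' @param cont_x,cont_y Continuized distributions for forms X and Y.
#' @param Sigma `(J+K) x (J+K)` block-diagonal probability covariance.
#' @param x_points Evaluation points on the X scale.
#' @return Vector of SEEs with attribute `g_prime_small` flagging points
#'   where the target density at the equated value is below `1e-8`.
#' @export
see_original <- function(cont_x, cont_y, Sigma, x_points) {
  out <- numeric(length(x_points))
  flag <- logical(length(x_points))
  for (i in seq_along(x_points)) {
    cm <- see_components(cont_x, cont_y, x_points[i])
    flag[i] <- cm$g_prime < 1e-8
    out[i] <- quad_form_sqrt(c(cm$d_e_d_r, cm$d_e_d_s), Sigma)
  }
  structure(out, g_prime_small = flag)
}

# Richardson-extrapolated central difference of a smooth scalar function
richardson_deriv <- function(f, t, h0, levels = 4L) {
  D <- matrix(0, levels, levels)
  hh <- h0
  for (i in seq_len(levels)) {
    D[i, 1] <- (f(t + hh) - f(t - hh)) / (2 * hh)
    hh <- hh / 2
  }
  for (j in 2:levels)
    for (i in j:levels)
      D[i, j] <- (4^(j - 1) * D[i, j - 1] - D[i - 1, j - 1]) / (4^(j - 1) - 1)
  D[levels, levels]
}

# replace the probability vector without re-validation (free-vector
# perturbations used in implicit differentiation do not preserve the simplex)
dist_free_probs <- function(dist, probs) {
  structure(list(scores = dist$scores, probs = probs, n = dist$n, cov = NULL),
            class = "score_distribution")
}

#' Second derivatives of PEN1 at the selected bandwidth
#'
#' The implicit-function delta method needs `d^2 PEN1 / d h^2` (a scalar,
#' positive at a proper minimum) and `d^2 PEN1 / d h d r'` (a `1 x J`
#' vector). Both are obtained by Richardson-extrapolated central differences
#' of the closed-form first derivative [pen1_deriv], in `h` and in each
#' probability coordinate treated as a free vector.
#'
#' @param dist A [score_distribution].
#' @param h The PEN1-minimizing bandwidth.
#' @return List with `d2_dh2` (scalar) and `d2_dhdr` (vector).
#' @export
pen1_cross_derivatives <- function(dist, h) {
  d2_dh2 <- richardson_deriv(function(t) pen1_deriv(dist, t), h,
                             h0 = 1e-2 * max(h, 0.05))
  if (!is.finite(d2_dh2) || d2_dh2 <= 0)
    stop("not a local minimum: d2 PEN1 / d h2 = ", d2_dh2)
  J <- length(dist$probs)
  d2_dhdr <- vapply(seq_len(J), function(j) {
    richardson_deriv(function(t) {
      p <- dist$probs
      p[j] <- t
      pen1_deriv(dist_free_probs(dist, p), h)
    }, dist$probs[j], h0 = 1e-3)
  }, numeric(1))
  list(d2_dh2 = d2_dh2, d2_dhdr = d2_dhdr)
}

#' Implicit-function gradient of the bandwidth in the score probabilities
#'
#' At the PEN1 minimizer the first-order condition `d PEN1/d h = 0` defines
#' `h` implicitly as a function of the probability vector; the implicit
#' function theorem gives
#' `d h / d r = -(d^2 PEN1/d h^2)^{-1} d^2 PEN1/(d h d r')`.
#'
#' @inheritParams pen1_cross_derivatives
#' @return Length-`J` gradient vector.
#' @export
bandwidth_gradient <- function(dist, h) {
  cd <- pen1_cross_derivatives(dist, h)
  -cd$d2_dhdr / cd$d2_dh2
}

#' Asymptotic variance and standard error of the bandwidth estimator
#'
#' Delta method for implicit functions: `Var(h-hat) = g Sigma_r g'` with
#' `g` the [bandwidth_gradient].
#'
#' @inheritParams pen1_cross_derivatives
#' @param cov_r `J x J` covariance of the estimated probabilities.
#' @return List with `var` and `se`.
#' @export
bandwidth_se <- function(dist, h, cov_r) {
  g <- bandwidth_gradient(dist, h)
  v <- drop(g %*% cov_r %*% g)
  if (v < -1e-12) stop("negative bandwidth variance: ", v)
  v <- max(v, 0)
  list(var = v, se = sqrt(v))
}

#' Derivatives of the equating function in the two bandwidths
#'
#' `d e/d h_X = (1/G') dF_hX(x)/d h_X` and
#' `d e/d h_Y = -(1/G') dG_hY(e(x))/d h_Y`, with the CDF bandwidth
#' derivatives in closed form (the bandwidth enters through both the
#' shrinkage coefficient and the kernel scale).
#'
#' @param cont_x,cont_y Continuized distributions.
#' @param x Scalar X-scale evaluation point.
#' @return Named vector `c(de_dhx, de_dhy)`.
#' @export
equate_bandwidth_gradient <- function(cont_x, cont_y, x) {
  cm <- see_components(cont_x, cont_y, x)
  c(de_dhx = cm$d_e_d_hx, de_dhy = cm$d_e_d_hy)
}

#' Modified standard error of equating with bandwidth variability
#'
#' Adds to the classical delta-method variance a second quadratic form that
#' carries the sampling variability of the PEN1-minimizing bandwidths:
#' `Var = A Sigma A' + B Sigma B'` where `A = d e/d(r, s)` and
#' `B = d e/d(h_X, h_Y) . d(h_X, h_Y)/d(r, s)`, the latter factor
#' block-diagonal (the X bandwidth depends only on `r`, the Y bandwidth
#' only on `s`). No cross term between the two pathways is included. By
#' construction the modified SEE is at least the classical SEE at every
#' point.
#'
#' @inheritParams see_original
#' @return Vector of modified SEEs with attribute `g_prime_small` as in
#'   [see_original].
#' @export
see_modified <- function(cont_x, cont_y, Sigma, x_points) {
  gx <- bandwidth_gradient(cont_x$base, cont_x$h)
  gy <- bandwidth_gradient(cont_y$base, cont_y$h)
  out <- numeric(length(x_points))
  flag <- logical(length(x_points))
  for (i in seq_along(x_points)) {
    cm <- see_components(cont_x, cont_y, x_points[i])
    flag[i] <- cm$g_prime < 1e-8
    A <- c(cm$d_e_d_r, cm$d_e_d_s)
    B <- c(cm$d_e_d_hx * gx, cm$d_e_d_hy * gy)
    va <- drop(A %*% Sigma %*% A)
    vb <- drop(B %*% Sigma %*% B)
    if (va < -1e-12 || vb < -1e-12)
      stop("negative variance in modified SEE quadratic forms")
    out[i] <- sqrt(max(va, 0) + max(vb, 0))
  }
  structure(out, g_prime_small = flag)
}
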