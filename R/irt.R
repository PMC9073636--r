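#' Latent-trait quadrature grid
#'
#' Equally spaced nodes with standard-normal weights, normalized to sum to 1.
#' The latent distribution is fixed to N(0, 1), as the equivalent-groups
#' design implies a single common population.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param range Endpoints of the grid (default `c(-6, 6)`).
#' @return List with `nodes` and `weights`.
#' @export
latent_quadrature <- function(n_nodes = 61L, range = c(-6, 6)) {
  if (n_nodes < 11) stop("quadrature needs at least 11 nodes")
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' Construct a 2-PL item parameter set
#'
#' @param discriminations Positive slope parameters, one per item.
#' @param difficulties Location parameters, one per item.
#' @param param_cov Optional `2J x 2J` covariance of the stacked estimator
#'   `(a_1..a_J, b_1..b_J)`.
#' @param converged Logical convergence flag (for fitted sets).
#' @return Object of class `item_parameter_set`.
#' @export
item_parameter_set <- function(discriminations, difficulties,
                               param_cov = NULL, converged = TRUE) {
  if (length(discriminations) != length(difficulties))
    stop("discriminations and difficulties must have equal length")
  if (any(discriminations <= 0)) stop("discriminations must be positive")
  if (!is.null(param_cov)) {
    param_cov <- as.matrix(param_cov)
    p <- 2L * length(discriminations)
    if (!all(dim(param_cov) == c(p, p))) stop("param_cov must be 2J x 2J")
    param_cov <- (param_cov + t(param_cov)) / 2
  }
  structure(
    list(discriminations = as.numeric(discriminations),
         difficulties = as.numeric(difficulties),
         param_cov = param_cov, converged = isTRUE(converged)),
    class = "item_parameter_set"
  )
}

#' @export
print.item_parameter_set <- function(x, ...) {
  cat("2-PL item parameter set:", length(x$discriminations), "items,",
      if (x$converged) "converged" else "NOT converged",
      if (is.null(x$param_cov)) "(no covariance)" else "(covariance attached)",
      "\n")
  invisible(x)
}

# item response probabilities: J x Q matrix of P(correct | theta_q)
two_pl_prob <- function(a, b, nodes) {
  stats::plogis(outer(a, nodes, function(ai, th) ai * th) - a * b)
}

#' Fit a two-parameter logistic IRT model by EM
#'
#' Marginal maximum likelihood with the latent trait fixed to N(0, 1) on a
#' fixed quadrature grid. The E-step computes posterior node weights per
#' person; the M-step updates each item's `(a, b)` by Newton steps on the
#' expected complete-data log-likelihood. Convergence is declared when the
#' maximum absolute parameter change falls below `tol`.
#'
#' The asymptotic covariance of the stacked estimator is computed from the
#' empirical Fisher information: per-person score vectors of the marginal
#' log-likelihood obtained via Fisher's identity (posterior-weighted
#' complete-data scores), cross-multiplied and inverted.
#'
#' @param responses Persons-by-items binary matrix.
#' @param quadrature A [latent_quadrature] grid.
#' @param tol Convergence tolerance on parameter change (default 1e-4).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An [item_parameter_set] with `param_cov` and `converged` set,
#'   plus attributes `loglik` and `iterations`.
#' @export
fit_2pl_em <- function(responses, quadrature = latent_quadrature(),
                       tol = 1e-4, max_iter = 500L) {
  U <- as.matrix(responses)
  if (!all(U %in% c(0, 1))) stop("responses must be binary 0/1")
  storage.mode(U) <- "double"
  J <- ncol(U); n <- nrow(U)
  pbar <- colMeans(U)
  degenerate <- which(pbar <= 0 | pbar >= 1)
  if (length(degenerate))
    stop("item(s) with all-0 or all-1 responses: ",
         paste(degenerate, collapse = ", "))
  th <- quadrature$nodes; w <- quadrature$weights; Q <- length(th)

  a <- rep(1, J)
  b <- -stats::qlogis(pbar)
  logw <- log(w)

  e_step <- function(a, b) {
    P <- two_pl_prob(a, b, th)             # J x Q
    LL <- U %*% log(P) + (1 - U) %*% log(1 - P)  # n x Q
    LL <- sweep(LL, 2, logw, "+")
    mx <- apply(LL, 1, max)
    post <- exp(LL - mx)
    rs <- rowSums(post)
    list(post = post / rs, loglik = sum(mx + log(rs)), P = P)
  }

  item_newton <- function(aj, bj, rbar, nbar) {
    # maximize sum_q rbar log p + (nbar - rbar) log(1-p), p = plogis(aj(th-bj))
    for (it in 1:25) {
      p <- stats::plogis(aj * (th - bj))
      resid <- rbar - nbar * p
      ga <- sum(resid * (th - bj))
      gb <- sum(resid) * (-aj)
      wq <- nbar * p * (1 - p)
      haa <- -sum(wq * (th - bj)^2)
      hbb <- -sum(wq) * aj^2
      hab <- sum(wq * (th - bj)) * aj - sum(resid)
      det <- haa * hbb - hab^2
      if (!is.finite(det) || abs(det) < 1e-300) break
      da <- (hbb * ga - hab * gb) / det
      db <- (haa * gb - hab * ga) / det
      step <- 1
      # damp steps that would leave the admissible region
      while (aj - step * da <= 1e-3 && step > 1e-6) step <- step / 2
      aj <- aj - step * da
      bj <- bj - step * db
      if (max(abs(step * c(da, db))) < 1e-9) break
    }
    c(aj, bj)
  }

  converged <- FALSE
  iter <- 0L
  ll <- -Inf
  for (iter in seq_len(max_iter)) {
    es <- e_step(a, b)
    nbar <- colSums(es$post)               # expected count per node
    Rbar <- crossprod(U, es$post)          # J x Q expected corrects
    a_new <- a; b_new <- b
    for (j in seq_len(J)) {
      upd <- item_newton(a[j], b[j], Rbar[j, ], nbar)
      a_new[j] <- upd[1]; b_new[j] <- upd[2]
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    ll <- es$loglik
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")

  # empirical Fisher information from per-person marginal scores
  es <- e_step(a, b)
  G <- matrix(0, n, 2L * J)
  for (j in seq_len(J)) {
    pj <- es$P[j, ]                                    # length Q
    Wj <- es$post * (matrix(U[, j], n, Q) -
                     matrix(pj, n, Q, byrow = TRUE))   # n x Q
    G[, j]     <- Wj %*% (th - b[j])                   # d/da_j
    G[, J + j] <- rowSums(Wj) * (-a[j])                # d/db_j
  }
  info <- crossprod(G)
  param_cov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    eg <- eigen(info, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    eg$vectors[, pos, drop = FALSE] %*%
      (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  })
  out <- item_parameter_set(a, b, param_cov, converged)
  attr(out, "loglik") <- ll
  attr(out, "iterations") <- iter
  out
}

# Lord-Wingersky recursion: distribution of the number-correct score given
# per-item probabilities p (length J); returns vector of length J + 1.
lw_recursion <- function(p) {
  f <- 1
  for (pj in p) f <- c(f * (1 - pj), 0) + c(0, f * pj)
  f
}

#' Model-implied score probabilities (Lord-Wingersky recursion)
#'
#' Computes the marginal number-correct score distribution implied by a 2-PL
#' item parameter set: the conditional score distribution at each quadrature
#' node by the Lord-Wingersky recursion, averaged over the N(0, 1) latent
#' weights.
#'
#' @param items An [item_parameter_set].
#' @param quadrature A [latent_quadrature] grid.
#' @param n Sample size to record on the resulting distribution.
#' @return A [score_distribution] on scores `0..J` (without covariance;
#'   see [score_prob_covariance]).
#' @export
score_probabilities <- function(items, quadrature = latent_quadrature(),
                                n = 1L) {
  J <- length(items$discriminations)
  if (J < 1) stop("at least 1 item required")
  P <- two_pl_prob(items$discriminations, items$difficulties,
                   quadrature$nodes)                  # J x Q
  probs <- rep(0, J + 1)
  for (q in seq_along(quadrature$nodes))
    probs <- probs + quadrature$weights[q] * lw_recursion(P[, q])
  probs <- probs / sum(probs)
  score_distribution(0:J, probs, n)
}

#' Delta-method covariance of model-implied score probabilities
#'
#' Propagates the item-parameter covariance through the score-probability
#' map: `cov = B param_cov B'` with `B` the Jacobian of the probabilities
#' with respect to the stacked `(a, b)` vector, obtained by central finite
#' differences with step `1e-5 * max(1, |param|)`.
#'
#' @param items An [item_parameter_set] with `param_cov`.
#' @param quadrature A [latent_quadrature] grid.
#' @return `(J+1) x (J+1)` covariance matrix.
#' @export
score_prob_covariance <- function(items, quadrature = latent_quadrature()) {
  if (is.null(items$param_cov))
    stop("item parameter covariance is missing")
  J <- length(items$discriminations)
  theta <- c(items$discriminations, items$difficulties)
  probs_of <- function(par) {
    it <- item_parameter_set(par[1:J], par[(J + 1):(2 * J)])
    score_probabilities(it, quadrature)$probs
  }
  B <- matrix(0, J + 1, 2 * J)
  for (k in seq_len(2 * J)) {
    hstep <- 1e-5 * max(1, abs(theta[k]))
    up <- theta; up[k] <- up[k] + hstep
    dn <- theta; dn[k] <- dn[k] - hstep
    B[, k] <- (probs_of(up) - probs_of(dn)) / (2 * hstep)
  }
  cov <- B %*% items$param_cov %*% t(B)
  (cov + t(cov)) / 2
}

#' Score distribution from IRT presmoothing
#'
#' Convenience wrapper: fit the 2-PL, compute model-implied score
#' probabilities and their delta-method covariance.
#'
#' @inheritParams fit_2pl_em
#' @return A [score_distribution] with covariance attached; the fitted
#'   [item_parameter_set] is available as attribute `items`.
#' @export
irt_presmooth <- function(responses, quadrature = latent_quadrature(),
                          tol = 1e-4, max_iter = 500L) {
  fit <- fit_2pl_em(responses, quadrature, tol, max_iter)
  sd0 <- score_probabilities(fit, quadrature, n = nrow(responses))
  cov <- score_prob_covariance(fit, quadrature)
  out <- score_distribution(sd0$scores, sd0$probs, nrow(responses), cov)
  attr(out, "items") <- fit
  out
}
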