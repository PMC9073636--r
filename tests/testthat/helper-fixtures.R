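# shared fixtures and small independent oracles

# a fixed 6-point distribution with unequal probabilities
toy_dist <- function(n = 1000L) {
  counts <- c(40, 180, 310, 260, 150, 60)
  multinomial_distribution(0:5, counts * (n / sum(counts)))
}

random_dist <- function(J, seed, n = 1000L, min_p = 0.02) {
  set.seed(seed)
  p <- runif(J) + min_p
  p <- p / sum(p)
  score_distribution(0:(J - 1), p, n,
                     cov = (diag(p) - tcrossprod(p)) / n)
}

# term-by-term scalar-call kernel CDF/pdf oracle (independent of the
# vectorized implementation)
oracle_cdf <- function(scores, probs, h, x) {
  mu <- sum(scores * probs)
  s2 <- sum((scores - mu)^2 * probs)
  a <- sqrt(s2 / (s2 + h^2))
  tot <- 0
  for (j in seq_along(scores))
    tot <- tot + probs[j] * pnorm((x - a * scores[j] - (1 - a) * mu) / (a * h))
  tot
}

oracle_pdf <- function(scores, probs, h, x) {
  mu <- sum(scores * probs)
  s2 <- sum((scores - mu)^2 * probs)
  a <- sqrt(s2 / (s2 + h^2))
  tot <- 0
  for (j in seq_along(scores))
    tot <- tot + probs[j] * dnorm((x - a * scores[j] - (1 - a) * mu) / (a * h))
  tot / (a * h)
}

# free-vector probability replacement (mirrors the internal helper; used to
# build finite-difference oracles in r)
fd_dist <- function(dist, probs) {
  structure(list(scores = dist$scores, probs = probs, n = dist$n, cov = NULL),
            class = "score_distribution")
}

# precise PEN1 re-minimization: root of the central-difference slope of
# pen1 itself (independent of the analytic derivative path)
reminimize_pen1 <- function(dist, near, width = 0.05) {
  slope <- function(t) (pen1(dist, t + 1e-5) - pen1(dist, t - 1e-5)) / 2e-5
  uniroot(slope, c(near - width, near + width), tol = 1e-13)$root
}

# deterministic 2-PL response sample used across IRT tests
fixture_2pl <- function(J = 20, n = 4000, seed = 42,
                        b_mean = 0, a = NULL, b = NULL) {
  set.seed(seed)
  if (is.null(a)) a <- runif(J, 0.5, 2)
  if (is.null(b)) b <- rnorm(J, b_mean, 1)
  items <- item_parameter_set(a, b)
  list(items = items, responses = generate_responses(items, n))
}
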