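test_that("CDF probability gradient matches finite differences", {
  set.seed(201)
  for (rep in 1:4) {
    d <- random_dist(sample(6:15, 1), seed = 300 + rep)
    h <- runif(1, 0.2, 1.2)
    cont <- continuize(d, h)
    for (x in runif(5, 0, max(d$scores))) {
      eps <- 1e-6
      fd <- vapply(seq_along(d$probs), function(j) {
        up <- d$probs; up[j] <- up[j] + eps
        dn <- d$probs; dn[j] <- dn[j] - eps
        (kernel_cdf(continuize(fd_dist(d, up), h), x) -
           kernel_cdf(continuize(fd_dist(d, dn), h), x)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(fd - cdf_prob_gradient(cont, x))), 1e-6)
    }
  }
})

test_that("two-point CDF probability gradient agrees with scalar arithmetic", {
  d <- score_distribution(c(0, 1), c(0.5, 0.5), 100)
  h <- 0.4
  cont <- continuize(d, h)
  x <- 0.3
  mu <- 0.5; s2 <- 0.25
  a <- sqrt(s2 / (s2 + h^2))
  R <- (x - a * c(0, 1) - (1 - a) * mu) / (a * h)
  z <- (c(0, 1) - mu) / sqrt(s2)
  M <- 0.5 * (x - mu) * (1 - a^2) * z^2 + (1 - a) * c(0, 1)
  f <- sum(0.5 * dnorm(R)) / (a * h)
  expect_equal(cdf_prob_gradient(cont, x), pnorm(R) - M * f,
               tolerance = 1e-12)
})

test_that("classical SEE: zero covariance, root-N scaling, numerical delta", {
  dx <- random_dist(9, 401, n = 1000)
  dy <- random_dist(9, 402, n = 1000)
  cx <- continuize(dx, 0.5)
  cy <- continuize(dy, 0.6)
  xs <- 2:6
  Sigma0 <- matrix(0, 18, 18)
  expect_equal(max(see_original(cx, cy, Sigma0, xs)), 0)

  Sigma <- gkequate:::block_diag(dx$cov, dy$cov)
  see_n <- see_original(cx, cy, Sigma, xs)
  see_4n <- see_original(cx, cy, Sigma / 4, xs)
  expect_equal(as.numeric(see_n / see_4n), rep(2, length(xs)),
               tolerance = 1e-6)

  # end-to-end numerical delta method with bandwidths held fixed
  eps <- 1e-6
  for (x in xs) {
    grad <- numeric(18)
    for (j in 1:9) {
      up <- dx$probs; up[j] <- up[j] + eps
      dn <- dx$probs; dn[j] <- dn[j] - eps
      grad[j] <- (equate_score(continuize(fd_dist(dx, up), 0.5), cy, x) -
                    equate_score(continuize(fd_dist(dx, dn), 0.5), cy, x)) /
        (2 * eps)
    }
    for (k in 1:9) {
      up <- dy$probs; up[k] <- up[k] + eps
      dn <- dy$probs; dn[k] <- dn[k] - eps
      grad[9 + k] <- (equate_score(cx, continuize(fd_dist(dy, up), 0.6), x) -
                        equate_score(cx, continuize(fd_dist(dy, dn), 0.6), x)) /
        (2 * eps)
    }
    see_num <- sqrt(drop(grad %*% Sigma %*% grad))
    expect_equal(see_original(cx, cy, Sigma, x)[1], see_num,
                 tolerance = 1e-5)
  }
})

test_that("PEN1 second derivatives match naive central differences", {
  for (seed in c(501, 502)) {
    d <- random_dist(10, seed)
    h <- as.numeric(suppressWarnings(select_bandwidth(d)))
    cd <- pen1_cross_derivatives(d, h)
    expect_gt(cd$d2_dh2, 0)

    e <- 1e-4
    fd_h2 <- (pen1(d, h + e) - 2 * pen1(d, h) + pen1(d, h - e)) / e^2
    expect_equal(cd$d2_dh2, fd_h2, tolerance = 1e-4 * abs(fd_h2))

    fd_hr <- vapply(seq_along(d$probs), function(j) {
      pj <- function(dp, dh) {
        p <- d$probs; p[j] <- p[j] + dp
        pen1(fd_dist(d, p), h + dh)
      }
      (pj(e, e) - pj(e, -e) - pj(-e, e) + pj(-e, -e)) / (4 * e^2)
    }, numeric(1))
    expect_lt(max(abs(cd$d2_dhdr - fd_hr)),
              1e-4 * max(abs(fd_hr)))
  }
})

test_that("implicit bandwidth gradient predicts re-minimized bandwidths", {
  d <- random_dist(12, 601)
  h <- as.numeric(suppressWarnings(select_bandwidth(d)))
  h <- reminimize_pen1(d, h)
  g <- bandwidth_gradient(d, h)
  set.seed(602)
  for (i in 1:20) {
    delta <- rnorm(12); delta <- delta - mean(delta)
    delta <- 1e-5 * delta / sqrt(sum(delta^2))
    d2 <- fd_dist(d, d$probs + delta)
    h2 <- reminimize_pen1(d2, h)
    pred <- sum(g * delta)
    expect_lt(abs((h2 - h) - pred), 0.01 * max(abs(pred), 1e-9))
  }
  # null perturbation moves nothing
  expect_equal(reminimize_pen1(fd_dist(d, d$probs), h), h, tolerance = 1e-10)
})

test_that("bandwidth gradient respects distribution symmetry", {
  p <- c(0.05, 0.15, 0.30, 0.30, 0.15, 0.05)
  d <- score_distribution(0:5, p, 1000)
  h <- as.numeric(suppressWarnings(select_bandwidth(d)))
  g <- bandwidth_gradient(d, h)
  expect_equal(g, rev(g), tolerance = 1e-6 * max(abs(g)))
  # pure function of (probs, h): identical on a rebuilt copy
  g2 <- bandwidth_gradient(score_distribution(0:5, p, 77), h)
  expect_identical(g, g2)
})

test_that("bandwidth SE scales as the delta method requires", {
  d <- toy_dist(1000)
  h <- as.numeric(suppressWarnings(select_bandwidth(d)))
  expect_equal(bandwidth_se(d, h, matrix(0, 6, 6))$se, 0)
  se_n <- bandwidth_se(d, h, d$cov)$se
  se_4n <- bandwidth_se(d, h, d$cov / 4)$se
  expect_equal(se_n / se_4n, 2, tolerance = 1e-8)
})

test_that("equating bandwidth derivatives match finite differences", {
  dx <- random_dist(10, 701)
  dy <- random_dist(10, 702)
  hx <- 0.55; hy <- 0.45
  cx <- continuize(dx, hx)
  cy <- continuize(dy, hy)
  set.seed(703)
  eps <- 1e-6
  for (x in runif(20, 1, 8)) {
    an <- equate_bandwidth_gradient(cx, cy, x)
    fd_x <- (equate_score(continuize(dx, hx + eps), cy, x) -
               equate_score(continuize(dx, hx - eps), cy, x)) / (2 * eps)
    fd_y <- (equate_score(cx, continuize(dy, hy + eps), x) -
               equate_score(cx, continuize(dy, hy - eps), x)) / (2 * eps)
    expect_lt(abs(an[["de_dhx"]] - fd_x), 1e-6)
    expect_lt(abs(an[["de_dhy"]] - fd_y), 1e-6)
  }
})

test_that("bandwidth derivatives vanish or cancel under symmetry", {
  # identical forms at the common median: equal bandwidth shifts cancel
  d <- toy_dist()
  cont <- continuize(d, 0.5)
  med <- gkequate:::invert_kernel_cdf(cont, 0.5)
  an <- equate_bandwidth_gradient(cont, cont, med)
  expect_lt(abs(sum(an)), 1e-8)

  # symmetric X: its CDF at the center does not move with h
  ps <- c(0.05, 0.15, 0.3, 0.3, 0.15, 0.05)
  ds <- score_distribution(0:5, ps, 100)
  cs <- continuize(ds, 0.6)
  dy <- continuize(random_dist(8, 704), 0.5)
  an2 <- equate_bandwidth_gradient(cs, dy, cs$mu)
  expect_lt(abs(an2[["de_dhx"]]), 1e-10)
})

test_that("modified SEE dominates the classical SEE and vanishes with it", {
  for (seed in c(801, 802, 803)) {
    dx <- random_dist(11, seed, n = 1000)
    dy <- random_dist(11, seed + 50, n = 1000)
    hx <- reminimize_pen1(dx, as.numeric(suppressWarnings(select_bandwidth(dx))))
    hy <- reminimize_pen1(dy, as.numeric(suppressWarnings(select_bandwidth(dy))))
    cx <- continuize(dx, hx)
    cy <- continuize(dy, hy)
    Sigma <- gkequate:::block_diag(dx$cov, dy$cov)
    xs <- dx$scores
    so <- as.numeric(see_original(cx, cy, Sigma, xs))
    sm <- as.numeric(see_modified(cx, cy, Sigma, xs))
    expect_true(all(sm >= so - 1e-12))

    expect_equal(max(see_modified(cx, cy, Sigma * 0, xs)), 0)

    # the gap closes as the covariance shrinks
    gap1 <- mean(sm - so)
    sm_small <- as.numeric(see_modified(cx, cy, Sigma / 100, xs))
    so_small <- as.numeric(see_original(cx, cy, Sigma / 100, xs))
    expect_lt(mean(sm_small - so_small), gap1 / 9)
  }
})
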