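#' Simulation study configuration
#'
#' Conditions of the Monte Carlo design: two 2-PL test forms with
#' discriminations drawn from U(0.5, 2) and difficulties from N(-0.25, 1)
#' (form X) and N(+0.25, 1) (form Y), equivalent-groups sampling from a
#' standard-normal population, and either raw multinomial or 2-PL IRT
#' presmoothing of each replication's scores.
#'
#' @param n_items Test length (each form); 20, 40 and 80 are the canonical
#'   conditions.
#' @param n_examinees Sample size per form (1000, 4000 and 16000 canonical).
#' @param n_reps Number of Monte Carlo replications (at least 2).
#' @param seed Master seed; every source of randomness derives from it.
#' @param presmoothing `"multinomial"` or `"irt2pl"`.
#' @param discrimination_range U(lo, hi) range for slopes.
#' @param difficulty_mean_x,difficulty_mean_y Means of the N(., 1)
#'   difficulty distributions for the two forms.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_items = 20L, n_examinees = 1000L,
                              n_reps = 500L, seed = 1L,
                              presmoothing = c("multinomial", "irt2pl"),
                              discrimination_range = c(0.5, 2),
                              difficulty_mean_x = -0.25,
                              difficulty_mean_y = 0.25) {
  presmoothing <- match.arg(presmoothing)
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (n_items < 2 || n_examinees < 1) stop("invalid condition sizes")
  structure(
    list(n_items = as.integer(n_items),
         n_examinees = as.integer(n_examinees),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         presmoothing = presmoothing,
         discrimination_range = discrimination_range,
         difficulty_mean_x = difficulty_mean_x,
         difficulty_mean_y = difficulty_mean_y),
    class = "simulation_config"
  )
}

#' Draw a pair of test forms
#'
#' Item parameters are drawn once per study and held fixed across
#' replications: slopes from U(0.5, 2) for both forms, difficulties from
#' N(-0.25, 1) for form X and N(+0.25, 1) for form Y (form X is the
#' slightly easier form).
#'
#' @param config A [simulation_config].
#' @param seed Seed for the draw (defaults to the config seed).
#' @return List with [item_parameter_set]s `x` and `y`.
#' @export
generate_test_forms <- function(config, seed = config$seed) {
  set.seed(seed)
  J <- config$n_items
  lo <- config$discrimination_range[1]
  hi <- config$discrimination_range[2]
  x <- item_parameter_set(stats::runif(J, lo, hi),
                          stats::rnorm(J, config$difficulty_mean_x, 1))
  y <- item_parameter_set(stats::runif(J, lo, hi),
                          stats::rnorm(J, config$difficulty_mean_y, 1))
  list(x = x, y = y)
}

#' Simulate 2-PL item responses
#'
#' Latent traits are drawn i.i.d. N(0, 1) and responses as Bernoulli with
#' probability `plogis(a_j (theta_i - b_j))`.
#'
#' @param items An [item_parameter_set].
#' @param n Number of examinees.
#' @param seed Optional seed.
#' @return `n x J` binary matrix.
#' @export
generate_responses <- function(items, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stop("n must be positive")
  theta <- stats::rnorm(n)
  a <- items$discriminations; b <- items$difficulties
  P <- stats::plogis(outer(theta, a) - matrix(a * b, n, length(a),
                                              byrow = TRUE))
  (matrix(stats::runif(n * length(a)), n) < P) + 0L
}

# one replication of the pipeline; returns a list of results or a condition
run_replication <- function(config, forms, pop, rep_seed) {
  set.seed(rep_seed)
  if (config$presmoothing == "multinomial") {
    cx <- stats::rmultinom(1, config$n_examinees, pop$r$probs)[, 1]
    cy <- stats::rmultinom(1, config$n_examinees, pop$s$probs)[, 1]
    dist_x <- multinomial_distribution(pop$r$scores, cx)
    dist_y <- multinomial_distribution(pop$s$scores, cy)
    presmooth_ok <- TRUE
  } else {
    ux <- generate_responses(forms$x, config$n_examinees)
    uy <- generate_responses(forms$y, config$n_examinees)
    dist_x <- suppressWarnings(irt_presmooth(ux))
    dist_y <- suppressWarnings(irt_presmooth(uy))
    presmooth_ok <- attr(dist_x, "items")$converged &&
      attr(dist_y, "items")$converged
  }
  res <- suppressWarnings(kernel_equate(dist_x, dist_y))
  ok <- presmooth_ok && res$h_x_interior && res$h_y_interior &&
    all(is.finite(c(res$equated, res$h_x, res$h_y,
                    res$se_h_x, res$se_h_y,
                    res$see_original, res$see_modified)))
  list(ok = ok, presmooth_ok = presmooth_ok, res = res)
}

#' Run the Monte Carlo study
#'
#' Per replication: sample equivalent-groups data, presmooth both forms,
#' select PEN1 bandwidths, equate, and compute the analytic standard errors
#' (classical and modified) and the bandwidth standard errors. Aggregates
#' compare the mean analytic quantities with their Monte Carlo counterparts
#' (sample SDs across replications) and report 95% confidence-interval
#' coverage against the population equating function — the equating of the
#' model-implied population score distributions using their own
#' PEN1-optimal bandwidths.
#'
#' @param config A [simulation_config].
#' @param progress Print a progress line every `progress` replications
#'   (0 = silent).
#' @return Object of class `simulation_report`: per-score table
#'   (`asee`, `asee_mod`, `mcsee`, coverage by method), bandwidth summary
#'   (`ase` vs `mcse` per form), convergence rate, and the interior-score
#'   aggregates. Failed replications are recorded and excluded from
#'   aggregates.
#' @export
run_study <- function(config, progress = 0L) {
  set.seed(config$seed)
  rep_seeds <- sample.int(2^31 - 2, config$n_reps)
  forms <- generate_test_forms(config)

  pop <- list(r = score_probabilities(forms$x),
              s = score_probabilities(forms$y))
  h0x <- suppressWarnings(select_bandwidth(pop$r))
  h0y <- suppressWarnings(select_bandwidth(pop$s))
  cont0x <- continuize(pop$r, as.numeric(h0x))
  cont0y <- continuize(pop$s, as.numeric(h0y))
  scores <- pop$r$scores
  true_eq <- equate_score(cont0x, cont0y, scores)

  n_sc <- length(scores)
  nr <- config$n_reps
  H <- matrix(NA_real_, nr, 2)
  SEH <- matrix(NA_real_, nr, 2)
  EQ <- matrix(NA_real_, nr, n_sc)
  SO <- matrix(NA_real_, nr, n_sc)
  SM <- matrix(NA_real_, nr, n_sc)
  ok <- logical(nr)
  failures <- character(0)

  for (i in seq_len(nr)) {
    rep_out <- tryCatch(run_replication(config, forms, pop, rep_seeds[i]),
                        error = function(e) e)
    if (inherits(rep_out, "error")) {
      failures <- c(failures, sprintf("rep %d: %s", i, conditionMessage(rep_out)))
      next
    }
    ok[i] <- rep_out$ok
    r <- rep_out$res
    H[i, ] <- c(r$h_x, r$h_y)
    SEH[i, ] <- c(r$se_h_x, r$se_h_y)
    EQ[i, ] <- r$equated
    SO[i, ] <- r$see_original
    SM[i, ] <- r$see_modified
    if (progress > 0 && i %% progress == 0)
      message("replication ", i, "/", nr)
  }

  use <- which(ok)
  if (length(use) < 2) stop("fewer than 2 successful replications")
  cover <- function(see_mat) {
    inside <- abs(EQ[use, , drop = FALSE] -
                    matrix(true_eq, length(use), n_sc, byrow = TRUE)) <=
      stats::qnorm(0.975) * see_mat[use, , drop = FALSE]
    colMeans(inside)
  }
  per_score <- data.frame(
    score = scores,
    true_equated = true_eq,
    mean_equated = colMeans(EQ[use, , drop = FALSE]),
    asee = colMeans(SO[use, , drop = FALSE]),
    asee_mod = colMeans(SM[use, , drop = FALSE]),
    mcsee = apply(EQ[use, , drop = FALSE], 2, stats::sd),
    coverage_original = cover(SO),
    coverage_modified = cover(SM)
  )
  interior <- seq_len(n_sc) > 2 & seq_len(n_sc) <= n_sc - 2
  bandwidths <- data.frame(
    form = c("X", "Y"),
    h_population = c(as.numeric(h0x), as.numeric(h0y)),
    mean_h = colMeans(H[use, , drop = FALSE]),
    ase = colMeans(SEH[use, , drop = FALSE]),
    mcse = apply(H[use, , drop = FALSE], 2, stats::sd)
  )
  structure(
    list(config = config, per_score = per_score, bandwidths = bandwidths,
         interior = interior,
         convergence_rate = mean(ok),
         n_success = length(use), n_failed_hard = length(failures),
         failures = failures,
         rep_seeds = rep_seeds,
         summary = data.frame(
           ase_x = bandwidths$ase[1], mcse_x = bandwidths$mcse[1],
           ase_y = bandwidths$ase[2], mcse_y = bandwidths$mcse[2],
           mean_abs_diff_asee = mean(abs(per_score$asee - per_score$mcsee)[interior]),
           mean_abs_diff_asee_mod = mean(abs(per_score$asee_mod - per_score$mcsee)[interior]),
           coverage_original_interior = mean(per_score$coverage_original[interior]),
           coverage_modified_interior = mean(per_score$coverage_modified[interior]),
           coverage_original_all = mean(per_score$coverage_original),
           coverage_modified_all = mean(per_score$coverage_modified),
           convergence_rate = mean(ok))),
    class = "simulation_report"
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Monte Carlo study: %d items, N = %d per form, %d reps, %s presmoothing\n",
    cfg$n_items, cfg$n_examinees, cfg$n_reps, cfg$presmoothing))
  cat(sprintf("  convergence rate: %.1f%% (%d hard failures)\n",
              100 * x$convergence_rate, x$n_failed_hard))
  cat(sprintf("  bandwidth X: ASE %.5f vs MCSE %.5f;  Y: ASE %.5f vs MCSE %.5f\n",
              x$summary$ase_x, x$summary$mcse_x,
              x$summary$ase_y, x$summary$mcse_y))
  cat(sprintf("  interior coverage: original %.3f, modified %.3f\n",
              x$summary$coverage_original_interior,
              x$summary$coverage_modified_interior))
  invisible(x)
}
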