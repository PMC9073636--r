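#' Construct a discrete score distribution
#'
#' A `score_distribution` holds the possible number-correct score values of a
#' test form, the probability of each score in the target population, the
#' sample size behind the estimate, and the asymptotic covariance matrix of
#' the probability estimator (on the sampling scale, i.e. `Var(r-hat)`).
#'
#' @param scores Strictly increasing numeric vector of score values.
#' @param probs Probability vector of the same length; must sum to 1.
#' @param n Positive integer sample size.
#' @param cov Symmetric, positive semi-definite covariance matrix of the
#'   estimated probabilities. May be `NULL` when no sampling variability is
#'   attached (e.g. a population distribution).
#' @return An object of class `score_distribution`.
#' @export
score_distribution <- function(scores, probs, n, cov = NULL) {
  scores <- as.numeric(scores)
  probs <- as.numeric(probs)
  if (length(scores) != length(probs))
    stop("`scores` and `probs` must have the same length")
  if (any(diff(scores) <= 0))
    stop("`scores` must be strictly increasing")
  if (any(probs < -1e-12))
    stop("`probs` must be nonnegative")
  probs <- pmax(probs, 0)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must sum to 1")
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (nrow(cov) != length(probs) || ncol(cov) != length(probs))
      stop("`cov` must be J x J")
    if (max(abs(cov - t(cov))) > 1e-10 * max(1, max(abs(cov))))
      stop("`cov` must be symmetric")
    cov <- (cov + t(cov)) / 2
  }
  structure(
    list(scores = scores, probs = probs, n = as.integer(n), cov = cov),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Discrete score distribution:", length(x$scores), "score points on [",
      min(x$scores), ",", max(x$scores), "], n =", x$n, "\n")
  m <- score_moments(x)
  cat(sprintf("  mean = %.4f, sd = %.4f, cov %s\n", m$mu, sqrt(m$sigma2),
              if (is.null(x$cov)) "absent" else "attached"))
  invisible(x)
}

#' Multinomial score distribution from observed frequencies
#'
#' Estimates the score probabilities as relative frequencies and attaches
#' the standard multinomial covariance `(diag(p) - p p') / N`.
#'
#' @param score_values Strictly increasing vector of score values.
#' @param counts Nonnegative integer vector of observed frequencies.
#' @return A [score_distribution].
#' @export
multinomial_distribution <- function(score_values, counts) {
  if (length(score_values) != length(counts))
    stop("`score_values` and `counts` must have the same length")
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("empty sample: all counts are zero")
  p <- counts / n
  cov <- (diag(p) - tcrossprod(p)) / n
  score_distribution(score_values, p, n, cov)
}

#' First two moments of a discrete score distribution
#'
#' @param dist A [score_distribution].
#' @return List with elements `mu` (mean) and `sigma2` (variance).
#' @export
score_moments <- function(dist) {
  mu <- sum(dist$scores * dist$probs)
  sigma2 <- sum((dist$scores - mu)^2 * dist$probs)
  list(mu = mu, sigma2 = sigma2)
}

#' Read a score frequency table from CSV
#'
#' Expects a header row and two columns `score,count`; scores need not be
#' contiguous.
#'
#' @param path Path to the CSV file.
#' @return A [score_distribution] with multinomial covariance.
#' @export
read_score_frequencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("score", "count") %in% names(df)))
    stop("frequency CSV must have columns `score` and `count`: ", path)
  bad <- which(!is.finite(df$score) | !is.finite(df$count) | df$count < 0)
  if (length(bad))
    stop("malformed frequency rows (1-based, excluding header): ",
         paste(bad, collapse = ", "), " in ", path)
  df <- df[order(df$score), ]
  multinomial_distribution(df$score, df$count)
}

#' Read a binary item-response matrix from CSV
#'
#' Persons as rows, items as columns, cells in `{0, 1}`, header row of item
#' identifiers.
#'
#' @param path Path to the CSV file.
#' @return Integer matrix with item identifiers as column names.
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!all(m %in% c(0L, 1L)))
    stop("response matrix must contain only 0/1 cells: ", path)
  storage.mode(m) <- "integer"
  m
}
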