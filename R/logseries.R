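#' Zero-truncated logseries probability mass
#'
#' Fisher's logseries assigns a species abundance `n >= 1` probability
#' `p(n) = -x^n / (n * log(1 - x))` with `0 < x < 1`.
#'
#' @param n Positive integer abundances.
#' @param x Logseries parameter in (0, 1).
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities.
#' @export
dlogseries <- function(n, x, log = FALSE) {
  stopifnot(x > 0, x < 1)
  lp <- n * base::log(x) - base::log(n) - base::log(-log1p(-x))
  if (log) lp else exp(lp)
}

#' Sample abundances from the logseries
#'
#' Inversion sampling on the cumulative mass, vectorised over draws.
#'
#' @param S Number of species to draw.
#' @param x Logseries parameter in (0, 1).
#' @return Integer vector of `S` abundances.
#' @export
rlogseries <- function(S, x) {
  stopifnot(x > 0, x < 1)
  u <- runif(S)
  # cumulative mass; extend the table adaptively for heavy tails
  nmax <- 1024L
  repeat {
    cm <- cumsum(dlogseries(seq_len(nmax), x))
    if (cm[nmax] > max(u) || nmax > 2^26) break
    nmax <- nmax * 4L
  }
  findInterval(u, cm) + 1L
}

#' Fit Fisher's logseries by maximum likelihood
#'
#' The maximum-likelihood `x` for a zero-truncated logseries solves the
#' classical Fisher relationship `S = alpha * log(1 + N/alpha)` with
#' `x = N/(N + alpha)`; the root is bracketed and solved numerically.
#' The maximised log-likelihood is
#' `N log x - sum(log n_i) - S log(-log(1 - x))`.
#'
#' @param abundance Vector of positive integer abundances with at least
#'   two species and `N > S` (an all-singleton vector has no interior
#'   maximum and raises an error).
#' @return An object of class `logseries_fit` with elements `x`,
#'   `fisher_alpha`, `logL`, `k` (= 1), `S`, `N`.
#' @examples
#' fit <- fit_logseries(c(1, 1, 1, 2, 186, 306, 436))
#' glance(fit)  # AICc 67.16
#' @export
fit_logseries <- function(abundance) {
  abundance <- check_abundance(abundance)
  S <- length(abundance)
  N <- sum(abundance)
  if (S < 2) abort("logseries fit needs at least 2 species",
                   class = "rarecomm_value_error")
  if (N <= S) {
    abort("logseries degenerate: N must exceed S (vector of singletons has no interior MLE)",
          class = "rarecomm_value_error")
  }
  alpha <- uniroot(function(a) a * log(1 + N / a) - S,
                   lower = 1e-10, upper = 1e10, tol = 1e-12)$root
  x <- N / (N + alpha)
  logL <- N * log(x) - sum(log(abundance)) - S * log(-log1p(-x))
  structure(
    list(x = x, fisher_alpha = alpha, logL = logL, k = 1L, S = S, N = N,
         model = "logseries"),
    class = c("logseries_fit", "sad_fit")
  )
}
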