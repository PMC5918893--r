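#' Poisson-lognormal species probability
#'
#' The compound probability `P(n; mu, sigma) = integral over lambda of
#' Poisson(n; lambda) * Lognormal(lambda; mu, sigma)`, evaluated by
#' adaptive quadrature on the log-lambda scale.  The integrand is peaked
#' near `log n` when `n` is large and near the lognormal body otherwise;
#' the integral is split at the integrand's maximum so that the adaptive
#' rule cannot step over a narrow peak, and rescaled by that maximum for
#' numerical stability.
#'
#' @param n Non-negative integer counts.
#' @param mu Lognormal location (of log lambda).
#' @param sigma Lognormal scale, positive.
#' @param log Return log probabilities?
#' @param truncated If `TRUE`, condition on `n >= 1` (the zero-truncated
#'   form used to model observed species).
#' @return Numeric vector of (log) probabilities.
#' @export
dpln <- function(n, mu, sigma, log = FALSE, truncated = FALSE) {
  stopifnot(sigma > 0, all(n >= 0), all(n == floor(n)))
  lp <- vapply(n, pln_logprob1, numeric(1), mu = mu, sigma = sigma)
  if (truncated) {
    l0 <- pln_logprob1(0, mu, sigma)
    lp <- lp - log1p(-exp(l0))
  }
  if (log) lp else exp(lp)
}

pln_logprob1 <- function(k, mu, sigma) {
  lg <- function(y) dnorm(y, mu, sigma, log = TRUE) + dpois(k, exp(y), log = TRUE)
  lo <- mu - 15 * sigma
  hi <- mu + 15 * sigma
  if (k >= 1) {
    lo <- min(lo, log(k) - 12)
    hi <- max(hi, log(k) + 12)
  }
  pk <- optimize(lg, c(lo, hi), maximum = TRUE, tol = 1e-10)
  m <- pk$objective
  if (!is.finite(m)) return(-Inf)
  y0 <- pk$maximum
  # the log integrand is concave in y, so mass beyond a few dozen
  # Laplace-approximation standard deviations of the peak is negligible;
  # clipping to that window keeps the adaptive rule from overlooking a
  # spike that is narrow relative to the full support (tiny sigma, large n)
  curv <- 1 / sigma^2 + exp(min(y0, 700))
  halfwidth <- 40 / sqrt(curv)
  lo <- max(lo, y0 - halfwidth)
  hi <- min(hi, y0 + halfwidth)
  f <- function(y) exp(lg(y) - m)
  v <- integrate(f, lo, y0, rel.tol = 1e-12, subdivisions = 1000L)$value +
    integrate(f, y0, hi, rel.tol = 1e-12, subdivisions = 1000L)$value
  m + log(v)
}

#' Expected proportion of the PLN mass in a count range
#'
#' `E_Lognormal[ P(a <= Poisson(lambda) <= b) ]`, used to verify that the
#' per-count probabilities together with a tail term sum to one without
#' evaluating every count individually.
#'
#' @param a,b Integer count range (use `b = Inf` for an upper tail).
#' @param mu,sigma PLN parameters.
#' @return A probability.
#' @export
pln_mass <- function(a, b, mu, sigma) {
  f <- function(y) {
    lam <- exp(y)
    upper <- if (is.infinite(b)) 1 else ppois(b, lam)
    lowr <- if (a <= 0) 0 else ppois(a - 1, lam)
    dnorm(y, mu, sigma) * (upper - lowr)
  }
  integrate(f, mu - 15 * sigma, mu + 15 * sigma,
            rel.tol = 1e-12, subdivisions = 1000L)$value
}

#' Sample species abundances from the zero-truncated Poisson lognormal
#'
#' Draws `lambda ~ Lognormal(mu, sigma)` and `n ~ Poisson(lambda)`,
#' rejecting zeros (unobserved species).
#'
#' @param S Number of species.
#' @param mu,sigma PLN parameters.
#' @return Integer vector of `S` positive abundances.
#' @export
rpln <- function(S, mu, sigma) {
  out <- integer(0)
  while (length(out) < S) {
    lam <- rlnorm(2L * (S - length(out)) + 8L, mu, sigma)
    n <- rpois(length(lam), lam)
    out <- c(out, n[n > 0])
  }
  out[seq_len(S)]
}

#' Fit the zero-truncated Poisson lognormal by maximum likelihood
#'
#' Maximises `sum_i log[ P(n_i; mu, sigma) / (1 - P(0; mu, sigma)) ]` over
#' `(mu, log sigma)` with Nelder–Mead from a moment-based start (mean and
#' standard deviation of log abundances) plus several perturbed and
#' wide-dispersion starts, because the truncated-PLN surface is multimodal
#' for small species counts.  For some species-poor, strongly bimodal
#' vectors the truncated likelihood has no interior maximum at all: it
#' keeps rising along a ridge with `mu` decreasing and `sigma` growing.
#' The fit then reports the best point reached and flags it with
#' `boundary = TRUE` rather than pretending convergence to an MLE.
#'
#' @param abundance Vector of positive integer abundances, at least 3
#'   species (two parameters plus a small-sample AICc denominator).
#' @param starts Optional list of additional `(mu, log sigma)` starting
#'   points.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param multistart Use the full start battery? `FALSE` keeps only the
#'   moment-based start, which is much faster and adequate for
#'   well-behaved (e.g. simulated) data.
#' @return An object of class `pln_fit`: `mu`, `sigma`, `logL`, `k` (= 2),
#'   `S`, `N`, `convergence` (0 = every start converged), `boundary`.
#' @examples
#' \donttest{
#' fit <- fit_pln(c(3, 3, 5, 7, 9, 21, 50))
#' glance(fit)
#' }
#' @export
fit_pln <- function(abundance, starts = NULL, reltol = 1e-10,
                    multistart = TRUE) {
  abundance <- check_abundance(abundance)
  S <- length(abundance)
  if (S < 3) abort("PLN fit needs at least 3 species",
                   class = "rarecomm_value_error")
  # collapse duplicates: the likelihood only needs unique counts
  tab <- table(abundance)
  un <- as.numeric(names(tab))
  wt <- as.numeric(tab)
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    lp <- vapply(un, pln_logprob1, numeric(1), mu = mu, sigma = sigma)
    l0 <- pln_logprob1(0, mu, sigma)
    val <- -(sum(wt * lp) - S * log1p(-exp(l0)))
    if (!is.finite(val)) 1e10 else val
  }
  mu0 <- mean(log(abundance))
  s0 <- max(sd(log(abundance)), 0.5)
  start_list <- if (multistart) {
    list(c(mu0, log(s0)), c(mu0 - 2, log(2 * s0)), c(mu0 + 1, log(s0)),
         c(mu0, log(s0 / 2)), c(mu0 - 5, log(3 * s0)), c(-2, log(4)),
         c(mu0 - 10, log(4 * s0)))
  } else {
    list(c(mu0, log(s0)))
  }
  if (!is.null(starts)) start_list <- c(start_list, starts)
  best <- NULL
  codes <- integer(0)
  for (st in start_list) {
    o <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 3000)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    codes <- c(codes, o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    abort("PLN fit failed from every starting point",
          class = "rarecomm_fit_error")
  }
  mu <- best$par[1]
  sigma <- exp(best$par[2])
  boundary <- sigma > 8 || mu < mu0 - 10 * s0
  structure(
    list(mu = mu, sigma = sigma, logL = -best$value, k = 2L,
         S = S, N = sum(abundance),
         convergence = max(codes), boundary = boundary, model = "pln"),
    class = c("pln_fit", "sad_fit")
  )
}
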