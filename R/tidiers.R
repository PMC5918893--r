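#' @export
print.sad_fit <- function(x, ...) {
  cat(x$model, "fit: S =", x$S, ", N =", x$N, "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
logLik.sad_fit <- function(object, ...) {
  structure(object$logL, df = object$k, class = "logLik")
}

#' @rdname tidy
#' @title Tidy summaries of fitted SAD models
#' @description `tidy()` returns the estimated parameters, one per row;
#'   `glance()` returns a one-row model summary with `logL`, `k`, `S`,
#'   `N` and `AICc`.
#' @param x A fitted model from [fit_logseries()], [fit_pln()] or
#'   [fit_gambin()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.logseries_fit <- function(x, ...) {
  tibble::tibble(term = c("x", "fisher_alpha"),
                 estimate = c(x$x, x$fisher_alpha))
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.pln_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.gambin_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "max_octave"),
                 estimate = c(x$alpha, x$max_octave))
}

#' @rdname tidy
#' @exportS3Method generics::glance
glance.sad_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logL = x$logL, k = x$k, S = x$S,
                 N = x$N, AICc = aicc(x$logL, x$k, x$S))
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.tokeshi_test <- function(x, ...) {
  tibble::tibble(term = c("Pc", "Pl", "Pr"),
                 p.value = c(x$Pc, x$Pl, x$Pr),
                 class_tested = c(which.max(x$counts), x$left_class,
                                  x$right_class))
}

#' @rdname tidy
#' @exportS3Method generics::glance
glance.tokeshi_test <- function(x, ...) {
  tibble::tibble(S = x$S, k = x$k, Pc = x$Pc, Pl = x$Pl, Pr = x$Pr,
                 alpha_level = x$alpha_level,
                 classification = x$classification)
}
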