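#' Octave histogram of species abundance distributions
#'
#' Stacked octave histogram per assemblage, indigenous (endemic + native)
#' versus introduced species, with the abundance class range on the x
#' axis.
#'
#' @param x An assemblage tibble.
#' @return A ggplot object.
#' @examples
#' plot_sad(laurisilva_assemblage())
#' @export
plot_sad <- function(x) {
  dat <- deconstruct_sad(x) |>
    tidyr::pivot_longer(c("n_indigenous", "n_introduced"),
                        names_to = "layer", values_to = "n") |>
    dplyr::mutate(layer = ifelse(.data$layer == "n_indigenous",
                                 "indigenous", "introduced"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$octave, y = .data$n,
                                    fill = .data$layer)) +
    ggplot2::geom_col(colour = "grey25", linewidth = 0.2) +
    ggplot2::facet_wrap(~ island + taxon_group, scales = "free") +
    ggplot2::scale_fill_manual(values = c(indigenous = "darkgreen",
                                          introduced = "white")) +
    ggplot2::labs(x = "abundance octave (log2 class)",
                  y = "number of species", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Occupancy frequency distribution histogram
#'
#' Species counts per proportional occupancy class, with the introduced
#' species' contribution highlighted.
#'
#' @param x An assemblage tibble.
#' @param k Number of occupancy classes.
#' @return A ggplot object.
#' @examples
#' plot_ofd(laurisilva_assemblage())
#' @export
plot_ofd <- function(x, k = 10) {
  dat <- build_ofd(x, k = k, by_status = TRUE) |>
    tidyr::pivot_longer(c("n_indigenous", "n_introduced"),
                        names_to = "layer", values_to = "n") |>
    dplyr::mutate(layer = ifelse(.data$layer == "n_indigenous",
                                 "indigenous", "introduced"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$n,
                                    fill = .data$layer)) +
    ggplot2::geom_col(colour = "grey25", linewidth = 0.2) +
    ggplot2::facet_wrap(~ island + taxon_group, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq_len(k)) +
    ggplot2::scale_fill_manual(values = c(indigenous = "grey70",
                                          introduced = "darkgreen")) +
    ggplot2::labs(x = "occupancy class (proportional)",
                  y = "number of species", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gambin_fit <- function(object, ...) {
  obs <- tibble::tibble(octave = seq_along(object$octave_counts) - 1,
                        count = object$octave_counts)
  fitted <- tibble::tibble(
    octave = 0:object$max_octave,
    count = object$S * gambin_probs(object$alpha, object$max_octave,
                                    method = object$method))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$octave, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey25", linewidth = 0.2) +
    ggplot2::geom_point(data = fitted, colour = "red", size = 2) +
    ggplot2::geom_line(data = fitted, colour = "red") +
    ggplot2::labs(x = "abundance octave (log2 class)",
                  y = "number of species",
                  title = sprintf("gambin fit, alpha = %.2f", object$alpha)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tokeshi_test <- function(object, ...) {
  dat <- tibble::tibble(class = seq_along(object$counts),
                        count = object$counts)
  expected <- object$S / object$k
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey25", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = expected, linetype = 2, colour = "red") +
    ggplot2::scale_x_continuous(breaks = dat$class) +
    ggplot2::labs(x = "occupancy class", y = "number of species",
                  title = paste("Tokeshi classification:",
                                object$classification)) +
    ggplot2::theme_minimal()
}
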