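#' Plot a trajectory's composition over time
#'
#' Line plot of the four type fractions against time, a direct view of the
#' two stages of consensus formation: the fast equalization of the two
#' hypocrite types followed by the slow random walk to consensus.
#'
#' @param object a `cvm_trajectory` from [run_cvm()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cvm_trajectory <- function(object, ...) {
  N <- attr(object, "params")$N
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::any_of(c("n_Rb", "n_Br", "n_Rr", "n_Bb", "n_R")),
                        names_to = "type", values_to = "count") |>
    dplyr::mutate(fraction = .data$count / N)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$fraction,
                                     colour = .data$type)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "fraction of the group", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble-mean hypocrite-gap decay
#'
#' The ensemble mean of `|D(t)| = |rho_Rb - rho_Br|` on a log scale,
#' together with the theoretical exponential decay at rate `e + i`. A
#' straight line of slope `-(e + i)` confirms the equalization law; its
#' inverse is the equalization time.
#'
#' @param object a `cvm_ensemble` run with a time grid.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cvm_ensemble <- function(object, ...) {
  if (is.null(object$gap)) {
    stop("ensemble has no gap series; rerun run_ensemble() with a grid",
         call. = FALSE)
  }
  p <- object$params
  D0 <- p$ic$rho_Rb - p$ic$rho_Br
  df <- dplyr::filter(object$gap, .data$D_bar != 0)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = abs(.data$D_bar))) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "|mean hypocrite gap|") +
    ggplot2::theme_minimal()
  if (D0 != 0) {
    theo <- tibble(t = df$t,
                   D = abs(mean_gap(df$t, D0, p$rates)))
    gg <- gg + ggplot2::geom_line(data = theo,
                                  ggplot2::aes(x = .data$t, y = .data$D),
                                  linetype = "dashed")
  }
  gg
}

#' Plot the mean-field attractor curve
#'
#' The arch-shaped curve of hypocrite abundance against the frank-red
#' fraction onto which trajectories collapse during the first stage.
#'
#' @param rates a [rate_set()].
#' @param n number of curve points.
#' @return A ggplot object.
#' @export
plot_attractor <- function(rates, n = 201) {
  rates <- as_rate_set(rates)
  z <- seq(0, 1, length.out = n)
  df <- tibble(rho_Rr = z,
               rho_hyp = attractor_hypocrite_fraction(z, rates))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho_Rr, y = .data$rho_hyp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frank-red fraction",
                  y = "hypocrite fraction (each type)") +
    ggplot2::theme_minimal()
}
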