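#' Plot a trajectory
#'
#' Line plot of the four components against time, faceted with free vertical
#' scales (RISC runs orders of magnitude above the other components at the
#' reference rates, so a shared axis would flatten them).
#'
#' @param object An `rnai_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnai_trajectory
#' @export
autoplot.rnai_trajectory <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("S", "R", "C", "M")),
                        names_to = "component", values_to = "amount") |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("S", "R", "C", "M")))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$amount)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time", y = "amount (molecules)")
}

#' Plot an ensemble
#'
#' Spaghetti plot of replicates (thin, translucent) with the pointwise
#' ensemble mean overlaid, faceted by component.
#'
#' @param object An `rnai_ensemble`.
#' @param max_reps Plot at most this many replicates (the mean always uses
#'   all of them).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnai_ensemble
#' @export
autoplot.rnai_ensemble <- function(object, max_reps = 50, ...) {
  mom <- ensemble_moments(object)
  keep <- utils::head(unique(object$replicate), max_reps)
  long <- tibble::as_tibble(object) |>
    dplyr::filter(.data$replicate %in% keep) |>
    tidyr::pivot_longer(dplyr::all_of(c("S", "R", "C", "M")),
                        names_to = "component", values_to = "amount") |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("S", "R", "C", "M")))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$amount)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.2, linewidth = 0.2) +
    ggplot2::geom_line(data = mom,
                       ggplot2::aes(.data$t, .data$mean),
                       colour = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time", y = "amount (molecules)")
}

#' Plot a strong-convergence study
#'
#' Log-log plot of strong error against step size with the fitted power law.
#'
#' @param object An `rnai_order` from [rnai_strong_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnai_order
#' @export
autoplot.rnai_order <- function(object, ...) {
  ggplot2::ggplot(object$errors, ggplot2::aes(.data$dt, .data$error)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step size", y = "strong error",
                  title = sprintf("%s: fitted order %.2f",
                                  object$scheme, object$slope))
}
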