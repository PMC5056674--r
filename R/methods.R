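#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' @param x An `mph_sim`.
#' @param ... Unused.
#' @return Long tibble `time`, `series` (`d`, `l`, `total`), `conc`
#'   (ng/mL).
#' @method tidy mph_sim
#' @export
tidy.mph_sim <- function(x, ...) {
  x$plasma |>
    tidyr::pivot_longer(-"time", names_to = "series", values_to = "conc",
                        names_prefix = "conc_")
}

#' One-row summary of a simulation
#'
#' @param x An `mph_sim`.
#' @param ... Unused.
#' @return Tibble with Cmax/Tmax/AUC of the total-drug plasma curve, the
#'   terminal fate fractions, the hepatic oxidation share and the ledger
#'   balance.
#' @method glance mph_sim
#' @export
glance.mph_sim <- function(x, ...) {
  curve <- data.frame(time = x$plasma$time, conc = x$plasma$conc_total)
  pk <- cmax_tmax(curve)
  led <- x$ledger[nrow(x$ledger), ]
  tibble::tibble(
    cmax = pk$cmax, tmax = pk$tmax, auc = auc_trapezoid(curve),
    absorbed_pct = x$fate$absorbed_pct,
    fecal_solid_pct = x$fate$fecal_solid_pct,
    fecal_dissolved_pct = x$fate$fecal_dissolved_pct,
    oxidation_fraction = if (led$oxidation + led$hydrolysis > 0)
      led$oxidation / (led$oxidation + led$hydrolysis) else NA_real_,
    balance = led$balance
  )
}

#' @method tidy mph_population
#' @export
tidy.mph_population <- function(x, ...) x$band

#' @method glance mph_population
#' @export
glance.mph_population <- function(x, ...) {
  wide <- x$metric_summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd", "median"),
                       names_glue = "{metric}_{.value}")
  dplyr::bind_cols(wide, tibble::tibble(n = x$n, n_failed = x$n_failed))
}

#' @method tidy mph_nsc
#' @export
tidy.mph_nsc <- function(x, ...) {
  tibble::tibble(parameter = attr(x, "parameter"), time = x$time,
                 nsc = x$nsc)
}

#' @method glance mph_nsc
#' @export
glance.mph_nsc <- function(x, ...) {
  tibble::tibble(parameter = attr(x, "parameter"),
                 max_abs_nsc = attr(x, "max_abs_nsc"),
                 time_of_max = attr(x, "time_of_max"),
                 classification = attr(x, "classification"))
}

#' Plot a simulated plasma profile
#'
#' @param object An `mph_sim`.
#' @param ... Unused.
#' @return A ggplot: per-enantiomer and total plasma concentration vs time.
#' @method autoplot mph_sim
#' @export
autoplot.mph_sim <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$conc,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a population simulation band
#'
#' @param object An `mph_population`.
#' @param ... Unused.
#' @return A ggplot: pointwise mean with the 90% interval ribbon.
#' @method autoplot mph_population
#' @export
autoplot.mph_population <- function(object, ...) {
  object$band |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)") +
    ggplot2::theme_minimal()
}

#' @method autoplot mph_nsc
#' @export
autoplot.mph_nsc <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$nsc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Normalized sensitivity coefficient",
                  subtitle = attr(object, "parameter")) +
    ggplot2::theme_minimal()
}

#' Overlay a predicted curve on observed data with the two-fold band
#'
#' @param predicted Data frame `time`, `conc` (model curve).
#' @param observed Data frame `time`, `mean` (and optionally `sd`).
#' @return A ggplot: prediction line, shaded two-fold envelope, observed
#'   points (with SD error bars when available).
#' @export
plot_overlay <- function(predicted, observed) {
  p <- ggplot2::ggplot(predicted, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conc / 2,
                                      ymax = .data$conc * 2), alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$conc)) +
    ggplot2::geom_point(data = observed,
                        ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)") +
    ggplot2::theme_minimal()
  if ("sd" %in% names(observed) && any(!is.na(observed$sd))) {
    p <- p + ggplot2::geom_errorbar(
      data = observed,
      ggplot2::aes(x = .data$time, ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      width = 0.15, inherit.aes = FALSE)
  }
  p
}
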