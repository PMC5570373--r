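#' Tidy a simulation into long format
#'
#' @param x a `spine_sim`.
#' @param series which trace family to return.
#' @param ... unused.
#' @return Long tibble `time`, `series`, `value`.
#' @export
tidy.spine_sim <- function(x, series = c("calcium", "voltage", "open"), ...) {
  series <- match.arg(series)
  cols <- switch(series,
    calcium = c("ca_psd", "ca_cyt", "ca_neck", "ca_shaft", "ca_spine"),
    voltage = c("v_spine", "v_shaft"),
    open = grep("^open_", names(x$traces), value = TRUE))
  tidyr::pivot_longer(x$traces[, c("time", cols)], -"time",
                      names_to = "series", values_to = "value")
}

#' One-row summary of a simulation
#' @param x a `spine_sim`.
#' @param ... unused.
#' @export
glance.spine_sim <- function(x, ...) {
  s <- summarize_simulation(x)
  out <- tibble::as_tibble(as.list(setNames(s$value, s$output)))
  out$protocol <- x$protocol$label
  out$n_pulses <- length(x$protocol$pulses)
  dplyr::relocate(out, "protocol", "n_pulses")
}

#' @export
tidy.sensitivity_experiment <- function(x, ...) x$prcc

#' @export
glance.sensitivity_experiment <- function(x, ...) {
  tibble::tibble(protocol = x$protocol$label, n = nrow(x$design),
                 n_used = x$n_used, n_failed = length(x$failed),
                 n_significant = sum(x$prcc$significant, na.rm = TRUE))
}

#' @export
tidy.posterior_sample <- function(x, ...) x$summary

#' @export
glance.posterior_sample <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws), acceptance = x$acceptance,
                 max_rhat = max(x$summary$rhat), min_ess = min(x$summary$ess))
}

#' Plot simulation traces
#'
#' Calcium (per compartment) and membrane potential panels.
#'
#' @param object a `spine_sim`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spine_sim <- function(object, ...) {
  ca <- tidy.spine_sim(object, "calcium")
  ca$panel <- "free Ca (uM)"
  v <- tidy.spine_sim(object, "voltage")
  v$panel <- "membrane potential (mV)"
  df <- dplyr::bind_rows(ca, v)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = paste("spine simulation:", object$protocol$label)) +
    ggplot2::theme_minimal()
}

#' Plot a glutamate trace
#' @param object a `glutamate_trace`.
#' @param ... unused.
#' @export
autoplot.glutamate_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "[Glu] (uM)",
                  title = paste("glutamate,", attr(object, "zone"))) +
    ggplot2::theme_minimal()
}

#' PRCC heat map
#' @param object a `sensitivity_experiment` or `sensitivity_result`.
#' @param masked show only significant cells.
#' @param ... unused.
#' @export
autoplot.sensitivity_experiment <- function(object, masked = TRUE, ...) {
  pr <- if (inherits(object, "sensitivity_experiment")) object$prcc else object
  pr <- dplyr::mutate(pr, shown = ifelse(!masked | .data$significant,
                                         .data$prcc, NA_real_))
  ggplot2::ggplot(pr, ggplot2::aes(.data$output, .data$factor,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$shown), "", sprintf("%.2f", .data$shown))),
      size = 2.5, colour = "white") +
    ggplot2::scale_fill_gradient2(low = "blue", high = "red", mid = "grey85",
                                  midpoint = 0, na.value = "white",
                                  limits = c(-1, 1), name = "PRCC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.sensitivity_result <- autoplot.sensitivity_experiment

#' Posterior marginal densities
#' @param object a `posterior_sample`.
#' @param ... unused.
#' @export
autoplot.posterior_sample <- function(object, ...) {
  df <- tidyr::pivot_longer(object$draws, dplyr::everything(),
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}
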