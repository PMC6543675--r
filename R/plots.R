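#' Plot a Kaplan-Meier fit
#'
#' Step curves per group, starting at S(0) = 1, in the altered/not-altered
#' style of the screen's figures.
#'
#' @param object A `secep_km` object from [km_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot secep_km
#' @export
autoplot.secep_km <- function(object, ...) {
  steps <- object$steps
  origin <- dplyr::distinct(steps, .data$group)
  origin$time <- 0
  origin$survival <- 1
  df <- dplyr::bind_rows(origin, steps[c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot combination-screen results
#'
#' Altered fraction against -log10 log-rank p in the first cohort, with
#' passing combinations highlighted; a quick overview of where the screen's
#' thresholds bite.
#'
#' @param object A `secep_screen` tibble from [screen_combos()].
#' @param cohort Cohort name to plot (default: first cohort found).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot secep_screen
#' @export
autoplot.secep_screen <- function(object, cohort = NULL, ...) {
  cfg <- attr(object, "config")
  nm <- cohort %||% sub("_n$", "", grep("_n$", names(object), value = TRUE)[1])
  fr <- object[[paste0(nm, "_altered_fraction")]]
  p <- object[[paste0(nm, "_logrank_p")]]
  df <- tibble::tibble(
    fraction = fr, logp = -log10(p),
    passes = object$passes, k = factor(object$k)
  )
  df <- df[is.finite(df$logp), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$logp,
                                   colour = .data$passes,
                                   shape = .data$k)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = cfg$min_altered_fraction,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha), linetype = "dashed") +
    ggplot2::labs(x = paste0("Altered fraction (", nm, ")"),
                  y = expression(-log[10] ~ "log-rank p"),
                  colour = "passes", shape = "k") +
    ggplot2::theme_minimal()
}
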