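# ggplot2 displays: the F_C plot (fluorescence against cycle) and the LRE
# plot (efficiency against fluorescence with the fitted line), the two
# standard views of a profile.

#' Plot fluorescence profiles
#'
#' The F_C plot: baseline-subtracted (or raw) fluorescence against cycle, one
#' line per profile.
#'
#' @param profiles Long-format profile table; if a `fc` column is present it
#'   is plotted, otherwise raw `fluorescence`.
#' @param colour Column (character) used for the line colour; default
#'   `profile_id`.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, colour = "profile_id") {
  profiles <- as_tibble(profiles)
  ycol <- if ("fc" %in% names(profiles)) "fc" else "fluorescence"
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$cycle, y = .data[[ycol]],
    colour = .data[[colour]], group = .data$profile_id
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Cycle", y = "Fluorescence (baseline subtracted)",
      colour = colour
    ) +
    ggplot2::theme_minimal()
}

#' LRE plot of a fitted profile
#'
#' Per-cycle efficiency against cycle fluorescence with the fitted LRE line;
#' window cycles are filled, cycles outside the window hollow. The Y-intercept
#' of the line is E_max and its slope is Delta E.
#'
#' @param object An [fit_lre()] result.
#' @param profile Optional full baselined profile (columns `cycle`, `fc`,
#'   `ec`) to show the cycles outside the window as well.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lre_fit <- function(object, profile = NULL, ...) {
  pts <- object$data
  pts$in_window <- TRUE
  if (!is.null(profile)) {
    extra <- profile[!(profile$cycle %in% pts$cycle) & is.finite(profile$ec),
      c("cycle", "fc", "ec"),
      drop = FALSE
    ]
    if (nrow(extra)) {
      extra$in_window <- FALSE
      pts <- dplyr::bind_rows(pts, extra)
    }
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fc, y = .data$ec)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_window), size = 2) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "LRE window", `FALSE` = "outside window"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "Cycle fluorescence F_C", y = "Cycle efficiency E_C",
      subtitle = if (object$valid) {
        sprintf(
          "E_max = %.3f, ΔE = %.3g, F_max = %.4g, R² = %.5f",
          object$emax, object$delta_e, object$fmax, object$r2
        )
      } else {
        "invalid fit"
      }
    ) +
    ggplot2::theme_minimal()
  if (object$valid) {
    p <- p + ggplot2::geom_abline(
      intercept = object$emax, slope = object$delta_e,
      colour = "firebrick"
    )
  }
  p
}
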