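# Tidiers and plot methods for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state result into its radial profile
#'
#' @param x A `steady_state` object.
#' @param ... Unused.
#' @return A tibble with columns `r`, `region`, `A`, `H`.
#' @export
tidy.steady_state <- function(x, ...) x$profile

#' One-row summary of a steady-state result
#'
#' @param x A `steady_state` object.
#' @param ... Unused.
#' @return A one-row tibble: configuration, solution method, current,
#'   surface and core analyte concentrations, and the configuration's
#'   correction factors.
#' @export
glance.steady_state <- function(x, ...) {
  out <- tibble(configuration = x$params$configuration,
                method = x$method,
                current_pA = x$current_pA,
                A_surface = x$A_surface,
                A_core = x$A_core)
  if (length(x$factors)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(x$factors))
  }
  out
}

#' @exportS3Method base::print
print.steady_state <- function(x, ...) {
  cat("<steady_state>", x$params$configuration, "(", x$method, ")\n")
  cat(sprintf("  current: %.6g pA  A(r2): %.6g uM  A(r1): %.6g uM\n",
              x$current_pA, x$A_surface, x$A_core))
  if (length(x$factors)) {
    cat("  factors:",
        paste(names(x$factors),
              signif(unlist(x$factors), 6), sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Plot a steady-state concentration profile
#'
#' @param object A `steady_state` object.
#' @param ... Unused.
#' @return A ggplot of the analyte and peroxide radial profiles, with
#'   region boundaries marked.
#' @export
autoplot.steady_state <- function(object, ...) {
  prof <- tidyr::pivot_longer(object$profile, c("A", "H"),
                              names_to = "species",
                              values_to = "concentration")
  prof$species <- dplyr::recode(prof$species, A = "analyte", H = "H2O2")
  edges <- unique(c(object$params$regions$r_in,
                    object$params$regions$r_out))
  edges <- edges[is.finite(edges)]
  ggplot2::ggplot(prof, ggplot2::aes(.data$r, .data$concentration)) +
    ggplot2::geom_vline(xintercept = edges, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$region)) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "radius (um)", y = "concentration (uM)",
                  title = paste("Steady state:",
                                object$params$configuration)) +
    ggplot2::theme_minimal()
}

#' Tidy a transient result into its current trace
#'
#' @param x A `transient_result` object.
#' @param ... Unused.
#' @return The trace tibble (`time`, `current_pA`, and segment columns for
#'   protocol runs).
#' @export
tidy.transient_result <- function(x, ...) x$trace

#' One-row summary of a transient result
#'
#' @param x A `transient_result` object.
#' @param ... Unused.
#' @return A one-row tibble with the final current, steadiness flag and
#'   time, step size and scheme.
#' @export
glance.transient_result <- function(x, ...) {
  tibble(configuration = x$params$configuration,
         t_end = x$trace$time[nrow(x$trace)],
         current_pA = x$trace$current_pA[nrow(x$trace)],
         steady_reached = x$steady_reached,
         steady_time = x$steady_time,
         dt = x$dt, scheme = x$scheme)
}

#' @exportS3Method base::print
print.transient_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<transient_result>", x$params$configuration,
      sprintf("t = [0, %.4g] s, final current %.6g pA\n",
              x$trace$time[n], x$trace$current_pA[n]))
  cat("  steady_reached:", x$steady_reached,
      if (!is.na(x$steady_time)) sprintf("(~%.3g s)", x$steady_time) else "",
      "\n")
  invisible(x)
}

#' Plot a transient current trace
#'
#' @param object A `transient_result` object.
#' @param ... Unused.
#' @return A ggplot of current against time (coloured by environment for
#'   protocol runs).
#' @export
autoplot.transient_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(.data$time, .data$current_pA))
  p <- if ("environment" %in% names(object$trace)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$environment,
                                        group = 1))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' @param object A `sweep_result` object.
#' @param ... Unused.
#' @return A ggplot of the calibration mismatch (percent of the true
#'   concentration) against the varied parameter.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, 100 * .data$mismatch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1],
                  y = "measured / true concentration (%)") +
    ggplot2::theme_minimal()
}
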