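#' Plot time-dependent G-values
#'
#' @param object A [simulate_track_yields()] result.
#' @param species Optional subset of species to draw.
#' @param ... Unused.
#' @return A ggplot: G(t) per species on a logarithmic time axis, with a
#'   +/- 1 SEM ribbon.
#' @method autoplot gvalue_series
#' @export
autoplot.gvalue_series <- function(object, species = NULL, ...) {
  df <- object
  if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$g,
                                   colour = .data$species,
                                   fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$g - .data$sem,
                                      ymax = .data$g + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "G (molecules / 100 eV)",
                  colour = "species", fill = "species")
}

#' Plot a track-segment yield curve
#'
#' @param object A [integrate_segment_yields()] result.
#' @param what `"gprime"` (yield per energy step) or `"n"` (accumulated
#'   molecules per track).
#' @param ... Unused.
#' @return A ggplot against ion energy, one line per evaluation time.
#' @method autoplot segment_yield_curve
#' @export
autoplot.segment_yield_curve <- function(object, what = c("gprime", "n"),
                                         ...) {
  what <- match.arg(what)
  ylab <- if (what == "gprime") "G' (molecules / 100 eV)" else
    "N (molecules per track)"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$energy, y = .data[[what]],
                               colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "energy (MeV/u)", y = ylab, colour = "time (s)")
}

#' Plot species counts of one chemistry run
#'
#' @param object A `chemistry_result`.
#' @param species Optional subset of species.
#' @param ... Unused.
#' @return A ggplot of counts versus time (log x).
#' @method autoplot chemistry_result
#' @export
autoplot.chemistry_result <- function(object, species = NULL, ...) {
  df <- object$counts
  if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  df <- df[df$count > 0 | df$species %in% unique(object$initial$species), ,
           drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "molecules", colour = "species")
}
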