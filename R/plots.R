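#' @importFrom ggplot2 autoplot ggplot aes geom_density geom_point geom_rect
#'   geom_vline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a posterior predictive check
#'
#' Observed concentration densities (black) overlaid with a handful of
#' replicated data sets (colored) per response; aligned densities indicate an
#' unbiased model.
#'
#' @param object An `hsur_ppc`.
#' @param n_overlay Replicated data sets to draw.
#' @param ... Unused.
#' @method autoplot hsur_ppc
#' @export
autoplot.hsur_ppc <- function(object, n_overlay = 20, ...) {
  M <- length(object$responses)
  reps <- purrr::map_dfr(seq_len(min(n_overlay, dim(object$y_rep)[1])),
                         function(r)
    purrr::map_dfr(seq_len(M), function(m) {
      ok <- object$mask[, m]
      tibble(rep = r, response = object$responses[m],
             value = object$y_rep[r, ok, m])
    }))
  obs <- purrr::map_dfr(seq_len(M), function(m) {
    ok <- object$mask[, m]
    tibble(response = object$responses[m], value = object$observed[ok, m])
  })
  ggplot(reps, aes(x = .data$value, group = .data$rep)) +
    geom_density(color = "#b19cd9", linewidth = 0.3) +
    geom_density(data = obs, aes(x = .data$value), inherit.aes = FALSE,
                 color = "black", linewidth = 0.8) +
    facet_wrap(~response, scales = "free") +
    labs(x = "concentration", y = "density",
         title = "Posterior predictive check") +
    theme_minimal()
}

#' Plot a two-nutrient recommendation
#'
#' The accepted proposal cloud shaded by confidence with the reported
#' 2.5%/97.5% recommendation rectangle; for a failed recommendation the full
#' evaluated cloud is shown instead.
#'
#' @param object A `recommendation` with two queried nutrients.
#' @param ... Unused.
#' @method autoplot recommendation
#' @export
autoplot.recommendation <- function(object, ...) {
  qn <- object$query$queried
  if (length(qn) != 2)
    abort("autoplot.recommendation expects two queried nutrients")
  df <- if (object$succeeded) object$accepted else object$samples
  pl <- ggplot(df, aes(x = .data[[qn[1]]], y = .data[[qn[2]]],
                       color = .data$confidence)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = qn[1], y = qn[2],
         title = sprintf("Patient %s: intake recommendation%s",
                         object$patient,
                         if (object$succeeded) "" else " (target not reached)")) +
    theme_minimal()
  if (object$succeeded) {
    b <- object$bounds
    pl <- pl + ggplot2::annotate(
      "rect", xmin = b$q_min[1], xmax = b$q_max[1],
      ymin = b$q_min[2], ymax = b$q_max[2],
      fill = NA, color = "black", linewidth = 0.6)
  }
  pl
}

#' Plot effect estimates with credible intervals
#'
#' @param effects A tibble from [tidy.hsur_fit()].
#' @export
plot_effects <- function(effects) {
  ggplot(effects,
         aes(x = .data$estimate, y = .data$predictor)) +
    geom_point() +
    ggplot2::geom_errorbarh(aes(xmin = .data$conf.low,
                                xmax = .data$conf.high), height = 0.2) +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~response, scales = "free_x") +
    labs(x = "additive effect on concentration", y = NULL) +
    theme_minimal()
}
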