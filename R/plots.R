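#' Plot the centered partial effect of a smooth term
#'
#' Estimate with a pointwise 95% band on the link scale (or the
#' back-transformed response scale for log links when available), with the
#' isolation cutoff marked for exposure smooths.
#'
#' @param object A [partial_effect()].
#' @param cutoff Optional vertical reference line (e.g. 12 for the LSNS
#'   isolation cutoff).
#' @param response Plot the response-scale estimates when present?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot partial_effect
#' @export
autoplot.partial_effect <- function(object, cutoff = NULL, response = FALSE,
                                    ...) {
  use_resp <- response && "response_estimate" %in% names(object)
  df <- tibble::tibble(
    grid = object$grid,
    est = if (use_resp) object$response_estimate else object$estimate,
    se = if (use_resp) object$response_se else object$se)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$est)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$est - 1.96 * .data$se,
                                      ymax = .data$est + 1.96 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "term"),
                  y = if (use_resp) "partial effect (response scale)"
                      else "partial effect (link scale)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  p
}

#' Plot the effect-share decomposition across the score range
#'
#' Bars of per-score weighted absolute-gradient magnitude, split at the
#' isolation cutoff, with the below-cutoff share annotated.
#'
#' @param object An [effect_share()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_share
#' @export
autoplot.effect_share <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  shares <- attr(object, "shares")
  df <- tibble::tibble(score = object$score,
                       magnitude = object$weighted_magnitude,
                       isolated = object$score < cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$magnitude,
                                   fill = .data$isolated)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = cutoff - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "LSNS score", y = "|gradient| x frequency",
                  fill = "isolated",
                  subtitle = sprintf("share below cutoff: %.1f%%",
                                     100 * shares$share_below)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
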