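# ggplot2 views of the main result types.

#' Plot per-guide enrichment scores along the protein
#'
#' Scatter of guide scores at their representative residues, coloured
#' by outcome class, with the control-derived hit-calling band drawn
#' as dashed lines when present.
#'
#' @param scored Scored tibble from [score_screen()] / [call_hits()].
#' @return A ggplot object.
#' @export
plot_guide_scores <- function(scored) {
  dat <- filter(scored, !is.na(.data$score),
                !is.na(.data$representative_residue))
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$representative_residue, y = .data$score,
    colour = .data$outcome_class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::labs(x = "residue", y = "normalized log2 enrichment",
                  colour = "outcome") +
    ggplot2::theme_minimal()
  thr <- attr(scored, "thresholds")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = c(thr$lower[1], thr$upper[1]),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @export
autoplot.residue_track <- function(object, ...) {
  cl <- clusters(object)
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$residue,
                                    y = .data$neglog10_padj)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "residue", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
  if (nrow(cl) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = cl, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_res - 0.5,
                   xmax = .data$end_res + 0.5,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  p
}

#' @export
autoplot.assay_fit <- function(object, ...) {
  aug <- augment(object)
  xvar <- if ("dose" %in% names(aug)) "dose" else "t"
  yvar <- if ("response" %in% names(aug)) "response" else "y"
  p <- ggplot2::ggplot(aug, ggplot2::aes(x = .data[[xvar]],
                                         y = .data[[yvar]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted),
                       colour = "steelblue") +
    ggplot2::theme_minimal()
  if (object$model %in% c("kd", "pl4") &&
      all(aug[[xvar]] > 0)) {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}
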