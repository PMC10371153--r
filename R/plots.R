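#' Scatter plot of a delta-binding vs delta-expression correlation
#'
#' @param object A `cisom_correlation` from [correlate_deltas()] (its
#'   `data` field must be present).
#' @param ... Unused.
#' @return A ggplot object mirroring the published correlation panels:
#'   delta-binding (bits) on x, delta-expression on y, with rho and p in the
#'   subtitle.
#' @method autoplot cisom_correlation
#' @export
autoplot.cisom_correlation <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This correlation carries no paired data; use correlate_deltas().")
  }
  ggplot(object$data, aes(x = .data$delta, y = .data$delta_expr)) +
    geom_point(alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.4, colour = "grey40") +
    labs(
      x = sprintf("delta %s binding (bits)", object$tf),
      y = "delta expression",
      title = sprintf("%s binding change vs expression change", object$tf),
      subtitle = sprintf("Spearman rho = %.3f, p = %.3g, n = %d (%s)",
                         object$estimate, object$p.value, object$n,
                         object$method)
    ) +
    theme_bw()
}

#' Bar chart of per-gene / per-chromosome variant burden
#'
#' @param burden Tibble from [burden_summary()].
#' @param top Show at most this many bars per group (default 20).
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, top = 20) {
  b <- burden |>
    group_by(.data$group) |>
    slice_max(.data$n_variants, n = top, with_ties = FALSE) |>
    ungroup()
  ggplot(b, aes(x = stats::reorder(.data$name, .data$n_variants),
                y = .data$n_variants)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~group, scales = "free_y") +
    labs(x = NULL, y = "putative variants in CisOMs") +
    theme_bw()
}
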