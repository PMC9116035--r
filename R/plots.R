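#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline geom_histogram facet_wrap labs scale_y_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the copy-number evolution across stages
#'
#' Histograms of the per-reference molecule totals captured in a run's
#' per-stage snapshots, one facet per stage - the standard view of how the
#' synthesized distribution skews through decay/PCR and collapses under
#' sampling.
#'
#' @param run A `channel_run` (or its `snapshots` tibble).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(run, bins = 40) {
  snaps <- if (inherits(run, "channel_run")) run$snapshots else run
  snaps <- mutate(snaps, stage = factor(stage, levels = unique(stage)))
  ggplot(snaps, aes(x = total)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "grey20",
                   linewidth = 0.1) +
    facet_wrap(~stage, scales = "free") +
    labs(x = "molecules per reference", y = "references") +
    theme_minimal()
}

#' @export
autoplot.channel_summary <- function(object, ...) {
  ne <- mutate(object$N_e, what = "voting errors")
  lost <- tibble(errors = NA_integer_, n_seq = object$N_l, what = "lost")
  df <- bind_rows(ne, lost)
  df$label <- ifelse(is.na(df$errors), "lost", as.character(df$errors))
  df$label <- factor(df$label, levels = c(as.character(sort(unique(
    ne$errors))), "lost"))
  ggplot(df, aes(x = label, y = n_seq, fill = what)) +
    geom_col() +
    labs(x = "errors per sequence after voting", y = "sequences",
         fill = NULL) +
    theme_minimal()
}

#' @export
autoplot.alpha_scan <- function(object, ...) {
  tgt <- 1 - attr(object, "target")
  ggplot(as_tibble(object), aes(x = alpha, y = p_f)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(yintercept = tgt, linetype = "dashed", colour = "firebrick") +
    scale_y_log10() +
    labs(x = expression(alpha), y = "failure probability") +
    theme_minimal()
}

#' @export
autoplot.redundancy_plan <- function(object, ...) {
  p1 <- ggplot(object$density, aes(x = L_RS, y = 100 * density)) +
    geom_col(fill = "steelblue") +
    labs(x = expression(L[RS] ~ "(bytes)"), y = "information density (%)") +
    theme_minimal()
  p2 <- autoplot(object$alpha_scan)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2)
  } else {
    p2
  }
}
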