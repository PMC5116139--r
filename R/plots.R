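#' Plot per-class enrichment folds
#'
#' Bar chart of observed/expected fold per TE class, coloured by BH
#' significance, the standard way to display peak/TE-class enrichment
#' against a matched random control.
#'
#' @param object a `te_enrichment` object.
#' @param alpha q-value threshold used for the colouring (default 0.05).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.te_enrichment <- function(object, alpha = 0.05, ...) {
  d <- filter(object$results, !is.na(.data$fold))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$fold), y = .data$fold,
    fill = .data$q_value < alpha)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      name = sprintf("q < %.2g", alpha)) +
    ggplot2::labs(x = NULL, y = "fold over matched random") +
    ggplot2::theme_minimal()
}

#' Plot a meta-profile around anchors
#'
#' @param object a `meta_profile` from [anchor_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.meta_profile <- function(object, ...) {
  bs <- attr(object, "binsize")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset + bs / 2,
                                       y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "distance from anchor (bp)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Plot coverage (or enrichment ratio) along a consensus element
#'
#' @param profile tibble from [consensus_profile()].
#' @param what `"ip"`, `"input"` or `"ratio"`.
#' @return A ggplot object.
#' @export
plot_consensus_profile <- function(profile, what = c("ratio", "ip", "input")) {
  what <- match.arg(what)
  if (what == "ratio" && all(is.na(profile$ratio))) what <- "ip"
  ggplot2::ggplot(profile, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                        y = .data[[what]])) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position on consensus (bp)", y = what) +
    ggplot2::theme_minimal()
}

#' Plot family overlap fractions in age order
#'
#' Unique and ambiguous (inclusive-mapping) peak-overlap fractions per
#' family, youngest family first.
#'
#' @param summary tibble from [family_age_summary()].
#' @return A ggplot object.
#' @export
plot_family_age_summary <- function(summary) {
  d <- tidyr::pivot_longer(summary, c("frac_unique", "frac_ambiguous"),
                           names_to = "mode", names_prefix = "frac_",
                           values_to = "fraction")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_rank, y = .data$fraction,
                                  colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = summary$age_rank,
                                labels = summary$family) +
    ggplot2::labs(x = "family (young to old)",
                  y = "fraction of copies with a peak", colour = "peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot binned 5mC/5hmC along a consensus element
#'
#' @param profile tibble from [methylation_profile()].
#' @return A ggplot object.
#' @export
plot_methylation_profile <- function(profile) {
  levels <- intersect(c("level_5mC", "level_5hmC", "level_modified"),
                      names(profile))
  d <- tidyr::pivot_longer(profile, all_of(levels), names_to = "mark",
                           names_prefix = "level_", values_to = "level")
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$level, colour = .data$mark)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position on consensus (bp)", y = "level") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
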