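# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
autoplot.subst_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alt_aa, y = .data$ref_aa,
                                   fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#3b4cc0", mid = "grey85",
                                  high = "#b40426", midpoint = 0.5,
                                  limits = c(0, 1), na.value = "white",
                                  name = "mean score") +
    ggplot2::scale_y_discrete(limits = rev(AA_ORDER)) +
    ggplot2::scale_x_discrete(limits = AA_ORDER) +
    ggplot2::labs(x = "alternate amino acid", y = "reference amino acid",
                  title = sprintf("Mean substitution scores (%s)",
                                  object$restriction)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.blosum_fit <- function(object, scheme = threshold_scheme(), ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$blosum, y = .data$mean_score)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6,
                         ggplot2::aes(colour = is_snv_reachable(.data$ref_aa,
                                                                .data$alt_aa))) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#e08214",
                                            `FALSE` = "#4393c3"),
                                 name = "SNV-reachable") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::geom_hline(yintercept = c(scheme$benign_cutoff,
                                       scheme$pathogenic_cutoff),
                        linetype = c("dashed", "dotdash"), colour = "grey40") +
    ggplot2::labs(x = "BLOSUM62 score", y = "mean pathogenicity score",
                  subtitle = sprintf("r = %.3f, p = %.2g", object$r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.residue_profile <- function(object, mode = c("snv", "all"), ...) {
  mode <- match.arg(mode)
  col <- paste0("mean_", mode)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data[[col]])) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~protein_acc, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue position",
                  y = sprintf("mean score (%s mode)", mode)) +
    ggplot2::theme_minimal()
}

#' Histogram of scores by clinical label
#'
#' Mirrors the benign/pathogenic score-distribution panels used when
#' benchmarking a single protein: one histogram per label with the
#' threshold band edges marked.
#'
#' @param joined Tibble with `score` and `label` columns (see
#'   [join_scores_labels()]).
#' @param scheme A [threshold_scheme()] drawn as vertical lines.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_score_histograms <- function(joined, scheme = threshold_scheme(),
                                  binwidth = 0.05) {
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(scheme$benign_cutoff,
                                       scheme$pathogenic_cutoff),
                        linetype = "dashed", colour = "red3") +
    ggplot2::facet_wrap(~label, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "pathogenicity score", y = "variants") +
    ggplot2::theme_minimal()
}
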