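#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   facet_wrap labs theme_minimal scale_colour_manual
NULL

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a coefficient-versus-evidence panel per stage for DC results, a biplot
#' for cluster-topology PCA, and fold-enrichment bars per stratum.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name sexbiasnet-plots
NULL

#' @rdname sexbiasnet-plots
#' @export
autoplot.dc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$coef, y = -log10(pmax(.data$lfdr, 1e-6)),
                 colour = .data$direction)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(attr(object, "threshold") %||% 0.1),
               linetype = "dashed") +
    facet_wrap(~stage, nrow = 1) +
    scale_colour_manual(values = c(M = "#2166ac", F = "#b2182b", none = "grey60")) +
    labs(x = "stage x balance coefficient (M direction positive)",
         y = "-log10 stage-2 lFDR", colour = "bias") +
    theme_minimal()
}

#' @rdname sexbiasnet-plots
#' @export
autoplot.topology_pca <- function(object, ...) {
  sc <- object$scores
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(alpha = 0.8) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}

#' @rdname sexbiasnet-plots
#' @param enrichment A tibble from [stratum_fold_enrichment()].
#' @export
plot_fold_enrichment <- function(enrichment) {
  ggplot(enrichment, aes(x = .data$stratum, y = .data$fold, fill = .data$class)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "phylostratum (old to young)", y = "fold enrichment") +
    theme_minimal()
}
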