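#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy and summarise fitted pipeline objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` one row per fit.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name sexbiasnet-tidiers
NULL

#' @rdname sexbiasnet-tidiers
#' @export
tidy.dc_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname sexbiasnet-tidiers
#' @export
glance.dc_result <- function(x, ...) {
  tibble(n_tests = sum(!is.na(x$p)),
         n_significant = sum(x$significant),
         n_clusters = length(unique(x$cluster)),
         threshold = attr(x, "threshold") %||% NA_real_)
}

#' @rdname sexbiasnet-tidiers
#' @export
tidy.topology_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"variable",
                      names_to = "component", values_to = "loading")
}

#' @rdname sexbiasnet-tidiers
#' @export
glance.topology_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained)
}

#' @rdname sexbiasnet-tidiers
#' @export
tidy.model_avg <- function(x, ...) x$terms

#' @rdname sexbiasnet-tidiers
#' @export
glance.model_avg <- function(x, ...) {
  tibble(n_models = nrow(x$models),
         best_aicc = min(x$models$aicc),
         weight_sum = sum(x$models$weight))
}

#' @rdname sexbiasnet-tidiers
#' @export
tidy.stratum_models <- function(x, ...) {
  bind_rows(density = x$density$terms, hub_score = x$hub_score$terms,
            .id = "response")
}

#' @rdname sexbiasnet-tidiers
#' @export
glance.stratum_models <- function(x, ...) {
  tibble(response = c("density", "hub_score"),
         n_models = c(nrow(x$density$models), nrow(x$hub_score$models)),
         n_nodes = nrow(x$data))
}
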