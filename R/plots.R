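#' Plot variance components of a univariate twin fit
#'
#' Stacked bar of the standardized A/C/E proportions.
#'
#' @param object An `"ace_fit"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ace_fit <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = c("a2", "c2", "e2"),
                        labels = c("A", "C", "E"))
  ggplot(d, aes(x = .data$model, y = .data$estimate,
                fill = .data$component)) +
    geom_col(position = position_stack(reverse = TRUE), width = 0.5) +
    scale_fill_brewer(palette = "Set2", name = "Source") +
    labs(x = NULL, y = "Proportion of variance") +
    theme_minimal()
}

plot_biv_decomp <- function(d, title) {
  d <- tidyr::pivot_longer(d, c("common", "specific"),
                           names_to = "kind", values_to = "share")
  d$source <- factor(d$source, levels = c("A", "C", "E"))
  ggplot(d, aes(x = .data$trait, y = .data$share, fill = .data$source,
                alpha = .data$kind)) +
    geom_col(position = position_stack(reverse = TRUE)) +
    ggplot2::scale_alpha_manual(values = c(common = 1, specific = 0.55),
                                name = NULL) +
    scale_fill_brewer(palette = "Set2", name = "Source") +
    labs(title = title, x = NULL, y = "Share of total variance") +
    theme_minimal()
}

#' Plot common vs specific variance shares of a bivariate decomposition
#'
#' Stacked bars per trait: for each source (A, C, E), the share transmitted
#' through the common factor (solid) and the trait-specific share (faded).
#'
#' @param object A `"chol_fit"` or `"ip_fit"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.chol_fit <- function(object, ...) {
  plot_biv_decomp(object$decomposition,
                  sprintf("Cholesky decomposition (order %s, %s)",
                          object$traits[1], object$traits[2]))
}

#' @rdname autoplot.chol_fit
#' @export
autoplot.ip_fit <- function(object, ...) {
  plot_biv_decomp(object$decomposition,
                  "Constrained independent-pathway decomposition")
}

#' Plot univariate variance components across phenotypes and scopes
#'
#' @param object A `"twin_pipeline"` result.
#' @param model Which fitted model's components to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.twin_pipeline <- function(object, model = "ACE", ...) {
  d <- object$model_fits
  d <- d[d$model == model, c("phenotype", "scope", "a2", "c2", "e2")]
  d <- tidyr::pivot_longer(d, c("a2", "c2", "e2"),
                           names_to = "component", values_to = "share")
  d$component <- factor(d$component, levels = c("a2", "c2", "e2"),
                        labels = c("A", "C", "E"))
  ggplot(d, aes(x = .data$phenotype, y = .data$share,
                fill = .data$component)) +
    geom_col(position = position_stack(reverse = TRUE)) +
    facet_wrap(~scope) +
    scale_fill_brewer(palette = "Set2", name = "Source") +
    labs(x = NULL, y = "Proportion of variance") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
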