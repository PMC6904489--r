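# ggplot2 views of the main result types.

#' @describeIn trait_gene_screen Correlation heatmap of a screen result:
#'   genes by traits, tiles coloured by the Spearman coefficient, `~` marking
#'   unadjusted p below the tilde threshold and `*` adjusted p below the star
#'   threshold.
#' @param object,x A `screen_result`.
#' @param ... Unused.
#' @export
autoplot.screen_result <- function(object, ...) {
  flag_lab <- mutate(as_tibble(object),
                     flag = dplyr::case_when(.data$star ~ "*",
                                             .data$tilde ~ "~",
                                             TRUE ~ ""))
  ggplot2::ggplot(flag_lab,
                  ggplot2::aes(x = .data$trait, y = .data$gene,
                               fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$flag), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::facet_grid(. ~ genotype + tissue, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' @export
plot.screen_result <- function(x, ...) print(autoplot(x, ...))

#' @describeIn progression_profile Presence progression lines: presence (%)
#'   against CAG length, one panel per age and direction, coloured by set.
#' @param object,x A `progression_profile`.
#' @param ... Unused.
#' @export
autoplot.progression_profile <- function(object, ...) {
  ggplot2::ggplot(object$presence,
                  ggplot2::aes(x = .data$cag, y = .data$presence,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(direction ~ age,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "CAG repeats", y = "presence among top DEGs (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @export
plot.progression_profile <- function(x, ...) print(autoplot(x, ...))

#' @describeIn nb_wald_test MA plot of a DE result: log2 fold change against
#'   mean normalized count, significant genes highlighted.
#' @param object A `de_result`.
#' @param fdr Highlight threshold on adjusted p.
#' @export
autoplot.de_result <- function(object, fdr = 0.05, ...) {
  dat <- filter(as_tibble(object), .data$status != "untested") |>
    mutate(sig = !is.na(.data$q) & .data$q < fdr)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$base_mean, y = .data$log2fc,
                                    colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change",
                  colour = sprintf("q < %.3g", fdr)) +
    ggplot2::theme_minimal()
}

#' @export
plot.de_result <- function(x, ...) print(autoplot(x, ...))

#' Whisker-and-box view of a trait by genotype and performer label
#'
#' @param table A phenotype tibble.
#' @param labels Optional tibble from [classify_performers()]; when given,
#'   boxes are split by performer label within genotype.
#' @param trait Trait to plot.
#' @param timepoint Optional timepoint filter.
#' @return A ggplot object.
#' @export
plot_trait <- function(table, labels = NULL, trait, timepoint = NULL) {
  dat <- filter(as_tibble(table), .data$trait == !!trait)
  if (!is.null(timepoint)) dat <- filter(dat, .data$timepoint %in% !!timepoint)
  if (!is.null(labels)) {
    dat <- inner_join(dat, labels, by = c("animal", "genotype"))
    aes <- ggplot2::aes(x = .data$genotype, y = .data$value,
                        fill = .data$label)
  } else {
    aes <- ggplot2::aes(x = .data$genotype, y = .data$value)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = trait) +
    ggplot2::theme_minimal()
}
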