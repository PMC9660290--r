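# ggplot2 views of the main result types.

#' Plot the quasi-adaptive weight components
#'
#' Left: the distance pre-weight step function (log-bp axis). Right: the
#' LD pre-weight, unimodal at `r2_opt`.
#'
#' @param config A [round_config()].
#' @return A ggplot object (faceted).
#' @export
plot_weight_functions <- function(config = round_config()) {
  dgrid <- tibble(x = 10^seq(2, 6.2, length.out = 400),
                  value = preweight_d(10^seq(2, 6.2, length.out = 400)),
                  component = "w_d vs distance [bp, log10]",
                  xplot = log10(10^seq(2, 6.2, length.out = 400)))
  rgrid <- tibble(x = seq(0, 1, length.out = 400),
                  value = preweight_r2(seq(0, 1, length.out = 400),
                                       config$r2_opt, config$r2_form),
                  component = "w_r2 vs r2",
                  xplot = seq(0, 1, length.out = 400))
  ggplot2::ggplot(bind_rows(dgrid, rgrid),
                  ggplot2::aes(x = .data$xplot, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "pre-weight") +
    ggplot2::theme_minimal()
}

#' Plot discovered signal chains
#'
#' Conditional -log10 p of every declared signal by genomic position,
#' shaped by signal order, with the SNP-specific threshold overlaid.
#'
#' @param object A `qadapt_chains` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qadapt_chains <- function(object, ...) {
  sig <- tidy(object)
  if (nrow(sig) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no signals") +
             ggplot2::theme_void())
  }
  sig <- sig %>%
    left_join(object$loci %>% select("locus_id", "chrom"),
              by = "locus_id")
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$locus_id,
                                    y = -log10(.data$p_c),
                                    shape = .data$category)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_point(ggplot2::aes(y = -log10(.data$G)), shape = 95,
                        size = 5, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "-log10 conditional p",
                  shape = "signal order",
                  caption = "dashes: SNP-specific alpha-threshold G") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Discovery-versus-replication effect scatter
#'
#' Conditional discovery effects against conditional replication effects
#' with 95% error bars, colored by replication call; the identity line is
#' dashed.
#'
#' @param calls Tibble with `beta_gcta, se_gcta, beta_ukbb, se_ukbb,
#'   replicated`, e.g. [novel_signal_replication()].
#' @return A ggplot object.
#' @export
plot_replication_concordance <- function(calls = novel_signal_replication()) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$beta_gcta, y = .data$beta_ukbb,
                                      colour = .data$replicated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_ukbb - 1.96 * .data$se_ukbb,
                                        ymax = .data$beta_ukbb + 1.96 * .data$se_ukbb),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_gcta - 1.96 * .data$se_gcta,
                                         xmax = .data$beta_gcta + 1.96 * .data$se_gcta),
                            height = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(x = "discovery conditional effect",
                  y = "replication conditional effect",
                  colour = "replicated") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
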