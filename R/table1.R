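# Packaged replication summary of the 27 novel independent eGFR signals:
# per-signal discovery (GWAS meta-analysis marginal and conditional) and
# UK Biobank replication statistics, with the quasi-adaptive
# alpha-threshold each signal was declared at.

#' Novel independent eGFR signals with replication statistics
#'
#' Loads the packaged table of 27 novel independent eGFR-associated
#' signals (secondary and higher order) detected by the quasi-adaptive
#' method, with marginal GWAS meta-analysis statistics, conditional
#' (summary-level) discovery statistics, the assigned SNP-specific
#' alpha-threshold, and conditional replication statistics from the
#' UK Biobank.
#'
#' @return A 27-row tibble with columns `category` (secondary ... sixth),
#'   `chr, signal, index, closest_gene, d_bp, r2, pos_b37, ea, eaf`,
#'   effect/SE/p blocks `*_gwas` (marginal), `*_gcta` (conditional
#'   discovery), `*_ukbb` (conditional replication), and
#'   `alpha_threshold`.
#' @export
novel_signal_table <- function() {
  path <- system.file("extdata", "novel_signals_replication.tsv",
                      package = "qadapt", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    category = readr::col_character(),
                    chr = readr::col_character(),
                    signal = readr::col_character(),
                    index = readr::col_character(),
                    closest_gene = readr::col_character(),
                    ea = readr::col_character(),
                    .default = readr::col_double()
                  )) %>%
    mutate(category = factor(.data$category,
                             levels = c("secondary", "tertiary", "fourth",
                                        "fifth", "sixth")))
}

#' Replication calls for the packaged novel-signal table
#'
#' Applies the per-category Bonferroni correction ([replication_calls()])
#' to the UK Biobank conditional p-values of [novel_signal_table()]:
#' within each signal category the threshold is `alpha` divided by the
#' number of signals tested in that category.
#'
#' @param alpha Replication budget per category.
#' @return The table with `n_category, threshold, replicated` appended.
#' @export
novel_signal_replication <- function(alpha = 0.05) {
  novel_signal_table() %>% replication_calls(alpha = alpha, p_col = "p_ukbb")
}

#' Concordance of discovery and replication effect estimates
#'
#' Pearson correlation between the conditional discovery effects and the
#' conditional replication effects over the replicated signals.
#'
#' @param calls Tibble from [novel_signal_replication()] (or any tibble
#'   with `beta_gcta`, `beta_ukbb` and `replicated`).
#' @param replicated_only Restrict to replicated signals (default).
#' @return One-row tibble: `n, pearson_r, r_squared`.
#' @export
effect_concordance <- function(calls = novel_signal_replication(),
                               replicated_only = TRUE) {
  x <- if (replicated_only) calls %>% filter(.data$replicated) else calls
  r <- cor(x$beta_gcta, x$beta_ukbb)
  tibble(n = nrow(x), pearson_r = r, r_squared = r^2)
}
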