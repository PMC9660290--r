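# Iterative quasi-adaptive signal discovery: round r tests all remaining
# candidates of the loci that gained a signal in round r-1, conditioning on
# the index SNP and every previously confirmed signal of the locus. LD and
# distance are always taken to the primary index SNP, so pre-weights do not
# change across rounds; only m (tested SNPs) and the conditioning sets do.

#' One round of quasi-adaptive signal detection
#'
#' For every candidate of every active locus computes `r^2` and distance to
#' the primary index SNP, the normalized weight over the pooled
#' `m = m_round` candidates, the SNP-specific threshold `G`, and the
#' conditional p-value given the locus index plus all previously confirmed
#' signals. At most one signal is declared per locus: the candidate with
#' the smallest conditional p-value among those with `p_c < G` (strict).
#' Ties are broken by larger `W`, then smaller `d`, then rsid.
#'
#' @param sumstats Harmonized sumstats tibble.
#' @param loci Active loci tibble.
#' @param panel A [genotype_panel()].
#' @param config A [round_config()].
#' @param confirmed Named list (by `locus_id`) of already-confirmed signal
#'   rsids.
#' @param sigma2 Trait variance (estimated once per run upstream).
#' @return List with `declared` (tibble of new signals), `m` (tested SNP
#'   count) and `weights` (the full per-candidate audit table).
#' @export
run_round <- function(sumstats, loci, panel, config = round_config(),
                      confirmed = list(), sigma2 = NULL) {
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(sumstats, panel)
  cand_tables <- purrr::map(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    cc <- enumerate_candidates(sumstats, locus, panel,
                               exclude = confirmed[[locus$locus_id]] %||% character())
    if (nrow(cc) == 0) return(NULL)
    cc %>% mutate(
      locus_id = locus$locus_id,
      index_rsid = locus$index_rsid,
      r = ld_with(panel, locus$index_rsid, .data$rsid),
      r2 = .data$r^2,
      d = abs(.data$pos - locus$index_pos)
    )
  })
  cands <- bind_rows(cand_tables)
  if (is.null(cands) || nrow(cands) == 0) {
    return(list(declared = empty_signals(), m = 0L, weights = tibble()))
  }
  m_round <- nrow(cands)
  cands <- assign_weights(cands, config, m = m_round)
  results <- cands %>%
    dplyr::group_split(.data$locus_id) %>%
    purrr::map(function(cc) {
      locus_id <- cc$locus_id[1]
      cond <- c(cc$index_rsid[1], confirmed[[locus_id]] %||% character())
      pc <- conditional_from_summary(sumstats, cc$rsid, cond, panel,
                                     sigma2 = sigma2, config = config)
      cc %>%
        mutate(beta_c = pc$beta_c, se_c = pc$se_c, p_c = pc$p_c,
               status = pc$status,
               conditioned_on = pc$conditioned_on)
    }) %>%
    bind_rows()
  declared <- results %>%
    filter(.data$status == "ok", .data$p_c < .data$G) %>%
    group_by(.data$locus_id) %>%
    arrange(.data$p_c, dplyr::desc(.data$W), .data$d, .data$rsid,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("locus_id", "rsid", "beta_c", "se_c", "p_c",
           "G", "W", "r2", "d", "conditioned_on")
  list(declared = declared, m = m_round, weights = results)
}

empty_signals <- function() {
  tibble(locus_id = character(), rsid = character(), beta_c = numeric(),
         se_c = numeric(), p_c = numeric(), G = numeric(), W = numeric(),
         r2 = numeric(), d = numeric(), conditioned_on = character())
}

#' Iterative discovery of multiple independent signals
#'
#' Runs rounds of [run_round()] until a round declares nothing. Round 2
#' (secondary signals) tests all loci; each later round is restricted to
#' the loci that gained a signal in the previous round, with `m`
#' recomputed over their remaining candidates.
#'
#' @inheritParams run_round
#' @param loci Loci tibble, already merged and MHC-excluded.
#' @return An object of class `qadapt_chains`: list with `signals` (tibble
#'   `locus_id, rsid, order, beta_c, se_c, p_c, G, W, r2, d,
#'   conditioned_on`), `rounds` (per-round bookkeeping), `loci`, `config`,
#'   `sigma2`.
#' @export
run_discovery <- function(sumstats, loci, panel, config = round_config()) {
  sigma2 <- estimate_sigma2(sumstats, panel)
  confirmed <- setNames(vector("list", nrow(loci)), loci$locus_id)
  active <- loci
  signals <- list()
  rounds <- list()
  ord <- 2L
  while (nrow(active) > 0) {
    res <- run_round(sumstats, active, panel, config, confirmed, sigma2)
    rounds[[length(rounds) + 1]] <- tibble(
      round = ord, n_active_loci = nrow(active), m = res$m,
      n_declared = nrow(res$declared)
    )
    if (nrow(res$declared) == 0) break
    signals[[length(signals) + 1]] <- res$declared %>% mutate(order = ord)
    for (i in seq_len(nrow(res$declared))) {
      lid <- res$declared$locus_id[i]
      confirmed[[lid]] <- c(confirmed[[lid]], res$declared$rsid[i])
    }
    active <- active %>% semi_join(res$declared, by = "locus_id")
    ord <- ord + 1L
  }
  signals <- if (length(signals)) bind_rows(signals) else
    empty_signals() %>% mutate(order = integer())
  structure(
    list(signals = signals %>%
           select("locus_id", "rsid", "order", dplyr::everything()),
         rounds = bind_rows(rounds), loci = loci, config = config,
         sigma2 = sigma2),
    class = "qadapt_chains"
  )
}

#' @export
print.qadapt_chains <- function(x, ...) {
  cat(sprintf("<qadapt_chains> %d signal(s) across %d of %d loci; %d round(s)\n",
              nrow(x$signals), length(unique(x$signals$locus_id)),
              nrow(x$loci), nrow(x$rounds)))
  if (nrow(x$signals)) print(x$signals, n = 10)
  invisible(x)
}

#' Label discovered signals as known or novel
#'
#' A signal is known if it matches a published independent signal exactly
#' by rsid or has `r^2 > r2_cut` with one in the panel; otherwise novel.
#' Signals absent from the panel are labeled novel with a warning.
#'
#' @param signals Signals tibble (from a `qadapt_chains` object).
#' @param published Character vector of published signal rsids.
#' @param panel A [genotype_panel()].
#' @param r2_cut LD threshold for "known by proxy" (strictly greater).
#' @return `signals` with a logical `known` column.
#' @export
label_known <- function(signals, published, panel, r2_cut = 0.8) {
  pub_in <- intersect(published, colnames(panel$dosages))
  known <- purrr::map_lgl(signals$rsid, function(s) {
    if (s %in% published) return(TRUE)
    if (!s %in% colnames(panel$dosages)) {
      warn(sprintf("signal %s absent from panel; labeled novel", s))
      return(FALSE)
    }
    if (length(pub_in) == 0) return(FALSE)
    any(ld_with(panel, s, pub_in)^2 > r2_cut)
  })
  signals %>% mutate(known = known)
}

ORDER_LABELS <- c("2" = "secondary", "3" = "tertiary", "4" = "fourth",
                  "5" = "fifth", "6" = "sixth", "7" = "seventh")

order_label <- function(order) {
  unname(ifelse(as.character(order) %in% names(ORDER_LABELS),
                ORDER_LABELS[as.character(order)],
                paste0("order", order)))
}

#' Per-category Bonferroni replication thresholds
#'
#' Groups tested signals by category (signal order) and assigns each the
#' threshold `alpha / n_category`, where `n_category` is the number of
#' signals tested in that category; a signal replicates iff its
#' replication p-value is strictly below its threshold.
#'
#' @param tested Tibble with a `category` column and the p-value column
#'   named by `p_col`.
#' @param alpha Budget per category (default 0.05).
#' @param p_col Name of the p-value column.
#' @return `tested` with `n_category`, `threshold` and `replicated`
#'   columns appended.
#' @export
replication_calls <- function(tested, alpha = 0.05, p_col = "p_rep") {
  tested %>%
    group_by(.data$category) %>%
    mutate(n_category = n(),
           threshold = alpha / .data$n_category,
           replicated = .data[[p_col]] < .data$threshold) %>%
    ungroup()
}

#' Build replication plans for novel signals
#'
#' One plan per (by default novel) signal, ordered by category then locus.
#' The conditioning set of a plan is the locus index SNP, the known
#' signals of lower order, and the novel lower-order signals of the locus
#' *that replicate* -- the latter are carried as `cond_novel` and resolved
#' while [run_replication()] proceeds category by category, so that
#' earlier failed novel signals are excluded.
#'
#' @param chains A `qadapt_chains` object whose `signals` carry a `known`
#'   column ([label_known()]).
#' @param novel_only Plan only novel signals (default) or all.
#' @param alpha Replication budget per category.
#' @return Tibble of plans: `rsid, locus_id, order, category, threshold,
#'   cond_base, cond_novel` (list-columns).
#' @export
build_replication_plans <- function(chains, novel_only = TRUE, alpha = 0.05) {
  sig <- chains$signals
  if (!"known" %in% names(sig)) abort("signals must be labeled with label_known()")
  loci <- chains$loci
  tested <- if (novel_only) sig %>% filter(!.data$known) else sig
  tested <- tested %>%
    mutate(category = order_label(.data$order)) %>%
    group_by(.data$category) %>%
    mutate(n_category = n(), threshold = alpha / .data$n_category) %>%
    ungroup()
  plans <- purrr::map(seq_len(nrow(tested)), function(i) {
    s <- tested[i, ]
    locus_sig <- sig %>% filter(.data$locus_id == s$locus_id,
                                .data$order < s$order)
    index <- loci$index_rsid[match(s$locus_id, loci$locus_id)]
    tibble(
      rsid = s$rsid, locus_id = s$locus_id, order = s$order,
      category = s$category, n_category = s$n_category,
      threshold = s$threshold,
      cond_base = list(c(index, locus_sig$rsid[locus_sig$known])),
      cond_novel = list(locus_sig$rsid[!locus_sig$known])
    )
  }) %>% bind_rows()
  plans %>% arrange(.data$order, .data$locus_id)
}

#' Run the replication procedure on individual-level data
#'
#' Processes plans category by category (ascending order). Each signal is
#' tested by [conditional_individual()] conditioning on its base set plus
#' the lower-order novel signals that have replicated so far; novel
#' signals that failed are excluded from later conditioning sets. A signal
#' replicates iff `p_c < threshold`. Signals absent from the genotypes
#' fail with a reason.
#'
#' @param plans Tibble from [build_replication_plans()].
#' @param genos A [genotype_panel()] of the replication sample.
#' @param phenotype Numeric per-sample phenotype (residualized).
#' @param covariates Optional per-sample covariate columns.
#' @return `plans` with `beta_c, se_c, p_c, replicated, reason` appended.
#' @export
run_replication <- function(plans, genos, phenotype, covariates = NULL) {
  status <- setNames(rep(NA, nrow(plans)), plans$rsid)
  out <- vector("list", nrow(plans))
  for (i in order(plans$order, plans$locus_id)) {
    p <- plans[i, ]
    novel_ok <- p$cond_novel[[1]][!is.na(status[p$cond_novel[[1]]]) &
                                    status[p$cond_novel[[1]]]]
    cond <- unique(c(p$cond_base[[1]], novel_ok))
    cond <- intersect(cond, colnames(genos$dosages))
    if (!p$rsid %in% colnames(genos$dosages)) {
      res <- tibble(beta_c = NA_real_, se_c = NA_real_, p_c = NA_real_,
                    replicated = FALSE, reason = "absent from genotypes")
    } else {
      fit <- conditional_individual(genos, phenotype, covariates,
                                    candidate = p$rsid, cond_set = cond)
      res <- tibble(beta_c = fit$beta_c, se_c = fit$se_c, p_c = fit$p_c,
                    replicated = fit$p_c < p$threshold, reason = NA_character_)
    }
    status[p$rsid] <- res$replicated
    out[[i]] <- bind_cols(p, res)
  }
  bind_rows(out) %>% arrange(.data$order, .data$locus_id)
}
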