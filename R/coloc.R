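# Wakefield approximate-Bayes-factor colocalization of GWAS (conditional
# or unconditional) and cis-eQTL associations under the five standard
# hypotheses (H0 no association ... H4 one shared causal variant), with
# signal-to-gene pairing (eQTL record within +/-100 kb of the signal) and
# the TSS +/- 1 Mb cis window as the test region.

#' Colocalization configuration
#'
#' @param p1,p2 Prior probability that a variant associates with trait 1
#'   (GWAS) / trait 2 (eQTL).
#' @param p12 Prior probability that a variant associates with both.
#' @param prior_sd Effect-size prior standard deviation of the Wakefield
#'   ABF (quantitative-trait scale).
#' @param pp_cut Posterior probability above which a shared causal variant
#'   is called.
#' @param pair_window Signal-to-eQTL pairing window, bp.
#' @param cis_window Half-width of the cis test region around the TSS, bp.
#' @return A list of class `qadapt_coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, prior_sd = 0.15,
                         pp_cut = 0.80, pair_window = 1e5, cis_window = 1e6) {
  stopifnot(p1 + p2 + p12 < 1, pp_cut > 0, pp_cut < 1, prior_sd > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, prior_sd = prior_sd,
                 pp_cut = pp_cut, pair_window = pair_window,
                 cis_window = cis_window),
            class = "qadapt_coloc_config")
}

#' Log approximate Bayes factor (Wakefield)
#'
#' With `V = se^2`, `W = prior_sd^2`, `z = beta/se`:
#' `log ABF = 0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))`.
#' Vectorized; computed in log space.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param prior_sd Effect-size prior SD (> 0).
#' @return Log Bayes factor(s) in favor of association.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0, na.rm = TRUE) || anyNA(se)) {
    abort("se must be > 0", class = "qadapt_domain_error")
  }
  if (prior_sd <= 0) abort("prior_sd must be > 0", class = "qadapt_domain_error")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Posterior probabilities of colocalization
#'
#' Joins the two traits' per-variant statistics on `rsid` and evaluates
#' the five-hypothesis posterior: with per-variant log-ABFs `l1, l2`, the
#' unnormalized masses are `S0 = 1`, `S1 = p1 * sum(L1)`,
#' `S2 = p2 * sum(L2)`, `S3 = p1*p2 * (sum(L1)*sum(L2) - sum(L1*L2))`,
#' `S4 = p12 * sum(L1*L2)`, all accumulated with log-sum-exp.
#'
#' @param gwas Tibble with `rsid, beta, se` (trait 1; conditional or
#'   unconditional GWAS statistics).
#' @param eqtl Tibble with `rsid, beta, se` (trait 2).
#' @param config A [coloc_config()].
#' @return One-row tibble: `n_variants, pp0..pp4, called, lead_rsid` (the
#'   shared variant with the largest `l1 + l2`). Zero shared variants
#'   yield an `NA` row with `n_variants = 0`.
#' @export
coloc_pps <- function(gwas, eqtl, config = coloc_config()) {
  shared <- inner_join(
    gwas %>% select("rsid", beta1 = "beta", se1 = "se") %>%
      distinct(.data$rsid, .keep_all = TRUE),
    eqtl %>% select("rsid", beta2 = "beta", se2 = "se") %>%
      distinct(.data$rsid, .keep_all = TRUE),
    by = "rsid"
  )
  if (nrow(shared) == 0) {
    inform("coloc_pps: no shared variants; no test performed")
    return(tibble(n_variants = 0L, pp0 = NA_real_, pp1 = NA_real_,
                  pp2 = NA_real_, pp3 = NA_real_, pp4 = NA_real_,
                  called = NA, lead_rsid = NA_character_))
  }
  l1 <- log_abf(shared$beta1, shared$se1, config$prior_sd)
  l2 <- log_abf(shared$beta2, shared$se2, config$prior_sd)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  # log(sum_i sum_{j != i} L1_i L2_j) = log(sum L1 * sum L2 - sum L1 L2)
  ls3 <- if (nrow(shared) > 1) {
    ls1 + ls2 + log1p(-pmin(exp(ls12 - ls1 - ls2), 1))
  } else {
    -Inf
  }
  logS <- c(
    0,
    log(config$p1) + ls1,
    log(config$p2) + ls2,
    log(config$p1) + log(config$p2) + ls3,
    log(config$p12) + ls12
  )
  pp <- exp(logS - logsumexp(logS))
  pp <- pp / sum(pp)
  tibble(
    n_variants = nrow(shared),
    pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
    called = pp[5] >= config$pp_cut,
    lead_rsid = shared$rsid[which.max(l1 + l2)]
  )
}

#' Pair signals with gene-tissue colocalization tests
#'
#' A test is emitted for every gene-tissue pair having at least one eQTL
#' record within `pair_window` bp of a signal; the test region is the
#' gene's TSS plus/minus `cis_window`. Genes missing from the annotation
#' are skipped with a warning.
#'
#' @param signals Tibble with `rsid, chrom, pos` (one row per signal to
#'   test: index SNPs and/or independent signals).
#' @param eqtl eQTL catalog tibble ([read_eqtl()]).
#' @param annotation Gene annotation tibble ([read_gene_annotation()]).
#' @param config A [coloc_config()].
#' @return Tibble of tests: `signal, signal_chrom, signal_pos, gene,
#'   tissue, region_start, region_end`.
#' @export
pair_signals_to_tests <- function(signals, eqtl, annotation,
                                  config = coloc_config()) {
  tests <- purrr::map(seq_len(nrow(signals)), function(i) {
    s <- signals[i, ]
    hits <- eqtl %>%
      filter(.data$chrom == s$chrom,
             abs(.data$pos - s$pos) <= config$pair_window) %>%
      distinct(.data$gene, .data$tissue)
    if (nrow(hits) == 0) return(NULL)
    hits %>% mutate(signal = s$rsid, signal_chrom = s$chrom,
                    signal_pos = s$pos)
  }) %>% bind_rows()
  if (is.null(tests) || nrow(tests) == 0) {
    return(tibble(signal = character(), signal_chrom = character(),
                  signal_pos = numeric(), gene = character(),
                  tissue = character(), region_start = numeric(),
                  region_end = numeric()))
  }
  missing <- setdiff(unique(tests$gene), annotation$gene)
  if (length(missing) > 0) {
    warn(paste0("pair_signals_to_tests: no annotation for gene(s) ",
                paste(missing, collapse = ", "), "; tests skipped"))
  }
  tests %>%
    inner_join(annotation %>% select("gene", "tss"), by = "gene") %>%
    mutate(region_start = pmax(1, .data$tss - config$cis_window),
           region_end = .data$tss + config$cis_window) %>%
    select("signal", "signal_chrom", "signal_pos", "gene",
           "tissue", "region_start", "region_end")
}

#' Conditional GWAS statistics over a colocalization region
#'
#' Builds the per-variant conditional GWAS statistics used for
#' colocalization of one signal. For a locus index SNP the conditioning
#' set is all other confirmed signals of the locus; for an independent
#' signal it is the index plus all other signals except the signal itself.
#' With an empty conditioning set the unconditional statistics are
#' returned.
#'
#' @param sumstats Harmonized sumstats tibble.
#' @param chains A `qadapt_chains` object (or a list with `signals` and
#'   `loci` tibbles).
#' @param signal Rsid of the signal being colocalized (index SNP or
#'   independent signal).
#' @param panel A [genotype_panel()].
#' @param region Optional `c(start, end)` bounds restricting the variants
#'   (e.g. the cis window); default: the signal's locus bounds.
#' @param config A [round_config()].
#' @return Tibble `rsid, pos, beta, se, p` of conditional statistics over
#'   the region's variants (conditioning SNPs excluded).
#' @export
conditional_gwas_for_coloc <- function(sumstats, chains, signal, panel,
                                       region = NULL,
                                       config = round_config()) {
  loci <- chains$loci
  sig <- chains$signals
  if (signal %in% loci$index_rsid) {
    locus <- loci[loci$index_rsid == signal, ][1, ]
    cond <- sig$rsid[sig$locus_id == locus$locus_id]
  } else {
    row <- sig[sig$rsid == signal, ][1, ]
    if (nrow(row) == 0 || is.na(row$locus_id)) {
      abort(paste0("signal ", signal, " not found in chains"))
    }
    locus <- loci[loci$locus_id == row$locus_id, ][1, ]
    others <- sig$rsid[sig$locus_id == locus$locus_id & sig$rsid != signal]
    cond <- c(locus$index_rsid, others)
  }
  bounds <- region %||% c(locus$start, locus$end)
  vars <- sumstats %>%
    filter(.data$chrom == locus$chrom,
           .data$pos >= bounds[1], .data$pos <= bounds[2],
           .data$rsid %in% colnames(panel$dosages),
           !.data$rsid %in% cond)
  if (nrow(vars) == 0) {
    return(tibble(rsid = character(), pos = numeric(), beta = numeric(),
                  se = numeric(), p = numeric()))
  }
  res <- conditional_from_summary(sumstats, vars$rsid, cond, panel,
                                  config = config)
  tibble(rsid = vars$rsid, pos = vars$pos, beta = res$beta_c,
         se = res$se_c, p = res$p_c) %>%
    filter(!is.na(.data$beta))
}

#' Compare conditional and unconditional colocalization calls
#'
#' Classifies each gene-tissue test as called in both modes, in one mode
#' only, or in neither.
#'
#' @param uncond,cond Tibbles of colocalization results with columns
#'   `signal, gene, tissue, called`.
#' @return Tibble keyed by `signal, gene, tissue` with `called_uncond`,
#'   `called_cond` and `concordance` in
#'   `{"both", "conditional-only", "unconditional-only", "neither"}`.
#' @export
compare_modes <- function(uncond, cond) {
  dplyr::full_join(
    uncond %>% select("signal", "gene", "tissue",
                      called_uncond = "called"),
    cond %>% select("signal", "gene", "tissue",
                    called_cond = "called"),
    by = c("signal", "gene", "tissue")
  ) %>%
    mutate(
      called_uncond = dplyr::coalesce(.data$called_uncond, FALSE),
      called_cond = dplyr::coalesce(.data$called_cond, FALSE),
      concordance = case_when(
        .data$called_uncond & .data$called_cond ~ "both",
        .data$called_cond ~ "conditional-only",
        .data$called_uncond ~ "unconditional-only",
        TRUE ~ "neither"
      )
    )
}

#' Run colocalization for a set of tests
#'
#' For each test region computes the GWAS statistics (conditional via
#' [conditional_gwas_for_coloc()] when `mode = "conditional"`, marginal
#' otherwise), intersects them with the gene-tissue eQTL records, and
#' evaluates [coloc_pps()]. The eQTL effect direction of the lead variant
#' is reported aligned to the trait-lowering allele of the GWAS.
#'
#' @param tests Tibble from [pair_signals_to_tests()].
#' @param sumstats Harmonized sumstats tibble.
#' @param eqtl Harmonized eQTL catalog.
#' @param chains A `qadapt_chains` object (required for conditional mode).
#' @param panel A [genotype_panel()] (conditional mode).
#' @param mode `"unconditional"` or `"conditional"`.
#' @param config A [coloc_config()].
#' @param cond_config A [round_config()] for the conditional statistics.
#' @return Tibble: one row per test with `mode, n_variants, pp0..pp4,
#'   called, lead_rsid, direction`.
#' @export
run_coloc <- function(tests, sumstats, eqtl, chains = NULL, panel = NULL,
                      mode = c("unconditional", "conditional"),
                      config = coloc_config(),
                      cond_config = round_config()) {
  mode <- match.arg(mode)
  purrr::map(seq_len(nrow(tests)), function(i) {
    tt <- tests[i, ]
    gw <- if (mode == "conditional") {
      conditional_gwas_for_coloc(sumstats, chains, tt$signal, panel,
                                 region = c(tt$region_start, tt$region_end),
                                 config = cond_config)
    } else {
      sumstats %>%
        filter(.data$chrom == tt$signal_chrom,
               .data$pos >= tt$region_start, .data$pos <= tt$region_end) %>%
        select("rsid", "beta", "se")
    }
    eq <- eqtl %>%
      filter(.data$gene == tt$gene, .data$tissue == tt$tissue) %>%
      select("rsid", "beta", "se")
    pp <- coloc_pps(gw, eq, config)
    dir <- NA_real_
    if (!is.na(pp$lead_rsid)) {
      bg <- gw$beta[match(pp$lead_rsid, gw$rsid)]
      be <- eq$beta[match(pp$lead_rsid, eq$rsid)]
      # eQTL effect re-signed to the trait-lowering allele of the lead SNP
      dir <- sign(be) * ifelse(bg < 0, 1, -1)
    }
    bind_cols(tt %>% select("signal", "gene", "tissue"),
              tibble(mode = mode), pp, tibble(direction = dir))
  }) %>% bind_rows()
}
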