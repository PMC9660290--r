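test_that("log_abf matches the closed form and its limits", {
  expect_equal(log_abf(0.1, 0.02, 0.15), wakefield(0.1, 0.02, 0.15))
  # null effect: pure shrinkage term, negative
  expect_equal(log_abf(0, 0.05, 0.15), 0.5 * log(0.05^2 / (0.05^2 + 0.15^2)))
  expect_lt(log_abf(0, 0.05, 0.15), 0)
  # degenerate prior: no evidence either way
  expect_equal(log_abf(0.1, 0.02, 1e-8), 0, tolerance = 1e-4)
  expect_error(log_abf(0.1, 0, 0.15), class = "qadapt_domain_error")
})

test_that("posteriors equal exhaustive enumeration on small regions", {
  cfg_default <- coloc_config()
  for (draw in 1:100) {
    withr::with_seed(draw, {
      v <- sample(1:5, 1)
      beta1 <- stats::rnorm(v, 0, 0.1)
      beta2 <- stats::rnorm(v, 0, 0.2)
      se1 <- stats::runif(v, 0.01, 0.05)
      se2 <- stats::runif(v, 0.02, 0.1)
      p1 <- 10^stats::runif(1, -5, -3)
      p2 <- 10^stats::runif(1, -5, -3)
      p12 <- 10^stats::runif(1, -7, -5)
    })
    cfg <- coloc_config(p1 = p1, p2 = p2, p12 = p12)
    rsid <- paste0("v", seq_len(v))
    got <- coloc_pps(tibble::tibble(rsid = rsid, beta = beta1, se = se1),
                     tibble::tibble(rsid = rsid, beta = beta2, se = se2),
                     cfg)
    want <- enumerate_pps(wakefield(beta1, se1, cfg$prior_sd),
                          wakefield(beta2, se2, cfg$prior_sd),
                          p1, p2, p12)
    expect_equal(unlist(got[paste0("pp", 0:4)]), want,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(unlist(got[paste0("pp", 0:4)])), 1, tolerance = 1e-9)
  }
})

test_that("a single strongly shared variant yields pp4 near 1", {
  got <- coloc_pps(tibble::tibble(rsid = "v1", beta = 0.9, se = 0.1),
                   tibble::tibble(rsid = "v1", beta = -1.0, se = 0.1))
  expect_gt(got$pp4, 0.95)
  expect_equal(got$pp3, 0)  # no distinct-variant configuration exists
})

test_that("prior limits behave as expected", {
  rsid <- paste0("v", 1:4)
  beta1 <- c(0.5, 0.1, 0, 0.05)
  beta2 <- c(0.45, 0.05, 0.02, 0)
  se <- rep(0.05, 4)
  gw <- tibble::tibble(rsid = rsid, beta = beta1, se = se)
  eq <- tibble::tibble(rsid = rsid, beta = beta2, se = se)
  # p12 -> 0 kills the shared hypothesis
  tiny <- coloc_pps(gw, eq, coloc_config(p12 = 1e-300))
  expect_lt(tiny$pp4, 1e-200)
  # all ABFs equal: pp4 / pp1 depends only on priors and variant count
  flat_gw <- tibble::tibble(rsid = rsid, beta = 0.2, se = 0.05)
  flat <- coloc_pps(flat_gw, flat_gw, coloc_config())
  L <- exp(log_abf(0.2, 0.05, 0.15))
  s <- c(1, 1e-4 * 4 * L, 1e-4 * 4 * L, 1e-8 * 12 * L^2, 1e-5 * 4 * L^2)
  expect_equal(unlist(flat[paste0("pp", 0:4)]), s / sum(s),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("signals pair with gene-tissue tests inside the 100 kb window", {
  eqtl <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G3"),
    tissue = c("kidney", "liver", "kidney", "kidney"),
    rsid = c("e1", "e2", "e3", "e4"),
    chrom = "1", pos = c(1050000, 1049000, 1150001, 1010000),
    ea = "G", nea = "A", beta = 0.1, se = 0.05, n = 500
  )
  annot <- tibble::tibble(gene = c("G1", "G2"), chrom = "1",
                          tss = c(1100000, 1200000))
  signals <- tibble::tibble(rsid = "s1", chrom = "1", pos = 1000000)
  expect_warning(tests <- pair_signals_to_tests(signals, eqtl, annot),
                 "G3")
  # G1 within 50 kb in two tissues -> two tests; G2's record is 150001 bp
  # away -> none; G3 lacks annotation -> skipped
  expect_equal(nrow(tests), 2)
  expect_setequal(tests$tissue, c("kidney", "liver"))
  expect_equal(unique(tests$region_start), 1100000 - 1e6)
  expect_equal(unique(tests$region_end), 1100000 + 1e6)
})

test_that("conditional GWAS for coloc uses the correct conditioning sets", {
  sc <- sim_scenario(
    n_gwas = 6000, n_loci = 1, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = c(10, 40), beta = c(0.2, 0.15)),
    h2_locus = 0.04, seed = 61
  )
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  loci <- sim_loci(sc, panel)
  chains <- run_discovery(gw$sumstats, loci, panel)
  expect_gte(nrow(chains$signals), 1)
  sec <- chains$signals$rsid[1]

  # signal mode: conditions on the index (plus any other signals); the
  # signal itself stays in the region as the colocalization candidate
  cstats <- conditional_gwas_for_coloc(gw$sumstats, chains, sec, panel)
  expect_false("rs1_10" %in% cstats$rsid)
  expect_true(sec %in% cstats$rsid)
  # index mode: conditions on all signals, not on itself
  istats <- conditional_gwas_for_coloc(gw$sumstats, chains, "rs1_10", panel)
  expect_false(sec %in% istats$rsid)
  expect_true("rs1_10" %in% istats$rsid)
  # index-only chains: unchanged marginal statistics
  lone <- structure(list(signals = chains$signals[0, ], loci = loci),
                    class = "qadapt_chains")
  ustats <- conditional_gwas_for_coloc(gw$sumstats, lone, "rs1_10", panel)
  m <- gw$sumstats[match(ustats$rsid, gw$sumstats$rsid), ]
  expect_equal(ustats$beta, m$beta)
  expect_equal(ustats$se, m$se)
})

test_that("shared, distinct and absent eQTL causal variants are separated", {
  # single-causal GWAS so the one-causal-variant assumption holds
  sc <- sim_scenario(
    n_gwas = 8000, n_loci = 1, n_variants = 40, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = 20, beta = 0.2),
    h2_locus = 0.03, seed = 71
  )
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  gstats <- dplyr::select(gw$sumstats, rsid, beta, se)

  shared <- sim_eqtl(sc, shared_variant = 20, effect = 1, h2 = 0.25,
                     n = 800, seed = 72)
  got_shared <- coloc_pps(gstats, shared)
  expect_gt(got_shared$pp4, 0.9)

  distinct <- sim_eqtl(sc, distinct_variant = 3, effect = 1, h2 = 0.25,
                       n = 800, seed = 73)
  expect_lt(ld(panel, "rs1_20", "rs1_3")$r2, 0.1)
  got_distinct <- coloc_pps(gstats, distinct)
  expect_gt(got_distinct$pp3, max(got_distinct$pp0, got_distinct$pp1,
                                  got_distinct$pp2, got_distinct$pp4))

  nocausal <- sim_eqtl(sc, NULL, NULL, n = 800, seed = 74)
  got_null <- coloc_pps(gstats, nocausal)
  expect_gt(got_null$pp1, 0.5)  # GWAS association only
})

test_that("conditioning rescues colocalization at multi-signal loci", {
  # two independent GWAS signals; the gene shares only the secondary
  sc <- sim_scenario(
    n_gwas = 10000, n_loci = 1, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = c(10, 40), beta = c(0.25, 0.18)),
    h2_locus = 0.05, seed = 81
  )
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  loci <- sim_loci(sc, panel)
  chains <- run_discovery(gw$sumstats, loci, panel)
  expect_gte(nrow(chains$signals), 1)
  expect_gt(ld(panel, chains$signals$rsid[1], "rs1_40")$r2, 0.8)
  sec <- chains$signals$rsid[1]
  eq <- sim_eqtl(sc, shared_variant = 40, effect = 1, h2 = 0.3,
                 n = 1000, seed = 82)
  eqstats <- dplyr::select(eq, rsid, beta, se)

  uncond <- coloc_pps(dplyr::select(gw$sumstats, rsid, beta, se), eqstats)
  cstats <- conditional_gwas_for_coloc(gw$sumstats, chains, sec, panel)
  cond <- coloc_pps(dplyr::select(cstats, rsid, beta, se), eqstats)
  expect_gt(cond$pp4, uncond$pp4)
  expect_gt(cond$pp4, 0.8)

  cmp <- compare_modes(
    tibble::tibble(signal = sec, gene = "G1", tissue = "kidney",
                   called = uncond$called),
    tibble::tibble(signal = sec, gene = "G1", tissue = "kidney",
                   called = cond$called)
  )
  expect_true(cmp$concordance %in% c("conditional-only", "both"))
})

test_that("zero shared variants yield a logged no-test result", {
  expect_message(
    res <- coloc_pps(tibble::tibble(rsid = "a", beta = 0.1, se = 0.05),
                     tibble::tibble(rsid = "b", beta = 0.1, se = 0.05)),
    "no shared"
  )
  expect_equal(res$n_variants, 0L)
  expect_true(is.na(res$pp4))
})
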