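test_that("run_round declares the best passing candidate, at most one per locus", {
  sc <- two_signal_scenario(n = 8000, seed = 5)
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  loci <- sim_loci(sc, panel)
  rr <- run_round(gw$sumstats, loci, panel)
  expect_equal(nrow(rr$declared), 1)
  expect_true(rr$declared$p_c < rr$declared$G)
  # declared candidate is the planted secondary or a close proxy
  expect_gt(ld(panel, rr$declared$rsid, "rs1_40")$r2, 0.8)
  # weights audit: all candidates tested, budget spent over m
  expect_equal(rr$m, 49L)
  expect_equal(sum(rr$weights$W), rr$m, tolerance = 1e-8)
})

test_that("loci with no passing candidate declare nothing", {
  sc <- null_scenario(n = 1500, n_loci = 2, n_variants = 30, seed = 41)
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  rr <- run_round(gw$sumstats, sim_loci(sc, panel), panel)
  # overwhelmingly nothing under the null; accept at most a rare false hit
  expect_lte(nrow(rr$declared), 1)
})

test_that("run_discovery declares the planted secondary in >= 90% of seeds", {
  detected <- 0
  for (seed in 1:20) {
    sc <- two_signal_scenario(n = 8000, seed = 200 + seed)
    panel <- sim_panel(sc)
    gw <- sim_gwas(panel, sc)
    ch <- run_discovery(gw$sumstats, sim_loci(sc, panel), panel)
    sec <- ch$signals[ch$signals$order == 2, ]
    if (nrow(sec) == 1 &&
        (sec$rsid == "rs1_40" || ld(panel, sec$rsid, "rs1_40")$r2 > 0.8)) {
      detected <- detected + 1
    }
  }
  expect_gte(detected, 18)
})

test_that("discovery iterates, restricts to advancing loci, and terminates", {
  sc <- sim_scenario(
    n_gwas = 12000, n_loci = 2, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = c(1, 1, 1, 2),
                            idx = c(10, 25, 40, 25),
                            beta = c(0.2, 0.15, 0.15, 0.2)),
    h2_locus = 0.05, seed = 9
  )
  panel <- sim_panel(sc)
  gw <- sim_gwas(panel, sc)
  ch <- run_discovery(gw$sumstats, sim_loci(sc, panel), panel)
  sig1 <- ch$signals[ch$signals$locus_id == "locus_rs1_10", ]
  # the three-causal locus yields a chain of length >= 2 (orders 2, 3, ...)
  expect_gte(nrow(sig1), 2)
  expect_equal(sig1$order, seq(2, 1 + nrow(sig1)))
  # a locus inactive after a round is never revisited
  r <- ch$rounds
  expect_true(all(diff(r$n_active_loci) <= 0))
  expect_equal(r$n_declared[nrow(r)], 0)
  # conditioning sets grow along the chain
  expect_match(sig1$conditioned_on[2], sig1$rsid[1])
  # every declared signal passed its own threshold
  expect_true(all(ch$signals$p_c < ch$signals$G))
  # tidy/glance accessors
  expect_equal(nrow(tidy(ch)), nrow(ch$signals))
  expect_equal(glance(ch)$n_signals, nrow(ch$signals))
})

test_that("the batched round-2 engine agrees with run_round exactly", {
  sc <- null_scenario(n = 2000, n_loci = 3, n_variants = 40, seed = 7)
  panel <- sim_panel(sc)
  loci <- sim_loci(sc, panel)
  prep <- qadapt:::round2_prep(panel, loci)
  for (s in 1:10) {
    gw <- sim_gwas(panel, sc, seed = 300 + s)
    rb <- qadapt:::round2_batch(prep, matrix(gw$phenotype, ncol = 1))
    eng <- unlist(lapply(rb$loci, function(l) {
      if (!is.na(l$declared[1])) l$rsid[l$declared[1]] else NULL
    }))
    if (is.null(eng)) eng <- character()
    rr <- run_round(gw$sumstats, loci, panel)
    expect_setequal(eng, rr$declared$rsid)
  }
})

test_that("label_known matches exact rsids and r2 > 0.8 proxies", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  panel <- panel_from_columns(
    sig1 = g, pub1 = g,                       # r2 = 1 proxy
    sig2 = c(1, 0, 2, 1, 2, 0, 1, 1),        # unrelated
    pos = c(100, 200, 300)
  )
  signals <- tibble::tibble(locus_id = "L1",
                            rsid = c("sig1", "sig2", "pub2", "ghost"),
                            order = 2:5)
  expect_warning(
    lab <- label_known(signals, c("pub1", "pub2"), panel),
    "absent from panel"
  )
  # r2 = 1 proxy, unrelated, exact published match, absent from panel
  expect_equal(lab$known, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("replication plans carry per-category Bonferroni thresholds", {
  # chains with 9 novel secondary, 1 novel sixth-order, 1 known tertiary
  signals <- dplyr::bind_rows(
    tibble::tibble(locus_id = paste0("L", 1:9), rsid = paste0("s", 1:9),
                   order = 2L, known = FALSE),
    tibble::tibble(locus_id = "L1", rsid = "t1", order = 3L, known = TRUE),
    tibble::tibble(locus_id = "L1", rsid = "x1", order = 6L, known = FALSE)
  )
  loci <- tibble::tibble(locus_id = paste0("L", 1:9),
                         index_rsid = paste0("i", 1:9))
  chains <- structure(list(signals = signals, loci = loci),
                      class = "qadapt_chains")
  plans <- build_replication_plans(chains)
  expect_equal(nrow(plans), 10)
  expect_equal(unique(plans$threshold[plans$category == "secondary"]), 0.05 / 9)
  expect_equal(plans$threshold[plans$category == "sixth"], 0.05)
  # known signals are not planned but do join conditioning sets
  expect_false("t1" %in% plans$rsid)
  p_x1 <- plans[plans$rsid == "x1", ]
  expect_true(all(c("i1", "t1") %in% p_x1$cond_base[[1]]))
  expect_equal(p_x1$cond_novel[[1]], "s1")
})

test_that("replication conditions on earlier replicated novel signals only", {
  sc <- sim_scenario(
    n_gwas = 6000, n_loci = 1, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = c(10, 25, 40),
                            beta = c(0.2, 0.15, 0.15)),
    h2_locus = 0.05, seed = 51
  )
  genos <- sim_panel(sc, seed = 99)
  gw <- sim_gwas(genos, sc, seed = 98)
  signals <- tibble::tibble(
    locus_id = "locus_rs1_10",
    rsid = c("rs1_25", "rs1_33", "rs1_40"),
    order = c(2L, 3L, 4L), known = FALSE
  )
  loci <- tibble::tibble(locus_id = "locus_rs1_10", index_rsid = "rs1_10")
  chains <- structure(list(signals = signals, loci = loci),
                      class = "qadapt_chains")
  plans <- build_replication_plans(chains)
  rep <- run_replication(plans, genos, gw$phenotype)
  expect_equal(rep$replicated, c(TRUE, FALSE, TRUE))
  # rs1_33 (null variant) failed, so the fourth-order conditioning set
  # contains the replicated rs1_25 but not rs1_33
  fit40 <- rep[rep$rsid == "rs1_40", ]
  expect_true(fit40$replicated)
  res_with <- conditional_individual(genos, gw$phenotype, NULL, "rs1_40",
                                     c("rs1_10", "rs1_25"))
  expect_equal(fit40$p_c, res_with$p_c)
})

test_that("quasi-adaptive detection dominates the fixed genome-wide rule", {
  # planted secondary sized so its conditional evidence sits near the
  # fixed genome-wide threshold (z about 5), where SNP-specific
  # thresholds matter most
  sc <- sim_scenario(
    n_gwas = 4000, n_loci = 1, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = c(25, 40), beta = c(0.2, 0.113)),
    h2_locus = 0.03, seed = 3
  )
  pw <- power_experiment(sc, R = 200, seed = 2)
  p_qa <- pw$power[pw$method == "quasi_adaptive"]
  p_fx <- pw$power[pw$method == "fixed_5e-8"]
  expect_gt(p_qa, p_fx)
  expect_gt(p_qa, 0.5)
})
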