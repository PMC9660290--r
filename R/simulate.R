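# Synthetic data with known ground truth: LD-blocked genotype panels
# (AR-correlated threshold-MVN haplotypes), multi-signal quantitative
# phenotypes with their marginal GWAS summary statistics, and cis-eQTL
# expression traits on an independent sample from the same LD process.
# Variant spacing maps variant index to bp so every distance step of the
# weighting scheme is exercised.

#' Simulation scenario
#'
#' @param n_gwas,n_panel,n_eqtl Sample sizes for the GWAS sample, an
#'   external LD panel, and the eQTL sample.
#' @param n_loci Number of independent loci (each on its own chromosome).
#' @param n_variants Variants per locus.
#' @param ld_rho Haplotype autoregressive correlation between adjacent
#'   variants, in \[0, 1).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5\].
#' @param causal Tibble with columns `locus, idx, beta`: causal variant
#'   positions (1-based index within the locus) and per-allele effects.
#' @param h2_locus Phenotypic variance explained by the causal set.
#' @param spacing Bp between adjacent variants (default 5 kb).
#' @param seed Default seed for the generators.
#' @return A list of class `qadapt_scenario`.
#' @export
sim_scenario <- function(n_gwas = 2000, n_panel = 2000, n_eqtl = 500,
                         n_loci = 1, n_variants = 50, ld_rho = 0.7,
                         maf_range = c(0.05, 0.5),
                         causal = tibble(locus = 1, idx = 25, beta = 1),
                         h2_locus = 0.01, spacing = 5e3, seed = 1) {
  causal <- as_tibble(causal)
  stopifnot(ld_rho >= 0, ld_rho < 1, h2_locus >= 0, h2_locus < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            nrow(causal) == 0 || all(causal$idx >= 1 & causal$idx <= n_variants),
            nrow(causal) == 0 || all(causal$locus >= 1 & causal$locus <= n_loci))
  structure(list(n_gwas = n_gwas, n_panel = n_panel, n_eqtl = n_eqtl,
                 n_loci = n_loci, n_variants = n_variants, ld_rho = ld_rho,
                 maf_range = maf_range, causal = causal,
                 h2_locus = h2_locus, spacing = spacing, seed = seed),
            class = "qadapt_scenario")
}

# haplotype block: latent AR(1) Gaussians thresholded at the MAF quantile.
# Thresholding attenuates correlation (2/pi * asin(rho) for a median
# split), so the latent autocorrelation is pre-compensated with the
# inverse map; ld_rho then approximates the realized adjacent-allele
# correlation rather than the latent one.
sim_haplotypes <- function(n_hap, maf, rho) {
  m <- length(maf)
  rho_lat <- sin(pi / 2 * rho)
  z <- matrix(0, n_hap, m)
  z[, 1] <- rnorm(n_hap)
  if (m > 1) {
    sdr <- sqrt(1 - rho_lat^2)
    for (j in 2:m) z[, j] <- rho_lat * z[, j - 1] + sdr * rnorm(n_hap)
  }
  t(t(z) < qnorm(maf)) + 0
}

#' Simulate an LD-blocked genotype panel
#'
#' Two haplotypes per sample are drawn from a latent AR(`ld_rho`) Gaussian
#' process thresholded at per-variant MAF quantiles and summed to dosages.
#' Loci are independent blocks placed on separate chromosome labels at
#' `spacing` bp between variants. Monomorphic columns (possible at small
#' n) get one carrier flipped so LD stays defined. Deterministic given
#' `seed`.
#'
#' @param scenario A [sim_scenario()].
#' @param n Sample size (default `scenario$n_gwas`).
#' @param seed Seed (default `scenario$seed`).
#' @return A [genotype_panel()].
#' @export
sim_panel <- function(scenario, n = scenario$n_gwas, seed = scenario$seed) {
  withr::with_seed(seed, {
    blocks <- purrr::map(seq_len(scenario$n_loci), function(l) {
      maf <- stats::runif(scenario$n_variants, scenario$maf_range[1],
                          scenario$maf_range[2])
      d <- sim_haplotypes(n, maf, scenario$ld_rho) +
        sim_haplotypes(n, maf, scenario$ld_rho)
      for (j in which(apply(d, 2, function(x) length(unique(x))) == 1)) {
        i <- sample.int(n, 1)
        d[i, j] <- if (d[i, j] == 0) 1 else d[i, j] - 1
      }
      list(
        dosages = d,
        variants = tibble(
          chrom = as.character(l),
          pos = 1e6 + (seq_len(scenario$n_variants) - 1) * scenario$spacing,
          rsid = sprintf("rs%d_%d", l, seq_len(scenario$n_variants)),
          ref = "A", alt = "G"
        )
      )
    })
    genotype_panel(do.call(cbind, purrr::map(blocks, "dosages")),
                   bind_rows(purrr::map(blocks, "variants")))
  })
}

# columns of the panel dosage matrix for the scenario's causal variants
causal_columns <- function(scenario, causal = scenario$causal) {
  (causal$locus - 1) * scenario$n_variants + causal$idx
}

# vectorized per-variant marginal OLS on a (possibly multi-column) y
marginal_stats_matrix <- function(X, Y) {
  n <- nrow(X)
  cmX <- colMeans(X)
  Sxx <- colSums(X^2) - n * cmX^2
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxy <- crossprod(X, Yc)                 # centered-y trick: == Xc' Yc
  Syy <- colSums(Yc^2)
  beta <- Sxy / Sxx
  SSE <- pmax(t(t(-beta * Sxy) + Syy), 0) # Syy - beta * Sxy, per column
  se <- sqrt(SSE / (n - 2) / Sxx)
  list(beta = beta, se = se, Sxx = Sxx, Syy = Syy, Sxy = Sxy)
}

#' Simulate a phenotype and its marginal GWAS summary statistics
#'
#' `y` is the causal dosage combination plus Gaussian noise scaled so that
#' the causal set explains `h2_locus` of the variance, then standardized.
#' Each variant's marginal simple regression yields one summary record.
#'
#' @param panel Panel from [sim_panel()] (the GWAS sample).
#' @param scenario The matching [sim_scenario()].
#' @param seed Seed.
#' @return List with `phenotype` (length-n vector) and `sumstats` (tibble
#'   in [read_sumstats()] layout, alleles aligned to the panel).
#' @export
sim_gwas <- function(panel, scenario, seed = scenario$seed + 1) {
  X <- panel$dosages
  n <- nrow(X)
  withr::with_seed(seed, {
    if (nrow(scenario$causal) == 0 || scenario$h2_locus == 0) {
      y <- rnorm(n)
    } else {
      g <- drop(X[, causal_columns(scenario), drop = FALSE] %*%
                  scenario$causal$beta)
      vg <- var(g)
      y <- g + rnorm(n, sd = sqrt(vg * (1 - scenario$h2_locus) /
                                    scenario$h2_locus))
    }
    y <- drop(scale(y))
  })
  ms <- marginal_stats_matrix(X, matrix(y, ncol = 1))
  beta <- unname(drop(ms$beta))
  se <- unname(drop(ms$se))
  z <- beta / se
  v <- panel$variants
  sumstats <- tibble(
    chrom = v$chrom, pos = v$pos, rsid = v$rsid,
    ea = v$alt, nea = v$ref, eaf = colMeans(X) / 2,
    beta = beta, se = se, pvalue = 2 * pnorm(-abs(z)), n = n
  )
  list(phenotype = y, sumstats = sumstats)
}

#' Simulate cis-eQTL summary statistics for one gene-tissue pair
#'
#' Expression is generated on an independent sample of `n` individuals
#' drawn from the same LD process as the panel; marginal per-variant
#' statistics are returned aligned to the panel alleles. `shared_variant`
#' and `distinct_variant` give the causal variant indices (within
#' `locus`): "shared" is meant to coincide with a GWAS causal variant of
#' the scenario, "distinct" not to; either or both may be `NULL` (no
#' causal variant: pure noise expression).
#'
#' @param scenario A [sim_scenario()].
#' @param shared_variant,distinct_variant Causal variant index/indices or
#'   `NULL`.
#' @param effect Per-allele expression effect for each causal variant.
#' @param h2 Expression variance explained by the causal set.
#' @param gene,tissue Labels for the records.
#' @param locus Locus whose block the gene sits in.
#' @param n eQTL sample size.
#' @param seed Seed.
#' @return Tibble in [read_eqtl()] layout.
#' @export
sim_eqtl <- function(scenario, shared_variant = NULL, distinct_variant = NULL,
                     effect = 1, h2 = 0.1, gene = "GENE1",
                     tissue = "tissue1", locus = 1, n = scenario$n_eqtl,
                     seed = scenario$seed + 2) {
  idx <- c(shared_variant, distinct_variant)
  causal <- if (length(idx)) {
    tibble(locus = locus, idx = idx, beta = rep(effect, length.out = length(idx)))
  } else {
    tibble(locus = integer(), idx = integer(), beta = numeric())
  }
  expr_scenario <- sim_scenario(
    n_gwas = n, n_loci = scenario$n_loci, n_variants = scenario$n_variants,
    ld_rho = scenario$ld_rho, maf_range = scenario$maf_range,
    causal = causal, h2_locus = if (length(idx)) h2 else 0,
    spacing = scenario$spacing, seed = seed
  )
  epanel <- sim_panel(expr_scenario, n = n, seed = seed)
  gw <- sim_gwas(epanel, expr_scenario, seed = seed + 1)
  gw$sumstats %>%
    filter(.data$chrom == as.character(locus)) %>%
    mutate(gene = gene, tissue = tissue) %>%
    select("gene", "tissue", "rsid", "chrom", "pos",
           "ea", "nea", "beta", "se", "n")
}

#' Loci tibble for a simulated scenario
#'
#' Builds the analysis loci directly from the scenario's planted index
#' SNPs (the first causal variant of each locus), spanning each whole
#' block.
#'
#' @param scenario A [sim_scenario()].
#' @param panel The matching panel.
#' @return Loci tibble as from [define_loci()].
#' @export
sim_loci <- function(scenario, panel) {
  idx <- scenario$causal %>%
    group_by(.data$locus) %>%
    slice(1) %>%
    ungroup()
  cols <- causal_columns(scenario, idx)
  v <- panel$variants[cols, ]
  tibble(
    locus_id = paste0("locus_", v$rsid),
    chrom = v$chrom,
    start = 1,
    end = max(panel$variants$pos) + 1,
    index_rsid = v$rsid,
    index_pos = v$pos,
    index_pvalue = NA_real_,
    merged_from = as.list(v$rsid)
  )
}
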