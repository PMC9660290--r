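# FWER and power experiments. Replicates share one genotype panel (the LD
# reference and GWAS sample coincide, as in null calibration) and redraw
# the phenotype; marginal statistics and the round-2 conditional analysis
# are evaluated as exact OLS algebra batched across replicates, which is
# what run_discovery computes variant by variant on the same data.

# Per-locus cross-product structures and pooled weights for round 2.
round2_prep <- function(panel, loci, config = round_config()) {
  X <- panel$dosages
  n <- nrow(X)
  cmX <- colMeans(X)
  Sxx <- colSums(X^2) - n * cmX^2
  per_locus <- purrr::map(seq_len(nrow(loci)), function(l) {
    locus <- loci[l, ]
    v <- panel$variants
    in_locus <- v$chrom == locus$chrom & v$pos >= locus$start &
      v$pos <= locus$end
    i <- which(v$rsid == locus$index_rsid)
    cc <- setdiff(which(in_locus), i)
    xci <- X[, i] - cmX[i]
    Sci <- drop(crossprod(X[, cc, drop = FALSE], xci))
    r2 <- Sci^2 / (Sxx[cc] * Sxx[i])
    list(index_col = i, cand_cols = cc, rsid = v$rsid[cc],
         Sci = Sci, r2 = r2, d = abs(v$pos[cc] - locus$index_pos),
         collinear = r2 > config$collinear_r2)
  })
  wt <- bind_rows(purrr::map(per_locus, ~ tibble(r2 = .x$r2, d = .x$d))) %>%
    assign_weights(config)
  offset <- 0
  for (l in seq_along(per_locus)) {
    k <- length(per_locus[[l]]$cand_cols)
    per_locus[[l]]$G <- wt$G[offset + seq_len(k)]
    per_locus[[l]]$W <- wt$W[offset + seq_len(k)]
    offset <- offset + k
  }
  list(X = X, n = n, Sxx = Sxx, per_locus = per_locus, m = nrow(wt),
       config = config)
}

# Round-2 declarations for a batch of phenotypes (columns of Y).
# Returns any_declared (length-B logical), per-locus declared candidate
# index (NA when none) and, when detail = TRUE, the conditional p matrix.
round2_batch <- function(prep, Y, detail = FALSE) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  B <- ncol(Yc)
  Syy <- colSums(Yc^2)
  Sxy <- crossprod(prep$X, Yc)            # centered-y: equals Xc' Yc
  n <- prep$n
  any_declared <- rep(FALSE, B)
  locus_out <- purrr::map(prep$per_locus, function(pl) {
    i <- pl$index_col
    cc <- pl$cand_cols
    Sxx_i <- prep$Sxx[i]
    Sxx_c <- prep$Sxx[cc]
    denom <- Sxx_c - pl$Sci^2 / Sxx_i
    b <- (Sxy[cc, , drop = FALSE] -
            (pl$Sci / Sxx_i) %o% Sxy[i, ]) / denom
    SSE_S <- Syy - Sxy[i, ]^2 / Sxx_i
    SSE <- pmax(t(t(-(b^2) * denom) + SSE_S), 0)
    se <- sqrt(SSE / (n - 3) / denom)
    p <- 2 * pnorm(-abs(b / se))
    pass <- (p < pl$G) & !pl$collinear
    declared <- rep(NA_integer_, B)
    hit <- which(colSums(pass) > 0)
    for (j in hit) {
      cand <- which(pass[, j])
      declared[j] <- cand[which.min(p[cand, j])]
    }
    any_declared[hit] <<- TRUE
    out <- list(declared = declared, rsid = pl$rsid)
    if (detail) out$p <- p
    out
  })
  list(any_declared = any_declared, loci = locus_out)
}

# Phenotype batch for a scenario on a fixed panel: causal combination plus
# scaled noise, columns standardized.
phenotype_batch <- function(panel, scenario, B, seed) {
  n <- nrow(panel$dosages)
  withr::with_seed(seed, {
    E <- matrix(rnorm(n * B), n, B)
    if (nrow(scenario$causal) == 0 || scenario$h2_locus == 0) {
      Y <- E
    } else {
      g <- drop(panel$dosages[, causal_columns(scenario), drop = FALSE] %*%
                  scenario$causal$beta)
      s <- sqrt(var(g) * (1 - scenario$h2_locus) / scenario$h2_locus)
      Y <- g + s * E
    }
    scale(Y)
  })
}

#' Family-wise error rate experiment
#'
#' Simulates one genotype panel, plants only the index variant of each
#' locus as causal, and over `R` phenotype replicates counts how often the
#' quasi-adaptive round declares at least one (necessarily false)
#' independent signal. Under the null every declaration in any later
#' round presupposes one in round 2, so the FWER equals the round-2
#' declaration rate.
#'
#' @param scenario A [sim_scenario()] with exactly one causal variant per
#'   locus.
#' @param config A [round_config()].
#' @param R Number of phenotype replicates.
#' @param seed Seed.
#' @param chunk Replicates per batch (memory/BLAS trade-off).
#' @return Object of class `qadapt_fwer`: `fwer`, `n_false`, `R`,
#'   `alpha`, `bound` (the binomial two-sigma acceptance bound
#'   `alpha + 2 * sqrt(alpha * (1 - alpha) / R)`), `m` (tested SNPs per
#'   round).
#' @export
fwer_experiment <- function(scenario, config = round_config(), R = 1000,
                            seed = 1, chunk = 250) {
  stopifnot(all(table(scenario$causal$locus) == 1))
  panel <- sim_panel(scenario, n = scenario$n_gwas, seed = seed)
  loci <- sim_loci(scenario, panel)
  prep <- round2_prep(panel, loci, config)
  n_false <- 0L
  done <- 0L
  b <- 0L
  while (done < R) {
    b <- b + 1L
    Bsz <- min(chunk, R - done)
    Y <- phenotype_batch(panel, scenario, Bsz, seed + 7919L * b)
    res <- round2_batch(prep, Y)
    n_false <- n_false + sum(res$any_declared)
    done <- done + Bsz
  }
  alpha <- config$alpha
  structure(list(fwer = n_false / R, n_false = n_false, R = R,
                 alpha = alpha,
                 bound = alpha + 2 * sqrt(alpha * (1 - alpha) / R),
                 m = prep$m, n_loci = nrow(loci)),
            class = "qadapt_fwer")
}

#' @export
print.qadapt_fwer <- function(x, ...) {
  cat(sprintf(
    "<qadapt_fwer> empirical FWER %.4f (%d/%d replicates), alpha %.3f, bound %.4f, m = %d\n",
    x$fwer, x$n_false, x$R, x$alpha, x$bound, x$m))
  invisible(x)
}

#' Power experiment: quasi-adaptive versus fixed genome-wide threshold
#'
#' Plants an index plus a secondary causal variant and compares, over `R`
#' phenotype replicates, how often each rule detects the secondary variant
#' (or a proxy with `r^2 > proxy_r2` to it): the quasi-adaptive rule
#' declares the smallest conditional p-value below its SNP-specific `G`;
#' the fixed rule the smallest conditional p-value below
#' `fixed_threshold`.
#'
#' @param scenario A [sim_scenario()] whose `causal` has two variants in
#'   the target locus: the index first, the planted secondary second.
#' @param config A [round_config()].
#' @param R Number of phenotype replicates.
#' @param seed Seed.
#' @param fixed_threshold The conventional genome-wide level (5e-8).
#' @param proxy_r2 LD above which a declared candidate counts as
#'   detecting the planted variant.
#' @param chunk Replicates per batch.
#' @return Tibble: `method, detections, R, power`.
#' @export
power_experiment <- function(scenario, config = round_config(), R = 200,
                             seed = 1, fixed_threshold = 5e-8,
                             proxy_r2 = 0.8, chunk = 200) {
  panel <- sim_panel(scenario, n = scenario$n_gwas, seed = seed)
  loci <- sim_loci(scenario, panel)
  prep <- round2_prep(panel, loci, config)
  target_locus <- scenario$causal$locus[duplicated(scenario$causal$locus)][1]
  tl <- which(loci$chrom == as.character(target_locus))
  planted <- scenario$causal %>% filter(.data$locus == target_locus) %>% slice(2)
  planted_rsid <- sprintf("rs%d_%d", planted$locus, planted$idx)
  pl <- prep$per_locus[[tl]]
  planted_pos <- match(planted_rsid, pl$rsid)
  r2_to_planted <- ld_with(panel, planted_rsid, pl$rsid)^2
  proxy <- which(r2_to_planted > proxy_r2 | seq_along(pl$rsid) == planted_pos)
  det_qa <- 0L
  det_fixed <- 0L
  done <- 0L
  b <- 0L
  while (done < R) {
    b <- b + 1L
    Bsz <- min(chunk, R - done)
    Y <- phenotype_batch(panel, scenario, Bsz, seed + 104729L * b)
    res <- round2_batch(prep, Y, detail = TRUE)
    lr <- res$loci[[tl]]
    det_qa <- det_qa + sum(!is.na(lr$declared) & lr$declared %in% proxy)
    p <- lr$p
    pass <- p < fixed_threshold & !pl$collinear
    for (j in seq_len(Bsz)) {
      cand <- which(pass[, j])
      if (length(cand) && cand[which.min(p[cand, j])] %in% proxy) {
        det_fixed <- det_fixed + 1L
      }
    }
    done <- done + Bsz
  }
  tibble(method = c("quasi_adaptive", "fixed_5e-8"),
         detections = c(det_qa, det_fixed), R = R,
         power = c(det_qa, det_fixed) / R)
}
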