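# Approximate conditional/joint association from marginal summary
# statistics plus a reference LD panel (the COJO construction), and exact
# conditional association by OLS on individual-level dosages.
#
# The summary-level reconstruction works on the centered cross-product
# scale: with sample covariances C from the panel and marginal betas, the
# normal equations of the multiple regression are rebuilt as
#   A b = rhs,  A_jk = (min(n_j, n_k) - 1) C_jk,  rhs_j = (n_j - 1) C_jj beta_j
# (the marginal OLS identity cov(g_j, y) = beta_j var(g_j)). When the panel
# is the sample that produced the summary statistics and N is constant this
# reproduces the individual-level OLS fit exactly.

#' Estimate the trait variance from summary statistics
#'
#' Per variant, `vp_j = var(g_j) * ((n_j - 2) * se_j^2 + beta_j^2)`
#' recovers the phenotypic variance implied by the marginal fit;
#' `var(g_j)` is the panel sample variance when a panel is given, else
#' `2 * eaf * (1 - eaf)`. The estimate is the median across variants. For
#' residualized/standardized phenotypes it is close to 1.
#'
#' @param sumstats Tibble with `eaf, beta, se, n` (and `rsid` if a panel
#'   is given).
#' @param panel Optional [genotype_panel()] for observed dosage variances.
#' @return Scalar trait variance.
#' @export
estimate_sigma2 <- function(sumstats, panel = NULL) {
  x <- sumstats %>% filter(.data$eaf > 0, .data$eaf < 1)
  if (nrow(x) == 0) {
    abort("no polymorphic variants: cannot estimate trait variance")
  }
  if (!is.null(panel)) {
    x <- x %>% filter(.data$rsid %in% colnames(panel$dosages))
    D <- apply(panel$dosages[, x$rsid, drop = FALSE], 2, var)
  } else {
    D <- 2 * x$eaf * (1 - x$eaf)
  }
  median(D * ((x$n - 2) * x$se^2 + x$beta^2))
}

# cross-product pieces for a set of rsids: sample covariance and variances
panel_xprod <- function(panel, rsids) {
  Y <- panel$dosages[, rsids, drop = FALSE]
  C <- stats::cov(Y)
  list(C = C, D = diag(C))
}

#' Conditional association from summary statistics
#'
#' Reconstructs, for each candidate, the multiple-regression coefficient
#' of the candidate given the conditioning set from marginal betas, SEs,
#' per-SNP sample sizes and panel LD. With an empty conditioning set the
#' marginal statistics are returned unchanged. Candidates whose `r^2` with
#' any conditioning SNP exceeds `config$collinear_r2` are returned with
#' `status = "collinear"` and `NA` estimates. P-values are two-sided
#' normal-tail probabilities of `beta_c / se_c`.
#'
#' @param sumstats Harmonized sumstats tibble containing both candidates
#'   and conditioning SNPs.
#' @param candidates Character vector of candidate rsids.
#' @param cond_set Character vector of conditioning rsids (may be empty).
#' @param panel A [genotype_panel()].
#' @param sigma2 Trait variance (see [estimate_sigma2()]).
#' @param config A [round_config()] (collinearity cutoff).
#' @return Tibble: `rsid, conditioned_on, beta_c, se_c, p_c, status`.
#' @export
conditional_from_summary <- function(sumstats, candidates, cond_set,
                                     panel, sigma2 = NULL,
                                     config = round_config()) {
  stopifnot(!any(candidates %in% cond_set))
  stats_of <- function(rsids) {
    i <- match(rsids, sumstats$rsid)
    if (anyNA(i)) abort(paste0("rsid(s) absent from sumstats: ",
                               paste(rsids[is.na(i)], collapse = ", ")))
    sumstats[i, , drop = FALSE]
  }
  cand <- stats_of(candidates)
  cond_label <- paste(cond_set, collapse = ",")
  if (length(cond_set) == 0) {
    return(tibble(rsid = candidates, conditioned_on = "",
                  beta_c = cand$beta, se_c = cand$se, p_c = cand$pvalue,
                  status = "ok"))
  }
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(sumstats, panel)
  cs <- stats_of(cond_set)
  all_ids <- c(cond_set, candidates)
  xp <- panel_xprod(panel, all_ids)
  iS <- seq_along(cond_set)
  iC <- length(cond_set) + seq_along(candidates)
  C_SS <- xp$C[iS, iS, drop = FALSE]
  C_Sc <- xp$C[iS, iC, drop = FALSE]          # |S| x n_cand
  D_S <- xp$D[iS]; D_c <- xp$D[iC]

  n_S <- cs$n; n_c <- cand$n
  n_min_S <- min(n_S)
  # pairwise min-N scaling (COJO convention); constant N reduces to OLS
  NS <- outer(n_S, n_S, pmin) - 1
  A_SS <- NS * C_SS
  rhs_S <- (n_S - 1) * D_S * cs$beta
  Ainv <- tryCatch(solve(A_SS), error = function(e)
    abort("singular LD submatrix of the conditioning set",
          class = "qadapt_numeric_error"))
  b_S <- drop(Ainv %*% rhs_S)

  n0 <- pmin(n_c, n_min_S)
  Syy <- sigma2 * (n0 - 1)
  SSE_S <- Syy - sum(b_S * rhs_S)

  # r^2 between each candidate and each conditioning SNP
  r2_mat <- (C_Sc / sqrt(D_S))^2 / rep(D_c, each = length(iS))
  collinear <- apply(r2_mat, 2, max) > config$collinear_r2

  s_Sc <- (outer(n_S, n_c, pmin) - 1) * C_Sc   # |S| x n_cand
  Sxx_c <- (n_c - 1) * D_c
  rhs_c <- Sxx_c * cand$beta
  AinvS <- Ainv %*% s_Sc                        # |S| x n_cand
  denom <- Sxx_c - colSums(s_Sc * AinvS)
  beta_c <- (rhs_c - drop(crossprod(s_Sc, b_S))) / denom
  SSE_full <- pmax(SSE_S - beta_c^2 * denom, 0)
  df <- n0 - length(cond_set) - 2
  se_c <- sqrt(SSE_full / df / denom)
  z <- beta_c / se_c
  p_c <- 2 * pnorm(-abs(z))
  bad <- collinear | denom <= .Machine$double.eps * Sxx_c * 100
  tibble(
    rsid = candidates,
    conditioned_on = cond_label,
    beta_c = unname(ifelse(bad, NA_real_, beta_c)),
    se_c = unname(ifelse(bad, NA_real_, se_c)),
    p_c = unname(ifelse(bad, NA_real_, p_c)),
    status = unname(ifelse(bad, "collinear", "ok"))
  )
}

#' Joint association from summary statistics
#'
#' Solves the reconstructed normal equations for all SNPs simultaneously,
#' returning per-SNP joint effects, SEs and normal-tail p-values. Under
#' the same-sample, constant-N contract this equals the individual-level
#' OLS joint fit.
#'
#' @inheritParams conditional_from_summary
#' @param rsids SNPs to fit jointly.
#' @return Tibble: `rsid, beta_j, se_j, p_j`.
#' @export
joint_from_summary <- function(sumstats, rsids, panel, sigma2 = NULL) {
  i <- match(rsids, sumstats$rsid)
  if (anyNA(i)) abort("rsid(s) absent from sumstats")
  x <- sumstats[i, , drop = FALSE]
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(sumstats, panel)
  xp <- panel_xprod(panel, rsids)
  n <- x$n
  A <- (outer(n, n, pmin) - 1) * xp$C
  rhs <- (n - 1) * xp$D * x$beta
  Ainv <- tryCatch(solve(A), error = function(e)
    abort("singular LD matrix", class = "qadapt_numeric_error"))
  b <- drop(Ainv %*% rhs)
  n0 <- min(n)
  Syy <- sigma2 * (n0 - 1)
  SSE <- max(Syy - sum(b * rhs), 0)
  df <- n0 - length(rsids) - 1
  se <- sqrt(SSE / df * diag(Ainv))
  z <- b / se
  tibble(rsid = rsids, beta_j = unname(b), se_j = unname(se),
         p_j = unname(2 * pnorm(-abs(z))))
}

#' Conditional association from individual-level data
#'
#' OLS fit of the phenotype on the candidate dosage, the conditioning
#' dosages and any covariates (plus an intercept); returns the candidate
#' term with a normal-approximation p-value.
#'
#' @param genos A [genotype_panel()] of the analysis sample.
#' @param phenotype Numeric vector, one value per panel sample.
#' @param covariates Optional numeric matrix/data frame of per-sample
#'   covariate columns.
#' @param candidate Candidate rsid.
#' @param cond_set Conditioning rsids (may be empty).
#' @return One-row tibble: `rsid, conditioned_on, beta_c, se_c, p_c, status`.
#' @export
conditional_individual <- function(genos, phenotype, covariates = NULL,
                                   candidate, cond_set = character()) {
  n <- length(phenotype)
  stopifnot(n == nrow(genos$dosages))
  g <- genos$dosages[, candidate, drop = FALSE]
  Gs <- if (length(cond_set)) genos$dosages[, cond_set, drop = FALSE] else NULL
  Cv <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  X <- cbind(`(Intercept)` = 1, g, Gs, Cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "qadapt_rank_error")
  }
  fit <- lm.fit(X, phenotype)
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  XtX_inv <- chol2inv(qr.R(qrX))
  pivot_back <- order(qrX$pivot)
  XtX_inv <- XtX_inv[pivot_back, pivot_back, drop = FALSE]
  se_all <- sqrt(rss / df * diag(XtX_inv))
  j <- match(candidate, colnames(X))
  beta_c <- unname(fit$coefficients[j])
  se_c <- se_all[j]
  z <- beta_c / se_c
  tibble(rsid = candidate,
         conditioned_on = paste(cond_set, collapse = ","),
         beta_c = beta_c, se_c = se_c, p_c = 2 * pnorm(-abs(z)),
         status = "ok")
}
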