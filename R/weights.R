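# Quasi-adaptive candidate weighting: LD and distance pre-weights combined
# by a k-weighted geometric mean, normalized across all tested SNPs of a
# round, and turned into SNP-specific alpha thresholds via the weighted
# Sidak correction G_i = 1 - (1 - alpha)^(W_i / m).

#' Round configuration for the quasi-adaptive procedure
#'
#' @param alpha Global family-wise error budget spent per round.
#' @param k Distance-emphasis exponent of the combined pre-weight
#'   `w = (w_d^k * w_r2)^(1/(k+1))`; larger `k` puts more emphasis on
#'   distance than on LD.
#' @param r2_opt LD value at which the LD pre-weight is maximal.
#' @param collinear_r2 Candidate-conditioning `r^2` above which a candidate
#'   is skipped as collinear in conditional analysis.
#' @param r2_form Algebraic form of the LD pre-weight, see [preweight_r2()].
#' @return A list of class `qadapt_config`.
#' @export
round_config <- function(alpha = 0.05, k = 5, r2_opt = 0.3,
                         collinear_r2 = 0.9,
                         r2_form = c("absolute", "shifted")) {
  stopifnot(alpha > 0, alpha < 1, k >= 0, k == as.integer(k),
            r2_opt > 0, r2_opt < 1)
  structure(list(alpha = alpha, k = k, r2_opt = r2_opt,
                 collinear_r2 = collinear_r2,
                 r2_form = match.arg(r2_form)),
            class = "qadapt_config")
}

#' LD pre-weight
#'
#' Unimodal in `r2` with maximum 1 at `r2 = r2_opt`:
#' `w_r2 = max(0, 1 - |r2 - r2_opt| / (1 - r2_opt))` (the `"absolute"`
#' form, the default). The `"shifted"` form
#' `1 - (|r2 - r2_opt| - r2_opt) / (1 - r2_opt)` is an alternative reading
#' of the same weighting family, kept behind this switch.
#'
#' @param r2 LD with the locus index SNP, in \[0, 1\]. Vectorized.
#' @param r2_opt Optimal LD (default 0.3).
#' @param form `"absolute"` (default) or `"shifted"`.
#' @return Non-negative pre-weight(s).
#' @export
preweight_r2 <- function(r2, r2_opt = 0.3, form = c("absolute", "shifted")) {
  form <- match.arg(form)
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE) || anyNA(r2)) {
    abort("r2 must lie in [0, 1]", class = "qadapt_domain_error")
  }
  if (form == "absolute") {
    pmax(0, 1 - abs(r2 - r2_opt) / (1 - r2_opt))
  } else {
    pmax(0, 1 - (abs(r2 - r2_opt) - r2_opt) / (1 - r2_opt))
  }
}

#' Distance pre-weight
#'
#' Step function down-weighting candidates far from the index SNP:
#' 1 for d <= 1 kb, 0.5 to 10 kb, 0.25 to 50 kb, 0.125 to 100 kb, and
#' 0.0625 beyond (the last step is continued past 500 kb so that
#' candidates in wide merged loci keep a positive weight).
#'
#' @param d Absolute distance to the index SNP in bp, > 0. Vectorized.
#' @return Pre-weight(s) in `{1, 0.5, 0.25, 0.125, 0.0625}`.
#' @export
preweight_d <- function(d) {
  if (any(d <= 0, na.rm = TRUE) || anyNA(d)) {
    abort("d must be > 0", class = "qadapt_domain_error")
  }
  dplyr::case_when(
    d <= 1e3 ~ 1,
    d <= 1e4 ~ 0.5,
    d <= 5e4 ~ 0.25,
    d <= 1e5 ~ 0.125,
    TRUE ~ 0.0625
  )
}

#' Combine distance and LD pre-weights
#'
#' Weighted geometric mean `w = (w_d^k * w_r2)^(1/(k+1))`; with the
#' default `k = 5` the distance pre-weight dominates. `w` is zero iff
#' either pre-weight is zero.
#'
#' @param w_d,w_r2 Pre-weights (vectorized).
#' @param k Distance-emphasis exponent.
#' @return Combined pre-weight(s).
#' @export
combine_weights <- function(w_d, w_r2, k = 5) {
  (w_d^k * w_r2)^(1 / (k + 1))
}

#' Normalize combined weights over the tested SNPs of a round
#'
#' `W_i = w_i * m / sum(w)`, so that the `W_i` sum to `m`, the number of
#' SNPs tested in the round.
#'
#' @param w Combined pre-weights of all tested SNPs.
#' @return Normalized weights summing to `length(w)`.
#' @export
normalize_weights <- function(w) {
  s <- sum(w)
  if (s <= 0) {
    abort("all combined weights are zero: degenerate round",
          class = "qadapt_degenerate_round")
  }
  w * length(w) / s
}

#' SNP-specific significance threshold (weighted Sidak)
#'
#' `G = 1 - (1 - alpha)^(W / m)`. The thresholds multiply back to the
#' global budget: the product of `1 - G_i` over all `m` tested SNPs equals
#' `1 - alpha` whenever the `W_i` sum to `m`. With uniform weights every
#' `G` reduces to the classical Sidak per-test level.
#'
#' @param W Normalized weight(s).
#' @param m Number of SNPs tested in the round.
#' @param alpha Global error budget.
#' @return Threshold(s) in \[0, alpha\] for `W <= m`.
#' @export
alpha_threshold <- function(W, m, alpha = 0.05) {
  stopifnot(all(W >= 0), m >= 1)
  -expm1(log1p(-alpha) * W / m)
}

#' Assign quasi-adaptive weights and thresholds to a candidate table
#'
#' Adds `w_r2, w_d, w, W, G` to a table of candidates carrying `r2` (LD
#' with the locus index SNP) and `d` (bp distance to it). Normalization
#' and the Sidak exponent use `m`, the total number of SNPs tested in the
#' round -- by default the number of rows, i.e. all candidates across the
#' active loci are pooled.
#'
#' @param candidates Tibble with columns `r2` and `d`.
#' @param config A [round_config()].
#' @param m Number of tested SNPs (default `nrow(candidates)`).
#' @return `candidates` with weight columns appended.
#' @export
assign_weights <- function(candidates, config = round_config(),
                           m = nrow(candidates)) {
  candidates %>%
    mutate(
      w_r2 = preweight_r2(.data$r2, config$r2_opt, config$r2_form),
      w_d = preweight_d(.data$d),
      w = combine_weights(.data$w_d, .data$w_r2, config$k),
      W = {
        s <- sum(.data$w)
        if (s <= 0) abort("all combined weights are zero: degenerate round",
                          class = "qadapt_degenerate_round")
        .data$w * m / s
      },
      G = alpha_threshold(.data$W, m, config$alpha)
    )
}
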