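# broom-style accessors for fitted objects.

#' Tidy a discovery result
#'
#' @param x A `qadapt_chains` object from [run_discovery()].
#' @param ... Unused.
#' @return The signals tibble with a human-readable `category` column.
#' @exportS3Method generics::tidy
tidy.qadapt_chains <- function(x, ...) {
  x$signals %>% mutate(category = order_label(.data$order))
}

#' One-row summary of a discovery result
#'
#' @param x A `qadapt_chains` object.
#' @param ... Unused.
#' @return Tibble with locus/signal/round counts, the error budget and
#'   the trait variance used.
#' @exportS3Method generics::glance
glance.qadapt_chains <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci),
    n_loci_with_signals = length(unique(x$signals$locus_id)),
    n_signals = nrow(x$signals),
    max_order = if (nrow(x$signals)) max(x$signals$order) else 1L,
    n_rounds = nrow(x$rounds),
    alpha = x$config$alpha,
    sigma2 = x$sigma2
  )
}

#' Tidy an FWER experiment
#'
#' @param x A `qadapt_fwer` object from [fwer_experiment()].
#' @param ... Unused.
#' @return One-row tibble with the empirical FWER, its binomial standard
#'   error and the two-sigma acceptance bound.
#' @exportS3Method generics::tidy
tidy.qadapt_fwer <- function(x, ...) {
  tibble(
    fwer = x$fwer, n_false = x$n_false, R = x$R, alpha = x$alpha,
    se = sqrt(x$fwer * (1 - x$fwer) / x$R), bound = x$bound, m = x$m
  )
}

#' @rdname tidy.qadapt_fwer
#' @exportS3Method generics::glance
glance.qadapt_fwer <- function(x, ...) tidy(x, ...)
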