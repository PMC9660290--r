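---
title: "SNP-specific significance thresholds for multiple independent GWAS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-specific significance thresholds for multiple independent GWAS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qadapt)
library(dplyr)
```

## The problem

Complex-trait GWAS loci are frequently allelically heterogeneous: behind the
index SNP (the variant with the smallest marginal p-value of a locus) further
variants carry independent association signals that only become visible after
conditioning on the signals already found. The conventional practice is to
test conditional associations against the genome-wide level $5\times10^{-8}$.
That level was calibrated for a genome-wide search; a conditional scan is
confined to a known locus, so the fixed threshold is needlessly conservative
there and secondary signals are missed.

`qadapt` implements a quasi-adaptive alternative: the type-I error budget
$\alpha$ of one conditional round is spent unevenly over the $m$ candidate
SNPs of that round, guided by where an independent signal is a priori more
plausible. Each candidate $i$ receives a SNP-specific level

$$G_i = 1 - (1-\alpha)^{W_i/m},$$

the weighted Šidák correction. Because the normalized weights $W_i$ sum to
$m$, the levels multiply back to the exact budget:
$\prod_i (1-G_i) = 1-\alpha$, so the family-wise error rate over a round is
controlled at $\alpha$ regardless of how the weights are chosen (the tests'
positive dependence through LD only makes the procedure conservative).

## The weights

Two pre-weights encode the prior plausibility of candidate $i$, both measured
against the **primary index SNP** of the locus:

* an LD pre-weight, maximal at an intermediate LD
  ($r^2_{\text{opt}} = 0.3$ by default):
  $w_{r^2} = \max\!\big(0,\, 1 - |r^2 - 0.3|/(1 - 0.3)\big)$.
  Variants in very high LD with the index mostly shadow its own signal,
  variants in LD zero carry no positional prior; intermediate LD is where
  distinct-but-linked causal variants tend to sit.
* a distance pre-weight, a step function of the bp distance $d$ to the
  index: $1$ up to 1 kb, then $0.5$, $0.25$, $0.125$ down to $0.0625$ for
  100--500 kb. We continue the last step beyond 500 kb instead of dropping
  such candidates: merged loci can legitimately contain candidates further
  than 500 kb from the merged index, and a zero weight would silently make
  them untestable.

They are combined by a $k$-weighted geometric mean,
$w = (w_d^k \, w_{r^2})^{1/(k+1)}$ with $k = 5$, which puts most of the
emphasis on distance, then normalized over all $m$ candidates of the round,
$W_i = w_i\, m / \sum_j w_j$. The constants $\alpha = 0.05$,
$r^2_{\text{opt}} = 0.3$ and $k = 5$ are the method's standard operating
point and are exposed in `round_config()`, not estimated from data.

One note on the LD pre-weight's algebraic form: the weighting family can be
written with the deviation $|r^2-0.3|$ entering either directly or shifted
by $0.3$ before scaling. We implement the direct form (above), which makes
the stated optimum $r^2 = 0.3$ the unique maximum with weight 1 and
decreases linearly to 0 at $r^2 = 1$; the shifted variant remains available
via `preweight_r2(..., form = "shifted")`. The choice affects only the
*shape* of the LD prior, never the error control, which rests entirely on
the normalization.

## Rounds, loci, and the iterative chain

Loci are 1 Mb windows centered on published index SNPs. Windows whose index
SNPs are closer than 1 Mb or correlated at $r^2 > 0.1$ are merged — we merge
transitively (iterated to a fixed point), the only reading that does not
depend on processing order — keeping the union of the bounds and the
smallest-p index. Loci overlapping the extended MHC (chr6:25--34 Mb on
GRCh37; the region's LD is too complex for reliable conditional
reconstruction) are removed. The MHC coordinates are configurable since
conventions differ by a few Mb.

Round 2 (secondary signals) tests all candidates of all loci, conditioning
each locus's candidates on its index SNP. A locus declares at most one
signal per round: the candidate with the smallest conditional p-value among
those with $p_c < G_i$ (strictly; ties, which have probability zero with
continuous data, are broken by larger $W$, then smaller $d$, then rsid, to
keep output deterministic). Round 3 is restricted to loci that declared in
round 2, conditions on the index *and* the secondary signal, and recomputes
$m$ over the remaining candidates; and so on until a round declares nothing.
Throughout, $r^2$ and $d$ keep referring to the primary index SNP — the LD
structure of the locus does not change between rounds, only the conditioning
set and $m$ do, which is what keeps the FWER argument valid round by round.

## Conditional analysis from summary statistics

Conditional effects are reconstructed from marginal summary statistics plus
a genotype reference panel, in the COJO tradition. We rebuild the normal
equations of the multiple regression on the centered cross-product scale:
with panel sample covariances $C$ and the marginal OLS identity
$\widehat{\mathrm{cov}}(g_j, y) = \hat\beta_j \widehat{\mathrm{var}}(g_j)$,

$$A\,b = r, \qquad A_{jk} = (\min(n_j, n_k) - 1)\, C_{jk}, \qquad
  r_j = (n_j - 1)\, C_{jj}\, \hat\beta_j .$$

The trait variance needed for standard errors is recovered per variant as
$\widehat{\mathrm{var}}(y) = \mathrm{var}(g_j)\{(n_j - 2)\,se_j^2 +
\hat\beta_j^2\}$ — the exact inversion of the marginal OLS algebra under the
sample-variance convention, which at GWAS sample sizes is numerically
indistinguishable from the usual $n\,se^2$ form — and aggregated as the
median over variants, once per run (re-estimating it per round would let
Monte-Carlo noise into every threshold comparison). When the panel *is* the
sample that produced the summary statistics and $N$ is constant, this
construction reproduces the individual-level OLS fit exactly; the test suite
asserts agreement to $10^{-6}$ relative error and observes $10^{-13}$.
Per-SNP sample sizes are honored through the pairwise $\min(n_j,n_k)$
scaling; candidates with $r^2 > 0.9$ to the conditioning set are skipped as
collinear rather than returned with exploding standard errors. P-values are
two-sided normal tails of $\beta_c / se_c$, consistent with meta-analysis
z-statistics, not $t$ quantiles.

Replication uses individual-level data: OLS of the (residualized) phenotype
on the candidate dosage, the conditioning dosages and covariates. A mixed
model would be preferable in samples with relatedness; our synthetic samples
are unrelated by construction, so OLS is the correct model here and keeps
the oracle equivalence exact. Replication proceeds category by category
(secondary, tertiary, ...) with a Bonferroni threshold of $0.05$ divided by
the number of *novel* signals tested in the category; the conditioning set
of a signal contains the index, the known lower-order signals, and the novel
lower-order signals that themselves replicated — failed novel signals are
excluded, which is why categories must be processed in order.

## Colocalization

For functional interpretation, each signal (index SNPs and independent
signals alike) is tested for a shared causal variant with cis-eQTLs:
gene-tissue pairs with an eQTL record within 100 kb of the signal are
paired, and the test region is the gene's TSS $\pm$ 1 Mb. Per variant we
compute Wakefield's approximate Bayes factor from `beta`, `se` and an
effect-size prior SD, and aggregate over the five standard hypotheses (no
association / trait 1 only / trait 2 only / two distinct causal variants /
one shared causal variant) with priors $p_1 = p_2 = 10^{-4}$ and
$p_{12} = 10^{-5}$. All sums run in log space (log-sum-exp), and the test
suite checks the posteriors against an exhaustive enumeration over
causal-variant configurations to $10^{-9}$. The prior SD defaults to 0.15,
the usual quantitative-trait operating point; only $p_{12}$ is a fixed
methodological constant here, so conclusions that hinge on the prior SD
should be re-run across `prior_sd` $\in \{0.1, 0.15, 0.2\}$, all of which
are plain arguments of `coloc_config()`.

The single-causal-variant assumption of this scheme is exactly what multiple
independent signals violate: a second GWAS signal in the region inflates the
evidence for "two distinct variants" (PP3) at the expense of PP4.
`conditional_gwas_for_coloc()` therefore rebuilds the GWAS side
conditionally — an index SNP is conditioned on all other signals of its
locus, an independent signal on the index plus all other signals except
itself — and `compare_modes()` classifies each gene-tissue test as called in
both modes, one mode, or neither. The packaged simulation reproduces the
expected pattern: with a two-signal locus and an eQTL sharing only the
secondary variant, the unconditional posterior is diluted while the
conditional one calls the gene (PP4 $\ge 0.8$).

## The synthetic-data generator

`sim_panel()` draws two haplotypes per individual from a latent Gaussian
AR(1) process thresholded at per-variant MAF quantiles and sums them to
dosages. Thresholding attenuates correlation, so the latent autocorrelation
is pre-compensated with the inverse of the median-split attenuation map
($\rho_{\text{latent}} = \sin(\tfrac{\pi}{2}\rho)$); `ld_rho` then
approximates the realized adjacent-variant correlation. Variants sit 5 kb
apart, so a 50-variant block spans 245 kb and candidates exercise every step
of the distance pre-weight. Defaults: `ld_rho = 0.7` (a moderately tight LD
block), MAFs uniform on the stated range, phenotypes standardized with the
causal set explaining `h2_locus` of the variance. What the generator does
*not* emulate: realistic human recombination maps and LD irregularity,
population structure or relatedness, binary traits, and allele-frequency
spectra — a green property suite here demonstrates the statistical
machinery, not robustness to those features of real cohorts.

All generators take explicit seeds and restore the RNG state; nothing
depends on the global random state.

## Experiment design and problem sizes

The error-control experiment plants only the index variant as causal in each
of 20 loci of 200 variants ($m = 3980$ candidates), simulates 1000 phenotype
replicates at $n = 10{,}000$ on a fixed panel, and counts replicates with at
least one declaration; the acceptance bound is the binomial two-sigma bound
$\alpha + 2\sqrt{\alpha(1-\alpha)/R} \approx 0.064$. Under a null locus a
declaration in any later round presupposes one in round 2, so the experiment
evaluates round 2 — batched across replicates as matrix algebra on the
centered cross-products, which the test suite verifies agrees declaration-
for-declaration with the variant-by-variant `run_discovery()` path. One
panel is shared across replicates (it is the LD reference *and* the GWAS
sample, the regime in which the conditional reconstruction is exact), so the
experiment isolates the thresholding procedure itself.

The power comparison plants a secondary effect sized so that its conditional
evidence sits near the fixed genome-wide threshold ($z \approx 5$, i.e.
conditional p around $10^{-7}$) — the regime the SNP-specific thresholds
were designed for — and scores each rule by detection of the planted variant
or an $r^2 > 0.8$ proxy. At desk scale ($m \approx 50$) the quasi-adaptive
thresholds are orders of magnitude more liberal than $5\times10^{-8}$ while
still multiplying to the same budget, and the measured power dominance is
substantial.

Smaller scenarios (1--5 loci, 30--60 variants, $n$ = 1000--12,000) are used
throughout the unit tests; they were chosen as the smallest sizes at which
the tested asymptotics (normal-tail p-values, parameter recovery within
2 SE, proxy detection) are comfortably in force.

## Numerical choices and degenerate inputs

* Thresholds are computed as `-expm1(log1p(-alpha) * W / m)`; the budget
  product is exact to $10^{-14}$ even for thousands of weights.
* A round in which every combined weight is zero is refused
  (`qadapt_degenerate_round`) rather than silently renormalized.
* Zero-variance dosage columns make LD undefined and error; the simulator
  flips one carrier at monomorphic columns so this cannot arise internally.
* Palindromic (A/T, C/G) variants with EAF in [0.4, 0.6] are excluded at
  harmonization as strand-ambiguous — the standard practice window; outside
  it the minor allele identifies the strand.
* Missing dosages are mean-imputed per variant (keeping LD estimable) with
  the missing fraction logged in the panel's variant table.
* Variant matching between summary statistics and panel goes by
  chromosome+position with rsid as tiebreak, which survives multiallelic
  splits; merged-locus merging compares index-SNP distance (not window
  edges), matching how adjacent loci are described.

## Known limitations

Conditional reconstruction with an *external* LD panel is approximate; the
guarantees here are proven exact only in the same-sample regime, and with an
external panel of the same population the conditional z-scores track the
oracle closely but not to machine precision. Conditional eQTL catalogs are
not modeled — the eQTL side of every colocalization is marginal, so a gene
with multiple eQTL signals keeps some PP3 inflation that conditioning the
GWAS side cannot remove. Stepwise model selection (COJO-slct) is
intentionally absent: the quasi-adaptive procedure replaces it.
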