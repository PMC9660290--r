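# Fixtures built in code: tiny summary-statistics files, hand-sized
# genotype panels, a minimal VCF, and shared simulation scenarios.

sumstats_header <- c("Chr", "Pos_b37", "RSID", "EA", "NEA", "EAF", "Beta",
                     "SE", "P", "N")

write_sumstats_file <- function(rows, path = withr::local_tempfile(
                                  fileext = ".tsv", .local_envir = parent.frame())) {
  readr::write_tsv(rows, path)
  path
}

# three valid records, incl. the rs147877018 line from the packaged
# replication table (eaf 0.081, beta -0.0047, se 0.0007)
tiny_sumstats_rows <- function() {
  tibble::tibble(
    Chr = c("3", "1", "1"),
    Pos_b37 = c(141813349, 1000, 2000),
    RSID = c("rs147877018", "rsA", "rsB"),
    EA = c("A", "G", "C"),
    NEA = c("G", "A", "T"),
    EAF = c(0.081, 0.3, 0.45),
    Beta = c(-0.0047, 0.02, -0.01),
    SE = c(0.0007, 0.01, 0.008),
    P = c(1.18e-12, 0.045, 0.21),
    N = c(783978, 10000, 10000)
  )
}

# small deterministic panel from explicit dosage columns
panel_from_columns <- function(..., chrom = NULL, pos = NULL,
                               ref = NULL, alt = NULL) {
  cols <- list(...)
  m <- length(cols)
  d <- do.call(cbind, cols)
  genotype_panel(
    d,
    tibble::tibble(
      chrom = chrom %||% rep("1", m),
      pos = pos %||% (1000 * seq_len(m)),
      rsid = names(cols) %||% paste0("v", seq_len(m)),
      ref = ref %||% rep("A", m),
      alt = alt %||% rep("G", m)
    )
  )
}

write_tiny_vcf <- function(path = withr::local_tempfile(
                             fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "1000", "rsA", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "2000", "rsB", "C", "T", ".", "PASS", ".", "GT:DS",
            "0/1:1.73", "0/0:0.21"), collapse = "\t"),
    paste(c("1", "3000", "rsC", "A", "G,T", ".", "PASS", ".", "GT",
            "0/1", "0/2"), collapse = "\t")
  ), path)
  path
}

# one-locus scenario with a planted secondary on common variants
two_signal_scenario <- function(n = 6000, beta2 = 0.14, seed = 3) {
  sim_scenario(
    n_gwas = n, n_loci = 1, n_variants = 50, ld_rho = 0.7,
    maf_range = c(0.2, 0.5),
    causal = tibble::tibble(locus = 1, idx = c(25, 40), beta = c(0.2, beta2)),
    h2_locus = 0.03, seed = seed
  )
}

null_scenario <- function(n = 4000, n_loci = 5, n_variants = 60, seed = 2) {
  sim_scenario(
    n_gwas = n, n_loci = n_loci, n_variants = n_variants, ld_rho = 0.7,
    maf_range = c(0.05, 0.5),
    causal = tibble::tibble(locus = seq_len(n_loci),
                            idx = ceiling(n_variants / 2), beta = 0.1),
    h2_locus = 0.02, seed = seed
  )
}

`%||%` <- rlang::`%||%`
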