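# Readers and writers for GWAS summary statistics, genotype panels,
# cis-eQTL catalogs and gene annotations, plus allele harmonization and
# pairwise LD. All coordinates are 1-based GRCh37 (b37); distances are
# absolute bp differences.

SUMSTATS_COLS <- c(
  Chr = "chrom", Pos_b37 = "pos", RSID = "rsid", EA = "ea", NEA = "nea",
  EAF = "eaf", Beta = "beta", SE = "se", P = "pvalue", N = "n"
)

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with header columns
#' `Chr, Pos_b37, RSID, EA, NEA, EAF, Beta, SE, P, N` (any order) into a
#' tibble with one row per variant. Rows violating the record invariants
#' (`ea != nea`, `eaf` in \[0, 1\], `se > 0`, `pvalue` in (0, 1\], `n > 0`)
#' are dropped; the number of dropped rows is reported and stored in the
#' `"n_dropped"` attribute.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `chrom, pos, rsid, ea, nea, eaf, beta,
#'   se, pvalue, n`.
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           Chr = readr::col_character(),
                           RSID = readr::col_character(),
                           EA = readr::col_character(),
                           NEA = readr::col_character(),
                           .default = readr::col_double()
                         ))
  missing <- setdiff(names(SUMSTATS_COLS), names(raw))
  if (length(missing) > 0) {
    abort(paste0("summary-statistics file is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "qadapt_format_error")
  }
  out <- raw %>%
    select(dplyr::all_of(names(SUMSTATS_COLS))) %>%
    rename(!!!setNames(names(SUMSTATS_COLS), unname(SUMSTATS_COLS))) %>%
    mutate(ea = toupper(.data$ea), nea = toupper(.data$nea))
  keep <- sumstats_valid(out)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("read_sumstats: dropped %d row(s) failing record invariants",
                   n_dropped))
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

sumstats_valid <- function(x) {
  ok <- !is.na(x$pos) & !is.na(x$beta) & !is.na(x$se) & !is.na(x$pvalue) &
    !is.na(x$eaf) & !is.na(x$n) &
    x$ea != x$nea & x$eaf >= 0 & x$eaf <= 1 & x$se > 0 &
    x$pvalue > 0 & x$pvalue <= 1 & x$n > 0
  ok & !is.na(ok)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_sumstats()]: writes the external column layout so that
#' a read/write round trip preserves all retained fields.
#'
#' @param sumstats Tibble as returned by [read_sumstats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- sumstats %>%
    select(dplyr::all_of(unname(SUMSTATS_COLS))) %>%
    rename(!!!setNames(unname(SUMSTATS_COLS), names(SUMSTATS_COLS)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a cis-eQTL catalog
#'
#' Tab-separated file with columns `gene, tissue, rsid, chrom, pos, ea,
#' nea, beta, se, n`. Rows with `se <= 0` are dropped.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble, one row per gene-tissue-variant association.
#' @export
read_eqtl <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene = readr::col_character(),
                           tissue = readr::col_character(),
                           rsid = readr::col_character(),
                           chrom = readr::col_character(),
                           ea = readr::col_character(),
                           nea = readr::col_character(),
                           .default = readr::col_double()
                         ))
  need <- c("gene", "tissue", "rsid", "chrom", "pos", "ea", "nea",
            "beta", "se", "n")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(paste0("eQTL catalog is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "qadapt_format_error")
  }
  bad <- is.na(out$se) | out$se <= 0
  if (any(bad)) {
    inform(sprintf("read_eqtl: dropped %d row(s) with non-positive SE", sum(bad)))
  }
  out[!bad, , drop = FALSE]
}

#' Read a gene annotation table
#'
#' Tab-separated file with columns `gene, chrom, tss` (1-based
#' transcription start site).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene = readr::col_character(),
                           chrom = readr::col_character(),
                           tss = readr::col_double()
                         ))
  missing <- setdiff(c("gene", "chrom", "tss"), names(out))
  if (length(missing) > 0) {
    abort(paste0("gene annotation is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "qadapt_format_error")
  }
  if (any(out$tss < 1)) abort("gene annotation: tss must be >= 1")
  out
}

# ---- genotype panel -------------------------------------------------------

#' Construct a genotype panel
#'
#' A panel is the LD reference: a samples-by-variants dosage matrix in
#' \[0, 2\] plus per-variant metadata. Missing dosages must already be
#' imputed (see [read_panel()]).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param variants Tibble with columns `chrom, pos, rsid, ref, alt` (and
#'   optionally `af`); one row per dosage column, same order.
#' @param samples Character vector of sample IDs (defaults to rownames).
#' @return An object of class `qadapt_panel`.
#' @export
genotype_panel <- function(dosages, variants, samples = NULL) {
  variants <- as_tibble(variants)
  if (ncol(dosages) != nrow(variants)) {
    abort("dosage column count must equal variant metadata row count")
  }
  if (is.null(samples)) {
    samples <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  }
  if (length(samples) != nrow(dosages)) {
    abort("sample count must equal dosage row count")
  }
  if (anyDuplicated(variants$rsid)) abort("duplicate variant rsids in panel")
  storage.mode(dosages) <- "double"
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9, na.rm = TRUE)) {
    abort("dosages must lie in [0, 2]")
  }
  dimnames(dosages) <- list(samples, variants$rsid)
  if (!"af" %in% names(variants)) variants$af <- colMeans(dosages) / 2
  structure(
    list(samples = samples, variants = variants, dosages = dosages),
    class = "qadapt_panel"
  )
}

#' @export
print.qadapt_panel <- function(x, ...) {
  cat(sprintf("<qadapt_panel> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.qadapt_panel <- function(x) dim(x$dosages)

#' Read a genotype panel from VCF or a dosage matrix
#'
#' For VCF input, per-genotype dosage is taken from the `DS` FORMAT field
#' when present, otherwise from `GT` (count of ALT alleles). Non-biallelic
#' records are skipped with a warning. For `dosage` input, `path` is a
#' tab-separated samples-by-variants matrix (first column `sample`) and
#' `variants` a tab-separated metadata sidecar with columns
#' `chrom, pos, rsid, ref, alt`. Missing dosages are mean-imputed per
#' variant; the per-variant missing fraction is stored in the panel's
#' variant table as `miss_frac`.
#'
#' @param path Path to the VCF or dosage matrix file.
#' @param format `"vcf"` or `"dosage"`; `"auto"` guesses from the extension.
#' @param variants Metadata sidecar path (dosage format only); defaults to
#'   `paste0(path, ".variants.tsv")`.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "dosage"),
                       variants = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "vcf") read_panel_vcf(path) else read_panel_dosage(path, variants)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) >= 1 & !is.na(fix$ALT)
  if (any(!biallelic)) {
    warn(sprintf("read_panel: skipped %d non-biallelic VCF record(s)",
                 sum(!biallelic)))
  }
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose_from_gt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  n_var <- nrow(fix)
  n_smp <- ncol(gt)
  d <- matrix(NA_real_, nrow = n_var, ncol = n_smp)
  if (!is.null(ds)) d <- ds
  for (j in seq_len(n_var)) {
    if (all(is.na(d[j, ]))) d[j, ] <- dose_from_gt(gt[j, ])
  }
  d <- d[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dos <- t(d)
  rownames(dos) <- colnames(gt)
  meta <- tibble(
    chrom = as.character(fix$CHROM),
    pos = as.numeric(fix$POS),
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT
  )
  impute_and_build(dos, meta)
}

read_panel_dosage <- function(path, variants = NULL) {
  variants <- variants %||% paste0(path, ".variants.tsv")
  mat <- readr::read_tsv(path, show_col_types = FALSE)
  samples <- as.character(mat[[1]])
  dos <- as.matrix(mat[, -1, drop = FALSE])
  rownames(dos) <- samples
  meta <- readr::read_tsv(variants, show_col_types = FALSE,
                          col_types = readr::cols(
                            chrom = readr::col_character(),
                            rsid = readr::col_character(),
                            ref = readr::col_character(),
                            alt = readr::col_character(),
                            .default = readr::col_double()
                          ))
  meta <- meta[match(colnames(dos), meta$rsid), , drop = FALSE]
  if (anyNA(meta$rsid)) abort("dosage matrix has variants absent from sidecar")
  impute_and_build(dos, meta)
}

impute_and_build <- function(dos, meta) {
  miss <- unname(colMeans(is.na(dos)))
  if (any(miss > 0)) {
    inform(sprintf("read_panel: mean-imputed missing dosages at %d variant(s)",
                   sum(miss > 0)))
    for (j in which(miss > 0)) {
      m <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- m
    }
  }
  meta$miss_frac <- miss
  genotype_panel(dos, meta)
}

#' Write a genotype panel as a (plain-text) VCF
#'
#' Dosages are written in the `DS` FORMAT field; hard calls in `GT` when
#' the dosage is integral.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  gt_of <- function(d) {
    ifelse(abs(d - round(d)) < 1e-9,
           c("0/0", "0/1", "1/1")[round(d) + 1], "./.")
  }
  v <- panel$variants
  for (j in seq_len(nrow(v))) {
    d <- panel$dosages[, j]
    cells <- paste0(gt_of(d), ":", formatC(d, digits = 4, format = "g"))
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       v$rsid[j], v$ref[j], v$alt[j], ".", "PASS", ".",
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- harmonization --------------------------------------------------------

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, nea) {
  !is.na(COMPLEMENT[ea]) & COMPLEMENT[ea] == nea
}

#' Harmonize summary statistics to a panel's allele orientation
#'
#' Matches records to panel variants by chromosome and position (rsid as
#' tiebreak when several panel variants share a position) and orients each
#' record to the panel's ALT allele: records whose effect allele equals the
#' panel ALT are kept unchanged; records with swapped alleles have `beta`
#' negated and `eaf` complemented. Palindromic (A/T or C/G) variants with
#' `eaf` inside `palindrome_eaf` are excluded as strand-ambiguous, as are
#' records whose alleles neither match nor swap. Exclusions are returned in
#' the `"exclusions"` attribute (columns `rsid, reason`).
#'
#' @param sumstats Tibble from [read_sumstats()] (or [read_eqtl()]; any
#'   tibble with `chrom, pos, rsid, ea, nea, eaf, beta`).
#' @param panel A [genotype_panel()].
#' @param palindrome_eaf Ambiguity window for palindromic variants.
#' @return Harmonized tibble restricted to panel-matched records, with a
#'   `flipped` logical column.
#' @export
harmonize_sumstats <- function(sumstats, panel,
                               palindrome_eaf = c(0.4, 0.6)) {
  pv <- panel$variants %>%
    mutate(.pk = paste(.data$chrom, .data$pos)) %>%
    select(".pk", panel_rsid = "rsid", "ref", "alt")
  x <- sumstats %>%
    mutate(.pk = paste(.data$chrom, .data$pos),
           .row = row_number()) %>%
    left_join(pv, by = ".pk", relationship = "many-to-many")
  # multiallelic splits share a position: prefer the panel variant with the
  # same rsid, then any allele-compatible one
  compat <- !is.na(x$panel_rsid) &
    ((x$ea == x$alt & x$nea == x$ref) | (x$ea == x$ref & x$nea == x$alt))
  x <- x %>%
    mutate(.pref = 2L * as.integer(dplyr::coalesce(.data$panel_rsid == .data$rsid,
                                                   FALSE)) +
             as.integer(compat)) %>%
    group_by(.data$.row) %>%
    slice_min(-.data$.pref, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select(-dplyr::all_of(c(".pref", ".row")))
  has_eaf <- "eaf" %in% names(x)
  eaf <- if (has_eaf) x$eaf else rep(NA_real_, nrow(x))
  status <- case_when(
    is.na(x$panel_rsid) ~ "absent",
    is_palindromic(x$ea, x$nea) & !is.na(eaf) &
      eaf >= palindrome_eaf[1] & eaf <= palindrome_eaf[2] ~ "palindromic",
    x$ea == x$alt & x$nea == x$ref ~ "match",
    x$ea == x$ref & x$nea == x$alt ~ "flip",
    TRUE ~ "mismatch"
  )
  excl <- tibble(rsid = x$rsid[!status %in% c("match", "flip")],
                 reason = status[!status %in% c("match", "flip")])
  keep <- status %in% c("match", "flip")
  out <- x[keep, , drop = FALSE]
  flip <- status[keep] == "flip"
  out$beta <- ifelse(flip, -out$beta, out$beta)
  if (has_eaf) out$eaf <- ifelse(flip, 1 - out$eaf, out$eaf)
  ea <- out$ea
  out$ea <- ifelse(flip, out$nea, out$ea)
  out$nea <- ifelse(flip, ea, out$nea)
  out$flipped <- flip
  out$rsid <- out$panel_rsid
  out <- out %>% select(-dplyr::all_of(c(".pk", "panel_rsid", "ref", "alt")))
  if (nrow(excl) > 0) {
    inform(sprintf("harmonize_sumstats: excluded %d record(s) (%s)",
                   nrow(excl),
                   paste(sprintf("%s: %d", names(table(excl$reason)),
                                 table(excl$reason)), collapse = ", ")))
  }
  attr(out, "exclusions") <- excl
  out
}

# ---- LD -------------------------------------------------------------------

#' Pairwise linkage disequilibrium from a panel
#'
#' Signed Pearson correlation `r` of the two dosage columns and its square.
#'
#' @param panel A [genotype_panel()].
#' @param a,b Variant rsids.
#' @return One-row tibble with `rsid_a, rsid_b, r, r2`.
#' @export
ld <- function(panel, a, b) {
  r <- ld_with(panel, a, b)
  tibble(rsid_a = a, rsid_b = b, r = r, r2 = r^2)
}

# r between `target` and each rsid in `others` (vectorized)
ld_with <- function(panel, target, others) {
  x <- panel$dosages[, target]
  Y <- panel$dosages[, others, drop = FALSE]
  sx <- sd(x)
  sy <- apply(Y, 2, sd)
  if (sx == 0 || any(sy == 0)) {
    abort("LD undefined: zero-variance dosage column", class = "qadapt_ld_error")
  }
  unname(drop(cor(x, Y)))
}

# full signed LD matrix for a set of rsids
ld_matrix <- function(panel, rsids) {
  Y <- panel$dosages[, rsids, drop = FALSE]
  if (any(apply(Y, 2, sd) == 0)) {
    abort("LD undefined: zero-variance dosage column", class = "qadapt_ld_error")
  }
  stats::cor(Y)
}
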