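#' Read GWAS summary statistics
#'
#' Reads a delimited table of per-variant trait associations with columns
#' CHR, BP, SNP, P, BETA and optionally PHE (phenotype label). Delimiter
#' (comma, tab, whitespace) is sniffed and header names are matched
#' case-insensitively with dots/underscores interchangeable.
#'
#' If a PHE column is present, only rows whose PHE equals `trait` are kept;
#' otherwise every row is assumed to belong to `trait`. Rows with missing or
#' non-finite P or BETA are dropped with a message; p-values of exactly 0 are
#' clamped to 1e-300.
#'
#' @param path path to the GWAS table.
#' @param trait phenotype name used to filter (if PHE present) and to label
#'   the returned table.
#' @return tibble with columns `chrom`, `bp`, `snp`, `p_gwas`, `beta` and
#'   attribute `"trait"`.
#' @export
read_gwas <- function(path, trait) {
  raw <- read_sniffed(path)
  tbl <- select_schema(raw,
    required = c(chrom = "chr", bp = "bp", snp = "snp", p_gwas = "p",
                 beta = "beta"),
    optional = c(phe = "phe"),
    what = "GWAS table")
  for (col in c("chrom", "bp", "p_gwas", "beta")) {
    stopifnot_numeric(tbl[[col]], toupper(col), "GWAS table")
  }
  if ("phe" %in% names(tbl)) {
    tbl <- filter(tbl, .data$phe == trait)
    tbl$phe <- NULL
    if (nrow(tbl) == 0) {
      abort(sprintf("no GWAS rows remain for trait '%s' after phenotype filtering",
                    trait),
            class = "qtlcoloc_empty_input_error")
    }
  }
  bad <- !is.finite(tbl$p_gwas) | !is.finite(tbl$beta)
  if (any(bad)) {
    inform(sprintf("dropped %d GWAS row(s) with missing/non-finite P or BETA",
                   sum(bad)))
    tbl <- tbl[!bad, ]
  }
  tbl$p_gwas <- clamp_pvalues(tbl$p_gwas, "GWAS p-value")
  validate_gwas(tbl)
  tbl$snp <- as.character(tbl$snp)
  attr(tbl, "trait") <- trait
  tbl
}

validate_gwas <- function(tbl) {
  if (any(tbl$p_gwas <= 0 | tbl$p_gwas > 1)) {
    abort("GWAS p-values must lie in (0, 1]", class = "qtlcoloc_validation_error")
  }
  if (any(tbl$bp < 1)) {
    abort("GWAS BP positions must be >= 1", class = "qtlcoloc_validation_error")
  }
  if (any(is.na(tbl$snp) | tbl$snp == "")) {
    abort("GWAS SNP identifiers must be non-empty", class = "qtlcoloc_validation_error")
  }
  invisible(tbl)
}

#' Read cis-eQTL summary statistics
#'
#' Reads a table of variant-by-gene-by-tissue expression associations with
#' columns SNP.Id, Gene.Symbol, P.value, NES (normalized effect size: the
#' slope of the expression-on-genotype regression, alternative vs reference
#' allele) and Tissue, plus an optional N (sample size, required later for
#' meta-analysis collapsing). Multiple tissues per variant are expected.
#'
#' @param path path to the eQTL table.
#' @return tibble with columns `snp`, `gene`, `p_eqtl`, `nes`, `tissue` and,
#'   when present in the file, `n`.
#' @export
read_eqtl <- function(path) {
  raw <- read_sniffed(path)
  tbl <- select_schema(raw,
    required = c(snp = "snpid", gene = "genesymbol", p_eqtl = "pvalue",
                 nes = "nes", tissue = "tissue"),
    optional = c(n = "n"),
    what = "eQTL table")
  stopifnot_numeric(tbl$p_eqtl, "P.value", "eQTL table")
  stopifnot_numeric(tbl$nes, "NES", "eQTL table")
  bad <- !is.finite(tbl$p_eqtl) | !is.finite(tbl$nes)
  if (any(bad)) {
    inform(sprintf("dropped %d eQTL row(s) with missing/non-finite P.value or NES",
                   sum(bad)))
    tbl <- tbl[!bad, ]
  }
  tbl$p_eqtl <- clamp_pvalues(tbl$p_eqtl, "eQTL p-value")
  tbl$snp <- as.character(tbl$snp)
  tbl$gene <- as.character(tbl$gene)
  tbl$tissue <- as.character(tbl$tissue)
  dup <- duplicated(tbl[c("snp", "gene", "tissue")])
  if (any(dup)) {
    first <- tbl[which(dup)[1], ]
    abort(sprintf("duplicate eQTL record for (%s, %s, %s)",
                  first$snp, first$gene, first$tissue),
          class = "qtlcoloc_validation_error")
  }
  if (any(tbl$p_eqtl <= 0 | tbl$p_eqtl > 1)) {
    abort("eQTL p-values must lie in (0, 1]", class = "qtlcoloc_validation_error")
  }
  if (any(tbl$gene == "") || any(tbl$tissue == "")) {
    abort("eQTL gene and tissue labels must be non-empty",
          class = "qtlcoloc_validation_error")
  }
  if ("n" %in% names(tbl) && any(!is.na(tbl$n) & (tbl$n < 1 | tbl$n != round(tbl$n)))) {
    abort("eQTL sample sizes N must be positive integers",
          class = "qtlcoloc_validation_error")
  }
  tbl
}

#' Read gene coordinates
#'
#' Reads a table with columns Gene, CHR, Start, Stop, Build and filters it to
#' the requested genome build. With `path = NULL` a small bundled
#' gene-coordinate table is used; real analyses should supply a full table
#' for their build.
#'
#' @param path path to a gene table, or `NULL` for the bundled default.
#' @param gbuild genome build, `"hg19"` or `"hg38"`.
#' @return tibble with columns `gene`, `chrom`, `start`, `stop`, `build`.
#' @export
read_genes <- function(path = NULL, gbuild = c("hg19", "hg38")) {
  gbuild <- match.arg(gbuild)
  if (is.null(path)) {
    path <- system.file("extdata", "genes_default.tsv", package = "qtlcoloc")
  }
  raw <- read_sniffed(path)
  tbl <- select_schema(raw,
    required = c(gene = "gene", chrom = "chr", start = "start", stop = "stop",
                 build = "build"),
    what = "gene table")
  tbl$gene <- as.character(tbl$gene)
  tbl$build <- as.character(tbl$build)
  if (any(!tbl$build %in% c("hg19", "hg38"))) {
    abort("gene table Build must be 'hg19' or 'hg38'",
          class = "qtlcoloc_validation_error")
  }
  if (any(tbl$start > tbl$stop)) {
    bad <- tbl$gene[which(tbl$start > tbl$stop)[1]]
    abort(sprintf("gene '%s' has Start > Stop", bad),
          class = "qtlcoloc_validation_error")
  }
  if (any(duplicated(tbl[c("gene", "build")]))) {
    abort("gene table has duplicate (Gene, Build) rows",
          class = "qtlcoloc_validation_error")
  }
  tbl <- filter(tbl, .data$build == gbuild)
  if (nrow(tbl) == 0) {
    abort(sprintf("gene table has no rows for build '%s'", gbuild),
          class = "qtlcoloc_empty_input_error")
  }
  tbl
}

#' Read pairwise linkage disequilibrium
#'
#' Reads a PLINK `--r2`-style whitespace-delimited table with columns BP_A,
#' SNP_A, BP_B, SNP_B, R2 (CHR_A/CHR_B tolerated and ignored). Pairs with an
#' endpoint absent from `gwas_snps` are dropped, since LD information is only
#' usable for variants present in the GWAS table; symmetric duplicates
#' (a,b)/(b,a) are deduplicated keeping the first occurrence.
#'
#' @param path path to the LD table.
#' @param gwas_snps character vector of variant ids present in the GWAS table.
#' @return tibble with columns `snp_a`, `bp_a`, `snp_b`, `bp_b`, `r2`.
#' @export
read_ld <- function(path, gwas_snps) {
  raw <- read_sniffed(path)
  tbl <- select_schema(raw,
    required = c(bp_a = "bpa", snp_a = "snpa", bp_b = "bpb", snp_b = "snpb",
                 r2 = "r2"),
    what = "LD table")
  stopifnot_numeric(tbl$r2, "R2", "LD table")
  if (any(tbl$r2 < 0 | tbl$r2 > 1)) {
    abort("LD R2 values must lie in [0, 1]", class = "qtlcoloc_validation_error")
  }
  tbl$snp_a <- as.character(tbl$snp_a)
  tbl$snp_b <- as.character(tbl$snp_b)
  if (any(tbl$snp_a == tbl$snp_b)) {
    abort("LD pairs must join two distinct variants",
          class = "qtlcoloc_validation_error")
  }
  tbl <- filter(tbl, .data$snp_a %in% gwas_snps, .data$snp_b %in% gwas_snps)
  key <- ifelse(tbl$snp_a < tbl$snp_b,
                paste(tbl$snp_a, tbl$snp_b), paste(tbl$snp_b, tbl$snp_a))
  tbl <- tbl[!duplicated(key), ]
  if (nrow(tbl) == 0) {
    warn("no LD pairs overlap the GWAS variant set; LD panels will be disabled")
  }
  tbl[c("snp_a", "bp_a", "snp_b", "bp_b", "r2")]
}

#' Write tables in their canonical dialects
#'
#' Writers matching the readers: GWAS, eQTL and gene tables as tab-separated
#' text with the canonical headers; LD as space-delimited PLINK-style output.
#' Reading a written table reproduces the records field for field.
#'
#' @param tbl a table as returned by the corresponding reader.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name table-writers
NULL

#' @rdname table-writers
#' @export
write_gwas_table <- function(tbl, path) {
  out <- data.frame(CHR = tbl$chrom, BP = tbl$bp, SNP = tbl$snp,
                    P = tbl$p_gwas, BETA = tbl$beta)
  if ("phe" %in% names(tbl)) out$PHE <- tbl$phe
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table-writers
#' @export
write_eqtl_table <- function(tbl, path) {
  out <- data.frame(SNP.Id = tbl$snp, Gene.Symbol = tbl$gene,
                    P.value = tbl$p_eqtl, NES = tbl$nes, Tissue = tbl$tissue,
                    check.names = FALSE)
  if ("n" %in% names(tbl)) out$N <- tbl$n
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table-writers
#' @export
write_genes_table <- function(tbl, path) {
  out <- data.frame(Gene = tbl$gene, CHR = tbl$chrom, Start = tbl$start,
                    Stop = tbl$stop, Build = tbl$build)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table-writers
#' @export
write_ld_table <- function(tbl, path) {
  out <- data.frame(BP_A = tbl$bp_a, SNP_A = tbl$snp_a, BP_B = tbl$bp_b,
                    SNP_B = tbl$snp_b, R2 = tbl$r2)
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
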