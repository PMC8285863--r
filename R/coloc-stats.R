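#' eQTL enrichment among GWAS-significant variants
#'
#' Tests whether variants that reach GWAS significance at the locus are
#' enriched for eQTLs of the gene of interest, by a two-sided Fisher exact
#' test on the 2x2 table
#' (GWAS-significant vs not) x (qualifying eQTL vs not).
#'
#' With `stratum = "congruous"` or `"incongruous"` the eQTL side of the table
#' is restricted to eQTLs of that congruence class: eQTL variants of the
#' other class (or with no defined direction) are excluded, non-eQTL variants
#' are kept, so each stratum gets its own 2x2 test.
#'
#' A degenerate margin — no GWAS-significant variants, or none
#' non-significant — yields a flagged result with p reported as 1 and a
#' warning rather than an error.
#'
#' @param locus_tbl a [build_locus_table()] result.
#' @param stratum `"all"`, `"congruous"` or `"incongruous"`.
#' @return list of class `"qtlcoloc_enrichment"`: counts `a` (significant
#'   eQTL), `b` (significant non-eQTL), `c` (non-significant eQTL), `d`
#'   (non-significant non-eQTL), `proportion_sig = a/(a+b)`,
#'   `proportion_nonsig = c/(c+d)`, `fisher_p`, `stratum`, `degenerate`.
#' @export
enrichment_test <- function(locus_tbl,
                            stratum = c("all", "congruous", "incongruous")) {
  stratum <- match.arg(stratum)
  tbl <- locus_tbl
  if (stratum != "all") {
    keep <- !tbl$has_eqtl | tbl$congruence_class == stratum
    tbl <- tbl[keep, ]
  }
  is_eqtl <- tbl$has_eqtl
  is_sig <- tbl$gwas_significant
  a <- sum(is_sig & is_eqtl)
  b <- sum(is_sig & !is_eqtl)
  cc <- sum(!is_sig & is_eqtl)
  d <- sum(!is_sig & !is_eqtl)
  degenerate <- (a + b) == 0 || (cc + d) == 0
  if (degenerate) {
    warn(sprintf("enrichment test (%s): a GWAS-significance margin is empty; p set to 1",
                 stratum))
    p <- 1
  } else {
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))$p.value
  }
  structure(list(
    a = a, b = b, c = cc, d = d,
    proportion_sig = if (a + b > 0) a / (a + b) else NA_real_,
    proportion_nonsig = if (cc + d > 0) cc / (cc + d) else NA_real_,
    fisher_p = p, stratum = stratum, degenerate = degenerate
  ), class = "qtlcoloc_enrichment")
}

#' P-P correlation between eQTL and GWAS significance
#'
#' For the locus variants that qualify as eQTLs, correlates GWAS and eQTL
#' significance on the -log10 p scale: Pearson r with its two-sided p-value
#' (t transform, n - 2 df) plus the least-squares line through the points
#' (x = -log10 p_eqtl, y = -log10 p_gwas). Correlating raw p-values instead
#' of their logs would be dominated by the near-1 bulk; the log scale is what
#' the P-P panel draws.
#'
#' @param locus_tbl a [build_locus_table()] result.
#' @param stratum `"all"`, or a congruence class to restrict the points to.
#' @return list of class `"qtlcoloc_correlation"`: `n_points`, `pearson_r`,
#'   `p_correlation`, `slope`, `intercept`, `stratum`, `defined` (FALSE when
#'   fewer than 3 points), and `points` (tibble `snp`, `x`, `y`).
#' @export
pp_correlation <- function(locus_tbl,
                           stratum = c("all", "congruous", "incongruous")) {
  stratum <- match.arg(stratum)
  keep <- locus_tbl$has_eqtl
  if (stratum != "all") keep <- keep & locus_tbl$congruence_class == stratum
  pts <- tibble(snp = locus_tbl$snp[keep],
                x = -log10(locus_tbl$p_eqtl[keep]),
                y = -log10(locus_tbl$p_gwas[keep]))
  if (nrow(pts) < 3) {
    return(structure(list(n_points = nrow(pts), pearson_r = NA_real_,
                          p_correlation = NA_real_, slope = NA_real_,
                          intercept = NA_real_, stratum = stratum,
                          defined = FALSE, points = pts),
                     class = "qtlcoloc_correlation"))
  }
  ct <- stats::cor.test(pts$x, pts$y, method = "pearson")
  slope <- stats::cov(pts$x, pts$y) / stats::var(pts$x)
  structure(list(
    n_points = nrow(pts),
    pearson_r = unname(ct$estimate),
    p_correlation = ct$p.value,
    slope = slope,
    intercept = mean(pts$y) - slope * mean(pts$x),
    stratum = stratum, defined = TRUE, points = pts
  ), class = "qtlcoloc_correlation")
}

#' Select the lead variant for LD annotation
#'
#' The lead variant anchors the LD coloring of the P-P panel. A user-supplied
#' id wins (it must occur in both the GWAS and LD tables); otherwise the
#' upper-right-most P-P point is chosen — the variant maximizing
#' `-log10 p_eqtl + -log10 p_gwas`, ties broken by the larger GWAS
#' coordinate, then lexicographically by id.
#'
#' @param pp_points tibble with columns `snp`, `x`, `y` (a
#'   [pp_correlation()] `$points`).
#' @param user_lead optional variant id.
#' @param gwas_snps,ld_snps variant-id universes used to validate
#'   `user_lead`.
#' @return the lead variant id.
#' @export
select_lead_variant <- function(pp_points, user_lead = NULL,
                                gwas_snps = NULL, ld_snps = NULL) {
  if (!is.null(user_lead)) {
    if (!is.null(gwas_snps) && !user_lead %in% gwas_snps) {
      abort(sprintf("lead variant '%s' is not in the GWAS table", user_lead),
            class = "qtlcoloc_lead_snp_error")
    }
    if (!is.null(ld_snps) && !user_lead %in% ld_snps) {
      abort(sprintf("lead variant '%s' is not in the LD table", user_lead),
            class = "qtlcoloc_lead_snp_error")
    }
    return(user_lead)
  }
  stopifnot(nrow(pp_points) >= 1)
  ord <- order(-(pp_points$x + pp_points$y), -pp_points$y, pp_points$snp)
  pp_points$snp[ord[1]]
}

rank_one <- function(key, gwas_tbl, eqtl_tbl, genes_table, config,
                     tissue_selector) {
  flagged_entry <- function() {
    tibble(key = key, pearson_r = NA_real_, p_correlation = NA_real_,
           n_points = 0L, flagged = TRUE)
  }
  res <- tryCatch({
    locus <- define_locus(config$gene %||% key, genes_table, config$range_kb)
    gene_eqtl <- filter(eqtl_tbl, .data$gene == locus$gene)
    collapsed <- collapse_tissues(gene_eqtl, tissue_selector,
                                  config$collapse_method,
                                  config$assume_equal_n)
    loc_tbl <- build_locus_table(gwas_tbl, collapsed, locus, config)
    pp_correlation(loc_tbl, "all")
  }, qtlcoloc_empty_locus_error = function(e) NULL,
     qtlcoloc_unknown_tissue_error = function(e) NULL)
  if (is.null(res) || !res$defined) return(flagged_entry())
  tibble(key = key, pearson_r = res$pearson_r,
         p_correlation = res$p_correlation, n_points = res$n_points,
         flagged = FALSE)
}

sort_ranking <- function(entries, key_name) {
  entries <- entries[order(entries$flagged, entries$p_correlation,
                           -abs(entries$pearson_r), entries$key), ]
  names(entries)[names(entries) == "key"] <- key_name
  class(entries) <- c("qtlcoloc_ranking", class(entries))
  attr(entries, "key_name") <- key_name
  entries
}

#' Rank genes by eQTL-GWAS P-P correlation
#'
#' Runs the locus pipeline (locus definition, tissue collapsing per the
#' configuration, GWAS/eQTL join, P-P Pearson correlation) for each gene in
#' `gene_list` and returns the genes ordered by correlation p-value — a
#' bird's-eye view of which genes' expression tracks the GWAS signal. No
#' figures are produced. Genes with fewer than 3 qualifying variants are
#' flagged and placed last.
#'
#' @param gwas_tbl,eqtl_tbl input tables.
#' @param gene_list character vector of gene symbols.
#' @param genes_table gene coordinates for the active build.
#' @param config a [coloc_config()]; `tissue` and `collapse_method` control
#'   the per-gene collapsing.
#' @return tibble of class `"qtlcoloc_ranking"` with columns `gene`,
#'   `pearson_r`, `p_correlation`, `n_points`, `flagged`, sorted ascending by
#'   `p_correlation` (ties: larger |r|, then name).
#' @export
rank_genes <- function(gwas_tbl, eqtl_tbl, gene_list, genes_table, config) {
  missing_g <- setdiff(gene_list, genes_table$gene)
  if (length(missing_g) > 0) {
    abort(sprintf("gene(s) absent from the gene table: %s",
                  paste(missing_g, collapse = ", ")),
          class = "qtlcoloc_unknown_gene_error")
  }
  cfg <- config
  entries <- bind_rows(lapply(gene_list, function(g) {
    cfg$gene <- g
    rank_one(g, gwas_tbl, eqtl_tbl, genes_table, cfg, config$tissue)
  }))
  sort_ranking(entries, "gene")
}

#' Rank tissues by eQTL-GWAS P-P correlation
#'
#' As [rank_genes()], but for one gene across tissues: each tissue is
#' analyzed on its own (no collapsing), and tissues are ordered by the
#' correlation p-value. `tissue_list = "all"` uses every tissue present in
#' the eQTL table.
#'
#' @param gwas_tbl,eqtl_tbl input tables.
#' @param gene the gene symbol to analyze.
#' @param tissue_list `"all"` or a character vector of tissue names.
#' @param genes_table gene coordinates for the active build.
#' @param config a [coloc_config()].
#' @return tibble of class `"qtlcoloc_ranking"` with columns `tissue`,
#'   `pearson_r`, `p_correlation`, `n_points`, `flagged`.
#' @export
rank_tissues <- function(gwas_tbl, eqtl_tbl, gene, tissue_list = "all",
                         genes_table, config) {
  if (identical(tissue_list, "all")) {
    tissue_list <- sort(unique(eqtl_tbl$tissue[eqtl_tbl$gene == gene]))
  }
  cfg <- config
  cfg$gene <- gene
  entries <- bind_rows(lapply(tissue_list, function(tis) {
    rank_one(tis, gwas_tbl, eqtl_tbl, genes_table, cfg, tis)
  }))
  sort_ranking(entries, "tissue")
}

#' @export
print.qtlcoloc_ranking <- function(x, ...) {
  key_name <- attr(x, "key_name")
  for (i in seq_len(nrow(x))) {
    if (x$flagged[i]) {
      cat(sprintf("eQTL analysis for %s %s: fewer than 3 qualifying variants\n",
                  key_name, x[[key_name]][i]))
    } else {
      cat(sprintf("eQTL analysis for %s %s: Pearson correlation: %s, p-value: %s\n",
                  key_name, x[[key_name]][i],
                  format(signif(x$pearson_r[i], 3)),
                  format(signif(x$p_correlation[i], 3))))
    }
  }
  invisible(x)
}

#' @export
print.qtlcoloc_enrichment <- function(x, ...) {
  cat(sprintf(
    "eQTL enrichment (%s): a=%d b=%d c=%d d=%d; Fisher exact p = %s%s\n",
    x$stratum, x$a, x$b, x$c, x$d, format(signif(x$fisher_p, 3)),
    if (x$degenerate) " (degenerate margin)" else ""))
  invisible(x)
}

#' @export
print.qtlcoloc_correlation <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("P-P correlation (%s): undefined (%d points)\n",
                x$stratum, x$n_points))
  } else {
    cat(sprintf("P-P correlation (%s): Pearson correlation: %s, p-value: %s (n = %d)\n",
                x$stratum, format(signif(x$pearson_r, 3)),
                format(signif(x$p_correlation, 3)), x$n_points))
  }
  invisible(x)
}
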