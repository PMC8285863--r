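#' Define the locus of interest around a gene
#'
#' The analysis region is the gene's coordinates extended by `range_kb`
#' kilobases on each side (floored at position 1).
#'
#' @param gene gene symbol; must occur in `genes_table`.
#' @param genes_table gene coordinates as from [read_genes()].
#' @param range_kb flank size in kilobases (default 200).
#' @return list of class `"qtlcoloc_locus"` with `gene`, `chrom`, `start_bp`,
#'   `stop_bp`, `gene_start`, `gene_stop`.
#' @export
define_locus <- function(gene, genes_table, range_kb = 200) {
  row <- genes_table[genes_table$gene == gene, ]
  if (nrow(row) == 0) {
    pool <- sort(unique(genes_table$gene))
    pos <- sum(pool < gene)
    near <- pool[max(1, pos - 2):min(length(pool), pos + 3)]
    abort(sprintf("gene '%s' not found in the gene table; nearby symbols: %s",
                  gene, paste(near, collapse = ", ")),
          class = "qtlcoloc_unknown_gene_error")
  }
  row <- row[1, ]
  structure(list(
    gene = gene, chrom = row$chrom,
    start_bp = max(1, row$start - range_kb * 1000),
    stop_bp = row$stop + range_kb * 1000,
    gene_start = row$start, gene_stop = row$stop
  ), class = "qtlcoloc_locus")
}

#' Sample-size weighted Z meta-analysis of p-values
#'
#' Combines two-sided p-values across studies (here: tissues) with the
#' weighted Z (Stouffer) method. Each p is converted to a z-score signed by
#' its effect direction, `z_i = sign(nes_i) * qnorm(1 - p_i / 2)`, weighted by
#' the square root of its sample size, and the combined two-sided p is
#' `2 * (1 - pnorm(|sum(w_i z_i)| / sqrt(sum(w_i^2))))`. Signing by the NES
#' direction means concordant effects reinforce and discordant effects cancel,
#' which is what direction-of-effect congruence semantics require.
#'
#' @param p_values two-sided p-values in (0, 1].
#' @param nes_signs effect directions; only the sign is used (0 treated as +).
#' @param sample_sizes per-study sample sizes; may be `NULL` with
#'   `assume_equal_n = TRUE`.
#' @param assume_equal_n treat all studies as equally sized when sample sizes
#'   are unavailable.
#' @return the combined two-sided p-value.
#' @export
#' @examples
#' weighted_z_meta(c(0.05, 0.05), c(1, 1), c(100, 100))
weighted_z_meta <- function(p_values, nes_signs, sample_sizes = NULL,
                            assume_equal_n = FALSE) {
  stopifnot(length(p_values) >= 1, all(p_values > 0), all(p_values <= 1))
  if (is.null(sample_sizes) || anyNA(sample_sizes)) {
    if (!assume_equal_n) {
      abort(paste("meta-analysis collapsing needs a sample size N for every",
                  "eQTL record; rerun with assume_equal_n = TRUE to treat all",
                  "tissues as equally sized (results may be inaccurate)"),
            class = "qtlcoloc_meta_n_error")
    }
    sample_sizes <- rep(1, length(p_values))
  }
  s <- ifelse(nes_signs < 0, -1, 1)
  z <- s * stats::qnorm(p_values / 2, lower.tail = FALSE)
  w <- sqrt(sample_sizes)
  z_comb <- sum(w * z) / sqrt(sum(w^2))
  2 * stats::pnorm(abs(z_comb), lower.tail = FALSE)
}

#' Collapse eQTL records across tissues
#'
#' Reduces a gene's per-tissue eQTL records to one record per variant, for
#' pan-tissue (`tissue_selector = "all"`) or multi-tissue (a vector of tissue
#' names) analyses. Methods:
#' \describe{
#'   \item{min}{take p-value and NES from the tissue with the smallest p
#'     (ties: larger |NES|, then tissue name).}
#'   \item{median / mean}{element-wise median/mean of p and of NES across the
#'     tissues in which the variant was tested.}
#'   \item{meta}{sample-size weighted Z meta-analysis of the p-values (see
#'     [weighted_z_meta()]); no combined NES is produced, so downstream
#'     figures draw these variants at a fixed size.}
#' }
#' A single selected tissue is returned unchanged whatever the method.
#'
#' @param eqtl_tbl eQTL records for one gene, as from [read_eqtl()].
#' @param tissue_selector `"all"`, one tissue name, or a character vector.
#' @param method collapse method, see above.
#' @param assume_equal_n passed to [weighted_z_meta()] when sample sizes are
#'   missing.
#' @return tibble with one row per variant: `snp`, `p_eqtl`, `nes` (`NA`
#'   under meta), `source_tissue` (the minimizing tissue for `"min"`, else
#'   `"combined"`), `method`.
#' @export
collapse_tissues <- function(eqtl_tbl,
                             tissue_selector = "all",
                             method = c("min", "median", "mean", "meta"),
                             assume_equal_n = FALSE) {
  method <- match.arg(method)
  if (!identical(tissue_selector, "all")) {
    missing_t <- setdiff(tissue_selector, unique(eqtl_tbl$tissue))
    if (length(missing_t) > 0) {
      abort(sprintf("tissue(s) not present in the eQTL table: %s",
                    paste(missing_t, collapse = ", ")),
            class = "qtlcoloc_unknown_tissue_error")
    }
    eqtl_tbl <- filter(eqtl_tbl, .data$tissue %in% tissue_selector)
  }
  if (length(unique(eqtl_tbl$tissue)) <= 1) {
    return(tibble(snp = eqtl_tbl$snp, p_eqtl = eqtl_tbl$p_eqtl,
                  nes = eqtl_tbl$nes,
                  source_tissue = as.character(eqtl_tbl$tissue),
                  method = method))
  }
  if (method == "min") {
    out <- eqtl_tbl |>
      arrange(.data$snp, .data$p_eqtl, dplyr::desc(abs(.data$nes)),
              .data$tissue) |>
      group_by(.data$snp) |>
      slice(1) |>
      ungroup()
    tibble(snp = out$snp, p_eqtl = out$p_eqtl, nes = out$nes,
           source_tissue = out$tissue, method = method)
  } else if (method %in% c("median", "mean")) {
    f <- if (method == "median") stats::median else mean
    out <- eqtl_tbl |>
      group_by(.data$snp) |>
      summarise(p_eqtl = f(.data$p_eqtl), nes = f(.data$nes),
                .groups = "drop")
    tibble(snp = out$snp, p_eqtl = pmin(out$p_eqtl, 1), nes = out$nes,
           source_tissue = "combined", method = method)
  } else { # meta
    has_n <- "n" %in% names(eqtl_tbl) && !anyNA(eqtl_tbl$n)
    if (!has_n && !assume_equal_n) {
      abort(paste("meta-analysis collapsing needs a sample size N for every",
                  "eQTL record; rerun with assume_equal_n = TRUE to treat all",
                  "tissues as equally sized (results may be inaccurate)"),
            class = "qtlcoloc_meta_n_error")
    }
    out <- eqtl_tbl |>
      group_by(.data$snp) |>
      summarise(p_eqtl = weighted_z_meta(
        .data$p_eqtl, sign(.data$nes),
        if (has_n) .data$n else NULL,
        assume_equal_n = TRUE), .groups = "drop")
    tibble(snp = out$snp, p_eqtl = out$p_eqtl, nes = NA_real_,
           source_tissue = "combined", method = method)
  }
}

#' Classify direction-of-effect congruence
#'
#' A variant is congruous when its GWAS effect (beta) and its expression
#' effect (NES) share a sign — e.g. more expression, higher trait value — and
#' incongruous when the signs oppose. A zero effect on either side carries no
#' direction, so the variant is classed `not_applicable` and excluded from
#' the congruence split.
#'
#' @param beta GWAS effect size(s).
#' @param nes eQTL normalized effect size(s).
#' @return character vector in `{"congruous", "incongruous", "not_applicable"}`.
#' @export
classify_congruence <- function(beta, nes) {
  out <- rep("not_applicable", length(beta))
  ok <- is.finite(beta) & is.finite(nes) & beta * nes != 0
  out[ok & sign(beta) == sign(nes)] <- "congruous"
  out[ok & sign(beta) != sign(nes)] <- "incongruous"
  out
}

#' Join GWAS and collapsed eQTL records over a locus
#'
#' Restricts the GWAS table to variants inside the locus, attaches collapsed
#' eQTL evidence by exact variant-id match, and computes the flags every
#' downstream statistic and panel consumes: `has_eqtl` (an eQTL record exists
#' with `p_eqtl <= sigpvalue_eqtl`), `gwas_significant` (`p_gwas <`
#' `sigpvalue_gwas`, strict), and — when congruence mode is on — the
#' congruence class of each qualifying eQTL variant.
#'
#' @param gwas_tbl GWAS records as from [read_gwas()].
#' @param collapsed_eqtl collapsed records as from [collapse_tissues()].
#' @param locus a [define_locus()] result.
#' @param config a [coloc_config()].
#' @return tibble of locus variants: `snp`, `bp`, `p_gwas`, `beta`,
#'   `has_eqtl`, `p_eqtl`, `nes`, `congruence_class`, `gwas_significant`.
#' @export
build_locus_table <- function(gwas_tbl, collapsed_eqtl, locus, config) {
  inside <- gwas_tbl$chrom == locus$chrom &
    gwas_tbl$bp >= locus$start_bp & gwas_tbl$bp <= locus$stop_bp
  gw <- gwas_tbl[inside, ]
  if (nrow(gw) == 0) {
    abort(sprintf("no GWAS variants fall within the locus chr%s:%d-%d",
                  locus$chrom, locus$start_bp, locus$stop_bp),
          class = "qtlcoloc_empty_locus_error")
  }
  eq <- collapsed_eqtl[c("snp", "p_eqtl", "nes")]
  out <- left_join(gw[c("snp", "bp", "p_gwas", "beta")], eq, by = "snp")
  out$has_eqtl <- !is.na(out$p_eqtl) & out$p_eqtl <= config$sigpvalue_eqtl
  out$gwas_significant <- out$p_gwas < config$sigpvalue_gwas
  out$congruence_class <- "not_applicable"
  if (isTRUE(config$congruence)) {
    idx <- out$has_eqtl
    cls <- classify_congruence(out$beta[idx], out$nes[idx])
    out$congruence_class[idx] <- cls
    n_zero <- sum(cls == "not_applicable")
    if (n_zero > 0) {
      warn(sprintf(
        "%d eQTL variant(s) with a zero effect direction excluded from the congruence split",
        n_zero))
    }
  }
  out
}
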