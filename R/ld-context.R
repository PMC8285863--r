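#' Filter LD pairs for the locus heatmap
#'
#' Keeps pairs whose two endpoints are both qualifying eQTL variants within
#' the locus and whose R^2 strictly exceeds `r2min`.
#'
#' @param ld_pairs LD pairs as from [read_ld()].
#' @param locus_eqtl_snps ids of the locus's qualifying eQTL variants.
#' @param r2min R^2 threshold in `[0, 1]` (strict `>`).
#' @return the filtered pair tibble (possibly empty).
#' @export
filter_ld_pairs <- function(ld_pairs, locus_eqtl_snps, r2min = 0.1) {
  stopifnot(r2min >= 0, r2min <= 1)
  filter(ld_pairs,
         .data$snp_a %in% locus_eqtl_snps,
         .data$snp_b %in% locus_eqtl_snps,
         .data$r2 > r2min)
}

#' Thin heatmap variants by LD degree
#'
#' Keeps variants that are in (filtered) LD with at least `ldmin` other
#' variants — i.e. whose degree in the pair graph is `>= ldmin`. Variants in
#' `variants` that appear in no retained pair have degree 0, so they survive
#' only when `ldmin = 0`. This thinning pares the heatmap down to the most
#' informative variants.
#'
#' @param filtered_pairs output of [filter_ld_pairs()].
#' @param variants the candidate variant ids (the locus's qualifying eQTL
#'   variants).
#' @param ldmin minimum LD-partner count.
#' @return character vector of kept variant ids.
#' @export
degree_filter <- function(filtered_pairs, variants, ldmin = 10) {
  stopifnot(ldmin >= 0)
  deg <- table(factor(c(filtered_pairs$snp_a, filtered_pairs$snp_b),
                      levels = variants))
  names(deg)[deg >= ldmin]
}

#' Build the symmetric R^2 matrix for the heatmap
#'
#' @param kept_variants tibble with columns `snp`, `bp` for the retained
#'   variants; rows/columns of the matrix are ordered by position.
#' @param filtered_pairs LD pairs restricted to the kept variants.
#' @return symmetric numeric matrix with unit diagonal; pairs never observed
#'   in the LD table get 0.
#' @export
build_r2_matrix <- function(kept_variants, filtered_pairs) {
  stopifnot(nrow(kept_variants) >= 1)
  ord <- order(kept_variants$bp, kept_variants$snp)
  snps <- kept_variants$snp[ord]
  m <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  diag(m) <- 1
  pr <- filter(filtered_pairs, .data$snp_a %in% snps, .data$snp_b %in% snps)
  if (nrow(pr) > 0) {
    key <- ifelse(pr$snp_a < pr$snp_b,
                  paste(pr$snp_a, pr$snp_b), paste(pr$snp_b, pr$snp_a))
    dup <- duplicated(key)
    if (any(dup)) {
      agree <- tapply(pr$r2, key, function(v) length(unique(v)) == 1)
      if (!all(agree)) {
        abort(sprintf("conflicting duplicate R2 values for pair(s): %s",
                      paste(names(agree)[!agree], collapse = ", ")),
              class = "qtlcoloc_validation_error")
      }
      pr <- pr[!dup, ]
    }
    m[cbind(pr$snp_a, pr$snp_b)] <- pr$r2
    m[cbind(pr$snp_b, pr$snp_a)] <- pr$r2
  }
  m
}

#' Annotate P-P variants with R^2 to the lead variant
#'
#' @param ld_pairs LD pairs (locus-restricted or full; lookups are by id).
#' @param lead_snp the lead variant id.
#' @param pp_variants ids of the P-P points to annotate.
#' @return named numeric vector: R^2 with the lead for each variant; the lead
#'   itself gets 1, variants sharing no pair with the lead get 0.
#' @export
lead_r2_annotation <- function(ld_pairs, lead_snp, pp_variants) {
  out <- stats::setNames(rep(0, length(pp_variants)), pp_variants)
  hit_a <- ld_pairs$snp_a == lead_snp
  hit_b <- ld_pairs$snp_b == lead_snp
  partners <- c(ld_pairs$snp_b[hit_a], ld_pairs$snp_a[hit_b])
  r2 <- c(ld_pairs$r2[hit_a], ld_pairs$r2[hit_b])
  idx <- match(pp_variants, partners)
  out[!is.na(idx)] <- r2[idx[!is.na(idx)]]
  out[pp_variants == lead_snp] <- 1
  out
}

#' Assemble the LD context for a locus
#'
#' Convenience orchestration: filter pairs to the locus's qualifying eQTL
#' variants at `r2min`, thin by LD degree at `ldmin`, and build the ordered
#' R^2 matrix. When no variants survive, the heatmap is disabled (with a
#' warning) and the figure falls back to the no-LD layout.
#'
#' @param ld_pairs LD pairs as from [read_ld()].
#' @param locus_tbl a [build_locus_table()] result.
#' @param config a [coloc_config()] (uses `r2min`, `ldmin`).
#' @return list of class `"qtlcoloc_ld_context"`: `kept` (tibble `snp`, `bp`,
#'   ordered by position), `r2_matrix`, `pairs` (filtered pairs), `empty`.
#' @export
build_ld_context <- function(ld_pairs, locus_tbl, config) {
  eqtl_snps <- locus_tbl$snp[locus_tbl$has_eqtl]
  pairs <- filter_ld_pairs(ld_pairs, eqtl_snps, config$r2min)
  kept_ids <- degree_filter(pairs, eqtl_snps, config$ldmin)
  kept <- locus_tbl[locus_tbl$snp %in% kept_ids, c("snp", "bp")]
  kept <- kept[order(kept$bp, kept$snp), ]
  pairs <- filter(pairs, .data$snp_a %in% kept_ids, .data$snp_b %in% kept_ids)
  if (nrow(kept) < 2) {
    warn("fewer than 2 variants survive LD filtering; LD heatmap disabled")
    return(structure(list(kept = kept, r2_matrix = NULL, pairs = pairs,
                          empty = TRUE),
                     class = "qtlcoloc_ld_context"))
  }
  structure(list(kept = kept, r2_matrix = build_r2_matrix(kept, pairs),
                 pairs = pairs, empty = FALSE),
            class = "qtlcoloc_ld_context")
}
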