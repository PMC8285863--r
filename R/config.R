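#' Analysis configuration
#'
#' Collects every tunable of a colocalization analysis with its default.
#' Defaults follow the conventions of GWAS/eQTL summary-statistic practice:
#' genome-wide significance 5e-8 for the trait, nominal 0.05 for eQTLs, a
#' 200 kb flank around the gene, minimum-p tissue collapsing, and LD-heatmap
#' thinning at R^2 > 0.1 with at least 10 LD partners.
#'
#' @param gene gene symbol (or character vector of symbols for rankings).
#' @param trait GWAS phenotype name; used to filter a multi-phenotype GWAS
#'   table and to label outputs.
#' @param tissue `"all"` for a pan-tissue analysis, a single tissue name, or a
#'   character vector of tissues for a multi-tissue analysis.
#' @param sigpvalue_gwas GWAS significance threshold (strict `<`); also drawn
#'   as the horizontal cut line on the main panel. Default `5e-8`.
#' @param sigpvalue_eqtl eQTL qualification threshold; variants with
#'   `p_eqtl <= sigpvalue_eqtl` count as eQTLs, others are plotted as grey
#'   squares and excluded from enrichment/correlation. Default `0.05`.
#' @param range_kb flank, in kilobases, added on each side of the gene to
#'   define the locus of interest. Default `200`.
#' @param congruence if `TRUE`, split eQTL variants by direction-of-effect
#'   congruence (GWAS beta vs expression NES) and analyze the two groups
#'   separately. Default `FALSE`.
#' @param collapse_method one of `"min"`, `"median"`, `"mean"`, `"meta"`; how
#'   per-tissue eQTL records are collapsed to one record per variant.
#'   Default `"min"`.
#' @param r2min keep LD pairs with `R^2 >` this value (strict). Default `0.1`.
#' @param ldmin keep heatmap variants in LD with at least this many other
#'   variants after the `r2min` filter. Default `10`.
#' @param lead_snp optional variant id to use as the lead variant for LD
#'   coloring of P-P panels; must occur in both the GWAS and LD tables.
#' @param gbuild genome build of the gene table, `"hg19"` or `"hg38"`.
#' @param genometrackheight relative height of the gene-track panel. Default 2.
#' @param ldcolor `"color"` or `"black"` (greyscale) LD heatmap fill.
#' @param nes_size_limits optional `c(min, max)` fixing the NES size scale so
#'   it is comparable across figures.
#' @param res output raster resolution in dpi. Default `300`.
#' @param width figure width in inches; `NULL` resolves to 12 without LD data
#'   and 14 with LD data.
#' @param xlimd,ylima,ylimd optional axis maxima: P-P x axis, main-panel y
#'   axis, P-P y axis.
#' @param saveplot write the figure file. Default `TRUE`.
#' @param getplot return the figure object. Default `TRUE`.
#' @param assume_equal_n for `collapse_method = "meta"` without per-record
#'   sample sizes, assume all tissues share one sample size. Default `FALSE`.
#'
#' @return a list of class `"qtlcoloc_config"`.
#' @export
#' @examples
#' cfg <- coloc_config(gene = "BBS1", trait = "LDL")
#' cfg$sigpvalue_gwas
coloc_config <- function(gene = NULL, trait = NULL, tissue = "all",
                         sigpvalue_gwas = 5e-8, sigpvalue_eqtl = 0.05,
                         range_kb = 200, congruence = FALSE,
                         collapse_method = c("min", "median", "mean", "meta"),
                         r2min = 0.1, ldmin = 10, lead_snp = NULL,
                         gbuild = c("hg19", "hg38"), genometrackheight = 2,
                         ldcolor = c("color", "black"),
                         nes_size_limits = NULL, res = 300, width = NULL,
                         xlimd = NULL, ylima = NULL, ylimd = NULL,
                         saveplot = TRUE, getplot = TRUE,
                         assume_equal_n = FALSE) {
  collapse_method <- match.arg(collapse_method)
  gbuild <- match.arg(gbuild)
  ldcolor <- match.arg(ldcolor)
  stopifnot(sigpvalue_gwas > 0, sigpvalue_gwas <= 1,
            sigpvalue_eqtl > 0, sigpvalue_eqtl <= 1,
            range_kb >= 0, r2min >= 0, r2min <= 1, ldmin >= 0)
  structure(list(
    gene = gene, trait = trait, tissue = tissue,
    sigpvalue_gwas = sigpvalue_gwas, sigpvalue_eqtl = sigpvalue_eqtl,
    range_kb = range_kb, congruence = congruence,
    collapse_method = collapse_method, r2min = r2min, ldmin = ldmin,
    lead_snp = lead_snp, gbuild = gbuild,
    genometrackheight = genometrackheight, ldcolor = ldcolor,
    nes_size_limits = nes_size_limits, res = res, width = width,
    xlimd = xlimd, ylima = ylima, ylimd = ylimd,
    saveplot = saveplot, getplot = getplot,
    assume_equal_n = assume_equal_n
  ), class = "qtlcoloc_config")
}

#' Resolve the figure width for a configuration
#'
#' Width defaults to 12 inches for the basic layout and 14 inches when LD data
#' (and hence the heatmap panel) is present; an explicit `width` wins.
#'
#' @param config a [coloc_config()].
#' @param ld_supplied is pairwise LD data part of the figure?
#' @return width in inches.
#' @export
resolve_width <- function(config, ld_supplied) {
  config$width %||% if (isTRUE(ld_supplied)) 14 else 12
}
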