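#' Tissue label used in filenames and titles
#'
#' `"PanTissue"` for a pan-tissue analysis (`tissue = "all"`),
#' `"MultiTissue"` for a tissue list, otherwise the tissue name itself.
#'
#' @param tissue_selector the `tissue` configuration value.
#' @return a single label string.
#' @export
tissue_label <- function(tissue_selector) {
  if (identical(tissue_selector, "all")) "PanTissue"
  else if (length(tissue_selector) > 1) "MultiTissue"
  else as.character(tissue_selector)
}

#' Output filename for a colocalization figure
#'
#' Dot-separated template
#' `<gene>.<trait>.<tissue>.<Congruent|NoCongruence>.<LD|NoLD>.qtlcoloc.<fmt>`,
#' e.g. `BBS1.LDL.PanTissue.NoCongruence.NoLD.qtlcoloc.png`.
#'
#' @param gene,trait analysis labels.
#' @param tissue the [tissue_label()].
#' @param congruence,ld_supplied logical mode flags.
#' @param fmt file extension (`"png"`, `"pdf"`, `"svg"`).
#' @return the file name (no directory).
#' @export
figure_filename <- function(gene, trait, tissue, congruence, ld_supplied,
                            fmt = "png") {
  paste(gene, trait, tissue,
        if (isTRUE(congruence)) "Congruent" else "NoCongruence",
        if (isTRUE(ld_supplied)) "LD" else "NoLD",
        "qtlcoloc", fmt, sep = ".")
}

#' Compose panels into a figure and optionally write it
#'
#' Stacks the panels into one of three layouts, determined solely by whether
#' LD data is in play and whether the analysis is congruence-stratified:
#' \describe{
#'   \item{basic}{main panel, gene track, then enrichment | P-P (4 panels).}
#'   \item{ld}{adds the LD heatmap between the track and the bottom row
#'     (5 panels).}
#'   \item{ld_congruence}{as ld, with separate congruous and incongruous
#'     P-P panels (6 panels).}
#' }
#' Height follows width with fixed aspect ratios (0.75 basic, 0.9 with LD).
#'
#' @param panels named list of ggplot panels (`main`, `gene_track`,
#'   optionally `ld_heatmap`, `enrichment`, and `pp` or
#'   `pp_congruous`/`pp_incongruous`).
#' @param config a [coloc_config()].
#' @param ld_supplied does the figure include the LD heatmap?
#' @param out_dir output directory.
#' @param fmt `"png"`, `"pdf"` or `"svg"`.
#' @return list: `figure` (patchwork object), `path` (written file or
#'   `NULL`), `layout`.
#' @export
compose_and_save <- function(panels, config, ld_supplied, out_dir = ".",
                             fmt = "png") {
  layout <- if (!ld_supplied) "basic"
            else if (isTRUE(config$congruence)) "ld_congruence"
            else "ld"
  gth <- config$genometrackheight
  bottom <- if (layout == "ld_congruence") {
    patchwork::wrap_plots(panels$enrichment, panels$pp_congruous,
                          panels$pp_incongruous, nrow = 1)
  } else {
    patchwork::wrap_plots(panels$enrichment, panels$pp, nrow = 1)
  }
  fig <- if (ld_supplied) {
    patchwork::wrap_plots(panels$main, panels$gene_track, panels$ld_heatmap,
                          bottom, ncol = 1, heights = c(4, gth, 3.5, 3))
  } else {
    patchwork::wrap_plots(panels$main, panels$gene_track, bottom,
                          ncol = 1, heights = c(4, gth, 3))
  }
  path <- NULL
  if (isTRUE(config$saveplot)) {
    width <- resolve_width(config, ld_supplied)
    height <- width * if (ld_supplied) 0.9 else 0.75
    if (!dir.exists(out_dir)) {
      abort(sprintf("output directory does not exist: %s", out_dir),
            class = "qtlcoloc_io_error")
    }
    path <- file.path(out_dir, figure_filename(
      config$gene, config$trait, tissue_label(config$tissue),
      config$congruence, ld_supplied, fmt))
    save_figure(fig, path, fmt, width, height, config$res)
  }
  list(figure = fig, path = path, layout = layout)
}

save_figure <- function(fig, path, fmt, width, height, res) {
  switch(fmt,
    png = {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = res, type = "cairo")
      print(fig)
      grDevices::dev.off()
    },
    pdf = {
      grDevices::cairo_pdf(path, width = width, height = height)
      print(fig)
      grDevices::dev.off()
    },
    svg = {
      grDevices::svg(path, width = width, height = height)
      print(fig)
      grDevices::dev.off()
    },
    abort(sprintf("unsupported figure format '%s'", fmt),
          class = "qtlcoloc_io_error")
  )
  invisible(path)
}

#' Run a full gene-trait colocalization analysis and figure
#'
#' The high-level entry point: defines the locus of interest around the
#' configured gene, collapses the gene's eQTL records across the selected
#' tissues, joins them to the GWAS variants in the locus, computes the
#' enrichment and P-P correlation statistics (stratified by congruence when
#' requested), assembles the LD context when pairwise LD is supplied, and
#' renders/saves the multi-panel figure.
#'
#' @param gwas_tbl GWAS records ([read_gwas()]).
#' @param eqtl_tbl eQTL records ([read_eqtl()]).
#' @param config a [coloc_config()] with at least `gene` and `trait` set.
#' @param genes_table gene coordinates; `NULL` loads the bundled table for
#'   `config$gbuild`.
#' @param ld_pairs optional LD pairs ([read_ld()]).
#' @param out_dir where to write the figure (when `config$saveplot`).
#' @param fmt output format, `"png"` (default), `"pdf"` or `"svg"`.
#' @return list of class `"qtlcoloc_result"`: `locus`, `locus_tbl`,
#'   `enrichment` (list by stratum), `correlations` (list by stratum),
#'   `lead_snps`, `ld_context`, `panels`, `figure`, `path`, `layout`,
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_locus(sim_params(seed = 7))
#' cfg <- coloc_config(gene = "GENE1", trait = "TRAIT", saveplot = FALSE)
#' res <- qtl_coloc(sim$gwas, sim$eqtl, cfg, genes_table = sim$genes)
#' res$correlations$all
qtl_coloc <- function(gwas_tbl, eqtl_tbl, config, genes_table = NULL,
                      ld_pairs = NULL, out_dir = ".", fmt = "png") {
  stopifnot(!is.null(config$gene), !is.null(config$trait))
  if (is.null(genes_table)) genes_table <- read_genes(NULL, config$gbuild)

  locus <- define_locus(config$gene, genes_table, config$range_kb)
  gene_eqtl <- filter(eqtl_tbl, .data$gene == config$gene)
  collapsed <- collapse_tissues(gene_eqtl, config$tissue,
                                config$collapse_method,
                                config$assume_equal_n)
  loc_tbl <- build_locus_table(gwas_tbl, collapsed, locus, config)

  ld_ctx <- NULL
  if (!is.null(ld_pairs) && nrow(ld_pairs) > 0) {
    ld_ctx <- build_ld_context(ld_pairs, loc_tbl, config)
    if (ld_ctx$empty) ld_ctx <- NULL  # fall back to the no-LD layout
  }
  ld_supplied <- !is.null(ld_ctx)

  strata <- if (isTRUE(config$congruence)) c("congruous", "incongruous")
            else "all"
  enrichment <- lapply(strata, function(s) enrichment_test(loc_tbl, s))
  names(enrichment) <- strata
  correlations <- lapply(strata, function(s) pp_correlation(loc_tbl, s))
  names(correlations) <- strata

  lead_snps <- NULL
  lead_r2 <- list()
  if (ld_supplied) {
    ld_snp_ids <- unique(c(ld_pairs$snp_a, ld_pairs$snp_b))
    lead_snps <- vapply(strata, function(s) {
      pts <- correlations[[s]]$points
      if (nrow(pts) == 0) return(NA_character_)
      select_lead_variant(pts, config$lead_snp,
                          gwas_snps = gwas_tbl$snp, ld_snps = ld_snp_ids)
    }, character(1))
    lead_r2 <- lapply(strata, function(s) {
      pts <- correlations[[s]]$points
      if (nrow(pts) == 0 || is.na(lead_snps[[s]])) return(NULL)
      lead_r2_annotation(ld_pairs, lead_snps[[s]], pts$snp)
    })
    names(lead_r2) <- strata
  }

  panels <- list(
    main = render_main_panel(loc_tbl, config, locus,
                             lead_snps = lead_snps[!is.na(lead_snps)]),
    gene_track = render_gene_track(genes_table, locus,
                                   config$genometrackheight)
  )
  if (ld_supplied) {
    panels$ld_heatmap <- render_ld_heatmap(ld_ctx, locus, config$ldcolor)
  }
  panels$enrichment <- render_enrichment_panel(enrichment)
  if (isTRUE(config$congruence) && ld_supplied) {
    panels$pp_congruous <- render_pp_panel(
      correlations$congruous, config,
      lead_r2 = lead_r2$congruous, lead_snp = lead_snps[["congruous"]])
    panels$pp_incongruous <- render_pp_panel(
      correlations$incongruous, config,
      lead_r2 = lead_r2$incongruous, lead_snp = lead_snps[["incongruous"]])
  } else if (isTRUE(config$congruence)) {
    panels$pp <- render_pp_panel(correlations, config)
  } else {
    panels$pp <- render_pp_panel(
      correlations$all, config,
      lead_r2 = if (ld_supplied) lead_r2$all,
      lead_snp = if (ld_supplied) lead_snps[["all"]])
  }

  composed <- compose_and_save(panels, config, ld_supplied, out_dir, fmt)
  structure(list(
    locus = locus, locus_tbl = loc_tbl, enrichment = enrichment,
    correlations = correlations, lead_snps = lead_snps,
    ld_context = ld_ctx, panels = panels,
    figure = if (isTRUE(config$getplot)) composed$figure,
    path = composed$path, layout = composed$layout, config = config
  ), class = "qtlcoloc_result")
}

#' @export
print.qtlcoloc_result <- function(x, ...) {
  cat(sprintf("Colocalization analysis: %s / %s (%s)\n",
              x$config$gene, x$config$trait, tissue_label(x$config$tissue)))
  cat(sprintf("Locus chr%s:%d-%d, %d variants (%d eQTL, %d GWAS-significant)\n",
              x$locus$chrom, x$locus$start_bp, x$locus$stop_bp,
              nrow(x$locus_tbl), sum(x$locus_tbl$has_eqtl),
              sum(x$locus_tbl$gwas_significant)))
  for (e in x$enrichment) print(e)
  for (cr in x$correlations) print(cr)
  if (!is.null(x$path)) cat("Figure written to:", x$path, "\n")
  invisible(x)
}
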