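#' @import ggplot2
NULL

# Shared x scale so the main panel, gene track and LD heatmap line up.
shared_x <- function(locus, label = NULL) {
  scale_x_continuous(
    name = label,
    limits = c(locus$start_bp, locus$stop_bp),
    labels = function(x) sprintf("%.2f", x / 1e6),
    expand = expansion(mult = 0.02)
  )
}

# Two-ramp fill used in congruence mode: blues for congruous variants,
# reds for incongruous, both darkening with eQTL significance.
CONGRUOUS_RAMP <- c("#C6DBEF", "#08306B")
INCONGRUOUS_RAMP <- c("#FCBBA1", "#67000D")

ramp_fill <- function(values, ramp) {
  rng <- range(values, finite = TRUE)
  span <- if (diff(rng) == 0) 1 else diff(rng)
  grDevices::colorRamp(ramp)((values - rng[1]) / span) |>
    (\(m) grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255))()
}

#' Render the main colocalization panel
#'
#' A regional association panel: position along the locus against GWAS
#' significance. Variants without qualifying eQTL evidence are grey squares;
#' eQTL variants are triangles pointing up/down with the GWAS direction of
#' effect, sized by |NES| (uniform under meta collapsing, which produces no
#' combined NES) and filled by eQTL significance — one warm ramp normally, a
#' blue (congruous) / red (incongruous) pair in congruence mode. The GWAS
#' significance threshold is drawn as a red horizontal line and lead
#' variants, when known, are labelled.
#'
#' @param locus_tbl a [build_locus_table()] result.
#' @param config a [coloc_config()].
#' @param locus the [define_locus()] result (x-axis bounds).
#' @param lead_snps optional ids to label.
#' @return a ggplot object.
#' @export
render_main_panel <- function(locus_tbl, config, locus, lead_snps = NULL) {
  tbl <- locus_tbl
  tbl$mlog_gwas <- -log10(tbl$p_gwas)
  grey_pts <- tbl[!tbl$has_eqtl, ]
  eq <- tbl[tbl$has_eqtl, ]
  meta_mode <- config$collapse_method == "meta" || all(is.na(eq$nes))
  eq$direction <- factor(ifelse(eq$beta >= 0, "up", "down"),
                         levels = c("up", "down"))
  eq$mlog_eqtl <- -log10(eq$p_eqtl)

  if (isTRUE(config$congruence)) {
    eq$fill_val <- NA_character_
    for (cls in c("congruous", "incongruous")) {
      sel <- eq$congruence_class == cls
      if (any(sel)) {
        ramp <- if (cls == "congruous") CONGRUOUS_RAMP else INCONGRUOUS_RAMP
        eq$fill_val[sel] <- ramp_fill(eq$mlog_eqtl[sel], ramp)
      }
    }
    eq <- eq[!is.na(eq$fill_val), ]  # drops direction-less eQTL variants
    fill_scale <- scale_fill_identity()
  } else {
    eq$fill_val <- eq$mlog_eqtl
    fill_scale <- scale_fill_distiller(palette = "YlOrRd", direction = 1,
                                       name = expression(-log[10](P[eQTL])))
  }

  p <- ggplot() +
    geom_point(data = grey_pts, aes(x = .data$bp, y = .data$mlog_gwas),
               shape = 15, colour = "grey60", size = 1.4) +
    geom_hline(yintercept = -log10(config$sigpvalue_gwas),
               colour = "red", linewidth = 0.4) +
    shared_x(locus, sprintf("Chromosome %s position (Mb)", locus$chrom)) +
    scale_shape_manual(values = c(up = 24, down = 25), drop = FALSE,
                       name = "GWAS direction") +
    fill_scale +
    labs(y = expression(-log[10](P[GWAS]))) +
    theme_bw()

  if (meta_mode) {
    p <- p + geom_point(data = eq,
                        aes(x = .data$bp, y = .data$mlog_gwas,
                            shape = .data$direction, fill = .data$fill_val),
                        size = 2.2)
  } else {
    p <- p +
      geom_point(data = eq,
                 aes(x = .data$bp, y = .data$mlog_gwas,
                     shape = .data$direction, fill = .data$fill_val,
                     size = abs(.data$nes))) +
      scale_size_continuous(range = c(1, 4), name = "|NES|",
                            limits = config$nes_size_limits)
  }
  if (!is.null(config$ylima)) {
    p <- p + coord_cartesian(ylim = c(0, config$ylima))
  }
  if (!is.null(lead_snps)) {
    lab <- tbl[tbl$snp %in% lead_snps, ]
    if (nrow(lab) > 0) {
      p <- p + geom_text(data = lab,
                         aes(x = .data$bp, y = .data$mlog_gwas,
                             label = .data$snp),
                         vjust = -1, size = 2.8)
    }
  }
  p
}

#' Render the gene track panel
#'
#' One labelled horizontal bar per gene overlapping the locus, clipped to the
#' locus bounds and sharing the main panel's x axis. An empty locus yields an
#' empty (but valid) track.
#'
#' @param genes_table gene coordinates for the active build.
#' @param locus the [define_locus()] result.
#' @param height_weight relative panel height (used at composition time).
#' @return a ggplot object.
#' @export
render_gene_track <- function(genes_table, locus, height_weight = 2) {
  g <- genes_table[genes_table$chrom == locus$chrom &
                     genes_table$start <= locus$stop_bp &
                     genes_table$stop >= locus$start_bp, ]
  p <- ggplot() + shared_x(locus) +
    scale_y_continuous(limits = c(-2.6, 0.9)) +
    theme_bw() +
    theme(axis.text.y = element_blank(), axis.ticks.y = element_blank(),
          axis.title.x = element_blank()) +
    labs(y = "Genes")
  if (nrow(g) > 0) {
    g <- g[order(g$start), ]
    g$row <- -(seq_len(nrow(g)) %% 3)  # stagger dense neighborhoods
    g$xmin <- pmax(g$start, locus$start_bp)
    g$xmax <- pmin(g$stop, locus$stop_bp)
    p <- p +
      geom_segment(data = g,
                   aes(x = .data$xmin, xend = .data$xmax,
                       y = .data$row, yend = .data$row),
                   linewidth = 3, colour = "#3182BD") +
      geom_text(data = g,
                aes(x = (.data$xmin + .data$xmax) / 2, y = .data$row,
                    label = .data$gene),
                vjust = -1.1, size = 2.8, fontface = "italic")
  }
  attr(p, "height_weight") <- height_weight
  p
}

#' Render the pairwise LD heatmap panel
#'
#' Classic rotated lower-triangle heatmap of the R^2 matrix for the filtered
#' variant set, drawn below the locus: each variant pair is a diamond, and a
#' guide segment connects every variant's chromosomal position (on the shared
#' x axis at the top) to its heatmap slot. Fill is a warm ramp, or greyscale
#' with `ldcolor = "black"`.
#'
#' @param ld_ctx a [build_ld_context()] result.
#' @param locus the [define_locus()] result.
#' @param ldcolor `"color"` or `"black"`.
#' @return a ggplot object, or `NULL` (with a warning) when fewer than 2
#'   variants survive filtering.
#' @export
render_ld_heatmap <- function(ld_ctx, locus, ldcolor = "color") {
  if (isTRUE(ld_ctx$empty) || nrow(ld_ctx$kept) < 2) {
    warn("LD heatmap skipped: fewer than 2 variants after filtering")
    return(NULL)
  }
  m <- ld_ctx$r2_matrix
  n <- nrow(m)
  slots <- seq(locus$start_bp, locus$stop_bp, length.out = n)
  h <- (locus$stop_bp - locus$start_bp) / max(1, n - 1)
  ij <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  cx <- (slots[ij[, 1]] + slots[ij[, 2]]) / 2
  cy <- -abs(ij[, 1] - ij[, 2]) * h / 2 - h / 2
  cells <- data.frame(
    id = rep(seq_along(cx), each = 4),
    x = as.vector(rbind(cx - h / 2, cx, cx + h / 2, cx)),
    y = as.vector(rbind(cy, cy + h / 2, cy, cy - h / 2)),
    r2 = rep(m[ij], each = 4)
  )
  ticks <- data.frame(bp = ld_ctx$kept$bp, slot = slots)
  p <- ggplot() +
    geom_polygon(data = cells,
                 aes(x = .data$x, y = .data$y, group = .data$id,
                     fill = .data$r2),
                 colour = NA) +
    geom_segment(data = ticks,
                 aes(x = .data$bp, xend = .data$slot, y = h * 0.45, yend = 0),
                 linewidth = 0.15, colour = "grey40") +
    geom_point(data = ticks, aes(x = .data$bp), y = h * 0.5, shape = 3,
               size = 0.5, colour = "grey20") +
    shared_x(locus) +
    theme_void() +
    theme(legend.position = "right")
  if (ldcolor == "black") {
    p + scale_fill_gradient(low = "white", high = "black", limits = c(0, 1),
                            name = expression(R^2))
  } else {
    p + scale_fill_distiller(palette = "YlOrRd", direction = 1,
                             limits = c(0, 1), name = expression(R^2))
  }
}

#' Render the eQTL enrichment panel
#'
#' Paired bars: the proportion of GWAS-significant and of non-significant
#' locus variants that qualify as eQTLs, annotated with the Fisher exact p;
#' one bar pair per congruence stratum when the analysis is stratified.
#'
#' @param enrichment_results list of [enrichment_test()] results.
#' @return a ggplot object.
#' @export
render_enrichment_panel <- function(enrichment_results) {
  df <- bind_rows(lapply(enrichment_results, function(e) {
    tibble(stratum = e$stratum,
           group = factor(c("GWAS significant", "not significant"),
                          levels = c("GWAS significant", "not significant")),
           proportion = c(e$proportion_sig %||% NA_real_,
                          e$proportion_nonsig %||% NA_real_),
           fisher_p = e$fisher_p, degenerate = e$degenerate)
  }))
  df$proportion[is.na(df$proportion)] <- 0
  ann <- df[!duplicated(df$stratum), ]
  ann$label <- ifelse(ann$degenerate, "p = n.s.",
                      paste0("p = ", format(signif(ann$fisher_p, 2))))
  ggplot(df, aes(x = .data$stratum, y = .data$proportion,
                 fill = .data$group)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_text(data = ann,
              aes(x = .data$stratum, label = .data$label),
              y = max(df$proportion) * 1.06 + 0.02, inherit.aes = FALSE,
              size = 3) +
    scale_fill_manual(values = c("GWAS significant" = "#D94801",
                                 "not significant" = "grey65"),
                      name = NULL) +
    scale_y_continuous(limits = c(0, max(df$proportion) * 1.15 + 0.05),
                       expand = expansion(mult = c(0, 0.02))) +
    labs(x = NULL, y = "Proportion that are eQTLs") +
    theme_bw()
}

#' Render a P-P correlation panel
#'
#' Scatter of eQTL against GWAS significance (-log10 p) for qualifying
#' variants, with the least-squares line and the Pearson r / p annotation.
#' With LD information the points are filled by R^2 to the lead variant,
#' which is drawn as a green diamond. In congruence mode without LD, both
#' strata are superimposed in one panel with per-stratum lines.
#'
#' @param corr_results list of [pp_correlation()] results (one, or the two
#'   congruence strata).
#' @param config a [coloc_config()].
#' @param lead_r2 optional named R^2-to-lead vector from
#'   [lead_r2_annotation()].
#' @param lead_snp optional lead variant id (required with `lead_r2`).
#' @return a ggplot object.
#' @export
render_pp_panel <- function(corr_results, config, lead_r2 = NULL,
                            lead_snp = NULL) {
  if (inherits(corr_results, "qtlcoloc_correlation")) {
    corr_results <- list(corr_results)
  }
  pts <- bind_rows(lapply(corr_results, function(cr) {
    if (nrow(cr$points) == 0) return(NULL)
    mutate(cr$points, stratum = cr$stratum)
  }))
  lines <- bind_rows(lapply(corr_results, function(cr) {
    if (!cr$defined) return(NULL)
    tibble(stratum = cr$stratum, slope = cr$slope, intercept = cr$intercept,
           label = sprintf("r = %s, p = %s",
                           format(signif(cr$pearson_r, 3)),
                           format(signif(cr$p_correlation, 3))))
  }))
  multi <- length(corr_results) > 1
  p <- ggplot() +
    labs(x = expression(-log[10](P[eQTL])),
         y = expression(-log[10](P[GWAS]))) +
    theme_bw()
  if (!is.null(pts) && nrow(pts) > 0) {
    if (!is.null(lead_r2)) {
      pts$r2_lead <- unname(lead_r2[pts$snp])
      lead_pt <- pts[pts$snp %in% lead_snp, ]
      p <- p +
        geom_point(data = pts[!pts$snp %in% lead_snp, ],
                   aes(x = .data$x, y = .data$y, fill = .data$r2_lead),
                   shape = 21, size = 2) +
        scale_fill_gradient(low = "#FFF5EB", high = "#CB181D",
                            limits = c(0, 1),
                            name = expression(R^2 ~ "with lead")) +
        geom_point(data = lead_pt, aes(x = .data$x, y = .data$y),
                   shape = 23, fill = "green3", colour = "black", size = 3.5)
    } else if (multi) {
      p <- p +
        geom_point(data = pts,
                   aes(x = .data$x, y = .data$y, colour = .data$stratum),
                   size = 2) +
        scale_colour_manual(values = c(congruous = "#08519C",
                                       incongruous = "#CB181D"),
                            name = NULL)
    } else {
      p <- p + geom_point(data = pts, aes(x = .data$x, y = .data$y),
                          colour = "#3182BD", size = 2)
    }
  }
  if (!is.null(lines) && nrow(lines) > 0) {
    if (multi) {
      p <- p + geom_abline(data = lines,
                           aes(slope = .data$slope,
                               intercept = .data$intercept,
                               colour = .data$stratum),
                           linewidth = 0.5)
    } else {
      p <- p + geom_abline(slope = lines$slope[1],
                           intercept = lines$intercept[1],
                           colour = "grey30", linewidth = 0.5)
    }
    p <- p + labs(subtitle = paste(
      ifelse(rep(multi, nrow(lines)),
             paste0(lines$stratum, ": ", lines$label), lines$label),
      collapse = "   "))
  } else {
    p <- p + labs(subtitle = "correlation undefined (fewer than 3 variants)")
  }
  if (!is.null(config$xlimd) || !is.null(config$ylimd)) {
    p <- p + coord_cartesian(
      xlim = if (!is.null(config$xlimd)) c(0, config$xlimd),
      ylim = if (!is.null(config$ylimd)) c(0, config$ylimd))
  }
  p
}
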