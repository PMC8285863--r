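#' Simulation parameters for a synthetic locus
#'
#' Describes a locus with block-structured linkage disequilibrium and a
#' single causal variant per signal. Variants are evenly spaced and split
#' into `n_blocks` equal LD blocks; within a block the genotype correlation
#' between variants i and j is `rho^|i-j|` (first-order autoregressive), and
#' zero across blocks. GWAS and per-tissue eQTL z-scores follow the standard
#' summary-statistic model: mean `lambda * r(., causal)` plus multivariate
#' normal noise with the same LD correlation, so marginal z-scores are
#' standard normal under the null. Effect sizes are scaled as `z / sqrt(N)`,
#' giving GTEx-like NES magnitudes of order 0.1-1.
#'
#' With `shared_causal = TRUE` the eQTL causal variant is the GWAS causal
#' variant (the middle of the central block): a colocalized locus. Otherwise
#' the eQTL signal is planted in the middle of the first block: overlapping
#' association peaks driven by different variants.
#'
#' Default signal strengths (`lambda_gwas = 12`, `lambda_eqtl = 10`) put the
#' causal variants far beyond genome-wide (5e-8) and nominal (0.05)
#' significance, the regime the colocalization display is designed for;
#' `rho = 0.9` gives LD blocks dense enough to exercise the R^2/degree
#' filters.
#'
#' @param n_variants total variant count (default 300).
#' @param n_blocks number of LD blocks (default 3).
#' @param rho within-block AR(1) correlation decay, in (0, 1) (default 0.9).
#' @param lambda_gwas GWAS signal strength (causal-variant mean z; default 12).
#' @param lambda_eqtl eQTL signal strength (default 10).
#' @param shared_causal do GWAS and eQTL share their causal variant?
#' @param tissues named integer vector: tissue sample sizes.
#' @param n_gwas GWAS sample size used to scale beta (default 100000).
#' @param chrom chromosome label (default 11).
#' @param start_bp position of the first variant (default 1e6).
#' @param spacing_bp distance between adjacent variants (default 1000).
#' @param r2_emit_min smallest within-block R^2 written to the LD table
#'   (default 0.01; keeps the pair list near-complete but bounded).
#' @param gbuild genome build tag for the gene record.
#' @param seed random seed; a fixed seed makes the output byte-identical.
#' @return list of class `"qtlcoloc_sim_params"`.
#' @export
sim_params <- function(n_variants = 300, n_blocks = 3, rho = 0.9,
                       lambda_gwas = 12, lambda_eqtl = 10,
                       shared_causal = TRUE,
                       tissues = c(Adipose_Subcutaneous = 500,
                                   Liver = 400,
                                   Whole_Blood = 300),
                       n_gwas = 1e5, chrom = 11, start_bp = 1e6,
                       spacing_bp = 1000, r2_emit_min = 0.01,
                       gbuild = "hg19", seed = 1) {
  stopifnot(n_variants >= n_blocks, n_blocks >= 1, rho > 0, rho < 1,
            lambda_gwas >= 0, lambda_eqtl >= 0, length(tissues) >= 1,
            !is.null(names(tissues)), all(tissues >= 1))
  structure(as.list(environment()), class = "qtlcoloc_sim_params")
}

# Sample one z-vector: mean lambda * r(., causal) + MVN(0, Sigma) noise,
# blockwise. `blocks` is the block index per variant, `r_causal` the signed
# correlation of each variant with the causal variant.
sample_z <- function(blocks, rho, lambda, r_causal) {
  z <- numeric(length(blocks))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    sigma <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
    noise <- drop(crossprod(chol(sigma), stats::rnorm(k)))
    z[idx] <- lambda * r_causal[idx] + noise
  }
  z
}

#' Simulate a synthetic locus
#'
#' Generates the four analysis inputs — GWAS summary statistics, per-tissue
#' cis-eQTL summary statistics, a one-gene coordinate table, and pairwise LD
#' — from [sim_params()]. The target gene spans the central LD block. LD
#' pairs are emitted once per unordered pair (R^2 = rho^(2|i-j|) within a
#' block) down to `r2_emit_min`.
#'
#' @param params a [sim_params()] list.
#' @return list of class `"qtlcoloc_sim"` with elements `gwas`, `eqtl`,
#'   `genes`, `ld` (tibbles in the shapes the readers produce), plus
#'   `causal_gwas`, `causal_eqtl` (variant ids) and `params`.
#' @export
simulate_locus <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  n <- p$n_variants
  idx <- seq_len(n)
  blocks <- ceiling(idx / ceiling(n / p$n_blocks))
  bp <- p$start_bp + (idx - 1L) * p$spacing_bp
  snp <- sprintf("rs%05d", idx)

  central <- ceiling(p$n_blocks / 2 + 0.5)
  block_mid <- function(b) {
    i <- which(blocks == b)
    i[ceiling(length(i) / 2)]
  }
  causal_g <- block_mid(central)
  causal_e <- if (p$shared_causal) causal_g else block_mid(1L)

  r_to <- function(causal) {
    r <- numeric(n)
    same <- blocks == blocks[causal]
    r[same] <- p$rho^abs(idx[same] - causal)
    r
  }

  z_g <- sample_z(blocks, p$rho, p$lambda_gwas, r_to(causal_g))
  gwas <- tibble(chrom = p$chrom, bp = bp, snp = snp,
                 p_gwas = clamp_pvalues(2 * stats::pnorm(abs(z_g), lower.tail = FALSE),
                                        "simulated GWAS p-value"),
                 beta = z_g / sqrt(p$n_gwas))

  r_e <- r_to(causal_e)
  eqtl <- bind_rows(lapply(names(p$tissues), function(tis) {
    z_e <- sample_z(blocks, p$rho, p$lambda_eqtl, r_e)
    tibble(snp = snp, gene = "GENE1",
           p_eqtl = clamp_pvalues(2 * stats::pnorm(abs(z_e), lower.tail = FALSE),
                                  "simulated eQTL p-value"),
           nes = z_e / sqrt(p$tissues[[tis]]),
           tissue = tis, n = as.integer(p$tissues[[tis]]))
  }))

  central_idx <- which(blocks == central)
  genes <- tibble(gene = "GENE1", chrom = p$chrom,
                  start = bp[min(central_idx)], stop = bp[max(central_idx)],
                  build = p$gbuild)

  pairs <- do.call(rbind, lapply(unique(blocks), function(b) {
    i <- which(blocks == b)
    g <- expand.grid(a = i, b = i)
    g <- g[g$a < g$b, ]
    g$r2 <- p$rho^(2 * (g$b - g$a))
    g[g$r2 >= p$r2_emit_min, ]
  }))
  ld <- tibble(snp_a = snp[pairs$a], bp_a = bp[pairs$a],
               snp_b = snp[pairs$b], bp_b = bp[pairs$b],
               r2 = pairs$r2)[, c("snp_a", "bp_a", "snp_b", "bp_b", "r2")]

  structure(list(gwas = gwas, eqtl = eqtl, genes = genes, ld = ld,
                 causal_gwas = snp[causal_g], causal_eqtl = snp[causal_e],
                 params = p),
            class = "qtlcoloc_sim")
}

#' Write a simulated locus as fixture files
#'
#' Writes the four tables in exactly the dialects the readers accept:
#' tab-separated GWAS/eQTL/gene tables and a space-delimited PLINK-style LD
#' table. Reading the files back reproduces the simulated records.
#'
#' @param sim a [simulate_locus()] result.
#' @param out_dir output directory (created if needed).
#' @param ld write the LD table too? (default `TRUE`).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(sim, out_dir, ld = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gwas = write_gwas_table(sim$gwas, file.path(out_dir, "gwas.tsv")),
    eqtl = write_eqtl_table(sim$eqtl, file.path(out_dir, "eqtl.tsv")),
    genes = write_genes_table(sim$genes, file.path(out_dir, "genes.tsv"))
  )
  if (ld) {
    paths <- c(paths,
               ld = write_ld_table(sim$ld, file.path(out_dir, "ld.txt")))
  }
  paths
}
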