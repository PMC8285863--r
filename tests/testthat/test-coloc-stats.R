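locus_from_counts <- function(a, b, c, d, class_a = "congruous") {
  n <- a + b + c + d
  make_locus_tbl(
    snp = sprintf("rs%03d", seq_len(n)),
    p_gwas = rep(c(1e-10, 0.5), c(a + b, c + d)),
    p_eqtl = ifelse(rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
                    0.01, NA_real_),
    nes = 0.5,
    congruence_class = rep(c(class_a, "not_applicable", class_a,
                             "not_applicable"), c(a, b, c, d)))
}

test_that("enrichment counts are conserved and symmetric tables give p = 1", {
  tbl <- locus_from_counts(5, 5, 5, 5)
  res <- enrichment_test(tbl)
  expect_equal(res$fisher_p, 1)
  expect_equal(with(res, a + b + c + d), nrow(tbl))
  expect_equal(res$a + res$b, sum(tbl$gwas_significant))
  expect_equal(res$proportion_sig, 0.5)

  skewed <- locus_from_counts(8, 2, 10, 80)
  r2 <- enrichment_test(skewed)
  expect_lt(r2$fisher_p, 1e-4)
  expect_equal(r2$fisher_p, fisher_enum_oracle(8, 2, 10, 80),
               tolerance = 1e-12)
})

test_that("enrichment with no significant variants degenerates to p = 1 with a warning", {
  tbl <- locus_from_counts(0, 0, 10, 80)
  expect_warning(res <- enrichment_test(tbl), "margin")
  expect_true(res$degenerate)
  expect_equal(res$fisher_p, 1)
  expect_true(is.na(res$proportion_sig))
})

test_that("congruence strata exclude eQTLs of the other class, keep non-eQTLs", {
  tbl <- rbind(
    make_locus_tbl("s1", 1e-10, 0.01, nes = 0.5,
                   congruence_class = "congruous"),
    make_locus_tbl("s2", 1e-10, 0.01, nes = -0.5,
                   congruence_class = "incongruous"),
    make_locus_tbl("s3", 1e-10, NA_real_),
    make_locus_tbl(c("s4", "s5"), c(0.4, 0.6), c(0.02, NA),
                   congruence_class = c("congruous", "not_applicable")))
  res <- enrichment_test(tbl, "congruous")
  # s2 (incongruous eQTL) is excluded entirely; non-eQTLs s3, s5 remain
  expect_equal(with(res, c(a, b, c, d)), c(1, 1, 1, 1))
  res_i <- enrichment_test(tbl, "incongruous")
  expect_equal(with(res_i, c(a, b, c, d)), c(1, 1, 0, 1))
})

test_that("P-P correlation reproduces closed forms on fixed points", {
  # identical coordinates: perfect correlation
  tbl <- make_locus_tbl(paste0("s", 1:4), p_gwas = 10^-(1:4),
                        p_eqtl = 10^-(1:4), gwas_significant = FALSE)
  expect_equal(pp_correlation(tbl)$pearson_r, 1, tolerance = 1e-12)

  # the 3-point (1,1),(2,3),(3,2) configuration has r = 0.5 exactly
  tbl3 <- make_locus_tbl(paste0("s", 1:3), p_gwas = 10^-c(1, 3, 2),
                         p_eqtl = 10^-c(1, 2, 3), gwas_significant = FALSE)
  res <- pp_correlation(tbl3)
  expect_equal(res$pearson_r, 0.5, tolerance = 1e-12)
  expect_equal(res$pearson_r, pearson_direct(c(1, 2, 3), c(1, 3, 2)),
               tolerance = 1e-14)
  expect_equal(res$n_points, 3)

  # regression line matches the least-squares closed form
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)

  # fewer than 3 qualifying points: flagged, not an error
  few <- make_locus_tbl(paste0("s", 1:5), p_gwas = rep(0.5, 5),
                        p_eqtl = c(0.01, 0.01, NA, NA, NA))
  out <- pp_correlation(few)
  expect_false(out$defined)
  expect_true(is.na(out$pearson_r))
})

test_that("only qualifying eQTL variants enter the P-P correlation", {
  tbl <- make_locus_tbl(paste0("s", 1:6), p_gwas = 10^-(1:6),
                        p_eqtl = c(10^-(1:4), 0.2, NA),
                        has_eqtl = c(rep(TRUE, 4), FALSE, FALSE))
  expect_equal(pp_correlation(tbl)$n_points, 4)
})

test_that("lead variant selection maximizes the P-P coordinate sum", {
  pts <- tibble::tibble(snp = c("v1", "v2", "v3"), x = c(3, 4, 5),
                        y = c(2, 4, 2))
  expect_equal(select_lead_variant(pts), "v2")
  expect_equal(select_lead_variant(pts[2, ]), "v2")
  tie <- tibble::tibble(snp = c("v1", "v2"), x = c(4, 5), y = c(4, 3))
  expect_equal(select_lead_variant(tie), "v1")  # equal sum, higher GWAS
  lex <- tibble::tibble(snp = c("vb", "va"), x = c(4, 4), y = c(4, 4))
  expect_equal(select_lead_variant(lex), "va")

  expect_equal(select_lead_variant(pts, user_lead = "v9",
                                   gwas_snps = c("v9"), ld_snps = c("v9")),
               "v9")
  expect_error(select_lead_variant(pts, user_lead = "v9",
                                   gwas_snps = "v1", ld_snps = "v9"),
               "GWAS", class = "qtlcoloc_lead_snp_error")
  expect_error(select_lead_variant(pts, user_lead = "v1",
                                   gwas_snps = "v1", ld_snps = "v9"),
               "LD", class = "qtlcoloc_lead_snp_error")
})

test_that("gene and tissue rankings are consistent, ordered, and flag sparse entries", {
  sim <- demo_sim()
  cfg <- demo_config()
  genes2 <- rbind(sim$genes,
                  tibble::tibble(gene = "GENE2", chrom = 11,
                                 start = sim$genes$start,
                                 stop = sim$genes$stop, build = "hg19"))
  eqtl2 <- rbind(sim$eqtl,
                 transform(sim$eqtl, gene = "GENE2"))

  rg <- rank_genes(sim$gwas, eqtl2, c("GENE1", "GENE2"), genes2, cfg)
  # identical data for both genes: identical correlations
  expect_equal(rg$pearson_r[1], rg$pearson_r[2], tolerance = 1e-12)
  # single-gene ranking equals the direct P-P computation
  one <- rank_genes(sim$gwas, sim$eqtl, "GENE1", sim$genes, cfg)
  direct <- qtl_coloc(sim$gwas, sim$eqtl, demo_config(saveplot = FALSE),
                      genes_table = sim$genes)
  expect_equal(one$pearson_r, direct$correlations$all$pearson_r,
               tolerance = 1e-12)
  expect_error(rank_genes(sim$gwas, sim$eqtl, "GENEX", sim$genes, cfg),
               "GENEX", class = "qtlcoloc_unknown_gene_error")

  rt <- rank_tissues(sim$gwas, sim$eqtl, "GENE1", "all", sim$genes, cfg)
  expect_equal(sort(rt$tissue), sort(unique(sim$eqtl$tissue)))
  expect_true(!is.unsorted(rt$p_correlation))
  out <- capture.output(print(rt))
  expect_match(out[1], "^eQTL analysis for tissue .*Pearson correlation")

  # a tissue in which no variant qualifies is flagged and placed last
  sparse <- rbind(sim$eqtl,
                  tibble::tibble(snp = sim$eqtl$snp[1], gene = "GENE1",
                                 p_eqtl = 0.9, nes = 0.1,
                                 tissue = "Desert", n = 100L))
  rt2 <- rank_tissues(sim$gwas, sparse, "GENE1", "all", sim$genes, cfg)
  expect_true(rt2$flagged[rt2$tissue == "Desert"])
  expect_equal(rt2$tissue[nrow(rt2)], "Desert")
})
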