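genes_fixture <- tibble::tibble(
  gene = c("GENEA", "GENEB"), chrom = c(1, 1),
  start = c(1000000, 50000), stop = c(1050000, 90000),
  build = "hg19")

test_that("locus bounds are gene bounds plus the kb flank, floored at 1", {
  loc <- define_locus("GENEA", genes_fixture, range_kb = 200)
  expect_equal(loc$start_bp, 800000)
  expect_equal(loc$stop_bp, 1250000)

  loc0 <- define_locus("GENEA", genes_fixture, range_kb = 0)
  expect_equal(c(loc0$start_bp, loc0$stop_bp), c(1000000, 1050000))

  # default flank is 200 kb
  expect_equal(formals(define_locus)$range_kb, 200)

  floored <- define_locus("GENEB", genes_fixture, range_kb = 200)
  expect_equal(floored$start_bp, 1)

  expect_error(define_locus("NOPE", genes_fixture), "GENEA",
               class = "qtlcoloc_unknown_gene_error")
})

test_that("tissue collapsing: identity, forced arithmetic, and tie-breaks", {
  eq <- tibble::tibble(snp = "rs1", gene = "G", p_eqtl = 0.03, nes = 0.4,
                       tissue = "Liver")
  for (m in c("min", "median", "mean")) {
    out <- collapse_tissues(eq, "all", m)
    expect_equal(out$p_eqtl, 0.03)
    expect_equal(out$nes, 0.4)
  }

  eq2 <- tibble::tibble(snp = "rs1", gene = "G",
                        p_eqtl = c(0.01, 0.2), nes = c(0.5, -0.3),
                        tissue = c("Liver", "Blood"))
  mn <- collapse_tissues(eq2, "all", "min")
  expect_equal(c(mn$p_eqtl, mn$nes), c(0.01, 0.5))
  expect_equal(mn$source_tissue, "Liver")
  me <- collapse_tissues(eq2, "all", "mean")
  expect_equal(c(me$p_eqtl, me$nes), c(0.105, 0.1))
  md <- collapse_tissues(eq2, "all", "median")
  expect_equal(c(md$p_eqtl, md$nes), c(0.105, 0.1))

  # tied smallest p: larger |nes| wins, then tissue name
  tie <- tibble::tibble(snp = "rs1", gene = "G", p_eqtl = c(0.01, 0.01, 0.01),
                        nes = c(0.2, -0.9, 0.9),
                        tissue = c("A", "C", "B"))
  won <- collapse_tissues(tie, "all", "min")
  expect_equal(won$source_tissue, "B")  # |0.9| tie broken lexicographically
  expect_equal(won$nes, 0.9)

  expect_error(collapse_tissues(eq2, c("Liver", "Muscle"), "min"), "Muscle",
               class = "qtlcoloc_unknown_tissue_error")
})

test_that("meta collapse combines p-values and drops NES", {
  eq <- tibble::tibble(snp = "rs1", gene = "G", p_eqtl = c(0.05, 0.05),
                       nes = c(0.4, 0.2), tissue = c("A", "B"),
                       n = c(200L, 200L))
  out <- collapse_tissues(eq, "all", "meta")
  expect_equal(out$p_eqtl, 0.005574, tolerance = 1e-3)
  expect_true(is.na(out$nes))
  expect_equal(out$source_tissue, "combined")

  no_n <- eq[setdiff(names(eq), "n")]
  expect_error(collapse_tissues(no_n, "all", "meta"), "assume_equal_n",
               class = "qtlcoloc_meta_n_error")
  ok <- collapse_tissues(no_n, "all", "meta", assume_equal_n = TRUE)
  expect_equal(ok$p_eqtl, out$p_eqtl)  # equal n gives the same combination
})

test_that("weighted-Z meta matches an error-function oracle and its identities", {
  # single study: the formula returns the input p for either sign
  for (p in c(0.5, 0.05, 1e-6)) {
    expect_equal(weighted_z_meta(p, 1, 100), p, tolerance = 1e-12)
    expect_equal(weighted_z_meta(p, -1, 100), p, tolerance = 1e-12)
  }
  # opposite signs, equal p and n: complete cancellation
  expect_equal(weighted_z_meta(c(0.05, 0.05), c(1, -1), c(300, 300)), 1)

  # two-study case against the erf-based oracle
  z <- erf_z_from_p(0.05)
  expect_equal(weighted_z_meta(c(0.05, 0.05), c(1, 1), c(100, 100)),
               erf_p_from_z(z * sqrt(2)), tolerance = 1e-10)

  # permutation invariance and monotonicity in a study's significance
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p <- stats::runif(k)
    s <- sample(c(-1, 1), k, replace = TRUE)
    n <- sample(50:500, k)
    perm <- sample(k)
    expect_equal(weighted_z_meta(p, s, n),
                 weighted_z_meta(p[perm], s[perm], n[perm]),
                 tolerance = 1e-12)
  }
  base <- c(0.2, 0.3)
  combined <- sapply(c(0.2, 0.1, 0.01, 1e-4), function(p1)
    weighted_z_meta(c(p1, base[2]), c(1, 1), c(100, 100)))
  expect_true(all(diff(combined) < 0))
})

test_that("congruence classification follows the effect signs", {
  expect_equal(classify_congruence(0.1, 0.8), "congruous")
  expect_equal(classify_congruence(0.1, -0.8), "incongruous")
  expect_equal(classify_congruence(-0.1, -0.8), "congruous")
  expect_equal(classify_congruence(0, 0.8), "not_applicable")
  expect_equal(classify_congruence(0.1, 0), "not_applicable")
  expect_equal(classify_congruence(c(1, -1, 0), c(1, 1, 1)),
               c("congruous", "incongruous", "not_applicable"))
})

test_that("locus table join keeps every GWAS variant in range exactly once", {
  gwas <- tibble::tibble(chrom = 1, bp = c(900000, 1010000, 1260000),
                         snp = c("rs1", "rs2", "rs3"),
                         p_gwas = c(1e-9, 0.5, 0.1), beta = c(0.2, -0.1, 0.1))
  collapsed <- tibble::tibble(snp = c("rs2", "rs9"), p_eqtl = c(0.06, 0.001),
                              nes = c(0.3, 0.5), source_tissue = "combined",
                              method = "min")
  loc <- define_locus("GENEA", genes_fixture, 200)
  cfg <- coloc_config(gene = "GENEA", trait = "T")
  tbl <- build_locus_table(gwas, collapsed, loc, cfg)

  expect_equal(nrow(tbl), 2)                 # rs3 outside the locus
  expect_false("rs9" %in% tbl$snp)           # eQTL-only variants never join
  expect_false(tbl$has_eqtl[tbl$snp == "rs2"])  # p = 0.06 > 0.05
  expect_false(tbl$has_eqtl[tbl$snp == "rs1"])  # no eQTL record: grey square
  expect_true(tbl$gwas_significant[tbl$snp == "rs1"])

  # qualification boundaries: eQTL <= threshold in, GWAS strict <
  collapsed$p_eqtl[1] <- 0.05
  tbl2 <- build_locus_table(gwas, collapsed, loc, cfg)
  expect_true(tbl2$has_eqtl[tbl2$snp == "rs2"])
  gwas$p_gwas[1] <- 5e-8
  tbl3 <- build_locus_table(gwas, collapsed, loc, cfg)
  expect_false(tbl3$gwas_significant[tbl3$snp == "rs1"])

  far <- define_locus("GENEB", genes_fixture, 0)
  expect_error(build_locus_table(gwas, collapsed, far, cfg), "50000",
               class = "qtlcoloc_empty_locus_error")
})

test_that("locus table size equals the GWAS rows inside the window (property)", {
  set.seed(5)
  for (i in 1:10) {
    sim <- simulate_locus(sim_params(n_variants = 80, n_blocks = 2,
                                     seed = i))
    loc <- define_locus("GENE1", sim$genes, range_kb = sample(0:100, 1))
    collapsed <- collapse_tissues(sim$eqtl, "all", "min")
    cfg <- demo_config()
    n_inside <- sum(sim$gwas$bp >= loc$start_bp & sim$gwas$bp <= loc$stop_bp)
    if (n_inside == 0) next
    tbl <- build_locus_table(sim$gwas, collapsed, loc, cfg)
    expect_equal(nrow(tbl), n_inside)
    expect_false(any(duplicated(tbl$snp)))
  }
})
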