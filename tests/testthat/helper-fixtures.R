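# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written from first principles (lchoose, deviation
# sums, explicit loops) so they share no code path with the implementation.

# Exhaustive hypergeometric enumeration of the two-sided Fisher exact p for a
# 2x2 table (a b / c d), point-probability rule: sum the probabilities of all
# tables with fixed margins whose probability does not exceed the observed
# one (with the conventional 1e-7 relative slack for float ties).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[x == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Pearson r by direct evaluation of the deviation-sum formula.
pearson_direct <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Normal quantile / CDF through the error function (pracma), an independent
# route to the weighted-Z arithmetic.
erf_z_from_p <- function(p) sqrt(2) * pracma::erfinv(1 - p)     # two-sided
erf_p_from_z <- function(z) pracma::erfc(z / sqrt(2))           # two-sided

# Brute-force per-variant tissue collapse by explicit loop.
collapse_brute <- function(eqtl_tbl, method) {
  snps <- unique(eqtl_tbl$snp)
  out <- lapply(snps, function(s) {
    rows <- eqtl_tbl[eqtl_tbl$snp == s, ]
    if (method == "min") {
      rows <- rows[order(rows$p_eqtl, -abs(rows$nes), rows$tissue), ]
      data.frame(snp = s, p_eqtl = rows$p_eqtl[1], nes = rows$nes[1])
    } else {
      f <- if (method == "median") stats::median else mean
      data.frame(snp = s, p_eqtl = f(rows$p_eqtl), nes = f(rows$nes))
    }
  })
  do.call(rbind, out)
}

# Brute-force LD degree per variant.
degree_brute <- function(pairs, variants) {
  vapply(variants, function(v) {
    sum(pairs$snp_a == v) + sum(pairs$snp_b == v)
  }, numeric(1))
}

# Minimal locus table constructor for statistics tests; eQTL qualification
# and GWAS significance flags are taken at face value.
make_locus_tbl <- function(snp, p_gwas, p_eqtl = NA_real_, beta = 0.1,
                           nes = NA_real_, has_eqtl = !is.na(p_eqtl),
                           gwas_significant = p_gwas < 5e-8,
                           congruence_class = "not_applicable",
                           bp = seq_along(snp) * 1000 + 1e6) {
  tibble::tibble(snp = snp, bp = bp, p_gwas = p_gwas, beta = beta,
                 p_eqtl = p_eqtl, nes = nes, has_eqtl = has_eqtl,
                 gwas_significant = gwas_significant,
                 congruence_class = congruence_class)
}

# Random eQTL fixture with up to `max_tissues` tissues for collapse tests.
random_eqtl_fixture <- function(n_snps, max_tissues) {
  n_tis <- sample(2:max_tissues, 1)
  tissues <- sprintf("tissue%02d", seq_len(n_tis))
  rows <- expand.grid(snp = sprintf("rs%03d", seq_len(n_snps)),
                      tissue = tissues, stringsAsFactors = FALSE)
  # each variant tested in a random subset of tissues (at least one)
  keep <- stats::runif(nrow(rows)) < 0.8
  first_per_snp <- !duplicated(rows$snp)
  rows <- rows[keep | first_per_snp, ]
  rows$gene <- "G"
  rows$p_eqtl <- stats::runif(nrow(rows))
  rows$nes <- stats::rnorm(nrow(rows))
  rows$n <- sample(100:900, nrow(rows), replace = TRUE)
  tibble::as_tibble(rows)
}

# A small deterministic colocalized locus shared by figure/CLI tests.
demo_sim <- function(seed = 42, shared_causal = TRUE) {
  simulate_locus(sim_params(n_variants = 120, n_blocks = 3, rho = 0.9,
                            seed = seed, shared_causal = shared_causal))
}

demo_config <- function(...) {
  coloc_config(gene = "GENE1", trait = "TRAIT", ...)
}
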