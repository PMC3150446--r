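test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(n_snps = -5), "positive")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("genotype simulation is deterministic and annotated", {
  cfg <- sim_config(n_samples = 100, n_snps = 40, seed = 77)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$geno), c(40L, 100L))
  expect_true(all(a$snp_annot$chr %in% 1:22))
  expect_true(all(a$snp_annot$pos >= 1))
  # missing entries appear at roughly the configured rate
  cfg2 <- sim_config(n_samples = 200, n_snps = 50, missing_rate = 0.1, seed = 78)
  g2 <- simulate_genotypes(cfg2)$geno
  expect_gt(mean(is.na(g2)), 0.07)
  expect_lt(mean(is.na(g2)), 0.13)
})

test_that("genotype frequencies follow Hardy-Weinberg at a fixed MAF", {
  n <- 4000
  cfg <- sim_config(n_samples = n, n_snps = 20, maf_range = c(0.5, 0.5),
                    ld_block_size = 1, seed = 79)
  g <- simulate_genotypes(cfg)$geno
  # expected (0.25, 0.5, 0.25); allow 3 binomial SDs per genotype class
  for (i in seq_len(nrow(g))) {
    for (cls in 0:2) {
      p_exp <- if (cls == 1) 0.5 else 0.25
      se <- sqrt(p_exp * (1 - p_exp) / n)
      expect_lt(abs(mean(g[i, ] == cls) - p_exp), 3 * se + 1e-9)
    }
  }
})

test_that("LD blocks create correlation; block size one leaves SNPs unlinked", {
  cfg1 <- sim_config(n_samples = 1000, n_snps = 60, ld_block_size = 1, seed = 80)
  g1 <- simulate_genotypes(cfg1)$geno
  r2_adjacent <- vapply(seq_len(nrow(g1) - 1), function(i) {
    suppressWarnings(ld_r2(g1[i, ], g1[i + 1, ]))
  }, numeric(1))
  expect_lt(median(r2_adjacent), 0.02)
  cfg2 <- sim_config(n_samples = 1000, n_snps = 60, ld_block_size = 5,
                     ld_decay = 0.05, seed = 81)
  g2s <- simulate_genotypes(cfg2)
  same_block <- g2s$snp_annot$block[-1] == g2s$snp_annot$block[-60]
  r2_b <- vapply(which(same_block), function(i) {
    suppressWarnings(ld_r2(g2s$geno[i, ], g2s$geno[i + 1, ]))
  }, numeric(1))
  expect_gt(median(r2_b), 0.5)   # (1 - 0.05)^2 ~ 0.9 expected
})

test_that("a planted effect reproduces its target explained variance", {
  cfg <- sim_config(n_samples = 1000, n_snps = 20, n_probes = 10,
                    n_batch_components = 0, platform_split = 1, seed = 82)
  g <- simulate_genotypes(cfg)
  eff <- data.frame(snp_id = "rs00003", probe_id = "hit", class = "cis",
                    target_r2 = 0.25, gene = "G1")
  ex <- simulate_expression(g, eff, cfg)
  e <- log2(ex$expr_raw$HT12)
  rho2 <- cor(rank(g$geno["rs00003", ]), rank(e["hit", ]))^2
  expect_lt(abs(rho2 - 0.25), 0.05)
  # cis geometry: probe within 250 kb of the SNP on the same chromosome
  pa <- ex$probe_annot[ex$probe_annot$probe_id == "hit", ]
  sa <- g$snp_annot[g$snp_annot$snp == "rs00003", ]
  expect_equal(pa$chr, sa$chr)
  expect_lte(abs(pa$midpoint - sa$pos), 250000)
  expect_error(simulate_expression(g, transform(eff, snp_id = "rs99999"), cfg),
               "rs99999")
})

test_that("a null simulation carries no genotype signal", {
  cfg <- sim_config(n_samples = 500, n_snps = 30, n_probes = 30,
                    n_batch_components = 0, platform_split = 1, seed = 83)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, plant_effects(g$snp_annot, 0, 0, seed = 1), cfg)
  sm <- spearman_matrix(g$geno, log2(ex$expr_raw$HT12))
  # max |rho| consistent with the null at n=500 over 900 tests
  expect_lt(max(abs(sm$rho)), 6 / sqrt(500))
})

test_that("batch components dominate the eigenstructure when strong", {
  cfg <- sim_config(n_samples = 300, n_snps = 10, n_probes = 120,
                    n_batch_components = 3, batch_sd = 3, noise_sd = 0.3,
                    platform_split = 1, seed = 84)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, plant_effects(g$snp_annot, 0, 0, seed = 1), cfg)
  st <- log2_center_scale(quantile_normalize_to_median(ex$expr_raw$HT12))
  pcs <- compute_sample_pcs(st$expr, k_max = 10)
  # scree gap after the third component
  expect_gt(sum(pcs$var_fraction[1:3]), 5 * sum(pcs$var_fraction[4:6]))
})

test_that("trans probes, platforms and shared probes respect the config", {
  cfg <- sim_config(n_samples = 200, n_snps = 40, n_probes = 30,
                    platform_split = 0.8, shared_probe_fraction = 0.4,
                    seed = 85)
  st <- simulate_study(cfg, n_cis = 3, n_trans = 4)
  tr <- st$truth$effects[st$truth$effects$class == "trans", ]
  for (i in seq_len(nrow(tr))) {
    pa <- st$probe_annot[st$probe_annot$probe_id == tr$probe_id[i], ]
    sa <- st$snp_annot[st$snp_annot$snp == tr$snp_id[i], ]
    expect_true(pa$chr != sa$chr || abs(pa$midpoint - sa$pos) >= 5e6)
  }
  expect_equal(ncol(st$expr_raw$HT12), 160)
  expect_equal(ncol(st$expr_raw$H8v2), 40)
  expect_equal(nrow(st$expr_raw$H8v2), 12)   # 0.4 of 30 probes shared
  expect_true(all(rownames(st$expr_raw$H8v2) %in% rownames(st$expr_raw$HT12)))
})

test_that("trait catalog plants unlinked convergent pairs deterministically", {
  cfg <- sim_config(n_samples = 100, n_snps = 60, n_probes = 40, seed = 86)
  g <- simulate_genotypes(cfg)
  eff <- plant_effects(g$snp_annot, n_cis = 2, n_trans = 2,
                       n_convergent_pairs = 2, seed = 5)
  conv <- attr(eff, "convergent_pairs")
  expect_equal(nrow(conv), 2L)
  for (i in 1:2) {
    ca <- g$snp_annot$chr[g$snp_annot$snp == conv$snpA[i]]
    cb <- g$snp_annot$chr[g$snp_annot$snp == conv$snpB[i]]
    expect_true(ca != cb)
    # both SNPs hit the same probe/gene in the effect table
    genes_a <- eff$gene[eff$snp_id == conv$snpA[i]]
    genes_b <- eff$gene[eff$snp_id == conv$snpB[i]]
    expect_true(conv$gene[i] %in% intersect(genes_a, genes_b))
  }
  tc1 <- simulate_trait_catalog(g$snp_annot, eff, n_traits = 4, seed = 9)
  tc2 <- simulate_trait_catalog(g$snp_annot, eff, n_traits = 4, seed = 9)
  expect_identical(tc1, tc2)
  expect_true(all(table(tc1$catalog$trait) >= 2))
  expect_error(simulate_trait_catalog(g$snp_annot, eff, n_traits = 1, seed = 1),
               "convergent")
})

test_that("planted convergent pairs are recovered from truth inputs", {
  st <- cached_study()
  tr <- st$truth$effects
  recs <- data.frame(snp = tr$snp_id, gene = tr$gene, p = 1e-9,
                     fdr_significant = TRUE)
  found <- find_converging_pairs(st$trait_catalog, recs, st$geno)
  truth <- st$truth$convergent_traits
  expect_gte(nrow(found), 1L)
  expect_true(all(paste(truth$snpA, truth$snpB) %in%
                    paste(found$snpA, found$snpB)))
  # zero planted pairs -> zero convergence on noiseless truth
  cfg0 <- sim_config(n_samples = 150, n_snps = 40, n_probes = 20, seed = 87)
  st0 <- simulate_study(cfg0, n_cis = 2, n_trans = 2, n_convergent_pairs = 0)
  tr0 <- st0$truth$effects
  recs0 <- data.frame(snp = tr0$snp_id, gene = tr0$gene, p = 1e-9,
                      fdr_significant = TRUE)
  expect_equal(nrow(find_converging_pairs(st0$trait_catalog, recs0, st0$geno)),
               0L)
})
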