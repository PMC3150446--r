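test_that("Spearman association matches the rank-then-Pearson oracle", {
  # a tie-free monotone pair is exactly +/-1
  expect_equal(spearman_assoc(c(0, 1, 2, 3, 4, 5), 1:6)$rho, 1)
  expect_equal(spearman_assoc(c(0, 1, 2, 3, 4, 5), 6:1)$rho, -1)
  # with tied genotypes the average-rank convention attenuates |rho| below 1,
  # exactly as the classical estimator does
  mono <- spearman_assoc(c(0, 0, 1, 1, 2, 2), 1:6)
  expect_equal(mono$rho,
               unname(suppressWarnings(
                 cor.test(c(0, 0, 1, 1, 2, 2), 1:6,
                          method = "spearman"))$estimate),
               tolerance = 1e-12)
  expect_equal(spearman_assoc(c(0, 0, 1, 1, 2, 2), 6:1)$rho, -mono$rho,
               tolerance = 1e-12)
  g <- c(0, 1, 1, 2, 2, 2)
  e <- c(1.0, 0.5, 2.0, 1.5, 3.0, 2.5)
  got <- spearman_assoc(g, e)
  oracle <- suppressWarnings(cor.test(g, e, method = "spearman"))
  expect_equal(got$rho, unname(oracle$estimate), tolerance = 1e-12)
  # z matches the two-sided p in magnitude and rho in sign
  expect_equal(2 * pnorm(-abs(got$z)), got$p, tolerance = 1e-10)
  expect_equal(sign(got$z), sign(got$rho))
  # undefined tests are skipped with a log entry
  expect_message(res <- spearman_assoc(c(1, 1, 1, 1), c(1, 2, 3, 4)), "skipped")
  expect_null(res)
})

test_that("Spearman association is invariant under monotone transforms", {
  set.seed(20)
  for (i in 1:5) {
    g <- sample(0:2, 30, replace = TRUE)
    e <- rnorm(30)
    base <- spearman_assoc(g, e)
    for (f in list(function(x) exp(x), function(x) x^3,
                   function(x) rank(x))) {
      expect_equal(spearman_assoc(g, f(e))$rho, base$rho, tolerance = 1e-12)
    }
  }
})

test_that("matrix scan agrees with the per-pair path, including missing genotypes", {
  set.seed(21)
  G <- matrix(sample(0:2, 8 * 40, replace = TRUE), 8, 40,
              dimnames = list(paste0("rs", 1:8), paste0("s", 1:40)))
  G[cbind(sample(8, 10, TRUE), sample(40, 10, TRUE))] <- NA
  E <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:40)))
  sm <- spearman_matrix(G, E)
  for (i in 1:8) for (j in 1:5) {
    ref <- spearman_assoc(G[i, ], E[j, ])
    expect_equal(sm$rho[i, j], ref$rho, tolerance = 1e-12)
    expect_equal(sm$p[i, j], ref$p, tolerance = 1e-12)
  }
})

test_that("cis and trans pair windows use inclusive boundaries", {
  snp_annot <- data.frame(snp = c("a", "b", "c", "d"),
                          chr = c(1, 1, 1, 2),
                          pos = c(1e6, 1e6 + 250000, 1e6 + 250001, 1e6))
  probe_annot <- data.frame(probe_id = "p", chr = 1, midpoint = 1e6)
  cp <- cis_pairs(snp_annot, probe_annot)
  expect_setequal(cp$snp, c("a", "b"))      # 250,000 in; 250,001 out; chr2 out
  snp_annot2 <- data.frame(snp = c("near", "edge", "far", "other"),
                           chr = c(1, 1, 1, 2),
                           pos = c(1e6 + 4.9e6, 1e6 + 5e6, 1e6 + 6e6, 1e6))
  tp <- trans_pairs(snp_annot2, probe_annot)
  expect_setequal(tp$snp, c("edge", "far", "other"))  # 4.9 Mb excluded; 5.0 in
})

test_that("weighted-Z combination has its closed forms", {
  expect_error(combine_weighted_z(numeric(0), numeric(0), numeric(0)), "empty")
  # single dataset: identity
  one <- combine_weighted_z(0.01, 1, 500)
  expect_equal(one$p, 0.01, tolerance = 1e-12)
  # equal n, equal z, same sign: sqrt(2) gain
  z <- qnorm(0.005, lower.tail = FALSE)
  two <- combine_weighted_z(c(0.01, 0.01), c(1, 1), c(300, 300))
  expect_equal(two$z, z * sqrt(2), tolerance = 1e-12)
  # opposite directions cancel
  opp <- combine_weighted_z(c(0.01, 0.01), c(1, -1), c(300, 300))
  expect_equal(opp$z, 0, tolerance = 1e-12)
  expect_equal(opp$p, 1, tolerance = 1e-12)
})

test_that("permutation FDR evaluates the ratio estimator literally", {
  # observed (1e-10, 0.5); one round (0.3, 0.7): at t=1e-10 FDR = 0/1
  fd <- permutation_fdr(c(1e-10, 0.5), list(c(0.3, 0.7)), target_fdr = 0.05)
  expect_equal(fd$n_significant, 1L)
  expect_equal(fd$p_threshold, 1e-10)
  expect_true(fd$significant[1] && !fd$significant[2])
  # observed identical to every permuted round: nothing passes at 0.05
  obs <- c(0.01, 0.2, 0.6)
  fd2 <- permutation_fdr(obs, list(obs, obs), target_fdr = 0.05)
  expect_equal(fd2$n_significant, 0L)
  # monotone in the target level
  set.seed(22)
  obs3 <- c(runif(50)^3)
  perm3 <- replicate(10, runif(50), simplify = FALSE)
  lo <- permutation_fdr(obs3, perm3, target_fdr = 0.05)
  hi <- permutation_fdr(obs3, perm3, target_fdr = 0.50)
  expect_true(all(which(lo$significant) %in% which(hi$significant)))
  expect_error(permutation_fdr(obs3, list()), "permutation")
})

test_that("regressing out cis effects annihilates the genotype signal", {
  set.seed(23)
  n <- 400
  g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  noise <- rnorm(n)
  beta <- sqrt(0.3 / 0.7 * var(noise) / var(g))
  E <- rbind(hit = beta * g + noise, bystander = rnorm(n))
  colnames(E) <- paste0("s", 1:n)
  G <- rbind(rs1 = g)
  colnames(G) <- colnames(E)
  recs <- data.frame(snp = "rs1", probe = "hit", p = 1e-20,
                     fdr_significant = TRUE)
  R <- regress_out_cis(E, recs, G)
  expect_lt(cor(R["hit", ], g)^2, 1e-3)
  expect_identical(R["bystander", ], E["bystander", ])
  expect_lte(var(R["hit", ]), var(E["hit", ]))
})

test_that("replication keeps only same-direction pairs below the nominal threshold", {
  disc <- data.frame(snp = c("a", "b", "c", "d"), probe = paste0("p", 1:4),
                     direction = c(1, 1, 1, -1))
  repl <- data.frame(snp = c("a", "b", "c"), probe = paste0("p", 1:3),
                     p = c(1e-6, 1e-4, 1e-6), direction = c(1, 1, -1))
  out <- replicate_eqtls(disc, repl)
  expect_equal(out$replicated$snp, "a")
  expect_setequal(out$dropped$drop_reason,
                  c("p_above_threshold", "direction_mismatch", "absent"))
})

test_that("multi-tissue meta-analysis reduces to one tissue and gains power with four", {
  set.seed(24)
  g <- simulate_genotypes(sim_config(n_samples = 120, n_snps = 10, seed = 5))
  gvec <- g$geno[1, ]
  E <- rbind(p1 = as.numeric(scale(gvec)) * 0.6 + rnorm(120, sd = 0.8))
  colnames(E) <- colnames(g$geno)
  pairs <- data.frame(snp = rownames(g$geno)[1], probe = "p1")
  one <- meta_multi_tissue(list(t1 = list(geno = g$geno, expr = E)),
                           pairs, n_perm = 20, seed = 6)
  single <- eqtl_scan(list(t1 = list(geno = g$geno, expr = E)), pairs,
                      n_perm = 20, seed = 6)
  expect_equal(one$records$p, single$records$p, tolerance = 1e-12)
  four <- meta_multi_tissue(rep(list(list(geno = g$geno, expr = E)), 4) |>
                              setNames(paste0("t", 1:4)),
                            pairs, n_perm = 20, seed = 6)
  expect_lt(four$records$p, one$records$p)
  bad <- list(t1 = list(geno = g$geno, expr = E),
              t2 = list(geno = g$geno[, 1:60], expr = E[, 1:60, drop = FALSE]))
  expect_error(meta_multi_tissue(bad, pairs), "mismatched")
})

test_that("synchronized permutations widen the null for correlated tissues", {
  set.seed(25)
  g <- simulate_genotypes(sim_config(n_samples = 100, n_snps = 5, seed = 9))
  shared <- rnorm(100)
  mk <- function() {
    E <- rbind(p1 = shared + rnorm(100, sd = 0.2))
    colnames(E) <- colnames(g$geno)
    E
  }
  tiss <- list(t1 = list(geno = g$geno, expr = mk()),
               t2 = list(geno = g$geno, expr = mk()))
  pairs <- expand.grid(snp = rownames(g$geno), probe = "p1",
                       stringsAsFactors = FALSE)
  sync <- eqtl_scan(tiss, pairs, n_perm = 40, seed = 1, synchronized = TRUE)
  indep <- eqtl_scan(tiss, pairs, n_perm = 40, seed = 1, synchronized = FALSE)
  z_of <- function(pp) qnorm(unlist(pp) / 2, lower.tail = FALSE)
  expect_gt(var(z_of(sync$permuted_p)), var(z_of(indep$permuted_p)))
})

test_that("explained variance equals 100 times the squared rank correlation", {
  set.seed(26)
  g <- simulate_genotypes(sim_config(n_samples = 200, n_snps = 4, seed = 2))
  E <- rbind(p1 = as.numeric(scale(g$geno[2, ])) + rnorm(200))
  colnames(E) <- colnames(g$geno)
  pairs <- expand.grid(snp = rownames(g$geno), probe = "p1",
                       stringsAsFactors = FALSE)
  sc <- eqtl_scan(list(d = list(geno = g$geno, expr = E)), pairs,
                  n_perm = 5, seed = 3)
  for (i in seq_len(nrow(pairs))) {
    rr <- cor(rank(g$geno[pairs$snp[i], ]), rank(E[1, ]))
    expect_equal(sc$records$explained_variance_pct[i], 100 * rr^2,
                 tolerance = 1e-8)
  }
})
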