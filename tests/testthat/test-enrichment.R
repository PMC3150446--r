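test_that("MHC membership is chr6 20-40 Mb inclusive", {
  expect_true(mhc_membership(6, 25e6))
  expect_false(mhc_membership(6, 19999999))
  expect_false(mhc_membership(7, 25e6))
  expect_true(mhc_membership("6", 20e6))
  expect_true(mhc_membership(6, 40e6))
  expect_false(mhc_membership(6, 40e6 + 1))
})

test_that("top-ranked category counting orders by p, |z|, then id", {
  rk <- data.frame(snp = c("s5", "s1", "s2", "s3", "s4"),
                   p = c(1e-8, 1e-6, 1e-6, 1e-3, 0.5),
                   z = c(6, 5, 4.9, 3, 1))
  incat <- function(ids) ids %in% c("s1", "s4")
  expect_equal(count_category_in_top(rk, 3, incat), 1L)  # s5, s1, s2 -> s1 only
  expect_equal(count_category_in_top(rk, 5, incat), 2L)
  expect_equal(count_category_in_top(rk, 2, function(ids) rep(TRUE, length(ids))), 2L)
  expect_equal(count_category_in_top(rk, 3, function(ids) rep(FALSE, length(ids))), 0L)
  expect_error(count_category_in_top(rk, 6, incat), "n_top")
  # p-ties broken by larger |z| first
  expect_equal(count_category_in_top(rk, 2, function(ids) ids == "s1"), 1L)
})

test_that("GEV enrichment p recovers a known tail quantile", {
  set.seed(40)
  null <- qgev(runif(1e4), loc = 5, scale = 1, shape = 0.1)
  obs <- qgev(0.99, loc = 5, scale = 1, shape = 0.1)
  res <- evd_enrichment_p(obs, null)
  expect_true(res$evd_ok)
  expect_gt(res$evd_p, 0.005)
  expect_lt(res$evd_p, 0.02)
  # empirical and fitted p agree within a factor of 3 inside the null range
  expect_lt(abs(log(res$evd_p / res$empirical_p)), log(3))
})

test_that("GEV enrichment handles left-tail, extrapolated and degenerate cases", {
  set.seed(41)
  null <- qgev(runif(100), loc = 5, scale = 1, shape = 0.05)
  below <- evd_enrichment_p(min(null) - 1, null)
  expect_gt(below$evd_p, 0.5)
  way_out <- evd_enrichment_p(max(null) * 10, null)
  expect_lt(way_out$evd_p, 1e-2)
  expect_gte(way_out$evd_p, 1e-16)            # finite, floored
  degen <- evd_enrichment_p(3, rep(1, 100))
  expect_false(degen$evd_ok)
  expect_true(is.na(degen$evd_p))
  expect_equal(degen$empirical_p, 1 / 101)
})

test_that("convergence summary reproduces the fold and false-positive arithmetic", {
  a <- convergence_summary(7, 0.15)
  expect_equal(a$fold_rounded, 47)
  expect_equal(round(a$false_positive_rate, 3), 0.021)
  b <- convergence_summary(18, 0.84)
  expect_equal(b$fold_rounded, 21)
  expect_equal(round(b$false_positive_rate, 3), 0.047)
})

test_that("convergent pairs require unlinked SNPs sharing a significant gene", {
  geno <- rbind(A = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1),
                B = c(2, 0, 1, 1, 2, 0, 1, 0, 2, 1),
                C = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1))  # C identical to A (r2=1)
  colnames(geno) <- paste0("s", 1:10)
  catalog <- data.frame(snp = c("A", "B", "A", "C", "A", "B"),
                        trait = c("t1", "t1", "t2", "t2", "t3", "t3"))
  recs <- data.frame(snp = c("A", "B", "C", "A", "B"),
                     gene = c("G", "G", "G", "H", "K"),
                     p = 1e-8, fdr_significant = TRUE)
  out <- find_converging_pairs(catalog, recs, geno, r2_max = 0.5)
  # t1: A-B share G and are unlinked at this ceiling; t2: A-C share G but r2=1
  expect_equal(out$trait, c("t1", "t3"))
  expect_true(all(out$ld_r2 < 0.5))
  expect_equal(out$genes[out$trait == "t1"], "G")
  # no intersection -> no pair even when unlinked
  recs2 <- data.frame(snp = c("A", "B"), gene = c("H", "K"),
                      p = 1e-8, fdr_significant = TRUE)
  expect_equal(nrow(find_converging_pairs(catalog, recs2, geno, r2_max = 0.5)), 0L)
})

test_that("pair discovery is invariant to catalog row order", {
  geno <- rbind(A = c(0, 1, 2, 0, 2, 1, 0, 2),
                B = c(2, 0, 0, 1, 1, 2, 0, 1))
  colnames(geno) <- paste0("s", 1:8)
  catalog <- data.frame(snp = c("A", "B"), trait = "t1")
  recs <- data.frame(snp = c("A", "B"), gene = "G", p = 1e-9,
                     fdr_significant = TRUE)
  a <- find_converging_pairs(catalog, recs, geno, r2_max = 0.9)
  b <- find_converging_pairs(catalog[2:1, ], recs[2:1, ], geno, r2_max = 0.9)
  expect_equal(a, b)
})

test_that("the convergence null replaces the trans set per permutation round", {
  geno <- rbind(A = c(0, 1, 2, 0, 2, 1, 0, 2),
                B = c(2, 0, 0, 1, 1, 2, 0, 1))
  colnames(geno) <- paste0("s", 1:8)
  catalog <- data.frame(snp = c("A", "B"), trait = "t1")
  cis <- data.frame(snp = "A", gene = "G", p = 1e-9, fdr_significant = TRUE)
  # round 1: B's best permuted trans hit is G -> converges; round 2: not
  rk1 <- data.frame(snp = c("B", "B"), gene = c("G", "X"), p = c(1e-6, 1e-2))
  rk2 <- data.frame(snp = c("B", "B"), gene = c("X", "G"), p = c(1e-6, 1e-2))
  res <- convergence_null(1, catalog, cis, list(rk1, rk2), n_real_trans = 1,
                          geno, r2_max = 0.9)
  expect_equal(res$null_samples, c(1, 0))
  expect_error(convergence_null(1, catalog, cis, list(rk1[1, ]), 2, geno),
               "fewer")
})
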