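#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for deviation from Hardy-Weinberg proportions, given
#' the three genotype counts of a biallelic SNP. The p-value is the sum of the
#' conditional probabilities (given the allele counts) of all heterozygote
#' counts that are no more likely than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (major homozygote,
#'   heterozygote, minor homozygote; the labelling is immaterial, the test
#'   folds to the minor allele).
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25)
#' hwe_exact_p(100, 0, 0)  # monomorphic: 1
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1L, length(n_Aa) == 1L, length(n_aa) == 1L)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  m <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # minor allele count
  probs <- hwe_het_distribution(n, m)
  k_obs <- n_Aa
  # valid heterozygote counts share the parity of m
  idx_obs <- (k_obs - (m %% 2L)) / 2L + 1L
  p_obs <- probs[idx_obs]
  # include classes whose probability does not exceed the observed one,
  # with a relative guard against floating-point ties
  p <- sum(probs[probs <= p_obs * (1 + 1e-10)])
  min(1, max(p, .Machine$double.xmin))
}

# Conditional distribution of the heterozygote count given n diploids and
# m copies of the minor allele. Returns probabilities for k = m%%2, m%%2+2, ...
# Computed by the standard ratio recurrence from the modal class.
hwe_het_distribution <- function(n, m) {
  ks <- seq.int(m %% 2L, m, by = 2L)
  ks <- ks[(m - ks) / 2 + ks <= n]   # minor homs + hets cannot exceed n
  lp <- vapply(ks, function(k) {
    a <- (m - k) / 2           # minor homozygotes
    b <- n - k - a             # major homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(k + 1) - lgamma(b + 1) +
      k * log(2) +
      lgamma(m + 1) + lgamma(2 * n - m + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Per-SNP allele statistics
#'
#' Minor allele frequency and call rate for one genotype column. Hard calls
#' are counted allele-wise; dosage columns use the mean dosage divided by two,
#' folded to the minor allele.
#'
#' @param g Numeric vector of genotypes: hard calls in \{0,1,2\} with `NA`
#'   missing, or dosages in \[0,2\].
#' @param dosage Logical; `NULL` (default) auto-detects from non-integer
#'   values.
#' @return List with `maf`, `call_rate` and `dosage` flag. An all-missing
#'   column yields `call_rate` 0 and `maf` `NA`.
#' @export
allele_stats <- function(g, dosage = NULL) {
  obs <- g[!is.na(g)]
  call_rate <- length(obs) / length(g)
  if (length(obs) == 0L) {
    return(list(maf = NA_real_, call_rate = 0, dosage = FALSE))
  }
  if (any(obs < 0 | obs > 2)) stop("genotype values must lie in [0, 2]")
  if (is.null(dosage)) dosage <- any(obs != round(obs))
  freq <- mean(obs) / 2
  maf <- min(freq, 1 - freq)
  list(maf = maf, call_rate = call_rate, dosage = dosage)
}

#' SNP quality-control filter
#'
#' Flags SNPs for removal when the minor allele frequency, call rate or exact
#' Hardy-Weinberg p-value falls strictly below its threshold (boundary values
#' are kept). Dosage columns skip the Hardy-Weinberg test.
#'
#' @param geno Genotype matrix, SNPs in rows, samples in columns (rownames =
#'   SNP ids).
#' @param maf_min,call_rate_min,hwe_p_min Removal thresholds (strict `<`).
#' @return List with `kept` (character vector of SNP ids) and `report`
#'   (data.frame: snp, maf, call_rate, hwe_p, pass).
#' @export
filter_snps <- function(geno, maf_min = 0.05, call_rate_min = 0.95,
                        hwe_p_min = 0.001) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  report <- do.call(rbind, lapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    st <- allele_stats(g)
    hwe_p <- NA_real_
    if (!st$dosage && st$call_rate > 0) {
      obs <- g[!is.na(g)]
      hwe_p <- hwe_exact_p(sum(obs == 0), sum(obs == 1), sum(obs == 2))
    }
    data.frame(snp = rownames(geno)[i], maf = st$maf,
               call_rate = st$call_rate, hwe_p = hwe_p)
  }))
  pass <- !is.na(report$maf) &
    report$maf >= maf_min &
    report$call_rate >= call_rate_min &
    (is.na(report$hwe_p) | report$hwe_p >= hwe_p_min)
  report$pass <- pass
  list(kept = report$snp[pass], report = report)
}

#' Composite linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype codes over pairwise-complete
#' samples (composite LD; no phasing).
#'
#' @param a,b Genotype vectors (hard calls or dosages, `NA` allowed).
#' @return r^2 in \[0, 1\]; 0 with a warning when undefined (fewer than two
#'   complete pairs, or zero variance).
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("LD r^2 undefined (too few complete pairs or zero variance); returning 0")
    return(0)
  }
  stats::cor(a[ok], b[ok])^2
}
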