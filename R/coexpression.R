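#' Number of unordered probe pairs
#'
#' `n * (n - 1) / 2`, exactly.
#'
#' @param n_probes Non-negative probe count.
#' @export
probe_pair_count <- function(n_probes) {
  if (n_probes < 0) stop("probe count must be non-negative")
  n_probes * (n_probes - 1) / 2
}

#' Bonferroni-corrected Pearson correlation threshold
#'
#' The smallest correlation coefficient whose two-sided p-value (t transform,
#' n-2 degrees of freedom) stays at or below `alpha` divided by the number of
#' probe pairs. The reported threshold is the exact value rounded up to two
#' decimals -- the smallest 2-dp coefficient that still guarantees
#' family-wise significance -- with the exact value retained.
#'
#' @param n_samples Sample count (>= 4).
#' @param n_pairs Number of pairwise tests corrected for.
#' @param alpha Family-wise error level (default 0.05).
#' @return List `r_exact`, `r_reported` (2 dp), `n_samples`, `n_pairs`,
#'   `alpha`.
#' @export
bonferroni_r_threshold <- function(n_samples, n_pairs, alpha = 0.05) {
  if (n_samples < 4) stop("need at least 4 samples")
  df <- n_samples - 2
  tcrit <- stats::qt(alpha / n_pairs / 2, df = df, lower.tail = FALSE)
  r <- tcrit / sqrt(df + tcrit^2)
  list(r_exact = r, r_reported = ceiling(round(r * 100, 6)) / 100,
       n_samples = n_samples, n_pairs = n_pairs, alpha = alpha)
}

#' Co-expression network above a correlation threshold
#'
#' Edges between probe pairs whose Pearson correlation (on the
#' confounder-corrected expression) reaches `r_threshold`.
#'
#' @param expr Probes x samples matrix.
#' @param probes Probe ids to consider (unknown ids are skipped with a
#'   message).
#' @param r_threshold Correlation threshold (`>=`).
#' @return Data frame `probeA`, `probeB`, `r`.
#' @export
coexpression_network <- function(expr, probes, r_threshold) {
  known <- probes %in% rownames(expr)
  if (any(!known)) {
    message("coexpression_network: skipping unknown probes: ",
            paste(probes[!known], collapse = ", "))
  }
  probes <- unique(probes[known])
  if (length(probes) < 2L) {
    return(data.frame(probeA = character(0), probeB = character(0),
                      r = numeric(0)))
  }
  cc <- stats::cor(t(expr[probes, , drop = FALSE]))
  idx <- which(upper.tri(cc) & cc >= r_threshold, arr.ind = TRUE)
  out <- data.frame(probeA = probes[idx[, 1L]], probeB = probes[idx[, 2L]],
                    r = cc[idx])
  out[order(out$probeA, out$probeB), , drop = FALSE]
}

#' One-sided co-expression shift test
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction) of
#' whether the correlations within an eQTL gene set exceed the background
#' pairwise correlations.
#'
#' @param set_correlations Pairwise correlations within the tested gene set.
#' @param background_correlations Background pairwise correlations.
#' @return One-sided (greater) p-value.
#' @export
coexpression_shift_test <- function(set_correlations,
                                    background_correlations) {
  if (length(set_correlations) == 0L || length(background_correlations) == 0L) {
    stop("both correlation sets must be non-empty")
  }
  stats::wilcox.test(set_correlations, background_correlations,
                     alternative = "greater", exact = FALSE)$p.value
}

#' Regress all significant eQTL effects out of the expression matrix
#'
#' Per probe, the least-squares residual on the genotype vectors of all its
#' significant eQTL SNPs (cis and trans); probes without eQTLs are untouched.
#' Used to ask whether observed co-expression survives removal of the shared
#' genetic signal.
#'
#' @param expr Probes x samples matrix.
#' @param eqtl_records Record data frame (rows with `fdr_significant` are
#'   used; needs `snp`, `probe`, `p`).
#' @param geno SNPs x samples genotype matrix.
#' @return Residual expression matrix.
#' @export
regress_out_eqtls <- function(expr, eqtl_records, geno) {
  regress_out_cis(expr, eqtl_records, geno)
}

#' Phenotypic-buffering comparison table
#'
#' Joins the explained expression variance of each eQTL (100 * rho^2) with
#' externally reported explained trait variance and flags rows where the
#' molecular effect exceeds the phenotypic one.
#'
#' @param eqtl_records Record data frame (`snp`, `probe`,
#'   `explained_variance_pct`, optionally `gene`).
#' @param trait_variance Data frame `trait`, `snp`, `trait_r2_pct` (reported
#'   explained trait variance, percent; may omit SNPs).
#' @return List: `rows` (one per record-trait join: trait, snp, probe, gene,
#'   expression_r2_pct, reported_trait_r2_pct, buffered flag) and `summary`
#'   (`n_rows`, `n_buffered` where expression r^2 strictly exceeds trait
#'   r^2).
#' @export
buffering_table <- function(eqtl_records, trait_variance) {
  m <- match(eqtl_records$snp, trait_variance$snp)
  rows <- data.frame(
    trait = trait_variance$trait[m],
    snp = eqtl_records$snp,
    probe = eqtl_records$probe,
    gene = if (!is.null(eqtl_records$gene)) eqtl_records$gene else NA_character_,
    expression_r2_pct = eqtl_records$explained_variance_pct,
    reported_trait_r2_pct = trait_variance$trait_r2_pct[m])
  rows$buffered <- !is.na(rows$reported_trait_r2_pct) &
    rows$expression_r2_pct > rows$reported_trait_r2_pct
  list(rows = rows,
       summary = list(n_rows = nrow(rows), n_buffered = sum(rows$buffered)))
}
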