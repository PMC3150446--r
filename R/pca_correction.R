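#' Principal components of the sample correlation matrix
#'
#' Eigen-decomposition of the sample-by-sample Pearson correlation matrix
#' (samples correlated over probes). Scores are eigenvectors scaled by the
#' corresponding singular values, so dominant batch and physiology structure
#' appears as per-sample score vectors.
#'
#' @param expr Standardized expression matrix, probes in rows, samples in
#'   columns.
#' @param k_max Number of components to retain (truncated with a warning when
#'   it exceeds the number of informative dimensions).
#' @return Object of class `pc_decomposition`: `scores` (samples x k),
#'   `var_fraction`, `genetically_controlled` (all `FALSE` until screened),
#'   `sample_ids`.
#' @export
compute_sample_pcs <- function(expr, k_max = 50L) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L, k_max >= 1L)
  n <- ncol(expr)
  if (k_max > n - 1L) {
    warning(sprintf("k_max truncated from %d to %d", k_max, n - 1L))
    k_max <- n - 1L
  }
  cmat <- stats::cor(expr)
  eig <- eigen(cmat, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- min(k_max, sum(vals > 0))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(vals[seq_len(k)]), each = n)
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 var_fraction = vals[seq_len(k)] / sum(vals),
                 genetically_controlled = rep(FALSE, k),
                 sample_ids = colnames(expr)),
            class = "pc_decomposition")
}

#' Remove expression principal components, protecting genetic ones
#'
#' Each probe is replaced by its least-squares residual after projection on
#' the first `k` component score vectors, skipping components flagged as
#' genetically controlled. Residuals are re-standardized (rank-based
#' association downstream is unaffected by the rescaling).
#'
#' @param expr Standardized expression, probes x samples.
#' @param pcs A `pc_decomposition`.
#' @param k Number of leading components considered for removal (`0` is the
#'   identity).
#' @param protect Logical vector of components to skip; defaults to the
#'   screened `genetically_controlled` flags.
#' @return Residual expression matrix, per-probe mean 0 / SD 1.
#' @export
regress_out_pcs <- function(expr, pcs, k, protect = NULL) {
  stopifnot(inherits(pcs, "pc_decomposition"))
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(expr)
  k <- min(k, ncol(pcs$scores))
  if (is.null(protect)) protect <- pcs$genetically_controlled
  use <- seq_len(k)[!protect[seq_len(k)]]
  if (length(use) == 0L) return(expr)
  P <- cbind(1, pcs$scores[, use, drop = FALSE])  # intercept keeps residuals
  stopifnot(nrow(P) == ncol(expr))                # orthogonal after rescaling
  # residual = E (I - P (P'P)^-1 P')
  coef <- solve(crossprod(P), crossprod(P, t(expr)))
  res <- expr - t(P %*% coef)
  standardize_rows(res)
}

standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  sds <- matrixStats::rowSds(x)
  sds[sds == 0] <- 1
  x / sds
}

#' Screen principal components for genetic control
#'
#' Every component score vector is tested against every SNP by Spearman rank
#' correlation; the permutation-FDR machinery of the association engine
#' provides the significance call. A component is flagged iff some SNP is
#' significant at the target FDR *and* its squared correlation exceeds
#' `r2_threshold` (strict inequality).
#'
#' @param pcs A `pc_decomposition`.
#' @param geno Genotype matrix, SNPs x samples (same samples as the scores).
#' @param r2_threshold Squared-correlation floor for flagging (default 0.05).
#' @param n_perm Permutation rounds for the FDR null (default 100).
#' @param fdr Target FDR (default 0.05).
#' @param seed Seed for the permutation scheme.
#' @return The `pc_decomposition` with `genetically_controlled` updated; the
#'   per-component best r^2 is attached as `screen_r2`.
#' @export
screen_genetic_pcs <- function(pcs, geno, r2_threshold = 0.05, n_perm = 100L,
                               fdr = 0.05, seed = 1L) {
  stopifnot(inherits(pcs, "pc_decomposition"), is.matrix(geno))
  if (ncol(geno) != nrow(pcs$scores)) {
    stop("genotype samples do not match PC score rows")
  }
  scores_t <- t(pcs$scores)                      # components x samples
  obs <- spearman_matrix(geno, scores_t)         # snps x components
  perm <- permuted_pvalue_rounds(geno, scores_t, n_perm = n_perm, seed = seed)
  fd <- permutation_fdr(as.vector(obs$p), perm, target_fdr = fdr)
  sig <- matrix(as.vector(obs$p) <= fd$p_threshold & fd$n_significant > 0,
                nrow = nrow(geno))
  r2 <- obs$rho^2
  flag <- vapply(seq_len(ncol(r2)), function(j) {
    any(sig[, j] & r2[, j] > r2_threshold)
  }, logical(1))
  pcs$genetically_controlled <- flag
  pcs$screen_r2 <- matrixStats::colMaxs(r2)
  pcs
}
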