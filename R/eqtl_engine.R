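#' Spearman rank association between one genotype and one expression vector
#'
#' Rank correlation over pairwise-complete observations; the two-sided
#' p-value uses the t approximation with n-2 degrees of freedom, and `z` is
#' the signed standard-normal deviate matching that p-value.
#'
#' @param g Genotype vector (hard calls or dosages, `NA` allowed).
#' @param e Expression vector.
#' @return List `rho`, `p`, `z`, `n`; `NULL` (with a message) when undefined
#'   (fewer than 3 complete pairs or zero variance).
#' @export
spearman_assoc <- function(g, e) {
  stopifnot(length(g) == length(e))
  ok <- !is.na(g) & !is.na(e)
  n <- sum(ok)
  if (n < 3L || stats::sd(g[ok]) == 0 || stats::sd(e[ok]) == 0) {
    message("spearman_assoc: undefined test skipped (n<3 or zero variance)")
    return(NULL)
  }
  rho <- stats::cor(rank(g[ok]), rank(e[ok]))
  st <- rho_to_stats(rho, n)
  list(rho = rho, p = st$p, z = st$z, n = n)
}

# Vectorized rho -> (p, z) via the t approximation; log-space so that z stays
# finite for |rho| near 1.
rho_to_stats <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  lp_half <- stats::pt(-abs(tt), df = n - 2, log.p = TRUE)  # log(p/2)
  p <- 2 * exp(lp_half)
  z <- -sign(rho) * stats::qnorm(lp_half, log.p = TRUE)
  list(p = p, z = z)
}

#' Spearman correlation of every SNP against every feature
#'
#' Workhorse for the association scans: ranks rows of both matrices and
#' computes all pairwise correlations by matrix multiplication. SNPs with
#' missing entries take a per-SNP pairwise-complete path.
#'
#' @param G SNPs x samples genotype matrix.
#' @param E Features x samples matrix (no missing values).
#' @return List with matrices `rho`, `p` (SNPs x features) and per-SNP `n`.
#' @export
spearman_matrix <- function(G, E) {
  stopifnot(is.matrix(G), is.matrix(E), ncol(G) == ncol(E))
  nf <- nrow(E)
  rho <- matrix(NA_real_, nrow(G), nf, dimnames = list(rownames(G), rownames(E)))
  nvec <- integer(nrow(G))
  has_na <- rowSums(is.na(G)) > 0L
  if (any(!has_na)) {
    RG <- matrixStats::rowRanks(G[!has_na, , drop = FALSE], ties.method = "average")
    RE <- matrixStats::rowRanks(E, ties.method = "average")
    rho[!has_na, ] <- stats::cor(t(RG), t(RE))
    nvec[!has_na] <- ncol(G)
  }
  for (i in which(has_na)) {
    ok <- !is.na(G[i, ])
    nvec[i] <- sum(ok)
    if (nvec[i] < 3L) next
    rg <- rank(G[i, ok])
    REs <- matrixStats::rowRanks(E[, ok, drop = FALSE], ties.method = "average")
    rho[i, ] <- stats::cor(rg, t(REs))
  }
  # zero-variance rows yield NA from cor(); propagate as NA (skipped tests)
  p <- matrix(NA_real_, nrow(G), nf, dimnames = dimnames(rho))
  fin <- is.finite(rho)
  nmat <- matrix(nvec, nrow(G), nf)
  st <- rho_to_stats(rho[fin], nmat[fin])
  p[fin] <- st$p
  list(rho = rho, p = p, n = nvec)
}

#' Enumerate cis SNP-probe pairs
#'
#' A pair is cis-testable iff SNP and probe are on the same chromosome and
#' the distance from SNP position to the probe transcript midpoint is at
#' most `window` (boundary inclusive).
#'
#' @param snp_annot Data frame: `snp`, `chr`, `pos`.
#' @param probe_annot Data frame: `probe_id`, `chr`, `midpoint`.
#' @param window Window in bp (default 250 kb).
#' @return Data frame `snp`, `probe` of testable pairs.
#' @export
cis_pairs <- function(snp_annot, probe_annot, window = 250000) {
  same_chr <- outer(snp_annot$chr, probe_annot$chr, "==")
  dist <- abs(outer(snp_annot$pos, probe_annot$midpoint, "-"))
  idx <- which(same_chr & dist <= window, arr.ind = TRUE)
  data.frame(snp = snp_annot$snp[idx[, 1L]],
             probe = probe_annot$probe_id[idx[, 2L]])
}

#' Enumerate trans SNP-probe pairs
#'
#' A pair is trans-testable iff SNP and probe midpoint are at least
#' `min_dist` apart (boundary inclusive) or lie on different chromosomes.
#'
#' @inheritParams cis_pairs
#' @param min_dist Minimum distance in bp (default 5 Mb).
#' @export
trans_pairs <- function(snp_annot, probe_annot, min_dist = 5e6) {
  same_chr <- outer(snp_annot$chr, probe_annot$chr, "==")
  dist <- abs(outer(snp_annot$pos, probe_annot$midpoint, "-"))
  idx <- which(!same_chr | dist >= min_dist, arr.ind = TRUE)
  data.frame(snp = snp_annot$snp[idx[, 1L]],
             probe = probe_annot$probe_id[idx[, 2L]])
}

#' Association scan with cross-dataset meta-analysis and permutation FDR
#'
#' Tests the given SNP-probe pairs in each dataset, combines statistics for
#' pairs present in several datasets by the square-root-sample-size weighted
#' Z-method, and controls the FDR by comparing the observed p-value
#' distribution with `n_perm` sample-relabelling rounds.
#'
#' @param datasets Named list; each element a list with `geno` (SNPs x
#'   samples) and `expr` (probes x samples). Sample sets may differ across
#'   datasets; SNP/probe ids must be consistent where shared.
#' @param pairs Data frame `snp`, `probe` of testable pairs (from
#'   [cis_pairs()] / [trans_pairs()]).
#' @param class `"cis"` or `"trans"`, recorded on the output.
#' @param n_perm Permutation rounds (default 100).
#' @param target_fdr Target FDR (default 0.05).
#' @param seed Seed driving the permutation scheme.
#' @param synchronized When `TRUE`, the same sample relabelling is applied in
#'   every dataset per round (datasets must then share the sample count);
#'   used for multi-tissue designs on the same individuals.
#' @return List: `records` (one row per pair: per-dataset rho and n, combined
#'   z and p, direction, `fdr_significant`, `explained_variance_pct`), `fdr`
#'   (the [permutation_fdr()] result), `permuted_p` (list of per-round
#'   combined p vectors).
#' @export
eqtl_scan <- function(datasets, pairs, class = "trans", n_perm = 100L,
                      target_fdr = 0.05, seed = 1L, synchronized = FALSE) {
  stopifnot(is.list(datasets), length(datasets) >= 1L, nrow(pairs) >= 1L)
  if (is.null(names(datasets))) names(datasets) <- paste0("d", seq_along(datasets))
  if (synchronized) {
    ns <- vapply(datasets, function(d) ncol(d$expr), integer(1))
    if (length(unique(ns)) != 1L) stop("synchronized permutations require matching sample sets")
  }
  per <- lapply(datasets, dataset_pair_stats, pairs = pairs)
  comb <- combine_dataset_stats(per)
  rs <- withr_seed(seed, {
    lapply(seq_len(n_perm), function(r) {
      shared_perm <- if (synchronized) sample.int(ncol(datasets[[1L]]$expr)) else NULL
      pp <- lapply(datasets, function(d) {
        perm <- if (synchronized) shared_perm else sample.int(ncol(d$expr))
        dataset_pair_stats(
          list(geno = d$geno, expr = d$expr[, perm, drop = FALSE]),
          pairs = pairs)
      })
      combine_dataset_stats(pp)$p
    })
  })
  fd <- permutation_fdr(comb$p, rs, target_fdr = target_fdr)
  records <- data.frame(snp = pairs$snp, probe = pairs$probe, class = class,
                        stringsAsFactors = FALSE)
  for (nm in names(per)) {
    records[[paste0("rho_", nm)]] <- per[[nm]]$rho
    records[[paste0("n_", nm)]] <- per[[nm]]$n
  }
  records$z <- comb$z
  records$p <- comb$p
  records$direction <- sign(comb$z)
  records$fdr_significant <- !is.na(comb$p) & comb$p <= fd$p_threshold
  records$explained_variance_pct <- 100 * comb$rho_main^2
  list(records = records, fdr = fd, permuted_p = rs)
}

# Per-dataset statistics for a fixed pair list: rho, z, n per pair (NA when a
# SNP/probe is absent from the dataset or the test is undefined).
dataset_pair_stats <- function(d, pairs) {
  gi <- match(pairs$snp, rownames(d$geno))
  pi <- match(pairs$probe, rownames(d$expr))
  keep <- !is.na(gi) & !is.na(pi)
  rho <- z <- rep(NA_real_, nrow(pairs))
  n <- rep(NA_integer_, nrow(pairs))
  if (any(keep)) {
    usnp <- sort(unique(gi[keep]))
    uprb <- sort(unique(pi[keep]))
    sm <- spearman_matrix(d$geno[usnp, , drop = FALSE], d$expr[uprb, , drop = FALSE])
    ii <- cbind(match(gi[keep], usnp), match(pi[keep], uprb))
    rho[keep] <- sm$rho[ii]
    n[keep] <- sm$n[ii[, 1L]]
    fin <- keep & is.finite(rho)
    st <- rho_to_stats(rho[fin], n[fin])
    z[fin] <- st$z
  }
  list(rho = rho, z = z, n = n)
}

# Weighted-Z combination across datasets; rho_main is the rho of the
# largest-n dataset contributing to each pair (used for explained variance).
combine_dataset_stats <- function(per) {
  zs <- vapply(per, `[[`, numeric(length(per[[1L]]$z)), "z")
  ns <- vapply(per, `[[`, numeric(length(per[[1L]]$n)), "n")
  rhos <- vapply(per, `[[`, numeric(length(per[[1L]]$rho)), "rho")
  if (is.null(dim(zs))) {                  # single pair edge case
    zs <- matrix(zs, nrow = 1); ns <- matrix(ns, nrow = 1); rhos <- matrix(rhos, nrow = 1)
  }
  w <- sqrt(ns)
  w[is.na(zs)] <- NA
  num <- rowSums(w * zs, na.rm = TRUE)
  den <- sqrt(rowSums(w^2, na.rm = TRUE))
  none <- rowSums(!is.na(zs)) == 0L
  zc <- ifelse(none, NA_real_, num / den)
  p <- 2 * stats::pnorm(-abs(zc))
  ns0 <- ns; ns0[is.na(zs)] <- -1
  main <- max.col(ns0, ties.method = "first")
  rho_main <- rhos[cbind(seq_len(nrow(rhos)), main)]
  list(z = zc, p = p, rho_main = rho_main)
}

# All permuted p-value rounds for a full matrix scan (used by the PC screen).
permuted_pvalue_rounds <- function(G, E, n_perm, seed) {
  withr_seed(seed, {
    lapply(seq_len(n_perm), function(r) {
      perm <- sample.int(ncol(E))
      as.vector(spearman_matrix(G, E[, perm, drop = FALSE])$p)
    })
  })
}

# Evaluate under a temporary RNG state so callers' streams are unaffected.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Combine per-dataset statistics by the weighted Z-method
#'
#' `z_comb = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i = sqrt(n_i)`; the
#' per-dataset z is the signed normal deviate of the two-sided p.
#'
#' @param p Vector of per-dataset two-sided p-values.
#' @param sign_rho Vector of allelic direction signs (+1/-1).
#' @param n Vector of per-dataset sample sizes.
#' @return List `z` and `p` (two-sided) of the combination.
#' @export
combine_weighted_z <- function(p, sign_rho, n) {
  if (length(p) == 0L) stop("empty dataset list")
  stopifnot(length(p) == length(sign_rho), length(p) == length(n))
  z <- -sign_rho * stats::qnorm(log(p) - log(2), log.p = TRUE)
  w <- sqrt(n)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z = zc, p = 2 * stats::pnorm(-abs(zc)))
}

#' Permutation-based FDR control
#'
#' `FDR(t)` is the average number of permuted p-values at or below `t` per
#' round, divided by the number of observed p-values at or below `t`; the
#' significance threshold is the largest observed p with `FDR(t)` at or below
#' the target.
#'
#' @param observed_p Vector of observed p-values (`NA` = skipped test).
#' @param permuted_p List with one vector of permuted p-values per round.
#' @param target_fdr Target FDR level.
#' @return List: `p_threshold` (`-Inf` when nothing passes), `significant`
#'   (logical over `observed_p`), `n_significant`, `fdr_curve`
#'   (data.frame `t`, `fdr`).
#' @export
permutation_fdr <- function(observed_p, permuted_p, target_fdr = 0.05) {
  if (length(permuted_p) == 0L) stop("at least one permutation round required")
  n_rounds <- length(permuted_p)
  obs <- observed_p[!is.na(observed_p)]
  pool <- sort(unlist(permuted_p, use.names = FALSE))
  ts <- sort(unique(obs))
  n_obs_le <- findInterval(ts, sort(obs))
  n_perm_le <- findInterval(ts, pool) / n_rounds
  fdr <- pmin(1, pmax(0, n_perm_le / n_obs_le))
  ok <- fdr <= target_fdr
  p_threshold <- if (any(ok)) max(ts[ok]) else -Inf
  significant <- !is.na(observed_p) & observed_p <= p_threshold
  list(p_threshold = p_threshold,
       significant = significant,
       n_significant = sum(significant),
       fdr_curve = data.frame(t = ts, fdr = fdr))
}

#' Regress significant cis effects out of the expression matrix
#'
#' For every probe with significant cis records, expression is replaced by
#' the least-squares residual on the corresponding genotype vectors (jointly,
#' ordered by significance; collinear later regressors are dropped). Probes
#' without significant cis records are untouched.
#'
#' @param expr Probes x samples matrix.
#' @param cis_records Record data frame from [eqtl_scan()]; only rows with
#'   `fdr_significant` are used.
#' @param geno SNPs x samples genotype matrix (same samples as `expr`;
#'   missing genotypes are mean-imputed for the regression design).
#' @return Residual expression matrix.
#' @export
regress_out_cis <- function(expr, cis_records, geno) {
  sig <- cis_records[cis_records$fdr_significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(expr)
  stopifnot(ncol(expr) == ncol(geno))
  out <- expr
  for (pr in unique(sig$probe)) {
    if (!pr %in% rownames(expr)) next
    rows <- sig[sig$probe == pr, , drop = FALSE]
    rows <- rows[order(rows$p), , drop = FALSE]
    X <- t(geno[rows$snp, , drop = FALSE])
    X <- apply(X, 2L, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      col
    })
    X <- cbind(1, X)
    fit <- stats::lm.fit(X, out[pr, ])        # rank-deficient X handled by QR
    out[pr, ] <- fit$residuals
  }
  out
}

#' Replication filter against an external summary-statistics table
#'
#' Keeps discovery records whose SNP-probe pair reaches the nominal
#' replication threshold with matching allelic direction.
#'
#' @param discovery_records Record data frame (needs `snp`, `probe`,
#'   `direction`).
#' @param replication_stats Data frame `snp`, `probe`, `p`, `direction`.
#' @param p_threshold Nominal replication p (default 1e-5, strict `<`).
#' @return List `replicated` and `dropped` (with a `drop_reason` column).
#' @export
replicate_eqtls <- function(discovery_records, replication_stats,
                            p_threshold = 1e-5) {
  key <- paste(discovery_records$snp, discovery_records$probe)
  rkey <- paste(replication_stats$snp, replication_stats$probe)
  m <- match(key, rkey)
  rep_p <- replication_stats$p[m]
  rep_dir <- replication_stats$direction[m]
  ok <- !is.na(rep_p) & rep_p < p_threshold &
    rep_dir == discovery_records$direction
  reason <- rep("absent", length(key))
  reason[!is.na(rep_p) & rep_p >= p_threshold] <- "p_above_threshold"
  reason[!is.na(rep_p) & rep_p < p_threshold &
           rep_dir != discovery_records$direction] <- "direction_mismatch"
  dropped <- discovery_records[!ok, , drop = FALSE]
  if (nrow(dropped)) dropped$drop_reason <- reason[!ok]
  list(replicated = discovery_records[ok, , drop = FALSE], dropped = dropped)
}

#' Multi-tissue meta-analysis with synchronized permutations
#'
#' Weighted-Z combination across tissues measured on the same individuals;
#' the permutation null applies the identical sample relabelling to every
#' tissue per round, preserving between-tissue correlation.
#'
#' @param tissues Named list of lists with `geno` and `expr`, all sharing the
#'   same sample set.
#' @param pairs Data frame `snp`, `probe`.
#' @param n_perm,target_fdr,seed As in [eqtl_scan()].
#' @return As [eqtl_scan()].
#' @export
meta_multi_tissue <- function(tissues, pairs, n_perm = 100L,
                              target_fdr = 0.05, seed = 1L) {
  samp <- lapply(tissues, function(d) colnames(d$expr))
  if (length(unique(vapply(samp, paste, character(1), collapse = "\r"))) != 1L) {
    stop("tissues have mismatched sample sets")
  }
  eqtl_scan(tissues, pairs, class = "trans", n_perm = n_perm,
            target_fdr = target_fdr, seed = seed, synchronized = TRUE)
}
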