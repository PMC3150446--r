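#' MHC membership of a SNP
#'
#' The major histocompatibility complex is taken as chromosome 6, positions
#' 20-40 Mb, end points inclusive.
#'
#' @param chr Chromosome (numeric or character).
#' @param pos 1-based position (vectors allowed).
#' @export
mhc_membership <- function(chr, pos) {
  as.character(chr) == "6" & pos >= 20e6 & pos <= 40e6
}

#' Count category members among the top-ranked eQTL SNPs
#'
#' Ranks unique SNPs by significance (p ascending, ties broken by |z|
#' descending, then lexicographic SNP id) and counts how many of the `n_top`
#' most significant satisfy the category predicate.
#'
#' @param ranking Data frame with `snp`, `p` and optionally `z`; one row per
#'   unique SNP (the best row per SNP is used otherwise).
#' @param n_top Number of top SNPs to inspect.
#' @param category_fn Predicate taking a vector of SNP ids and returning a
#'   logical vector.
#' @return Integer count.
#' @export
count_category_in_top <- function(ranking, n_top, category_fn) {
  if (is.null(ranking$z)) ranking$z <- 0
  o <- order(ranking$p, -abs(ranking$z), ranking$snp)
  ranking <- ranking[o, , drop = FALSE]
  ranking <- ranking[!duplicated(ranking$snp), , drop = FALSE]
  if (n_top > nrow(ranking)) stop("n_top exceeds the number of ranked SNPs")
  top <- ranking$snp[seq_len(n_top)]
  sum(category_fn(top))
}

#' Enrichment p-value from a permutation null via a GEV fit
#'
#' Fits a generalized extreme value distribution to the permutation null
#' counts by maximum likelihood; `evd_p` is the fitted upper-tail probability
#' of the observed count (floored at 1e-16), reported alongside the
#' empirical permutation p and the fold enrichment over the null mean.
#'
#' @param observed Observed statistic (a count).
#' @param null_samples One null statistic per permutation round.
#' @return Object of class `enrichment_result`: `observed`, `null_samples`,
#'   `evd_params` (or `NULL` on a degenerate null/fit failure, with
#'   `evd_ok = FALSE`), `evd_p`, `empirical_p`, `fold`, `fold_rounded`,
#'   `false_positive_rate`.
#' @export
evd_enrichment_p <- function(observed, null_samples) {
  stopifnot(length(observed) == 1L, length(null_samples) >= 1L)
  n <- length(null_samples)
  empirical_p <- (1 + sum(null_samples >= observed)) / (1 + n)
  fit <- fit_gev(null_samples)
  if (is.null(fit)) {
    evd_p <- NA_real_
    evd_ok <- FALSE
  } else {
    evd_p <- max(pgev(observed, fit$loc, fit$scale, fit$shape,
                      lower.tail = FALSE), 1e-16)
    evd_ok <- TRUE
  }
  structure(list(observed = observed, null_samples = null_samples,
                 evd_params = fit, evd_ok = evd_ok, evd_p = evd_p,
                 empirical_p = empirical_p,
                 fold = convergence_summary(observed, mean(null_samples))$fold,
                 fold_rounded = convergence_summary(observed,
                                                    mean(null_samples))$fold_rounded,
                 false_positive_rate = convergence_summary(
                   observed, mean(null_samples))$false_positive_rate),
            class = "enrichment_result")
}

#' Fold enrichment and implied false-positive rate
#'
#' `fold = observed / mean(null)` (reported rounded to the nearest integer);
#' the implied false-positive rate is `mean(null) / observed`.
#'
#' @param observed Observed count.
#' @param null_mean Mean of the permutation null counts.
#' @export
convergence_summary <- function(observed, null_mean) {
  fold <- if (null_mean > 0) observed / null_mean else Inf
  list(fold = fold,
       fold_rounded = round(fold),
       false_positive_rate = if (observed > 0) null_mean / observed else NA_real_)
}

#' Unlinked SNP pairs converging on shared eQTL genes
#'
#' Within each trait, every SNP pair is examined; a pair is reported when the
#' two SNPs are unlinked (LD r^2 below `r2_max`) and their significant eQTL
#' gene sets intersect.
#'
#' @param trait_catalog Data frame `snp`, `trait`.
#' @param eqtl_records Record data frame with `snp`, `gene`, `class`, `p`,
#'   `explained_variance_pct`, `fdr_significant` (only significant rows are
#'   used).
#' @param geno SNPs x samples genotype matrix for the LD computation (pairs
#'   with a SNP absent from it are skipped with a message).
#' @param r2_max LD ceiling (strict `<`) for calling a pair unlinked.
#' @return Data frame of convergent pairs: `trait`, `snpA`, `snpB`, `ld_r2`,
#'   `genes` (comma-collapsed), sorted and unique per (trait, snpA, snpB).
#' @export
find_converging_pairs <- function(trait_catalog, eqtl_records, geno,
                                  r2_max = 0.001) {
  sig <- eqtl_records[eqtl_records$fdr_significant, , drop = FALSE]
  gene_sets <- split(sig$gene, sig$snp)
  rows <- list()
  for (trait in unique(trait_catalog$trait)) {
    snps <- sort(unique(trait_catalog$snp[trait_catalog$trait == trait]))
    if (length(snps) < 2L) next
    cmb <- utils::combn(snps, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      ga <- unique(gene_sets[[a]]); gb <- unique(gene_sets[[b]])
      shared <- intersect(ga, gb)
      if (length(shared) == 0L) next
      if (!a %in% rownames(geno) || !b %in% rownames(geno)) {
        message("convergence: SNP missing from genotypes, pair skipped: ",
                a, " / ", b)
        next
      }
      r2 <- suppressWarnings(ld_r2(geno[a, ], geno[b, ]))
      if (r2 >= r2_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, snpA = a, snpB = b, ld_r2 = r2,
        genes = paste(sort(shared), collapse = ","))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(trait = character(0), snpA = character(0),
                      snpB = character(0), ld_r2 = numeric(0),
                      genes = character(0)))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$trait, out$snpA, out$snpB)), , drop = FALSE]
}

#' Permutation null for the convergence count
#'
#' Per permutation round the real cis-eQTL list is kept while the trans set
#' is replaced by the top `n_real_trans` associations of that round's
#' permuted trans ranking; the convergent-pair count is then recomputed. The
#' observed count is compared with the null by [evd_enrichment_p()].
#'
#' @param observed_count Real convergent-pair count.
#' @param trait_catalog,geno,r2_max As in [find_converging_pairs()].
#' @param cis_records Significant cis records (kept fixed).
#' @param permuted_trans_rankings List (one per round) of trans record data
#'   frames ranked or rankable by `p` (need `snp`, `gene`, `p`).
#' @param n_real_trans Size of the real trans set.
#' @return An `enrichment_result` with the per-round null counts in
#'   `null_samples`.
#' @export
convergence_null <- function(observed_count, trait_catalog, cis_records,
                             permuted_trans_rankings, n_real_trans, geno,
                             r2_max = 0.001) {
  counts <- vapply(permuted_trans_rankings, function(rk) {
    if (nrow(rk) < n_real_trans) {
      stop("permutation round has fewer tests than the real trans set")
    }
    rk <- rk[order(rk$p), , drop = FALSE][seq_len(n_real_trans), , drop = FALSE]
    rk$fdr_significant <- TRUE
    cis <- cis_records
    if (nrow(cis)) cis$fdr_significant <- TRUE
    recs <- rbind(cis[, c("snp", "gene", "p", "fdr_significant")],
                  rk[, c("snp", "gene", "p", "fdr_significant")])
    nrow(find_converging_pairs(trait_catalog, recs, geno, r2_max = r2_max))
  }, numeric(1))
  evd_enrichment_p(observed_count, counts)
}
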