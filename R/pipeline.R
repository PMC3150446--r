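#' Default pipeline parameters
#'
#' Thresholds of the discovery pipeline: cis window 250 kb, trans minimum
#' distance 5 Mb, 100 permutations, FDR 0.05 for cis and trans (0.50
#' optionally for hypothesis generation), 50 expression PCs removed on the
#' cis pathway and 25 on the trans pathway (with genetically controlled PCs
#' protected), LD thresholds r^2 > 0.1 for the primer-polymorphism filter and
#' r^2 < 0.001 for unlinked pairs, 2 Mb cross-hybridization window.
#'
#' @param ... Overrides for individual parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(cis_window = 250000, trans_min_dist = 5e6,
            n_perm = 100L, cis_fdr = 0.05, trans_fdr = 0.05,
            k_cis = 50L, k_trans = 25L, screen_pcs = TRUE,
            screen_r2 = 0.05, primer_ld_r2 = 0.1, crosshyb_window = 2e6,
            convergence_r2_max = 0.001, convergence_rounds = 100L,
            maf_min = 0.05, call_rate_min = 0.95, hwe_p_min = 0.001,
            seed = 1L)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

#' Run the full cis/trans-eQTL discovery pipeline
#'
#' Stage order: genotype QC, per-platform quantile normalization to the
#' median distribution plus log2/standardization, principal-component
#' removal (genetically controlled components protected), cis association
#' scan with cross-platform weighted-Z meta-analysis and permutation FDR,
#' regression of significant cis effects out of the expression, trans scan,
#' primer-polymorphism and cross-hybridization artifact filters, FDR
#' recomputation on the surviving trans tests, and (when a trait catalog is
#' present) the unlinked-SNP-pair convergence analysis.
#'
#' @param study Study bundle from [simulate_study()] or [load_study()].
#' @param params List from [pipeline_params()].
#' @return List: `cis` / `trans` scan results (records + FDR), `qc` report,
#'   `pcs` per platform, filter removals, `trans_records_final`,
#'   `convergence` (or `NULL`), and a `manifest` with per-stage row counts.
#' @export
run_pipeline <- function(study, params = pipeline_params()) {
  manifest <- list(config = params, stages = list())
  note <- function(stage, n_in, n_out, n_removed = n_in - n_out,
                   n_significant = NULL) {
    entry <- list(records_in = n_in, records_out = n_out,
                  records_removed = n_removed)
    if (!is.null(n_significant)) entry$n_significant <- n_significant
    manifest$stages[[stage]] <<- entry
  }

  # --- genotype QC ------------------------------------------------------
  qc <- filter_snps(study$geno, maf_min = params$maf_min,
                    call_rate_min = params$call_rate_min,
                    hwe_p_min = params$hwe_p_min)
  geno <- study$geno[qc$kept, , drop = FALSE]
  snp_annot <- study$snp_annot[study$snp_annot$snp %in% qc$kept, , drop = FALSE]
  note("genotype_qc", nrow(study$geno), nrow(geno))

  # --- normalization and PC removal per platform ------------------------
  platforms <- names(study$expr_raw)
  norm <- list(); pcs <- list(); cis_expr <- list(); trans_base <- list()
  zero_var <- character(0)
  for (plat in platforms) {
    qn <- quantile_normalize_to_median(study$expr_raw[[plat]])
    st <- log2_center_scale(qn)
    zero_var <- union(zero_var, st$zero_variance)
    e <- st$expr[!rownames(st$expr) %in% st$zero_variance, , drop = FALSE]
    norm[[plat]] <- e
    k_need <- max(1L, params$k_cis, params$k_trans)
    pc <- suppressWarnings(compute_sample_pcs(e, k_max = k_need))
    if (params$screen_pcs) {
      pc <- screen_genetic_pcs(pc, geno[, colnames(e), drop = FALSE],
                               r2_threshold = params$screen_r2,
                               n_perm = params$n_perm,
                               fdr = 0.05, seed = params$seed + 11L)
    }
    pcs[[plat]] <- pc
    cis_expr[[plat]] <- regress_out_pcs(e, pc, k = params$k_cis)
    trans_base[[plat]] <- regress_out_pcs(e, pc, k = params$k_trans)
  }
  note("normalization", sum(vapply(study$expr_raw, nrow, integer(1))),
       sum(vapply(norm, nrow, integer(1))))

  # --- cis scan ---------------------------------------------------------
  probe_annot <- study$probe_annot[!study$probe_annot$probe_id %in% zero_var, ,
                                   drop = FALSE]
  cp <- cis_pairs(snp_annot, probe_annot, window = params$cis_window)
  cis <- NULL
  if (nrow(cp) > 0L) {
    ds <- lapply(platforms, function(plat) {
      list(geno = geno[, colnames(cis_expr[[plat]]), drop = FALSE],
           expr = cis_expr[[plat]])
    })
    names(ds) <- platforms
    cis <- eqtl_scan(ds, cp, class = "cis", n_perm = params$n_perm,
                     target_fdr = params$cis_fdr, seed = params$seed + 21L)
    cis$records$gene <- probe_annot$gene[match(cis$records$probe,
                                               probe_annot$probe_id)]
    note("cis_scan", nrow(cp), nrow(cp), 0L,
         n_significant = sum(cis$records$fdr_significant))
  }

  # --- regress out significant cis effects, then trans scan -------------
  tp <- trans_pairs(snp_annot, probe_annot, min_dist = params$trans_min_dist)
  trans <- NULL
  if (nrow(tp) > 0L) {
    ds <- lapply(platforms, function(plat) {
      e <- trans_base[[plat]]
      g <- geno[, colnames(e), drop = FALSE]
      if (!is.null(cis)) e <- regress_out_cis(e, cis$records, g)
      list(geno = g, expr = e)
    })
    names(ds) <- platforms
    trans <- eqtl_scan(ds, tp, class = "trans", n_perm = params$n_perm,
                       target_fdr = params$trans_fdr,
                       seed = params$seed + 31L)
    trans$records$gene <- probe_annot$gene[match(trans$records$probe,
                                                 probe_annot$probe_id)]
    note("trans_scan", nrow(tp), nrow(tp), 0L,
         n_significant = sum(trans$records$fdr_significant))
  }

  # --- probe-artifact filters ------------------------------------------
  cis_kept <- cis$records
  cis_removed <- NULL
  if (!is.null(cis)) {
    ld_fn <- function(a, b) {
      if (a == b) return(1)
      if (!a %in% rownames(geno) || !b %in% rownames(geno)) return(0)
      suppressWarnings(ld_r2(geno[a, ], geno[b, ]))
    }
    pf <- primer_polymorphism_filter(cis$records, probe_annot,
                                     known_snps = snp_annot, ld_fn = ld_fn,
                                     r2_min = params$primer_ld_r2)
    cis_kept <- pf$kept
    cis_removed <- pf$removed
    note("primer_polymorphism_filter", nrow(cis$records), nrow(cis_kept))
  }
  trans_kept <- trans$records
  trans_removed <- NULL
  trans_refdr <- trans$fdr
  if (!is.null(trans) && !is.null(study$hits) && nrow(study$hits) > 0L) {
    xf <- discard_trans_near_snp(trans$records, study$hits, snp_annot,
                                 window = params$crosshyb_window)
    trans_kept <- xf$kept
    trans_removed <- xf$removed
    note("crosshyb_filter", nrow(trans$records), nrow(trans_kept))
    # repeat the multiple-testing correction on the surviving observed tests
    trans_refdr <- permutation_fdr(trans_kept$p, trans$permuted_p,
                                   target_fdr = params$trans_fdr)
    trans_kept$fdr_significant <- trans_refdr$significant
    note("trans_fdr_recompute", nrow(trans_kept), nrow(trans_kept), 0L,
         n_significant = sum(trans_kept$fdr_significant))
  }

  # --- convergence ------------------------------------------------------
  convergence <- NULL
  if (!is.null(study$trait_catalog) && !is.null(trans)) {
    sig <- rbind(
      if (!is.null(cis_kept))
        cis_kept[cis_kept$fdr_significant,
                 c("snp", "gene", "p", "fdr_significant"), drop = FALSE],
      trans_kept[trans_kept$fdr_significant,
                 c("snp", "gene", "p", "fdr_significant"), drop = FALSE])
    pairs_found <- find_converging_pairs(study$trait_catalog, sig, geno,
                                         r2_max = params$convergence_r2_max)
    n_real_trans <- sum(trans_kept$fdr_significant)
    enrich <- NULL
    if (n_real_trans > 0L) {
      rounds <- min(params$convergence_rounds, length(trans$permuted_p))
      rankings <- lapply(trans$permuted_p[seq_len(rounds)], function(pp) {
        data.frame(snp = trans$records$snp,
                   gene = trans$records$gene, p = pp)
      })
      cis_sig <- if (!is.null(cis_kept))
        cis_kept[cis_kept$fdr_significant,
                 c("snp", "gene", "p", "fdr_significant"), drop = FALSE]
      else data.frame(snp = character(0), gene = character(0),
                      p = numeric(0), fdr_significant = logical(0))
      enrich <- convergence_null(nrow(pairs_found), study$trait_catalog,
                                 cis_sig, rankings, n_real_trans, geno,
                                 r2_max = params$convergence_r2_max)
    }
    convergence <- list(pairs = pairs_found, enrichment = enrich)
  }

  list(qc = qc, pcs = pcs, normalized = norm,
       cis = cis, cis_records_final = cis_kept, cis_removed = cis_removed,
       trans = trans, trans_records_final = trans_kept,
       trans_removed = trans_removed, trans_fdr_final = trans_refdr,
       convergence = convergence, manifest = manifest)
}
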