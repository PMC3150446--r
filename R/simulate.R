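#' Simulation configuration
#'
#' Defines the stated world of the synthetic cohort: sample and SNP counts,
#' the minor-allele-frequency spectrum, LD-block structure, missingness,
#' low-rank batch structure dominating the expression variance, the
#' two-platform sample split, and artifact-probe counts. Defaults emulate the
#' study design this package targets: 1,469 samples split 1,240 / 229 over
#' two array platforms, with SNP/probe counts scaled to desk size.
#'
#' @param n_samples,n_snps,n_probes Cohort dimensions.
#' @param maf_range Interval in (0, 0.5] the per-block MAF is drawn from.
#' @param ld_block_size Number of adjacent SNPs forming one LD block.
#' @param ld_decay Per-site haplotype mutation probability within a block
#'   (adjacent-SNP haplotype correlation is `1 - ld_decay`).
#' @param missing_rate Fraction of genotype entries set missing.
#' @param n_batch_components,batch_sd Low-rank batch structure: number of
#'   per-sample components and the SD of the probe-specific loadings.
#' @param noise_sd Per-probe Gaussian noise SD.
#' @param platform_split Fraction of samples assigned to the larger (HT12)
#'   platform; `1` yields a single-platform study.
#' @param shared_probe_fraction Fraction of probes also present on the
#'   smaller (H8v2) platform.
#' @param platform_offset_sd SD of the per-probe additive H8v2 intensity
#'   offset (log2 scale).
#' @param n_crosshyb,n_primer_poly Numbers of planted artifact probes.
#' @param artifact_r2 Variance fraction the artifact signal explains.
#' @param n_chromosomes,chr_length Genome model (autosomes, 1-based
#'   positions).
#' @param seed Integer seed; a fixed seed makes every emitted object
#'   identical across runs.
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 1469L, n_snps = 300L, n_probes = 200L,
                       maf_range = c(0.05, 0.5), ld_block_size = 5L,
                       ld_decay = 0.1, missing_rate = 0,
                       n_batch_components = 5L, batch_sd = 2, noise_sd = 1,
                       platform_split = 1240 / 1469,
                       shared_probe_fraction = 0.5,
                       platform_offset_sd = 0.25,
                       n_crosshyb = 0L, n_primer_poly = 0L, artifact_r2 = 0.1,
                       n_chromosomes = 22L, chr_length = 120e6,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_probes = as.integer(n_probes), maf_range = maf_range,
              ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
              missing_rate = missing_rate,
              n_batch_components = as.integer(n_batch_components),
              batch_sd = batch_sd, noise_sd = noise_sd,
              platform_split = platform_split,
              shared_probe_fraction = shared_probe_fraction,
              platform_offset_sd = platform_offset_sd,
              n_crosshyb = as.integer(n_crosshyb),
              n_primer_poly = as.integer(n_primer_poly),
              artifact_r2 = artifact_r2,
              n_chromosomes = as.integer(n_chromosomes),
              chr_length = chr_length, seed = as.integer(seed))
  with(cfg, {
    if (n_samples <= 0 || n_snps <= 0 || n_probes <= 0 || ld_block_size <= 0)
      stop("dimensions must be positive")
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (platform_split <= 0 || platform_split > 1) stop("platform_split must be in (0,1]")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate genotypes with LD blocks under Hardy-Weinberg equilibrium
#'
#' Each LD block draws one MAF from `maf_range`; the founder site is drawn as
#' two Bernoulli haplotypes and subsequent sites copy the previous site's
#' haplotypes with per-site mutation probability `ld_decay` (redrawn at the
#' block MAF), so every site is marginally HWE while adjacent sites are
#' correlated. Missing entries are masked at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return List: `geno` (SNPs x samples integer matrix with `NA` missing) and
#'   `snp_annot` (data.frame `snp`, `chr`, `pos`, `allele1`, `allele2`,
#'   `block`, `maf_target`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n <- config$n_samples
    bs <- config$ld_block_size
    n_blocks <- ceiling(config$n_snps / bs)
    per_chr <- ceiling(n_blocks / config$n_chromosomes)
    geno <- matrix(NA_integer_, config$n_snps, n)
    chr <- pos <- block <- integer(config$n_snps)
    maf_t <- numeric(config$n_snps)
    i <- 0L
    for (b in seq_len(n_blocks)) {
      p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      size <- min(bs, config$n_snps - i)
      h1 <- stats::rbinom(n, 1L, p)
      h2 <- stats::rbinom(n, 1L, p)
      b_chr <- ((b - 1L) %% config$n_chromosomes) + 1L
      b_slot <- (b - 1L) %/% config$n_chromosomes
      b_start <- 1e6 + b_slot * 8e6
      for (j in seq_len(size)) {
        if (j > 1L) {
          m1 <- stats::runif(n) < config$ld_decay
          m2 <- stats::runif(n) < config$ld_decay
          h1[m1] <- stats::rbinom(sum(m1), 1L, p)
          h2[m2] <- stats::rbinom(sum(m2), 1L, p)
        }
        i <- i + 1L
        geno[i, ] <- h1 + h2
        chr[i] <- b_chr
        pos[i] <- b_start + (j - 1L) * 2000L
        block[i] <- b
        maf_t[i] <- p
      }
    }
    if (config$missing_rate > 0) {
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
    }
    ids <- sprintf("rs%05d", seq_len(config$n_snps))
    rownames(geno) <- ids
    colnames(geno) <- sprintf("S%04d", seq_len(n))
    list(geno = geno,
         snp_annot = data.frame(snp = ids, chr = chr, pos = pos,
                                allele1 = "A", allele2 = "B",
                                block = block, maf_target = maf_t))
  })
}

#' Plant cis, trans and convergent expression effects
#'
#' Chooses SNPs and invents probe identifiers for the requested numbers of
#' cis effects (probe placed within 250 kb of the SNP), trans effects (probe
#' on another chromosome), and convergent pairs (two SNPs on different
#' chromosomes both acting in trans on the same probe/gene).
#'
#' @param snp_annot SNP annotation from [simulate_genotypes()].
#' @param n_cis,n_trans,n_convergent_pairs Effect counts.
#' @param cis_r2,trans_r2 Ranges the per-effect explained-variance fraction
#'   is drawn from.
#' @param geno Optional genotype matrix; when supplied, convergent pair SNPs
#'   are additionally required to have a realised sample LD r^2 below 5e-4,
#'   so the planted pairs satisfy the unlinked-pair ceiling (r^2 < 0.001)
#'   under the finite-sample LD estimate the pipeline itself uses.
#' @param seed Seed.
#' @return Data frame `snp_id`, `probe_id`, `class`, `target_r2`, `gene` with
#'   attribute `convergent_pairs` (data.frame `snpA`, `snpB`, `gene`).
#' @export
plant_effects <- function(snp_annot, n_cis = 20L, n_trans = 10L,
                          n_convergent_pairs = 0L,
                          cis_r2 = c(0.05, 0.3), trans_r2 = c(0.05, 0.15),
                          geno = NULL, seed = 1L) {
  withr_seed(seed, {
    need <- n_cis + n_trans + 2L * n_convergent_pairs
    if (need > nrow(snp_annot)) stop("fewer SNPs than planted effects require")
    picked <- sample(snp_annot$snp, need)
    eff <- list()
    k <- 0L
    if (n_cis > 0L) {
      eff$cis <- data.frame(
        snp_id = picked[seq_len(n_cis)],
        probe_id = sprintf("cis_probe_%03d", seq_len(n_cis)),
        class = "cis",
        target_r2 = stats::runif(n_cis, cis_r2[1], cis_r2[2]),
        gene = sprintf("CISG%03d", seq_len(n_cis)))
      k <- n_cis
    }
    if (n_trans > 0L) {
      eff$trans <- data.frame(
        snp_id = picked[k + seq_len(n_trans)],
        probe_id = sprintf("trans_probe_%03d", seq_len(n_trans)),
        class = "trans",
        target_r2 = stats::runif(n_trans, trans_r2[1], trans_r2[2]),
        gene = sprintf("TRANSG%03d", seq_len(n_trans)))
      k <- k + n_trans
    }
    conv <- data.frame(snpA = character(0), snpB = character(0),
                       gene = character(0))
    if (n_convergent_pairs > 0L) {
      rows <- list()
      pair_ok <- function(a, b) {
        if (snp_annot$chr[snp_annot$snp == a] ==
            snp_annot$chr[snp_annot$snp == b]) return(FALSE)
        if (is.null(geno)) return(TRUE)
        # the downstream unlinked-pair rule uses the finite-sample LD
        # estimate, so require headroom below the 0.001 ceiling
        suppressWarnings(ld_r2(geno[a, ], geno[b, ])) < 5e-4
      }
      for (cp in seq_len(n_convergent_pairs)) {
        a <- picked[k + 2L * cp - 1L]; b <- picked[k + 2L * cp]
        if (!pair_ok(a, b)) {
          cand <- setdiff(snp_annot$snp, picked)
          cand <- cand[vapply(cand, function(s) pair_ok(a, s), logical(1))]
          if (length(cand) == 0L) stop("no unlinked SNP available for convergent pair")
          b <- cand[1L]
          picked <- c(picked, b)
        }
        gene <- sprintf("CONVG%03d", cp)
        probe <- sprintf("conv_probe_%03d", cp)
        r2 <- stats::runif(2, trans_r2[1], trans_r2[2])
        rows[[cp]] <- data.frame(
          snp_id = c(a, b), probe_id = probe, class = "trans",
          target_r2 = r2, gene = gene)
        conv <- rbind(conv, data.frame(snpA = min(a, b), snpB = max(a, b),
                                       gene = gene))
      }
      eff$conv <- do.call(rbind, rows)
    }
    out <- do.call(rbind, eff)
    if (is.null(out)) {
      out <- data.frame(snp_id = character(0), probe_id = character(0),
                        class = character(0), target_r2 = numeric(0),
                        gene = character(0))
    }
    rownames(out) <- NULL
    structure(out, convergent_pairs = conv)
  })
}

#' Simulate two-platform expression with planted effects and artifacts
#'
#' Every probe is the sum of its planted genotype effect (scaled so the
#' realised in-sample variance fraction equals `target_r2` exactly), shared
#' low-rank batch components with probe-specific loadings, and Gaussian
#' noise, exponentiated to raw intensities. Cross-hybridizing probes receive
#' extra signal from a decoy locus' SNP on another chromosome;
#' primer-polymorphism probes carry a spurious cis signal from a SNP inside
#' their own genomic interval.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param planted_effects Data frame from [plant_effects()] (may have zero
#'   rows).
#' @param config A [sim_config()].
#' @return List: `expr_raw` (named list of raw intensity matrices per
#'   platform), `probe_annot`, `hits` (alignment-hit table for the planted
#'   cross-hybridizers), `truth` (effects incl. artifacts, crosshyb and
#'   primer-polymorphism probe tables, convergent pairs), `platform_of`
#'   (sample -> platform).
#' @export
simulate_expression <- function(genotypes, planted_effects, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- genotypes$geno
  snp_annot <- genotypes$snp_annot
  missing_eff <- setdiff(planted_effects$snp_id, rownames(geno))
  if (length(missing_eff) > 0L) {
    stop("planted SNP id absent from genotypes: ", missing_eff[1L])
  }
  withr_seed(config$seed + 1L, {
    n <- ncol(geno)
    planted_probes <- unique(planted_effects$probe_id)
    n_special <- length(planted_probes) + config$n_crosshyb + config$n_primer_poly
    if (n_special > config$n_probes) {
      stop("n_probes too small for planted effects and artifacts")
    }
    ids <- c(planted_probes,
             if (config$n_crosshyb > 0) sprintf("xhyb_probe_%03d", seq_len(config$n_crosshyb)),
             if (config$n_primer_poly > 0) sprintf("ppoly_probe_%03d", seq_len(config$n_primer_poly)),
             sprintf("null_probe_%03d", seq_len(config$n_probes - n_special)))
    np <- length(ids)

    # --- probe placement -------------------------------------------------
    chrs <- integer(np); mids <- numeric(np); genes <- character(np)
    names(chrs) <- names(mids) <- names(genes) <- ids
    rand_pos <- function(k) round(stats::runif(k, 1e6, config$chr_length - 1e6))
    for (pid in planted_probes) {
      effs <- planted_effects[planted_effects$probe_id == pid, , drop = FALSE]
      snp_chr <- snp_annot$chr[match(effs$snp_id, snp_annot$snp)]
      snp_pos <- snp_annot$pos[match(effs$snp_id, snp_annot$snp)]
      genes[pid] <- effs$gene[1L]
      if (effs$class[1L] == "cis") {
        chrs[pid] <- snp_chr[1L]
        repeat {  # stay inside the cis window but clear of SNP positions
          mids[pid] <- max(1, snp_pos[1L] + round(stats::runif(1, -2e5, 2e5)))
          if (!any(snp_annot$chr == chrs[pid] &
                   abs(snp_annot$pos - mids[pid]) <= 30)) break
        }
      } else {
        free <- setdiff(seq_len(config$n_chromosomes), snp_chr)
        chrs[pid] <- if (length(free)) sample(free, 1L) else snp_chr[1L]
        mids[pid] <- rand_pos(1L)
      }
    }
    rest <- setdiff(ids, planted_probes)
    chrs[rest] <- sample(config$n_chromosomes, length(rest), replace = TRUE)
    mids[rest] <- rand_pos(length(rest))
    genes[rest] <- paste0("G_", rest)
    # keep non-artifact probe intervals clear of any SNP (25 bp margin)
    for (pid in rest) {
      while (any(snp_annot$chr == chrs[pid] &
                 abs(snp_annot$pos - mids[pid]) <= 30)) {
        mids[pid] <- rand_pos(1L)
      }
    }

    # --- artifact wiring -------------------------------------------------
    truth_xhyb <- data.frame(probe_id = character(0), decoy_snp = character(0),
                             decoy_chr = integer(0), decoy_pos = numeric(0))
    truth_ppoly <- data.frame(probe_id = character(0), snp_id = character(0))
    art_effects <- list()
    if (config$n_crosshyb > 0L) {
      xids <- ids[startsWith(ids, "xhyb_probe_")]
      for (pid in xids) {
        cand <- snp_annot[snp_annot$chr != chrs[pid], , drop = FALSE]
        s <- cand[sample(nrow(cand), 1L), ]
        truth_xhyb <- rbind(truth_xhyb, data.frame(
          probe_id = pid, decoy_snp = s$snp, decoy_chr = s$chr,
          decoy_pos = s$pos))
        art_effects[[pid]] <- data.frame(
          snp_id = s$snp, probe_id = pid, class = "trans",
          target_r2 = config$artifact_r2, gene = genes[pid])
      }
    }
    if (config$n_primer_poly > 0L) {
      pids <- ids[startsWith(ids, "ppoly_probe_")]
      for (pid in pids) {
        s <- snp_annot[sample(nrow(snp_annot), 1L), ]
        chrs[pid] <- s$chr
        mids[pid] <- s$pos          # SNP sits inside the probe interval
        truth_ppoly <- rbind(truth_ppoly,
                             data.frame(probe_id = pid, snp_id = s$snp))
        art_effects[[pid]] <- data.frame(
          snp_id = s$snp, probe_id = pid, class = "cis",
          target_r2 = config$artifact_r2, gene = genes[pid])
      }
    }
    all_effects <- rbind(
      if (nrow(planted_effects)) cbind(planted_effects, artifact = FALSE),
      if (length(art_effects)) cbind(do.call(rbind, art_effects), artifact = TRUE))

    # --- expression signal (log2 scale) ----------------------------------
    Z <- matrix(stats::rnorm(np * n, sd = config$noise_sd), np, n,
                dimnames = list(ids, colnames(geno)))
    if (config$n_batch_components > 0L) {
      B <- matrix(stats::rnorm(n * config$n_batch_components), n)
      L <- matrix(stats::rnorm(np * config$n_batch_components,
                               sd = config$batch_sd), np)
      Z <- Z + L %*% t(B)
    }
    if (!is.null(all_effects) && nrow(all_effects) > 0L) {
      for (pid in unique(all_effects$probe_id)) {
        effs <- all_effects[all_effects$probe_id == pid, , drop = FALSE]
        G <- geno[effs$snp_id, , drop = FALSE]
        G[is.na(G)] <- rowMeans(G, na.rm = TRUE)[which(is.na(G), arr.ind = TRUE)[, 1L]]
        Gc <- G - rowMeans(G)
        # orthogonalize the non-genetic part against the genotype design
        fit <- stats::lm.fit(cbind(1, t(Gc)), Z[pid, ])
        rest_o <- fit$residuals
        vr <- stats::var(rest_o)
        tot_r2 <- sum(effs$target_r2)
        if (tot_r2 >= 1) stop("combined target_r2 for probe ", pid, " must be < 1")
        sig <- rep(0, n)
        for (jj in seq_len(nrow(effs))) {
          beta <- sqrt(effs$target_r2[jj] / (1 - tot_r2) * vr /
                         stats::var(Gc[jj, ]))
          sig <- sig + beta * Gc[jj, ]
        }
        # The pipeline reports explained variance as the squared Spearman
        # correlation, which is attenuated relative to the linear scale by
        # the rank transform of the 3-valued genotype. Rescale the planted
        # signal so the realised rank-scale r^2 sums to the target.
        if (tot_r2 > 0 && stats::sd(sig) > 0) {
          rank_r2 <- function(m) {
            x <- m * sig + rest_o
            sum(vapply(seq_len(nrow(effs)), function(jj) {
              stats::cor(rank(Gc[jj, ]), rank(x))^2
            }, numeric(1)))
          }
          m <- tryCatch(
            stats::uniroot(function(m) rank_r2(m) - tot_r2,
                           interval = c(0.2, 5), extendInt = "upX",
                           tol = 1e-4)$root,
            error = function(e) 1)
          sig <- m * sig
        }
        Z[pid, ] <- sig + rest_o
      }
    }

    # --- platforms and raw intensities -----------------------------------
    n_ht12 <- max(1L, round(config$platform_split * n))
    platform_of <- stats::setNames(
      rep(c("HT12", "H8v2"), c(n_ht12, n - n_ht12)), colnames(geno))
    expr_raw <- list(HT12 = 2^(Z[, platform_of == "HT12", drop = FALSE] + 8))
    if (n_ht12 < n) {
      n_shared <- max(1L, round(config$shared_probe_fraction * np))
      shared <- sort(sample(ids, n_shared))
      offset <- stats::rnorm(n_shared, sd = config$platform_offset_sd)
      expr_raw$H8v2 <- 2^(Z[shared, platform_of == "H8v2", drop = FALSE] +
                            offset + 8)
    }

    sequences <- random_probe_sequences(np)
    probe_annot <- data.frame(
      probe_id = ids, chr = unname(chrs), midpoint = unname(mids),
      gene = unname(genes), sequence = sequences,
      probe_start = pmax(1, unname(mids) - 24), probe_end = unname(mids) + 25,
      mapping = "unique-locus")
    hits <- if (nrow(truth_xhyb) > 0L) {
      data.frame(probe_id = truth_xhyb$probe_id, chr = truth_xhyb$decoy_chr,
                 start = truth_xhyb$decoy_pos + 5e4,
                 end = truth_xhyb$decoy_pos + 5e4 + 20,
                 n_matches = 20L, n_mismatches = 1L, aligned_span = 21L)
    } else {
      data.frame(probe_id = character(0), chr = integer(0), start = numeric(0),
                 end = numeric(0), n_matches = integer(0),
                 n_mismatches = integer(0), aligned_span = integer(0))
    }
    list(expr_raw = expr_raw, probe_annot = probe_annot, hits = hits,
         truth = list(effects = all_effects %||%
                        data.frame(snp_id = character(0)),
                      crosshyb = truth_xhyb, primer_poly = truth_ppoly,
                      convergent_pairs = attr(planted_effects,
                                              "convergent_pairs")),
         platform_of = platform_of)
  })
}

random_probe_sequences <- function(k, len = 50L) {
  seqs <- character(k)
  repeat {
    todo <- which(seqs == "" | duplicated(seqs))
    if (length(todo) == 0L) break
    seqs[todo] <- vapply(todo, function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  seqs
}

#' Simulate a trait catalog with designated convergent SNP pairs
#'
#' Every planted convergent pair becomes one trait carrying exactly its two
#' unlinked SNPs; additional traits receive at least two randomly chosen
#' SNPs each.
#'
#' @param snp_annot SNP annotation.
#' @param planted_effects Effects from [plant_effects()] (its
#'   `convergent_pairs` attribute, if any, seeds the convergent traits).
#' @param n_traits Total number of traits (must cover the convergent pairs).
#' @param seed Seed.
#' @return List: `catalog` (data.frame `snp`, `trait`) and
#'   `truth` (data.frame `trait`, `snpA`, `snpB`, `gene`).
#' @export
simulate_trait_catalog <- function(snp_annot, planted_effects, n_traits = 5L,
                                   seed = 1L) {
  conv <- attr(planted_effects, "convergent_pairs")
  if (is.null(conv)) conv <- data.frame(snpA = character(0),
                                        snpB = character(0),
                                        gene = character(0))
  if (n_traits < nrow(conv)) stop("n_traits smaller than planted convergent pairs")
  withr_seed(seed, {
    cat_rows <- list(); truth_rows <- list()
    for (i in seq_len(nrow(conv))) {
      trait <- sprintf("trait_conv_%02d", i)
      cat_rows[[trait]] <- data.frame(snp = c(conv$snpA[i], conv$snpB[i]),
                                      trait = trait)
      truth_rows[[trait]] <- data.frame(trait = trait, snpA = conv$snpA[i],
                                        snpB = conv$snpB[i], gene = conv$gene[i])
    }
    n_extra <- n_traits - nrow(conv)
    pool <- setdiff(snp_annot$snp, c(conv$snpA, conv$snpB))
    for (i in seq_len(n_extra)) {
      k <- min(length(pool), sample(2:4, 1L))
      if (k < 2L) stop("fewer eligible SNPs than traits require")
      snps <- sample(pool, k)
      cat_rows[[length(cat_rows) + 1L]] <-
        data.frame(snp = snps, trait = sprintf("trait_null_%02d", i))
    }
    catalog <- do.call(rbind, cat_rows)
    rownames(catalog) <- NULL
    stopifnot(!anyDuplicated(paste(catalog$snp, catalog$trait)))
    list(catalog = catalog,
         truth = if (length(truth_rows)) do.call(rbind, truth_rows)
                 else data.frame(trait = character(0), snpA = character(0),
                                 snpB = character(0), gene = character(0)))
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_genotypes()], [plant_effects()],
#' [simulate_expression()] and [simulate_trait_catalog()] into one bundle
#' with a full truth table.
#'
#' @param config A [sim_config()].
#' @param n_cis,n_trans,n_convergent_pairs,cis_r2,trans_r2 Passed to
#'   [plant_effects()].
#' @param n_traits Passed to [simulate_trait_catalog()].
#' @return Study bundle list used throughout the pipeline.
#' @export
simulate_study <- function(config, n_cis = 20L, n_trans = 10L,
                           n_convergent_pairs = 0L,
                           cis_r2 = c(0.05, 0.3), trans_r2 = c(0.05, 0.15),
                           n_traits = max(5L, n_convergent_pairs)) {
  g <- simulate_genotypes(config)
  eff <- plant_effects(g$snp_annot, n_cis = n_cis, n_trans = n_trans,
                       n_convergent_pairs = n_convergent_pairs,
                       cis_r2 = cis_r2, trans_r2 = trans_r2,
                       geno = g$geno, seed = config$seed + 2L)
  ex <- simulate_expression(g, eff, config)
  tc <- simulate_trait_catalog(g$snp_annot, eff, n_traits = n_traits,
                               seed = config$seed + 3L)
  list(config = config, geno = g$geno, snp_annot = g$snp_annot,
       expr_raw = ex$expr_raw, probe_annot = ex$probe_annot, hits = ex$hits,
       platform_of = ex$platform_of, trait_catalog = tc$catalog,
       truth = c(ex$truth, list(convergent_traits = tc$truth)))
}
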