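#' Remove cis records affected by primer polymorphisms
#'
#' A cis SNP-probe combination is spurious when a known SNP lies inside the
#' probe's genomic hybridization interval and is in linkage disequilibrium
#' (r^2 above `r2_min`) with the cis SNP: allele-dependent hybridization then
#' mimics a cis effect.
#'
#' @param cis_records Record data frame (`snp`, `probe`, ...).
#' @param probe_annot Data frame with `probe_id`, `chr`, `probe_start`,
#'   `probe_end` (1-based inclusive).
#' @param known_snps Data frame `snp`, `chr`, `pos`.
#' @param ld_fn Function `(snp_id_a, snp_id_b) -> r^2` (e.g. a closure over
#'   [ld_r2()] and the genotype matrix).
#' @param r2_min LD threshold (strict `>` removes).
#' @return List `kept` and `removed` (with `removed_reason`).
#' @export
primer_polymorphism_filter <- function(cis_records, probe_annot, known_snps,
                                       ld_fn, r2_min = 0.1) {
  pa <- probe_annot[match(cis_records$probe, probe_annot$probe_id), ,
                    drop = FALSE]
  remove <- logical(nrow(cis_records))
  for (i in seq_len(nrow(cis_records))) {
    if (is.na(pa$probe_start[i]) || is.na(pa$probe_end[i])) {
      warning("probe without genomic interval kept: ", cis_records$probe[i])
      next
    }
    inside <- known_snps$chr == pa$chr[i] &
      known_snps$pos >= pa$probe_start[i] & known_snps$pos <= pa$probe_end[i]
    for (s in known_snps$snp[inside]) {
      if (ld_fn(cis_records$snp[i], s) > r2_min) {
        remove[i] <- TRUE
        break
      }
    }
  }
  removed <- cis_records[remove, , drop = FALSE]
  if (nrow(removed)) removed$removed_reason <- "primer_polymorphism"
  list(kept = cis_records[!remove, , drop = FALSE], removed = removed)
}

#' Relaxed local alignment of a probe against a target sequence
#'
#' Smith-Waterman local alignment under the relaxed-mapping scoring used for
#' cross-hybridization screening: match 10, mismatch 0, gap open -250, gap
#' extension -100 (the gap penalties effectively suppress gaps). Hits whose
#' fraction of identical bases falls below `min_identity` of the probe length
#' are discarded.
#'
#' @param probe_seq Probe sequence (ACGT, typically 50 bp).
#' @param target_seq Target sequence to scan.
#' @param chr,offset Optional coordinates of the target (hit start/end are
#'   reported as `offset` + subject position - 1).
#' @param match,mismatch,gap_open,gap_extend,min_identity Scoring scheme.
#' @return Data frame of accepted hits (possibly zero rows): `chr`, `start`,
#'   `end`, `n_matches`, `n_mismatches`, `aligned_span`.
#' @export
local_align_probe <- function(probe_seq, target_seq, chr = NA, offset = 1L,
                              match = 10, mismatch = 0, gap_open = -250,
                              gap_extend = -100, min_identity = 0.30) {
  for (s in c(probe_seq, target_seq)) {
    if (grepl("[^ACGT]", s)) stop("sequences must contain only A, C, G, T")
  }
  submat <- matrix(mismatch, 4, 4,
                   dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(submat) <- match
  aln <- Biostrings::pairwiseAlignment(
    pattern = probe_seq, subject = target_seq, type = "local",
    substitutionMatrix = submat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  empty <- data.frame(chr = character(0), start = numeric(0), end = numeric(0),
                      n_matches = integer(0), n_mismatches = integer(0),
                      aligned_span = integer(0))
  if (length(nm) == 0L || nm / nchar(probe_seq) < min_identity) return(empty)
  rng <- methods::slot(methods::slot(aln, "subject"), "range")
  data.frame(chr = chr,
             start = offset + BiocGenerics::start(rng) - 1L,
             end = offset + BiocGenerics::end(rng) - 1L,
             n_matches = nm, n_mismatches = nmm,
             aligned_span = nm + nmm)
}

#' Cross-hybridization acceptance rule for a relaxed alignment hit
#'
#' A hit is accepted as a plausible hybridization when it has at least a
#' 15-base overlap with no mismatches, or at least 20 matches with at most 1
#' mismatch, or at least 30 matches with at most 2 mismatches, or covers the
#' full 50-bp probe with at most 15 mismatches.
#'
#' @param n_matches,n_mismatches,aligned_span Hit statistics (vectors
#'   allowed).
#' @return Logical vector.
#' @export
crosshyb_accept <- function(n_matches, n_mismatches, aligned_span) {
  if (any(n_matches + n_mismatches > aligned_span) || any(aligned_span > 50)) {
    stop("invalid alignment hit: matches + mismatches must be <= span <= 50")
  }
  (aligned_span >= 15 & n_mismatches == 0) |
    (n_matches >= 20 & n_mismatches <= 1) |
    (n_matches >= 30 & n_mismatches <= 2) |
    (aligned_span == 50 & n_mismatches <= 15)
}

#' Discard trans records whose probe cross-hybridizes near the SNP
#'
#' A trans record is removed when any accepted alignment hit of its probe
#' lies on the SNP's chromosome within `window` of the SNP position; the
#' apparent trans signal is then attributable to local cross-hybridization.
#' The FDR must be recomputed on the surviving tests afterwards (see
#' [run_pipeline()]).
#'
#' @param trans_records Record data frame (`snp`, `probe`, ...).
#' @param hits Hit table (`probe_id`, `chr`, `start`, `end`, `n_matches`,
#'   `n_mismatches`, `aligned_span`); only hits passing [crosshyb_accept()]
#'   count.
#' @param snp_annot Data frame `snp`, `chr`, `pos`.
#' @param window Distance threshold in bp (default 2 Mb).
#' @return List `kept` and `removed` (with `removed_reason`).
#' @export
discard_trans_near_snp <- function(trans_records, hits, snp_annot,
                                   window = 2e6) {
  acc <- hits[crosshyb_accept(hits$n_matches, hits$n_mismatches,
                              hits$aligned_span), , drop = FALSE]
  sa <- snp_annot[match(trans_records$snp, snp_annot$snp), , drop = FALSE]
  remove <- vapply(seq_len(nrow(trans_records)), function(i) {
    h <- acc[acc$probe_id == trans_records$probe[i] & acc$chr == sa$chr[i], ,
             drop = FALSE]
    if (nrow(h) == 0L) return(FALSE)
    any(pmin(abs(h$start - sa$pos[i]), abs(h$end - sa$pos[i])) <= window |
          (h$start <= sa$pos[i] & h$end >= sa$pos[i]))
  }, logical(1))
  removed <- trans_records[remove, , drop = FALSE]
  if (nrow(removed)) removed$removed_reason <- "cross_hybridization"
  list(kept = trans_records[!remove, , drop = FALSE], removed = removed)
}
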