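#' Quantile-normalize samples to the median distribution
#'
#' Every sample (column) is forced onto a common target distribution: the
#' per-rank median across samples of the sorted intensity vectors. Ties within
#' a sample receive the mean of the target values over their tied ranks.
#'
#' @param expr Numeric matrix, probes in rows, samples in columns; no missing
#'   values.
#' @return Matrix of the same shape with identical per-sample distributions.
#' @export
quantile_normalize_to_median <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1L)
  if (anyNA(expr)) stop("missing values are not allowed; impute or drop upstream")
  sorted <- apply(expr, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, ncol = ncol(expr))
  target <- matrixStats::rowMedians(sorted)
  out <- apply(expr, 2L, assign_target_by_rank, target = target)
  dimnames(out) <- dimnames(expr)
  out
}

# Map a vector onto `target` (sorted) by rank; tied groups get the mean of
# the target values at the ranks the group occupies.
assign_target_by_rank <- function(x, target) {
  o <- order(x)
  runs <- rle(x[o])$lengths
  ends <- cumsum(runs)
  starts <- ends - runs + 1L
  ct <- cumsum(target)
  group_means <- (ct[ends] - c(0, ct[ends])[seq_along(ends)]) / runs
  # c(0, ct[ends])[i] is ct of the previous group's end (0 for the first)
  out <- numeric(length(x))
  out[o] <- rep(group_means, runs)
  out
}

#' Log2-transform, center and scale expression per probe
#'
#' Intensities are log2-transformed, then each probe (row) is centered to mean
#' zero and scaled to unit sample standard deviation (n-1 denominator).
#' Zero-variance probes are left centered and flagged; they must be excluded
#' from association testing.
#'
#' @param expr Positive intensity matrix, probes in rows.
#' @return List: `expr` (standardized matrix) and `zero_variance` (character
#'   vector of flagged probe ids).
#' @export
log2_center_scale <- function(expr) {
  stopifnot(is.matrix(expr))
  bad <- which(expr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-positive intensity at probe '%s', sample '%s'",
                 rownames(expr)[bad[1L, 1L]] %||% bad[1L, 1L],
                 colnames(expr)[bad[1L, 2L]] %||% bad[1L, 2L]))
  }
  lx <- log2(expr)
  mu <- rowMeans(lx)
  lx <- lx - mu
  sds <- matrixStats::rowSds(lx)
  zero <- sds == 0
  sds[zero] <- 1
  out <- lx / sds
  list(expr = out,
       zero_variance = rownames(expr)[zero] %||% which(zero))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonize probe identifiers across the two expression platforms
#'
#' Probes with identical 50-base sequences on both platforms take the HT12
#' identifier. Platform-one-only probes keep their identifier with the prefix
#' `Human_RefSeq-8_v2-`; the prefix also disambiguates identifier collisions
#' between different sequences.
#'
#' @param h8v2_annot,ht12_annot Data frames with at least `probe_id` and
#'   `sequence` columns.
#' @return List: `annotation` (unified data.frame with `probe_id`,
#'   `sequence`, `platforms`) and `id_map` (platform, original_id, unified_id).
#' @export
harmonize_probe_ids <- function(h8v2_annot, ht12_annot,
                                prefix = "Human_RefSeq-8_v2-") {
  for (a in list(h8v2_annot, ht12_annot)) {
    stopifnot(all(c("probe_id", "sequence") %in% names(a)))
    if (anyDuplicated(a$sequence)) {
      stop("duplicate probe sequence within one platform: ",
           a$sequence[duplicated(a$sequence)][1L])
    }
  }
  shared <- match(h8v2_annot$sequence, ht12_annot$sequence)
  h8_unified <- ifelse(!is.na(shared),
                       ht12_annot$probe_id[shared],
                       paste0(prefix, h8v2_annot$probe_id))
  id_map <- rbind(
    data.frame(platform = "HT12", original_id = ht12_annot$probe_id,
               unified_id = ht12_annot$probe_id),
    data.frame(platform = "H8v2", original_id = h8v2_annot$probe_id,
               unified_id = h8_unified))
  ann <- data.frame(
    probe_id = c(ht12_annot$probe_id, h8_unified[is.na(shared)]),
    sequence = c(ht12_annot$sequence, h8v2_annot$sequence[is.na(shared)]),
    platforms = c(ifelse(ht12_annot$sequence %in% h8v2_annot$sequence,
                         "HT12,H8v2", "HT12"),
                  rep("H8v2", sum(is.na(shared)))))
  stopifnot(!anyDuplicated(ann$probe_id))
  list(annotation = ann, id_map = id_map)
}
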