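# TSV interchange: matrices are written feature x sample with the feature id
# in the first column and a header row of sample ids; tables are plain TSV
# with a header. All coordinates are 1-based inclusive.

#' Write a feature-by-sample matrix as TSV
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_name Header for the feature-id column.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "id") {
  dt <- data.table::as.data.table(mat, keep.rownames = id_name)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#' @param path Input path (first column = feature id).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE),
    warning = function(w) stop("malformed TSV '", path, "': ",
                               conditionMessage(w)))
  ids <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(mat) <- ids
  mat
}

#' Write a data frame as TSV
#' @export
#' @param df Data frame.
#' @param path Output path.
write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a data frame from TSV
#' @export
#' @param path Input path.
read_table_tsv <- function(path) {
  as.data.frame(tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE),
    warning = function(w) stop("malformed TSV '", path, "': ",
                               conditionMessage(w))))
}

#' Write probe sequences as FASTA
#' @param probe_annot Probe annotation with `probe_id` and `sequence`.
#' @param path Output path.
#' @export
write_probe_fasta <- function(probe_annot, path) {
  ss <- Biostrings::DNAStringSet(probe_annot$sequence)
  names(ss) <- probe_annot$probe_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a synthetic study bundle to a directory
#'
#' Emits genotype, SNP-map, per-platform expression, probe-annotation,
#' probe-FASTA, trait-catalog, alignment-hit and truth-table files plus a
#' `study.yaml` config pointing at them.
#'
#' @param study Bundle from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Path of the written `study.yaml`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(study$geno, p("genotypes.tsv"), id_name = "snp")
  write_table_tsv(study$snp_annot, p("snp_map.tsv"))
  expr_files <- list()
  for (plat in names(study$expr_raw)) {
    f <- paste0("expression_", plat, ".tsv")
    write_matrix_tsv(study$expr_raw[[plat]], p(f), id_name = "probe_id")
    expr_files[[plat]] <- f
  }
  write_table_tsv(study$probe_annot, p("probe_annotation.tsv"))
  write_probe_fasta(study$probe_annot, p("probes.fasta"))
  write_table_tsv(study$trait_catalog, p("trait_catalog.tsv"))
  write_table_tsv(study$hits, p("alignment_hits.tsv"))
  write_table_tsv(study$truth$effects, p("truth_effects.tsv"))
  cfg <- list(files = c(list(genotypes = "genotypes.tsv",
                             snp_map = "snp_map.tsv",
                             probe_annotation = "probe_annotation.tsv",
                             probe_fasta = "probes.fasta",
                             trait_catalog = "trait_catalog.tsv",
                             alignment_hits = "alignment_hits.tsv"),
                        list(expression = expr_files)),
              seed = study$config$seed)
  yaml::write_yaml(cfg, p("study.yaml"))
  p("study.yaml")
}

#' Load and validate a study from a YAML config
#'
#' Reads every referenced file, checks the sample intersection between
#' genotypes and expression, warns on dropped samples, and aligns sample
#' order.
#'
#' @param config_path Path to a `study.yaml` written by [write_study()] (or
#'   hand-authored with the same keys).
#' @return Study bundle: `geno`, `snp_annot`, `expr_raw` (per platform),
#'   `probe_annot`, `trait_catalog`, `hits`, `platform_of`, `seed`,
#'   `n_dropped_samples`.
#' @export
load_study <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  p <- function(f) {
    fp <- file.path(base, f)
    if (!file.exists(fp)) stop("referenced file does not exist: ", fp)
    fp
  }
  geno <- read_matrix_tsv(p(cfg$files$genotypes))
  if (anyDuplicated(rownames(geno)) || anyDuplicated(colnames(geno))) {
    stop("duplicate SNP or sample ids in genotype matrix")
  }
  expr_raw <- lapply(cfg$files$expression, function(f) read_matrix_tsv(p(f)))
  n_dropped <- 0L
  platform_of <- character(0)
  for (plat in names(expr_raw)) {
    e <- expr_raw[[plat]]
    if (anyDuplicated(colnames(e))) stop("duplicate sample ids in ", plat)
    keep <- colnames(e) %in% colnames(geno)
    if (any(!keep)) {
      warning(sum(!keep), " expression sample(s) absent from genotypes dropped (",
              plat, ")")
      n_dropped <- n_dropped + sum(!keep)
      e <- e[, keep, drop = FALSE]
    }
    if (ncol(e) == 0L) stop("empty sample intersection for platform ", plat)
    expr_raw[[plat]] <- e
    platform_of[colnames(e)] <- plat
  }
  list(geno = geno,
       snp_annot = read_table_tsv(p(cfg$files$snp_map)),
       expr_raw = expr_raw,
       probe_annot = read_table_tsv(p(cfg$files$probe_annotation)),
       trait_catalog = if (!is.null(cfg$files$trait_catalog))
         read_table_tsv(p(cfg$files$trait_catalog)) else NULL,
       hits = if (!is.null(cfg$files$alignment_hits))
         read_table_tsv(p(cfg$files$alignment_hits)) else NULL,
       platform_of = platform_of,
       seed = cfg$seed %||% 1L,
       n_dropped_samples = n_dropped)
}
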