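#' @importFrom stats pt pf sd quantile cor.test fisher.test wilcox.test median var dist setNames
#' @importFrom utils read.delim write.table count.fields
#' @import methods
NULL

# ---------------------------------------------------------------------------
# delimiter handling

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else
    stop("cannot auto-detect delimiter (expected tab or comma) in: ", path)
}

.sep_from_dialect <- function(path, dialect) {
  switch(match.arg(dialect, c("auto", "tab", "comma")),
         auto = .detect_sep(path), tab = "\t", comma = ",")
}

# ---------------------------------------------------------------------------
# BetaMatrix: a numeric probes x samples matrix with values in [0,1] (NA ok)

#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions with probes in
#' rows and samples in columns. Every non-missing value must lie in
#' \eqn{[0, 1]}; probe and sample identifiers must be unique.
#'
#' @param x numeric matrix with rownames (probe ids) and colnames (sample ids).
#' @return `x`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix must carry probe rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate probe id: ", dup[1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample id: ", colnames(x)[duplicated(colnames(x))][1L])
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]],
                 x[bad[1L, 1L], bad[1L, 2L]]))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' The file must have a header row of sample ids; the first column holds
#' probe ids. Empty cells and `NA` become missing values. Values outside
#' \eqn{[0, 1]} are rejected with their coordinates.
#'
#' @param path file path (TSV or CSV).
#' @param dialect `"auto"` (default; tab then comma), `"tab"` or `"comma"`.
#' @return numeric matrix, probes x samples.
#' @export
load_beta_matrix <- function(path, dialect = "auto") {
  sep <- .sep_from_dialect(path, dialect)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix needs a probe-id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate probe id: ", dup[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    # non-numeric text that is not an empty cell is an error
    raw <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(is.na(m) & !(is.na(raw) | raw == "" | raw == "NA"),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric beta value at probe '%s', sample '%s'",
                   ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix as TSV
#'
#' @param x beta matrix.
#' @param path output path.
#' @param id_col name of the first (probe id) column.
#' @export
write_beta_matrix <- function(x, path, id_col = "probe_id") {
  validate_beta_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ProbeAnnotation

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `chrom`, `pos` (1-based), `snp` (logical or
#' 0/1: probe overlaps a SNP), `sex_chrom` (logical or 0/1).
#'
#' @param path TSV/CSV path.
#' @param dialect see [load_beta_matrix()].
#' @return data.frame with those five columns, `snp`/`sex_chrom` logical.
#' @export
load_annotation <- function(path, dialect = "auto") {
  sep <- .sep_from_dialect(path, dialect)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "snp", "sex_chrom")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id in annotation: ",
         df$probe_id[duplicated(df$probe_id)][1L])
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop("annotation positions must be integers >= 1")
  df$snp <- as.logical(df$snp)
  df$sex_chrom <- as.logical(df$sex_chrom)
  if (any(is.na(df$snp)) || any(is.na(df$sex_chrom)))
    stop("snp/sex_chrom flags must be logical or 0/1")
  df
}

#' Drop probes flagged as SNP-overlapping or on sex chromosomes
#'
#' Standard array cleanup: probes overlapping common SNPs and probes on the
#' X and Y chromosomes are removed before any modeling. The sample set is
#' untouched and probe order is preserved.
#'
#' @param x beta matrix.
#' @param annotation probe annotation (see [load_annotation()]).
#' @return beta matrix restricted to retained probes.
#' @export
filter_probes <- function(x, annotation) {
  validate_beta_matrix(x)
  miss <- setdiff(rownames(x), annotation$probe_id)
  if (length(miss))
    stop("probes missing from annotation: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (and %d more)", length(miss) - 5L))
  ann <- annotation[match(rownames(x), annotation$probe_id), ]
  keep <- !ann$snp & !ann$sex_chrom
  x[keep, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# SampleSheet

#' Read a sample sheet
#'
#' Columns: `sample_id`, `role` (`reference` or `tumor`), `subpopulation`
#' (reference rows only) and `ordinal` (integer rank along the
#' naive-to-mature order, reference rows only).
#'
#' @param path TSV/CSV path.
#' @param dialect see [load_beta_matrix()].
#' @return validated data.frame.
#' @export
load_sample_sheet <- function(path, dialect = "auto") {
  sep <- .sep_from_dialect(path, dialect)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "role")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"subpopulation" %in% colnames(df)) df$subpopulation <- NA_character_
  if (!"ordinal" %in% colnames(df)) df$ordinal <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df$ordinal <- as.integer(df$ordinal)
  validate_sample_sheet(df)
  df[, c("sample_id", "role", "subpopulation", "ordinal")]
}

#' Validate a sample sheet
#' @param df sample sheet data.frame.
#' @return `df`, invisibly.
#' @export
validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1L])
  if (!all(df$role %in% c("reference", "tumor")))
    stop("role must be 'reference' or 'tumor'")
  ref <- df[df$role == "reference", ]
  if (nrow(ref)) {
    if (any(is.na(ref$subpopulation)) || any(is.na(ref$ordinal)))
      stop("every reference sample needs a subpopulation and ordinal")
    tab <- table(ref$subpopulation)
    if (length(tab) < 2L)
      stop("need >= 2 reference subpopulations")
    if (any(tab < 2L))
      stop("every reference subpopulation needs >= 2 samples; offender: ",
           names(tab)[tab < 2L][1L])
    ords <- unique(ref[, c("subpopulation", "ordinal")])
    if (anyDuplicated(ords$subpopulation) || anyDuplicated(ords$ordinal))
      stop("subpopulation/ordinal mapping must be one-to-one")
  }
  invisible(df)
}

# ---------------------------------------------------------------------------
# GenomicRegionSet: BED <-> GRanges

#' Read a BED3+/BED6 interval file as a GRanges
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual 1-based closed convention. Columns 4-6 (name, score, strand), if
#' present, become `label`, `score` and the strand.
#'
#' @param path BED path (plain text, no header).
#' @param name a name for the region set, stored in `metadata(x)$name`.
#' @return `GRanges`.
#' @export
load_regions <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("empty region file: ", path)
  parts <- strsplit(lines, "[ \t]+")
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("BED line ", which(ncols < 3L)[1L], " has fewer than 3 fields")
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (any(is.na(start0)) || any(is.na(end0)))
    stop("non-numeric BED coordinate at line ",
         which(is.na(start0) | is.na(end0))[1L])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1L])
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = if (any(ncols >= 6L))
      vapply(parts, function(p) if (length(p) >= 6L && p[6L] %in% c("+", "-"))
        p[6L] else "*", "")
    else "*")
  if (any(ncols >= 4L))
    gr$label <- vapply(parts, function(p) if (length(p) >= 4L) p[4L]
                       else NA_character_, "")
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when labels or strands are informative, BED3 otherwise.
#'
#' @param gr `GRanges`.
#' @param path output path.
#' @export
write_regions <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  label <- if (!is.null(gr$label)) gr$label else rep(".", length(gr))
  if (all(strand == "*") && is.null(gr$label)) {
    df <- data.frame(chrom, start0, end0)
  } else {
    strand[strand == "*"] <- "."
    df <- data.frame(chrom, start0, end0, label, 0L, strand)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ExpressionMatrix

#' Read an expression matrix (features x samples)
#'
#' Same layout as [load_beta_matrix()] but values are normalized expression
#' (RPKM / rlog / RPM) and are not range-restricted; non-numeric cells are
#' rejected.
#'
#' @param path TSV/CSV path.
#' @param dialect see [load_beta_matrix()].
#' @return numeric matrix, features x samples.
#' @export
load_expression <- function(path, dialect = "auto") {
  sep <- .sep_from_dialect(path, dialect)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs an id column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    raw <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(is.na(m) & !(is.na(raw) | raw == "" | raw == "NA"),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression value at feature '%s', sample '%s'",
                   ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1L])
  m
}

#' Write an expression matrix as TSV
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with stable column order
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
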