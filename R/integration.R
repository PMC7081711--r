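# Linking disease-specific CpGs to transcripts: promoter windows,
# enhancer/miRNA assignment, methylation-expression correlation and
# region-set enrichment against the array background.

.probe_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$pos, width = 1L),
    probe_id = annotation$probe_id)
}

#' Promoter windows around gene TSS
#'
#' The promoter of a gene spans -2.5 kb to +0.5 kb around its TSS in
#' transcript orientation: a plus-strand TSS at position t gives the
#' 1-based span \eqn{[t - 2500, t + 500]}, a minus-strand TSS the
#' mirrored \eqn{[t - 500, t + 2500]}. Array probes are assigned by
#' position overlap.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (1-based),
#'   `strand` (`+`/`-`).
#' @param annotation optional probe annotation; when given, probes inside
#'   each window are listed.
#' @param upstream,downstream window extents in bases (defaults 2500/500).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, and
#'   `probe_ids` (comma-collapsed) plus `n_probes` when `annotation` is
#'   given.
#' @export
promoter_windows <- function(genes, annotation = NULL,
                             upstream = 2500, downstream = 500) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand: ",
         genes$strand[!genes$strand %in% c("+", "-")][1L])
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(1, start), end = end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    win <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$start, out$end))
    pr <- .probe_granges(annotation)
    hits <- GenomicRanges::findOverlaps(win, pr)
    by_win <- split(annotation$probe_id[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_len(nrow(out))))
    out$probe_ids <- vapply(by_win, paste, "", collapse = ",")
    out$n_probes <- lengths(by_win)
  }
  out
}

#' Simplify promoter segmentations and assign them to pri-miRNA TSS
#'
#' Promoter segment tracks from several sources are first simplified to
#' the regions supported by every source (per-source union, then
#' intersection across sources, then merging of touching pieces). A
#' simplified segment becomes a putative pri-miRNA promoter when it
#' overlaps the TSS or its closest edge lies within `max_distance`
#' upstream of the TSS in transcript orientation (the wide window absorbs
#' intronic miRNAs transcribed with a distant host-gene promoter).
#'
#' @param segment_sets list of `GRanges`, one per source.
#' @param mirnas data.frame with `mirna_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @param max_distance maximum upstream distance in bases, default 1e5.
#' @param combine `"intersection"` (default: segments present in all
#'   sources) or `"union"`.
#' @param annotation optional probe annotation to list probes per segment.
#' @return data.frame `mirna_id`, `chrom`, `start`, `end` (1-based
#'   segment), `distance` (0 when overlapping the TSS) and, with
#'   `annotation`, `probe_ids`/`n_probes`.
#' @export
assign_mirna_promoters <- function(segment_sets, mirnas,
                                   max_distance = 1e5,
                                   combine = c("intersection", "union"),
                                   annotation = NULL) {
  combine <- match.arg(combine)
  if (!length(segment_sets)) stop("empty segment set list")
  red <- lapply(segment_sets, function(g)
    GenomicRanges::reduce(GenomicRanges::granges(g), ignore.strand = TRUE))
  merged <- Reduce(if (combine == "intersection")
    function(a, b) GenomicRanges::intersect(a, b, ignore.strand = TRUE)
    else function(a, b) GenomicRanges::union(a, b, ignore.strand = TRUE),
    red)
  merged <- GenomicRanges::reduce(merged, min.gapwidth = 1L)
  if (!length(merged))
    return(data.frame(mirna_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      distance = numeric()))
  seg_chr <- as.character(GenomicRanges::seqnames(merged))
  seg_s <- GenomicRanges::start(merged)
  seg_e <- GenomicRanges::end(merged)
  rows <- lapply(seq_len(nrow(mirnas)), function(i) {
    t <- mirnas$tss[i]; chr <- mirnas$chrom[i]; st <- mirnas$strand[i]
    on_chr <- seg_chr == chr
    overlap <- on_chr & seg_s <= t & seg_e >= t
    if (st == "+") {
      ups <- on_chr & seg_e < t & (t - seg_e) <= max_distance
      dist <- ifelse(overlap, 0, t - seg_e)
    } else if (st == "-") {
      ups <- on_chr & seg_s > t & (seg_s - t) <= max_distance
      dist <- ifelse(overlap, 0, seg_s - t)
    } else stop("unknown strand: ", st)
    sel <- which(overlap | ups)
    if (!length(sel)) return(NULL)
    data.frame(mirna_id = mirnas$mirna_id[i], chrom = chr,
               start = seg_s[sel], end = seg_e[sel],
               distance = dist[sel], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      distance = numeric())
  if (!is.null(annotation) && nrow(out)) {
    win <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$start, out$end))
    pr <- .probe_granges(annotation)
    hits <- GenomicRanges::findOverlaps(win, pr)
    by_win <- split(annotation$probe_id[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_len(nrow(out))))
    out$probe_ids <- vapply(by_win, paste, "", collapse = ",")
    out$n_probes <- lengths(by_win)
  }
  rownames(out) <- NULL
  out
}

#' Correlate promoter methylation with transcript expression
#'
#' Every (feature, probe) pair in the map is tested across the samples
#' shared between the two matrices. A pair passes when `p < p_threshold`
#' and `|r| >= r_threshold`; the defaults follow the two rules used for
#' protein-coding genes (Pearson, |r| >= 0.7) and miRNAs (Spearman,
#' |rho| >= 0.35). Pairs with a constant vector on either side have no
#' defined correlation and are reported with `excluded = TRUE`.
#'
#' @param meth beta matrix.
#' @param expr expression matrix.
#' @param map data.frame with `feature_id` and `probe_id` columns (one row
#'   per pair to test), e.g. expanded from [promoter_windows()].
#' @param method `"pearson"` or `"spearman"`.
#' @param r_threshold minimum |r|; defaults to 0.7 for Pearson and 0.35
#'   for Spearman.
#' @param p_threshold significance cut-off, default 0.05.
#' @param fdr apply Benjamini-Hochberg adjustment across all tested pairs
#'   before thresholding (default FALSE: raw p, the method's convention).
#' @return data.frame `feature_id`, `probe_id`, `method`, `r`, `p_value`,
#'   `passes`, `excluded`.
#' @export
correlate <- function(meth, expr, map,
                      method = c("pearson", "spearman"),
                      r_threshold = NULL, p_threshold = 0.05,
                      fdr = FALSE) {
  method <- match.arg(method)
  if (is.null(r_threshold))
    r_threshold <- if (method == "pearson") 0.7 else 0.35
  shared <- intersect(colnames(meth), colnames(expr))
  if (length(shared) < 4L)
    stop("need >= 4 shared samples between methylation and expression")
  rows <- lapply(seq_len(nrow(map)), function(i) {
    f <- map$feature_id[i]; p <- map$probe_id[i]
    if (!f %in% rownames(expr) || !p %in% rownames(meth))
      return(data.frame(feature_id = f, probe_id = p, method = method,
                        r = NA_real_, p_value = NA_real_,
                        passes = FALSE, excluded = TRUE))
    x <- meth[p, shared]; y <- expr[f, shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(feature_id = f, probe_id = p, method = method,
                        r = NA_real_, p_value = NA_real_,
                        passes = FALSE, excluded = TRUE))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                    exact = FALSE))
    data.frame(feature_id = f, probe_id = p, method = method,
               r = unname(ct$estimate), p_value = ct$p.value,
               passes = NA, excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  p_sel <- if (fdr) stats::p.adjust(out$p_value, method = "BH") else
    out$p_value
  out$passes <- !out$excluded & !is.na(p_sel) & p_sel < p_threshold &
    abs(out$r) >= r_threshold
  out
}

#' Assign each region to its closest gene
#'
#' Distance is measured from the region to the gene TSS (0 when the TSS
#' falls inside the region). Ties go to the gene with the smaller TSS
#' coordinate, then to the lexicographically smaller gene id. Regions on
#' chromosomes without genes are returned unassigned and flagged.
#'
#' @param regions `GRanges`.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @return data.frame `chrom`, `start`, `end` (1-based region), `gene_id`
#'   (NA when unassigned), `distance`.
#' @export
closest_gene <- function(regions, genes) {
  chr <- as.character(GenomicRanges::seqnames(regions))
  s <- GenomicRanges::start(regions); e <- GenomicRanges::end(regions)
  rows <- lapply(seq_along(regions), function(i) {
    g <- genes[genes$chrom == chr[i], , drop = FALSE]
    if (!nrow(g))
      return(data.frame(chrom = chr[i], start = s[i], end = e[i],
                        gene_id = NA_character_, distance = NA_real_,
                        stringsAsFactors = FALSE))
    d <- pmax(0, pmax(s[i] - g$tss, g$tss - e[i]))
    o <- order(d, g$tss, g$gene_id)
    data.frame(chrom = chr[i], start = s[i], end = e[i],
               gene_id = g$gene_id[o[1L]], distance = d[o[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-set enrichment of called CpGs against the array background
#'
#' For each class label and region set, the foreground (probes of that
#' class) is compared with the full retained probe universe: the fold
#' change is the ratio of in-set proportions (foreground over background),
#' and a two-sided Fisher exact test is run on the 2x2 table of in-set
#' status versus foreground membership (background minus foreground as
#' the comparison group).
#'
#' @param calls call table ([call_classes()]).
#' @param annotation probe annotation of the retained universe (the
#'   background).
#' @param region_sets named list of `GRanges`.
#' @param classes class labels to test, default A-D.
#' @return data.frame `region_set`, `class`, `fg_hits`, `fg_total`,
#'   `bg_hits`, `bg_total`, `fold_change`, `log2_fc`, `p_value`.
#' @export
region_enrichment <- function(calls, annotation, region_sets,
                              classes = c("A", "B", "C", "D")) {
  if (is.null(names(region_sets)))
    names(region_sets) <- paste0("set", seq_along(region_sets))
  pr <- .probe_granges(annotation)
  bg_total <- nrow(annotation)
  rows <- list()
  for (set_name in names(region_sets)) {
    in_set_ids <- annotation$probe_id[
      IRanges::overlapsAny(pr, region_sets[[set_name]], ignore.strand = TRUE)]
    bg_hits <- length(in_set_ids)
    for (cl in classes) {
      fg <- calls$probe_id[calls$class == cl]
      if (!length(fg))
        stop("empty foreground for class ", cl)
      fg_hits <- sum(fg %in% in_set_ids)
      fg_total <- length(fg)
      fc <- if (bg_hits > 0) (fg_hits / fg_total) / (bg_hits / bg_total)
        else NA_real_
      tab <- matrix(c(fg_hits, fg_total - fg_hits,
                      bg_hits - fg_hits,
                      (bg_total - fg_total) - (bg_hits - fg_hits)),
                    2L, 2L)
      p <- fisher.test(tab, alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(region_set = set_name, class = cl,
                   fg_hits = fg_hits, fg_total = fg_total,
                   bg_hits = bg_hits, bg_total = bg_total,
                   fold_change = fc, log2_fc = log2(fc),
                   p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare target-gene expression between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per gene, with the direction of the
#' median shift (group 2 relative to group 1). All-tied values give p = 1.
#'
#' @param expr expression matrix.
#' @param genes gene ids to test (must be rows of `expr`).
#' @param groups named character/factor: sample id -> group, exactly two
#'   levels, >= 3 samples each.
#' @return data.frame `gene_id`, `median_1`, `median_2`, `direction`
#'   (`up`/`down`/`none`, group 2 vs group 1), `p_value`.
#' @export
compare_target_expression <- function(expr, genes, groups) {
  groups <- groups[names(groups) %in% colnames(expr)]
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop("exactly two groups required")
  g1 <- names(groups)[groups == lev[1L]]
  g2 <- names(groups)[groups == lev[2L]]
  if (length(g1) < 3L || length(g2) < 3L)
    stop("each group needs >= 3 samples")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("genes absent from expression matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  rows <- lapply(genes, function(g) {
    x <- expr[g, g1]; y <- expr[g, g2]
    if (length(unique(c(x, y))) == 1L) {
      p <- 1
    } else {
      p <- suppressWarnings(wilcox.test(x, y,
                                        alternative = "two.sided"))$p.value
    }
    m1 <- median(x); m2 <- median(y)
    data.frame(gene_id = g, median_1 = m1, median_2 = m2,
               direction = if (m2 > m1) "up" else if (m2 < m1) "down"
                 else "none",
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
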