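# Reference differentiation trajectory: dynamic-CpG selection, Manhattan
# distances, minimum-evolution phylogeny, differentiation axis, per-CpG
# linear model.

.ref_sheet <- function(sheet) {
  ref <- sheet[sheet$role == "reference", , drop = FALSE]
  if (!nrow(ref)) stop("sample sheet contains no reference samples")
  ref
}

.subpop_order <- function(sheet) {
  ref <- .ref_sheet(sheet)
  ords <- unique(ref[, c("subpopulation", "ordinal")])
  ords$subpopulation[order(ords$ordinal)]
}

# per-subpopulation mean beta profiles (probes x subpopulations)
.subpop_means <- function(ref_mat, sheet) {
  ref <- .ref_sheet(sheet)
  pops <- .subpop_order(sheet)
  out <- vapply(pops, function(p) {
    cols <- ref$sample_id[ref$subpopulation == p]
    rowMeans(ref_mat[, cols, drop = FALSE])
  }, numeric(nrow(ref_mat)))
  rownames(out) <- rownames(ref_mat)
  out
}

#' Identify differentiation-dynamic CpGs
#'
#' A CpG is dynamic when its mean beta value changes by more than
#' `delta_threshold` between the start (most naive) and end (most mature)
#' reference subpopulations and an equal-variance two-sample Student t-test
#' between those two groups gives `p < p_threshold`. Intermediate
#' subpopulations do not enter this contrast.
#'
#' @param ref beta matrix of reference samples (may contain tumors; only
#'   samples listed as reference in `sheet` are used).
#' @param sheet sample sheet (see [load_sample_sheet()]).
#' @param delta_threshold minimum absolute beta change, default 0.20
#'   (strictly greater than).
#' @param p_threshold t-test significance cut-off, default 0.05.
#' @param fdr apply Benjamini-Hochberg adjustment to the p-values before
#'   thresholding (default FALSE: raw p, the method's convention).
#' @return data.frame with columns `probe_id`, `delta` (mean end minus mean
#'   start), `p_value`, `dynamic`. Probes missing a value in any reference
#'   sample are dropped.
#' @export
identify_dynamic_cpgs <- function(ref, sheet, delta_threshold = 0.20,
                                  p_threshold = 0.05, fdr = FALSE) {
  refsheet <- .ref_sheet(sheet)
  pops <- .subpop_order(sheet)
  start_ids <- refsheet$sample_id[refsheet$subpopulation == pops[1L]]
  end_ids <- refsheet$sample_id[refsheet$subpopulation == pops[length(pops)]]
  if (length(start_ids) < 2L || length(end_ids) < 2L)
    stop("start and end subpopulations each need >= 2 samples")
  keep <- stats::complete.cases(ref[, refsheet$sample_id, drop = FALSE])
  x <- ref[keep, start_ids, drop = FALSE]
  y <- ref[keep, end_ids, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  tstat <- delta / se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  # zero variance in both groups: equal means -> no evidence (p = 1);
  # different means -> infinitely strong evidence (p = 0)
  degen <- se == 0
  p[degen & delta == 0] <- 1
  p[degen & delta != 0] <- 0
  p_sel <- if (fdr) stats::p.adjust(p, method = "BH") else p
  data.frame(probe_id = rownames(ref)[keep],
             delta = unname(delta),
             p_value = unname(p),
             dynamic = unname(abs(delta) > delta_threshold &
                                p_sel < p_threshold),
             stringsAsFactors = FALSE)
}

#' Manhattan distance matrix between samples
#'
#' \eqn{d(i,j) = \sum_p |\beta_{p,i} - \beta_{p,j}|} over the selected
#' probes.
#'
#' @param x beta matrix (probes x samples).
#' @param probes probe subset to sum over (default: all rows).
#' @return symmetric numeric matrix with zero diagonal, labeled by sample.
#' @export
manhattan_distances <- function(x, probes = rownames(x)) {
  if (!length(probes)) stop("empty probe subset")
  miss <- setdiff(probes, rownames(x))
  if (length(miss)) stop("probes absent from matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  sub <- x[probes, , drop = FALSE]
  if (anyNA(sub)) stop("missing values among selected probes")
  as.matrix(dist(t(sub), method = "manhattan"))
}

#' Build a balanced minimum-evolution tree from a distance matrix
#'
#' Neighbor-joining start tree followed by balanced nearest-neighbor
#' interchanges under the balanced minimum-evolution criterion (the
#' `fastme.bal` algorithm of Desper and Gascuel, via \pkg{ape}); negative
#' branch lengths are clamped at zero. Two taxa yield a single edge of
#' length `d(1,2)`.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   row/column names, >= 2 taxa.
#' @return an [ape::as.phylo] unrooted tree with branch lengths.
#' @export
build_me_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) stop("distance matrix needs taxon names")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = c(d[1L, 2L] / 2, d[1L, 2L] / 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::fastme.bal(stats::as.dist(d), nni = TRUE,
                        spr = FALSE, tbr = FALSE)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Extract the linear differentiation axis from the reference tree
#'
#' The backbone is the tree path from the start (most naive) to the end
#' (most mature) subpopulation leaf. Every other subpopulation's
#' attachment point on that path defines its raw distance from the start;
#' rescaling the end point to 100 yields the differentiation stage (d.s.,
#' percent of full differentiation programming). A branchedness score (the
#' fraction of total branch length lying off the backbone) quantifies how
#' tree-like, rather than path-like, the reference continuum is.
#'
#' @param tree `phylo` tree whose tips are subpopulation names.
#' @param sheet sample sheet defining subpopulation ordinals.
#' @param branchedness_tol warn when branchedness exceeds this (default 0.2).
#' @return an object of class `coo_trajectory`: list with `tree`, `backbone`
#'   (subpopulations ordered by d.s.), `ds_map` (named numeric, start = 0,
#'   end = 100), `raw_end` (Manhattan backbone length start to end) and
#'   `branchedness`.
#' @export
derive_axis <- function(tree, sheet, branchedness_tol = 0.2) {
  pops <- .subpop_order(sheet)
  if (!all(pops %in% tree$tip.label))
    stop("tree tips must include every reference subpopulation")
  start <- pops[1L]; end <- pops[length(pops)]
  tip_idx <- match(pops, tree$tip.label)
  D <- ape::dist.nodes(tree)
  s <- tip_idx[1L]; e <- tip_idx[length(pops)]
  raw_end <- D[s, e]
  if (raw_end <= 0) stop("start and end subpopulations are indistinguishable")
  # distance from start to the attachment of x on the start-end path
  raw <- (raw_end + D[s, tip_idx] - D[tip_idx, e]) / 2
  ds <- 100 * raw / raw_end
  names(ds) <- pops
  backbone <- pops[order(ds, match(pops, pops))]
  # branch length off the start-end path
  path_nodes <- ape::nodepath(tree, s, e)
  on_path <- apply(tree$edge, 1L, function(ed) {
    i <- match(ed[1L], path_nodes); j <- match(ed[2L], path_nodes)
    !is.na(i) && !is.na(j) && abs(i - j) == 1L
  })
  total <- sum(tree$edge.length)
  branchedness <- if (total > 0) 1 - sum(tree$edge.length[on_path]) / total else 0
  if (branchedness > branchedness_tol)
    warning(sprintf(paste0("trajectory branchedness %.3f exceeds tolerance ",
                           "%.3f; the reference continuum may not be linear"),
                    branchedness, branchedness_tol))
  structure(list(tree = tree, backbone = backbone, ds_map = ds,
                 raw_end = raw_end, branchedness = branchedness),
            class = "coo_trajectory")
}

#' @export
print.coo_trajectory <- function(x, ...) {
  cat("Differentiation trajectory over",
      length(x$ds_map), "reference subpopulations\n")
  cat("  backbone:", paste(x$backbone, collapse = " -> "), "\n")
  cat("  d.s.:", paste(sprintf("%s=%.1f", names(x$ds_map), x$ds_map),
                       collapse = ", "), "\n")
  cat(sprintf("  branchedness: %.3f\n", x$branchedness))
  invisible(x)
}

#' Fit the per-CpG linear model of methylation on differentiation stage
#'
#' Ordinary least squares of beta value on d.s. across all reference
#' samples, one model per CpG: \eqn{M = \alpha + \beta \cdot d.s.}. The
#' linearity verdict defaults to the overall regression F-test (equivalent
#' to the slope t-test) at `linearity_p`: a significant trend counts as
#' linear behavior. The alternative `"lack_of_fit"` test compares the
#' linear fit against the per-subpopulation-means model and calls a probe
#' linear when lack of fit is *not* significant; it is stricter against
#' monotone-but-curved programs. Coefficients are stored for every probe
#' so the model can predict the full methylome at any stage.
#'
#' @param ref beta matrix of reference samples.
#' @param sheet sample sheet.
#' @param trajectory `coo_trajectory` assigning a d.s. to every
#'   subpopulation.
#' @param linearity_p significance cut-off, default 0.05.
#' @param linearity_test `"overall"` (default) or `"lack_of_fit"`.
#' @return data.frame `probe_id`, `alpha`, `beta`, `sigma2` (residual
#'   variance), `linearity_p`, `linear`. Probes with missing reference
#'   values are dropped.
#' @export
fit_linear_model <- function(ref, sheet, trajectory, linearity_p = 0.05,
                             linearity_test = c("overall", "lack_of_fit")) {
  linearity_test <- match.arg(linearity_test)
  refsheet <- .ref_sheet(sheet)
  ds <- trajectory$ds_map[refsheet$subpopulation]
  if (anyNA(ds)) stop("every reference subpopulation needs a d.s.")
  if (length(unique(ds)) < 3L)
    stop("need >= 3 distinct d.s. values to assess linearity")
  y <- ref[, refsheet$sample_id, drop = FALSE]
  keep <- stats::complete.cases(y)
  y <- y[keep, , drop = FALSE]
  n <- length(ds)
  if (n < 4L) stop("need >= 4 reference samples")
  xc <- ds - mean(ds)
  sxx <- sum(xc^2)
  ybar <- rowMeans(y)
  beta <- as.vector(y %*% xc) / sxx
  alpha <- ybar - beta * mean(ds)
  fitted_dev <- outer(beta, xc)             # fitted minus row mean
  rss <- rowSums((y - ybar - fitted_dev)^2)
  sigma2 <- rss / (n - 2)
  if (linearity_test == "overall") {
    fstat <- beta^2 * sxx / sigma2
    pval <- pf(fstat, 1, n - 2, lower.tail = FALSE)
    pval[sigma2 == 0 & beta != 0] <- 0      # exact line
    pval[sigma2 == 0 & beta == 0] <- 1      # exact constant
    linear <- pval < linearity_p
  } else {
    grp <- factor(ds)
    k <- nlevels(grp)
    if (n - k < 1L) stop("lack-of-fit test needs replicate samples per stage")
    gm <- t(apply(y, 1L, function(r) tapply(r, grp, mean)))
    sse_pure <- rowSums((y - gm[, as.integer(grp), drop = FALSE])^2)
    fstat <- ((rss - sse_pure) / (k - 2)) / (sse_pure / (n - k))
    pval <- pf(fstat, k - 2, n - k, lower.tail = FALSE)
    pval[sse_pure == 0 & rss - sse_pure <= 1e-24] <- 1  # exact line
    pval[sse_pure == 0 & rss - sse_pure > 1e-24] <- 0
    linear <- pval >= linearity_p           # fail to reject linearity
  }
  data.frame(probe_id = rownames(y),
             alpha = unname(alpha), beta = unname(beta),
             sigma2 = unname(sigma2),
             linearity_p = unname(pval),
             linear = unname(linear),
             stringsAsFactors = FALSE)
}

#' Fit the full reference trajectory with the linearity refit
#'
#' Runs the complete reference-modeling pass: (1) dynamic-CpG selection on
#' the start-vs-end contrast; (2) minimum-evolution tree and axis on all
#' dynamic CpGs; (3) per-CpG linear model and linearity filter; (4) exactly
#' one refit: tree, axis and model are rebuilt on the linear-and-dynamic
#' CpG set only. Coefficients of the final model cover every retained
#' probe.
#'
#' @inheritParams identify_dynamic_cpgs
#' @param linearity_p linearity F-test cut-off, default 0.05.
#' @param linearity_test see [fit_linear_model()].
#' @param refit rebuild tree/axis/model on linear dynamic CpGs (default
#'   TRUE).
#' @return list of class `coo_fit`: `dynamic` (table with linearity columns
#'   merged in), `trajectory` (final), `model` (final, all probes),
#'   `first_pass` (list with the pre-refit trajectory and model),
#'   `cpgs` (the linear dynamic probe ids the final tree used).
#' @export
fit_reference_trajectory <- function(ref, sheet, delta_threshold = 0.20,
                                     p_threshold = 0.05, linearity_p = 0.05,
                                     linearity_test = "overall",
                                     refit = TRUE) {
  validate_sample_sheet(sheet)
  dyn <- identify_dynamic_cpgs(ref, sheet, delta_threshold, p_threshold)
  dyn_ids <- dyn$probe_id[dyn$dynamic]
  if (!length(dyn_ids)) stop("no dynamic CpGs at the given thresholds")
  means <- .subpop_means(ref[, , drop = FALSE], sheet)
  d1 <- manhattan_distances(means, dyn_ids)
  traj1 <- derive_axis(build_me_tree(d1), sheet)
  model1 <- fit_linear_model(ref, sheet, traj1, linearity_p, linearity_test)
  dyn$linear <- model1$linear[match(dyn$probe_id, model1$probe_id)] & dyn$dynamic
  dyn$linearity_p <- model1$linearity_p[match(dyn$probe_id, model1$probe_id)]
  if (!refit)
    return(structure(list(dynamic = dyn, trajectory = traj1, model = model1,
                          first_pass = NULL, cpgs = dyn_ids),
                     class = "coo_fit"))
  lin_ids <- dyn$probe_id[dyn$dynamic & dyn$linear %in% TRUE]
  if (!length(lin_ids)) stop("no linear dynamic CpGs; cannot refit")
  d2 <- manhattan_distances(means, lin_ids)
  traj2 <- derive_axis(build_me_tree(d2), sheet)
  model2 <- fit_linear_model(ref, sheet, traj2, linearity_p, linearity_test)
  structure(list(dynamic = dyn, trajectory = traj2, model = model2,
                 first_pass = list(trajectory = traj1, model = model1),
                 cpgs = lin_ids),
            class = "coo_fit")
}

#' @export
print.coo_fit <- function(x, ...) {
  cat("Cell-of-origin reference fit\n")
  cat(sprintf("  dynamic CpGs: %d of %d (%.1f%%)\n",
              sum(x$dynamic$dynamic), nrow(x$dynamic),
              100 * mean(x$dynamic$dynamic)))
  lin <- sum(x$dynamic$linear %in% TRUE)
  cat(sprintf("  linear dynamic CpGs: %d (%.1f%% of dynamic)\n", lin,
              100 * lin / max(1L, sum(x$dynamic$dynamic))))
  print(x$trajectory)
  invisible(x)
}
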