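# Placement of tumor samples on the normal differentiation trajectory and
# inference of the per-sample cell-of-origin methylome.

.place_one_phylo <- function(profile, means, traj, cpgs) {
  aug <- cbind(means[cpgs, , drop = FALSE], `__tumor__` = profile[cpgs])
  d <- as.matrix(dist(t(aug), method = "manhattan"))
  tr <- build_me_tree(d)
  pops <- colnames(means)
  tip_idx <- match(pops, tr$tip.label)
  t_idx <- match("__tumor__", tr$tip.label)
  D <- ape::dist.nodes(tr)
  s <- tip_idx[1L]; e <- tip_idx[length(pops)]
  raw_end <- D[s, e]
  raw <- (raw_end + D[s, t_idx] - D[t_idx, e]) / 2
  c(ds = 100 * raw / raw_end, dist = D[s, t_idx] - raw)
}

.place_joint_phylo <- function(profiles, means, traj, cpgs) {
  stopifnot(is.matrix(profiles))
  aug <- cbind(means[cpgs, , drop = FALSE], profiles[cpgs, , drop = FALSE])
  d <- as.matrix(dist(t(aug), method = "manhattan"))
  tr <- build_me_tree(d)
  pops <- colnames(means)
  tip_idx <- match(pops, tr$tip.label)
  D <- ape::dist.nodes(tr)
  s <- tip_idx[1L]; e <- tip_idx[length(pops)]
  raw_end <- D[s, e]
  t_idx <- match(colnames(profiles), tr$tip.label)
  raw <- (raw_end + D[s, t_idx] - D[t_idx, e]) / 2
  data.frame(sample_id = colnames(profiles),
             ds = 100 * raw / raw_end,
             placement_distance = D[s, t_idx] - raw,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Place tumor samples on the normal differentiation trajectory
#'
#' Two placement methods are available. `"phylogenetic"` (default) adds
#' each tumor, one at a time, to the reference subpopulation tree on the
#' linear dynamic CpGs (balanced minimum evolution, as for the reference
#' tree); the differentiation stage is the backbone distance from the
#' naive endpoint to the tumor branch's attachment point, rescaled to the
#' trajectory's 0-100 scale, and the placement distance is the remaining
#' path length from the attachment point to the tumor leaf. Adding tumors
#' singly keeps one aberrant sample from distorting another's placement.
#' `"projection"` slides the per-CpG linear model along a d.s. grid (step
#' 0.1, range 0 to `ds_max`) and takes the stage minimizing the Manhattan
#' distance between the tumor profile and the predicted methylome, which
#' permits extrapolation beyond the mature endpoint.
#'
#' @param tumors beta matrix of tumor samples.
#' @param ref beta matrix of reference samples.
#' @param sheet sample sheet.
#' @param trajectory fitted `coo_trajectory`.
#' @param cpgs linear dynamic probe ids the trajectory was built on.
#' @param method `"phylogenetic"` or `"projection"`.
#' @param model per-CpG linear model table (required for projection).
#' @param ds_max upper bound of the projection grid, default 120 (mild
#'   extrapolation past the mature endpoint, capped to keep the linear
#'   model in a plausible range).
#' @param max_missing maximum tolerated fraction of missing placement CpGs
#'   per tumor, default 0.2.
#' @return data.frame `sample_id`, `ds`, `placement_distance`.
#' @export
place_samples <- function(tumors, ref, sheet, trajectory, cpgs,
                          method = c("phylogenetic", "projection"),
                          model = NULL, ds_max = 120, max_missing = 0.2) {
  method <- match.arg(method)
  miss <- setdiff(cpgs, rownames(tumors))
  if (length(miss)) stop("placement CpGs absent from tumor matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  na_frac <- colMeans(is.na(tumors[cpgs, , drop = FALSE]))
  if (any(na_frac > max_missing))
    stop("tumor sample missing > ", round(100 * max_missing),
         "% of placement CpGs: ",
         colnames(tumors)[which.max(na_frac)])
  means <- .subpop_means(ref, sheet)
  if (method == "phylogenetic") {
    # impute the rare missing placement value with the probe's reference
    # mean so the Manhattan sums stay comparable across samples
    sub <- tumors[cpgs, , drop = FALSE]
    if (anyNA(sub)) {
      fill <- rowMeans(means[cpgs, , drop = FALSE])
      idx <- which(is.na(sub), arr.ind = TRUE)
      sub[idx] <- fill[idx[, 1L]]
    }
    res <- t(vapply(colnames(sub), function(sm)
      .place_one_phylo(sub[, sm], means, trajectory, cpgs),
      c(ds = 0, dist = 0)))
    out <- data.frame(sample_id = colnames(sub), ds = res[, "ds"],
                      placement_distance = res[, "dist"],
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    if (is.null(model)) stop("projection placement needs the linear model")
    mrows <- match(cpgs, model$probe_id)
    if (anyNA(mrows)) stop("model lacks coefficients for placement CpGs")
    alpha <- model$alpha[mrows]; beta <- model$beta[mrows]
    grid <- seq(0, ds_max, by = 0.1)
    pred <- pmin(pmax(outer(alpha, rep(1, length(grid))) +
                        outer(beta, grid), 0), 1)
    sub <- tumors[cpgs, , drop = FALSE]
    out <- do.call(rbind, lapply(colnames(sub), function(sm) {
      v <- sub[, sm]
      ok <- !is.na(v)
      dd <- colSums(abs(pred[ok, , drop = FALSE] - v[ok]))
      i <- which.min(dd)
      data.frame(sample_id = sm, ds = grid[i], placement_distance = dd[i],
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Cross-validate cell-of-origin placement by cohort resampling
#'
#' Per repetition the tumor cohort is split 70/30: the larger group is
#' drawn with replacement (duplicates collapse to one sample), the
#' smaller group is the untouched remainder, and every sample in each
#' group is re-placed on the trajectory. Quartiles of the per-repetition
#' stages measure the stability of each sample's cell-of-origin call
#' against cohort composition.
#'
#' Under the default `placement = "single"` each sample is re-placed with
#' the same cohort-independent operator as [place_samples()], so a
#' sample's assignment cannot be moved by its companions and the
#' cross-validated distribution collapses onto the point estimate — the
#' stability property holds by construction. `placement = "joint"`
#' instead places each subgroup jointly (all members in one
#' minimum-evolution tree with the reference subpopulations), emulating a
#' pooled analysis whose assignments do depend on cohort composition;
#' stage estimates under this mode carry a cohort-size-dependent bias, so
#' its quartiles quantify companionship sensitivity rather than pure
#' noise.
#'
#' @inheritParams place_samples
#' @param reps number of repetitions (default 5000; reduce for quick runs).
#' @param split fraction in the with-replacement group, default 0.70.
#' @param seed integer seed for the resampling.
#' @param placement `"single"` (default) or `"joint"`, see Details.
#' @return data.frame `sample_id`, `q1`, `median`, `q3`, `n_reps` (number
#'   of repetition-group placements of the sample).
#' @export
cross_validate <- function(tumors, ref, sheet, trajectory, cpgs,
                           reps = 5000, split = 0.70, seed = 1L,
                           placement = c("single", "joint")) {
  placement <- match.arg(placement)
  if (reps < 2L) stop("reps must be >= 2")
  n <- ncol(tumors)
  if (n < 4L) stop("need >= 4 tumor samples for cross-validation")
  means <- .subpop_means(ref, sheet)
  sub <- tumors[cpgs, , drop = FALSE]
  if (anyNA(sub)) {
    fill <- rowMeans(means[cpgs, , drop = FALSE])
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- fill[idx[, 1L]]
  }
  ids <- colnames(sub)
  single_ds <- NULL
  if (placement == "single") {
    single_ds <- setNames(vapply(ids, function(sm)
      .place_one_phylo(sub[, sm], means, trajectory, cpgs)[["ds"]],
      0), ids)
  }
  acc <- vector("list", n); names(acc) <- ids
  set.seed(seed)
  k <- max(2L, round(split * n))
  for (r in seq_len(reps)) {
    grp1 <- unique(sample(ids, k, replace = TRUE))
    grp2 <- setdiff(ids, grp1)
    for (g in list(grp1, grp2)) {
      if (length(g) < 1L) next
      ds <- if (placement == "single") single_ds[g] else
        setNames(.place_joint_phylo(sub[, g, drop = FALSE], means,
                                    trajectory, cpgs)$ds, g)
      for (sm in g) acc[[sm]] <- c(acc[[sm]], ds[[sm]])
    }
  }
  out <- do.call(rbind, lapply(ids, function(sm) {
    q <- quantile(acc[[sm]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(sample_id = sm, q1 = q[1L], median = q[2L], q3 = q[3L],
               n_reps = length(acc[[sm]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Infer the virtual cell-of-origin methylome of a sample
#'
#' Applies the per-CpG linear model at the sample's differentiation stage:
#' \eqn{M_p = \alpha_p + \beta_p \cdot d.s.}, clipped to \eqn{[0, 1]}.
#' Every modeled probe gets a value, including non-dynamic probes (whose
#' slope is near zero).
#'
#' @param model per-CpG linear model table ([fit_linear_model()]).
#' @param assignment data.frame with `sample_id` and `ds`
#'   ([place_samples()]).
#' @return beta matrix of inferred methylomes, probes x samples.
#' @export
infer_coo_methylome <- function(model, assignment) {
  m <- outer(model$beta, assignment$ds) + model$alpha
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(model$probe_id, assignment$sample_id)
  m
}
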