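# Disease-specific CpG calling: per-sample deviation from the inferred
# cell-of-origin methylome, classified into classes A-D.

#' Per-sample deviation from the cell-of-origin methylome
#'
#' \eqn{\Delta_{p,s} = observed_{p,s} - M_{p,s}}, the observed tumor beta
#' value minus the inferred cell-of-origin value, per probe and sample.
#'
#' @param tumors beta matrix of tumor samples.
#' @param coo inferred cell-of-origin methylomes ([infer_coo_methylome()]),
#'   same probe universe, one column per tumor.
#' @return numeric matrix of deltas in \eqn{[-1, 1]}, probes x samples
#'   (missing observations stay missing).
#' @export
compute_deltas <- function(tumors, coo) {
  miss <- setdiff(colnames(tumors), colnames(coo))
  if (length(miss))
    stop("no cell-of-origin methylome for sample(s): ",
         paste(miss, collapse = ", "))
  probes <- intersect(rownames(coo), rownames(tumors))
  if (!length(probes)) stop("no shared probes between tumors and model")
  tumors[probes, , drop = FALSE] -
    coo[probes, colnames(tumors), drop = FALSE]
}

#' Classify CpGs into disease-specific methylation classes A-D
#'
#' A CpG is aberrant in a patient when its methylation deviates from the
#' cell-of-origin value by strictly more than `delta_cut` (loss: delta
#' below `-delta_cut`; gain: above `+delta_cut`). A CpG becomes a
#' disease-specific call when the same direction of aberration affects at
#' least `patient_fraction` of the patients with a non-missing value.
#' Calls at differentiation-dynamic CpGs (sites with normal epigenetic
#' programming) are class A (loss) or B (gain); calls at stable CpGs are
#' class C (loss) or D (gain). With the default thresholds the four
#' classes partition the called probes; should a permissive configuration
#' (fractions <= 0.5) let both directions pass, the probe is labeled
#' `none` and flagged ambiguous.
#'
#' @param deltas delta matrix ([compute_deltas()]).
#' @param dynamic dynamic-CpG table ([identify_dynamic_cpgs()]) or a
#'   logical vector named by probe.
#' @param delta_cut aberration threshold, default 0.20 (strict).
#' @param patient_fraction required fraction of patients, default 0.75
#'   (inclusive).
#' @return data.frame `probe_id`, `dynamic`, `fraction_loss`,
#'   `fraction_gain`, `n_informative`, `class` (factor A/B/C/D/none),
#'   `ambiguous`.
#' @export
call_classes <- function(deltas, dynamic, delta_cut = 0.20,
                         patient_fraction = 0.75) {
  if (ncol(deltas) == 0L) stop("no tumor samples in delta matrix")
  if (is.data.frame(dynamic)) {
    dyn <- setNames(dynamic$dynamic, dynamic$probe_id)
  } else dyn <- dynamic
  dyn_v <- dyn[rownames(deltas)]
  dyn_v[is.na(dyn_v)] <- FALSE        # unassessed probes count as stable
  n_inf <- rowSums(!is.na(deltas))
  loss <- rowSums(deltas < -delta_cut, na.rm = TRUE)
  gain <- rowSums(deltas > delta_cut, na.rm = TRUE)
  f_loss <- ifelse(n_inf > 0, loss / n_inf, 0)
  f_gain <- ifelse(n_inf > 0, gain / n_inf, 0)
  pass_loss <- n_inf > 0 & f_loss >= patient_fraction
  pass_gain <- n_inf > 0 & f_gain >= patient_fraction
  ambiguous <- pass_loss & pass_gain
  cls <- rep("none", nrow(deltas))
  sel <- pass_loss & !ambiguous
  cls[sel] <- ifelse(dyn_v[sel], "A", "C")
  sel <- pass_gain & !ambiguous
  cls[sel] <- ifelse(dyn_v[sel], "B", "D")
  data.frame(probe_id = rownames(deltas),
             dynamic = unname(dyn_v),
             fraction_loss = unname(f_loss),
             fraction_gain = unname(f_gain),
             n_informative = unname(n_inf),
             class = factor(cls, levels = c("A", "B", "C", "D", "none")),
             ambiguous = unname(ambiguous),
             stringsAsFactors = FALSE)
}

#' Summarize disease-specific methylation calls
#'
#' @param calls call table ([call_classes()]).
#' @param deltas optional delta matrix for the per-sample, per-class mean
#'   and SD of deviation.
#' @return list with `counts` (named A/B/C/D/none), `n_hypo` (A + C),
#'   `n_hyper` (B + D), `n_calls`, and, when `deltas` is given,
#'   `per_sample`: data.frame `sample_id`, `class`, `mean_delta`,
#'   `sd_delta`.
#' @export
summarize_classes <- function(calls, deltas = NULL) {
  counts <- table(calls$class)
  out <- list(counts = setNames(as.integer(counts), names(counts)),
              n_hypo = sum(counts[c("A", "C")]),
              n_hyper = sum(counts[c("B", "D")]),
              n_calls = sum(counts[c("A", "B", "C", "D")]))
  if (!is.null(deltas)) {
    per <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(cl) {
      probes <- calls$probe_id[calls$class == cl]
      if (!length(probes)) return(NULL)
      sub <- deltas[probes, , drop = FALSE]
      data.frame(sample_id = colnames(sub), class = cl,
                 mean_delta = colMeans(sub, na.rm = TRUE),
                 sd_delta = apply(sub, 2L, sd, na.rm = TRUE),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    out$per_sample <- per
  }
  out
}
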