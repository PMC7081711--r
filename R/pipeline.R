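# End-to-end orchestration: filter -> dynamic CpGs -> tree/axis ->
# linearity -> refit -> placement -> cell-of-origin inference -> class
# calling -> correlation -> enrichment, with a deterministic manifest.

#' Build a pipeline run configuration
#'
#' Every threshold defaults to the method's standard value: 0.20 beta
#' change for dynamic and aberrant CpGs, 75% of patients for a call,
#' p < 0.05 throughout, |r| thresholds 0.7 (Pearson, genes) and 0.35
#' (Spearman, miRNAs).
#'
#' @param beta path to the beta matrix (or the matrix itself).
#' @param sheet path to the sample sheet (or data.frame).
#' @param annotation path to the probe annotation (or data.frame).
#' @param genes optional gene TSS table path/data.frame for promoter
#'   correlation.
#' @param expr_tumor optional tumor expression matrix (path or matrix).
#' @param regions optional named list of BED paths or `GRanges` for
#'   enrichment.
#' @param outdir output directory.
#' @param delta_threshold,p_threshold,linearity_p,delta_cut,patient_fraction,r_threshold,corr_p
#'   thresholds, see the stage functions.
#' @param placement_method `"phylogenetic"` or `"projection"`.
#' @param cv_reps cross-validation repetitions (0 disables; the method's
#'   standard full run uses 5000).
#' @param cv_split fraction in the with-replacement group, default 0.70.
#' @param seed integer seed (cross-validation resampling).
#' @return list of class `run_config`.
#' @export
run_config <- function(beta, sheet, annotation, genes = NULL,
                       expr_tumor = NULL, regions = NULL,
                       outdir = tempfile("methylCOO_run_"),
                       delta_threshold = 0.20, p_threshold = 0.05,
                       linearity_p = 0.05, delta_cut = 0.20,
                       patient_fraction = 0.75, r_threshold = 0.7,
                       corr_p = 0.05,
                       placement_method = "phylogenetic",
                       cv_reps = 0L, cv_split = 0.70, seed = 1L) {
  thr <- c(delta_threshold, p_threshold, linearity_p, delta_cut,
           patient_fraction, r_threshold, corr_p, cv_split)
  if (any(thr <= 0 | thr >= 1))
    stop("all thresholds must lie strictly within (0,1)")
  structure(as.list(environment()), class = "run_config")
}

.load_if_path <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    loader(x)
  } else x
}

#' Run the full cell-of-origin pipeline
#'
#' Executes probe filtering, dynamic-CpG selection, trajectory fitting
#' with the linearity refit, tumor placement, cell-of-origin methylome
#' inference, class A-D calling and, when the inputs are provided,
#' promoter correlation and region-set enrichment. All intermediate
#' tables are written to `config$outdir` as TSV together with a run
#' manifest; identical config and seed give byte-identical outputs.
#'
#' @param config `run_config` object.
#' @return invisibly, a list with all in-memory results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  beta <- .load_if_path(config$beta, load_beta_matrix)
  sheet <- .load_if_path(config$sheet, load_sample_sheet)
  annotation <- .load_if_path(config$annotation, load_annotation)
  validate_sample_sheet(sheet)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  beta <- filter_probes(beta, annotation)
  annotation <- annotation[match(rownames(beta), annotation$probe_id), ]
  ref_ids <- sheet$sample_id[sheet$role == "reference"]
  tumor_ids <- sheet$sample_id[sheet$role == "tumor"]
  if (!all(c(ref_ids, tumor_ids) %in% colnames(beta)))
    stop("stage filter: sample sheet names samples absent from beta matrix")
  ref <- beta[, ref_ids, drop = FALSE]
  tumors <- beta[, tumor_ids, drop = FALSE]

  fit <- fit_reference_trajectory(ref, sheet,
                                  delta_threshold = config$delta_threshold,
                                  p_threshold = config$p_threshold,
                                  linearity_p = config$linearity_p)
  dyn_out <- fit$dynamic
  dyn_out$linearity_p <- signif(dyn_out$linearity_p, 10)
  write_tsv(dyn_out, file.path(config$outdir, "dynamic_cpgs.tsv"))
  write_tsv(fit$model, file.path(config$outdir, "linear_model.tsv"))
  ape::write.tree(fit$trajectory$tree,
                  file.path(config$outdir, "trajectory.nwk"))
  write_tsv(data.frame(subpopulation = names(fit$trajectory$ds_map),
                       ds = as.numeric(fit$trajectory$ds_map)),
            file.path(config$outdir, "differentiation_stages.tsv"))

  assign <- NULL; coo <- NULL; deltas <- NULL; calls <- NULL
  cv <- NULL; corr <- NULL; enrich <- NULL
  if (length(tumor_ids)) {
    assign <- place_samples(tumors, ref, sheet, fit$trajectory, fit$cpgs,
                            method = config$placement_method,
                            model = fit$model)
    if (config$cv_reps >= 2L) {
      cv <- cross_validate(tumors, ref, sheet, fit$trajectory, fit$cpgs,
                           reps = config$cv_reps, split = config$cv_split,
                           seed = config$seed)
      assign <- merge(assign, cv[, c("sample_id", "q1", "median", "q3")],
                      by = "sample_id", sort = FALSE)
    }
    write_tsv(assign, file.path(config$outdir, "coo_assignments.tsv"))
    coo <- infer_coo_methylome(fit$model, assign)
    write_beta_matrix(coo, file.path(config$outdir, "coo_methylome.tsv"))
    deltas <- compute_deltas(tumors[rownames(coo), , drop = FALSE], coo)
    calls <- call_classes(deltas, fit$dynamic,
                          delta_cut = config$delta_cut,
                          patient_fraction = config$patient_fraction)
    write_tsv(calls, file.path(config$outdir, "class_calls.tsv"))
    summ <- summarize_classes(calls, deltas)
    write_tsv(data.frame(class = names(summ$counts),
                         n = as.integer(summ$counts)),
              file.path(config$outdir, "class_summary.tsv"))

    if (!is.null(config$genes) && !is.null(config$expr_tumor)) {
      genes <- .load_if_path(config$genes,
                             function(p) read.delim(p,
                                                    stringsAsFactors = FALSE))
      expr <- .load_if_path(config$expr_tumor, load_expression)
      called <- calls$probe_id[calls$class != "none"]
      prom <- promoter_windows(genes, annotation)
      map <- do.call(rbind, lapply(seq_len(nrow(prom)), function(i) {
        ids <- strsplit(prom$probe_ids[i], ",", fixed = TRUE)[[1L]]
        ids <- intersect(ids, called)
        if (!length(ids)) return(NULL)
        data.frame(feature_id = prom$gene_id[i], probe_id = ids,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(map) && nrow(map)) {
        corr <- correlate(tumors, expr, map, method = "pearson",
                          r_threshold = config$r_threshold,
                          p_threshold = config$corr_p)
        corr$r <- signif(corr$r, 10)
        corr$p_value <- signif(corr$p_value, 10)
        write_tsv(corr, file.path(config$outdir, "promoter_correlation.tsv"))
      }
    }

    if (!is.null(config$regions)) {
      regions <- lapply(config$regions,
                        function(r) .load_if_path(r, load_regions))
      present <- levels(droplevels(calls$class[calls$class != "none"]))
      if (length(present)) {
        enrich <- region_enrichment(calls, annotation, regions,
                                    classes = present)
        enrich$p_value <- signif(enrich$p_value, 10)
        write_tsv(enrich, file.path(config$outdir, "region_enrichment.tsv"))
      }
    }
  }

  manifest <- data.frame(
    key = c("package_version", "seed", "delta_threshold", "p_threshold",
            "linearity_p", "delta_cut", "patient_fraction",
            "placement_method", "cv_reps",
            "n_probes_retained", "n_reference", "n_tumors",
            "n_dynamic", "n_linear_dynamic",
            "n_calls_A", "n_calls_B", "n_calls_C", "n_calls_D"),
    value = c(as.character(utils::packageVersion("methylCOO")),
              config$seed, config$delta_threshold, config$p_threshold,
              config$linearity_p, config$delta_cut,
              config$patient_fraction, config$placement_method,
              config$cv_reps,
              nrow(beta), length(ref_ids), length(tumor_ids),
              sum(fit$dynamic$dynamic), length(fit$cpgs),
              if (is.null(calls)) rep(NA_integer_, 4L) else
                as.integer(table(calls$class)[c("A", "B", "C", "D")])),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))

  invisible(list(fit = fit, assignments = assign, coo = coo,
                 deltas = deltas, calls = calls, cv = cv,
                 correlation = corr, enrichment = enrich,
                 manifest = manifest, outdir = config$outdir))
}
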