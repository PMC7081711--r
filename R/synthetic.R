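# Seeded synthetic data with the statistical structure the cell-of-origin
# model assumes: a linear differentiation continuum with per-CpG
# intercept/slope programs, donor noise, non-linear contaminant CpGs, and
# tumor samples carrying planted class A-D aberrations with correlated
# expression changes.

#' Build a simulation configuration
#'
#' Defaults describe the study-scale scenario: 20,000 retained probes, six
#' reference subpopulations with three donors each, beta-scale Gaussian
#' donor noise of 0.02, and 34 tumors spread over the intermediate-to-
#' mature range of the axis carrying planted aberrations of magnitude 0.30
#' in 85% of tumors, with class counts proportioned like a loss-dominated
#' disease methylome (A 500, B 50, C 400, D 50).
#'
#' @param n_probes retained probes (SNP/sex-chromosome decoys are added on
#'   top and removed by filtering).
#' @param n_subpops reference subpopulations, equally spaced on the 0-100
#'   differentiation axis.
#' @param donors donors per subpopulation.
#' @param fraction_dynamic fraction of probes with a linear
#'   differentiation program (total beta change 0.25-0.70).
#' @param fraction_nonlinear fraction with a non-linear (sigmoidal or
#'   step) program of comparable endpoint change; together with the
#'   linear probes these are the truly differentiation-dynamic sites.
#' @param noise_sd Gaussian donor noise on the beta scale.
#' @param snp_fraction,sex_fraction decoy probes flagged for removal,
#'   as fractions of `n_probes`.
#' @param n_tumors number of tumor samples.
#' @param planted_stages differentiation stage per tumor (default: evenly
#'   spaced over 15-95).
#' @param planted_counts named vector, planted probes per class A/B/C/D.
#' @param magnitude planted aberration size on the beta scale.
#' @param carrier_fraction fraction of tumors carrying each planted event.
#' @param tumor_noise_sd Gaussian noise for tumor values (defaults to
#'   `noise_sd`).
#' @param n_corr_genes planted genes whose expression decreases with the
#'   methylation of a class-A promoter probe.
#' @param n_null_genes genes with expression independent of methylation.
#' @param expr_base,expr_slope,expr_noise_sd expression model for planted
#'   genes: `expr = expr_base + expr_slope * beta + noise` (log2-like
#'   units).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_probes = 20000L, n_subpops = 6L,
                              donors = 3L,
                              fraction_dynamic = 0.16,
                              fraction_nonlinear = 0.04,
                              noise_sd = 0.02,
                              snp_fraction = 0.01, sex_fraction = 0.01,
                              n_tumors = 34L,
                              planted_stages = NULL,
                              planted_counts = c(A = 500L, B = 50L,
                                                 C = 400L, D = 50L),
                              magnitude = 0.30,
                              carrier_fraction = 0.85,
                              tumor_noise_sd = NULL,
                              n_corr_genes = 60L, n_null_genes = 240L,
                              expr_base = 8, expr_slope = -8,
                              expr_noise_sd = 0.4,
                              seed = 1L) {
  if (is.null(planted_stages))
    planted_stages <- round(seq(15, 95, length.out = n_tumors), 1)
  if (length(planted_stages) != n_tumors)
    stop("planted_stages must have one stage per tumor")
  if (is.null(tumor_noise_sd)) tumor_noise_sd <- noise_sd
  fr <- c(fraction_dynamic, fraction_nonlinear, snp_fraction, sex_fraction,
          carrier_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (fraction_dynamic + fraction_nonlinear > 1)
    stop("dynamic + nonlinear fractions exceed 1")
  pc <- planted_counts[c("A", "B", "C", "D")]
  if (anyNA(pc)) stop("planted_counts needs names A, B, C, D")
  if (fraction_dynamic == 0 && (pc["A"] > 0 || pc["B"] > 0))
    stop("cannot plant class A/B events without dynamic CpGs")
  if (carrier_fraction < 0.75 && sum(pc) > 0)
    warning("carrier_fraction below 0.75: planted events will not reach ",
            "the default calling threshold")
  structure(list(n_probes = as.integer(n_probes),
                 n_subpops = as.integer(n_subpops),
                 donors = as.integer(donors),
                 fraction_dynamic = fraction_dynamic,
                 fraction_nonlinear = fraction_nonlinear,
                 noise_sd = noise_sd,
                 snp_fraction = snp_fraction, sex_fraction = sex_fraction,
                 n_tumors = as.integer(n_tumors),
                 planted_stages = planted_stages,
                 planted_counts = pc,
                 magnitude = magnitude,
                 carrier_fraction = carrier_fraction,
                 tumor_noise_sd = tumor_noise_sd,
                 n_corr_genes = as.integer(n_corr_genes),
                 n_null_genes = as.integer(n_null_genes),
                 expr_base = expr_base, expr_slope = expr_slope,
                 expr_noise_sd = expr_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_program_value <- function(truth, stage) {
  # program value of every probe at one stage
  v <- truth$alpha + truth$slope * stage
  nl <- truth$program == "sigmoid"
  v[nl] <- truth$alpha[nl] +
    truth$mag[nl] / (1 + exp(-(stage - 50) / 8))
  st <- truth$program == "step"
  v[st] <- truth$alpha[st] + truth$mag[st] * (stage > truth$break_at[st])
  v
}

#' Simulate the reference differentiation continuum
#'
#' Stable probes get a constant program drawn from a low/mid/high beta
#' mixture; dynamic probes follow a linear program whose total change over
#' the axis is 0.25-0.70 in either direction; non-linear contaminants
#' follow sigmoidal or single-step programs of comparable endpoint change.
#' Donor values are program value plus Gaussian noise, clipped to
#' \eqn{[0, 1]}. Decoy probes flagged as SNP-overlapping or on sex
#' chromosomes are appended so the filtering step has work to do.
#'
#' @param config `sim_config` ([simulation_config()]).
#' @return list with `beta` (probes x reference samples), `sheet`
#'   (reference rows), `annotation` (including decoys), `truth`
#'   (per-probe program table with `dynamic` and `stage` columns),
#'   `stages` (named subpopulation stages).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  n <- config$n_probes
  K <- config$n_subpops
  stages <- 100 * (seq_len(K) - 1) / (K - 1)
  pops <- sprintf("S%02d", seq_len(K))
  names(stages) <- pops

  n_dyn <- round(config$fraction_dynamic * n)
  n_nl <- round(config$fraction_nonlinear * n)
  program <- rep("stable", n)
  idx <- sample.int(n, n_dyn + n_nl)
  program[idx[seq_len(n_dyn)]] <- "linear"
  if (n_nl > 0)
    program[idx[n_dyn + seq_len(n_nl)]] <-
      sample(c("sigmoid", "step"), n_nl, replace = TRUE)

  alpha <- numeric(n); slope <- numeric(n)
  mag <- numeric(n); break_at <- rep(NA_real_, n)
  is_st <- program == "stable"
  n_st <- sum(is_st)
  comp <- sample.int(3L, n_st, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  alpha[is_st] <- c(stats::runif(n_st, 0.03, 0.25),
                    stats::runif(n_st, 0.75, 0.97),
                    stats::runif(n_st, 0.30, 0.70))[
                      (comp - 1L) * n_st + seq_len(n_st)]
  dynish <- program != "stable"
  n_d <- sum(dynish)
  m <- stats::runif(n_d, 0.25, 0.70) * sample(c(-1, 1), n_d, replace = TRUE)
  base <- stats::runif(n_d, 0.03, 0.97 - abs(m))
  alpha[dynish] <- ifelse(m > 0, base, base + abs(m))
  mag[dynish] <- m
  slope[program == "linear"] <- mag[program == "linear"] / 100
  nl_step <- program == "step"
  break_at[nl_step] <- sample(c(25, 50, 75), sum(nl_step), replace = TRUE)

  truth <- data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
                      program = program, alpha = alpha, slope = slope,
                      mag = mag, break_at = break_at,
                      stringsAsFactors = FALSE)
  ep <- .sim_program_value(truth, 100) - .sim_program_value(truth, 0)
  truth$endpoint_change <- ep
  truth$dynamic <- abs(ep) > 0.20

  sheet <- do.call(rbind, lapply(seq_len(K), function(k)
    data.frame(sample_id = sprintf("%s_d%d", pops[k], seq_len(config$donors)),
               role = "reference", subpopulation = pops[k], ordinal = k,
               stringsAsFactors = FALSE)))

  beta <- matrix(NA_real_, n, nrow(sheet),
                 dimnames = list(truth$probe_id, sheet$sample_id))
  for (k in seq_len(K)) {
    pv <- .sim_program_value(truth, stages[k])
    for (d in seq_len(config$donors)) {
      col <- sprintf("%s_d%d", pops[k], d)
      beta[, col] <- pmin(pmax(pv + stats::rnorm(n, 0, config$noise_sd),
                               0), 1)
    }
  }

  n_snp <- round(config$snp_fraction * n)
  n_sex <- round(config$sex_fraction * n)
  annotation <- data.frame(probe_id = truth$probe_id,
                           chrom = sample(paste0("chr", 1:22), n,
                                          replace = TRUE),
                           pos = sample.int(2e8, n, replace = TRUE),
                           snp = FALSE, sex_chrom = FALSE,
                           stringsAsFactors = FALSE)
  if (n_snp + n_sex > 0) {
    decoy_id <- sprintf("cgX%07d", seq_len(n_snp + n_sex))
    decoy <- data.frame(probe_id = decoy_id,
                        chrom = c(sample(paste0("chr", 1:22), n_snp,
                                         replace = TRUE),
                                  sample(c("chrX", "chrY"), n_sex,
                                         replace = TRUE)),
                        pos = sample.int(2e8, n_snp + n_sex, replace = TRUE),
                        snp = rep(c(TRUE, FALSE), c(n_snp, n_sex)),
                        sex_chrom = rep(c(FALSE, TRUE), c(n_snp, n_sex)),
                        stringsAsFactors = FALSE)
    annotation <- rbind(annotation, decoy)
    decoy_beta <- matrix(pmin(pmax(stats::runif(length(decoy_id)) +
                                     stats::rnorm(length(decoy_id) *
                                                    nrow(sheet), 0,
                                                  config$noise_sd), 0), 1),
                         length(decoy_id), nrow(sheet),
                         dimnames = list(decoy_id, sheet$sample_id))
    beta <- rbind(beta, decoy_beta)
  }

  list(beta = beta, sheet = sheet, annotation = annotation,
       truth = truth, stages = stages)
}

#' Simulate tumor methylomes and matched expression
#'
#' Each tumor arises at a planted differentiation stage: its baseline
#' methylome is the reference program evaluated there. Planted class A/C
#' probes are shifted down and B/D up by `magnitude` in a random
#' `carrier_fraction` subset of tumors (A/B at linear dynamic probes, C/D
#' at stable probes with room to shift without clipping), then Gaussian
#' noise is added and values are clipped. Expression for planted genes is
#' an affine-decreasing function of their class-A promoter-probe
#' methylation plus noise, in both tumors and reference samples; null
#' genes are independent of methylation.
#'
#' @param config `sim_config`.
#' @param ref result of [simulate_reference()].
#' @return list with `beta` (probes x tumors), `sheet` (tumor rows),
#'   `truth` (per-probe planted class and carrier count), `stages`
#'   (planted stage per tumor), `genes` (TSS table with `planted` flag and
#'   anchor probe), `expr_tumor`, `expr_ref`, `regions` (named list with a
#'   super-enhancer-like set covering many class-A probes).
#' @export
simulate_tumors <- function(config, ref) {
  set.seed(config$seed + 1L)
  truth <- ref$truth
  n <- nrow(truth)
  nt <- config$n_tumors
  stages <- config$planted_stages
  tumor_ids <- sprintf("T%02d", seq_len(nt))
  names(stages) <- tumor_ids
  mag <- config$magnitude

  # eligibility: planted shifts must not clip
  smin <- min(stages); smax <- max(stages)
  v_lo <- .sim_program_value(truth, smin)
  v_hi <- .sim_program_value(truth, smax)
  vmin <- pmin(v_lo, v_hi); vmax <- pmax(v_lo, v_hi)
  elig <- list(
    A = which(truth$program == "linear" & vmin >= mag + 0.03),
    B = which(truth$program == "linear" & vmax <= 0.97 - mag),
    C = which(truth$program == "stable" & vmin >= mag + 0.03),
    D = which(truth$program == "stable" & vmax <= 0.97 - mag))
  planted_class <- rep("none", n)
  used <- integer()
  for (cl in c("A", "B", "C", "D")) {
    k <- config$planted_counts[[cl]]
    pool <- setdiff(elig[[cl]], used)
    if (k > length(pool))
      stop("not enough eligible probes for class ", cl,
           " (need ", k, ", have ", length(pool), ")")
    pick <- sample(pool, k)
    planted_class[pick] <- cl
    used <- c(used, pick)
  }

  n_carriers <- ceiling(config$carrier_fraction * nt)
  carrier <- matrix(FALSE, n, nt, dimnames = list(truth$probe_id, tumor_ids))
  planted_idx <- which(planted_class != "none")
  for (i in planted_idx)
    carrier[i, sample.int(nt, n_carriers)] <- TRUE

  beta <- matrix(NA_real_, n, nt, dimnames = list(truth$probe_id, tumor_ids))
  shift <- ifelse(planted_class %in% c("A", "C"), -mag,
                  ifelse(planted_class %in% c("B", "D"), mag, 0))
  for (s in seq_len(nt)) {
    v <- .sim_program_value(truth, stages[s])
    v <- v + shift * carrier[, s]
    beta[, s] <- pmin(pmax(v + stats::rnorm(n, 0, config$tumor_noise_sd),
                           0), 1)
  }

  sheet <- data.frame(sample_id = tumor_ids, role = "tumor",
                      subpopulation = NA_character_, ordinal = NA_integer_,
                      stringsAsFactors = FALSE)

  tumor_truth <- data.frame(probe_id = truth$probe_id,
                            planted_class = planted_class,
                            n_carriers = ifelse(planted_class == "none", 0L,
                                                n_carriers),
                            stringsAsFactors = FALSE)

  # genes: planted ones anchored on class-A promoter probes
  a_idx <- which(planted_class == "A")
  if (config$n_corr_genes > length(a_idx))
    stop("not enough class-A probes to anchor planted genes")
  anchors <- sample(a_idx, config$n_corr_genes)
  null_pool <- setdiff(which(planted_class == "none"), anchors)
  null_anchors <- sample(null_pool, config$n_null_genes)
  ann <- ref$annotation[match(truth$probe_id, ref$annotation$probe_id), ]
  mk_genes <- function(idx, prefix, planted) {
    data.frame(gene_id = sprintf("%s%04d", prefix, seq_along(idx)),
               chrom = ann$chrom[idx],
               tss = ann$pos[idx] + 1000L,
               strand = rep("+", length(idx)),
               planted = rep(planted, length(idx)),
               anchor_probe = truth$probe_id[idx],
               stringsAsFactors = FALSE)
  }
  genes <- rbind(mk_genes(anchors, "GENE", TRUE),
                 mk_genes(null_anchors, "NULLG", FALSE))

  n_genes <- nrow(genes)
  expr_tumor <- matrix(NA_real_, n_genes, nt,
                       dimnames = list(genes$gene_id, tumor_ids))
  ref_cols <- colnames(ref$beta)
  expr_ref <- matrix(NA_real_, n_genes, length(ref_cols),
                     dimnames = list(genes$gene_id, ref_cols))
  for (g in seq_len(n_genes)) {
    p <- genes$anchor_probe[g]
    if (genes$planted[g]) {
      expr_tumor[g, ] <- config$expr_base +
        config$expr_slope * beta[p, ] +
        stats::rnorm(nt, 0, config$expr_noise_sd)
      expr_ref[g, ] <- config$expr_base +
        config$expr_slope * ref$beta[p, ref_cols] +
        stats::rnorm(length(ref_cols), 0, config$expr_noise_sd)
    } else {
      expr_tumor[g, ] <- stats::rnorm(nt, 5, 1)
      expr_ref[g, ] <- stats::rnorm(length(ref_cols), 5, 1)
    }
  }

  # a super-enhancer-like region set covering 60% of class-A probes plus
  # as many random background intervals
  cov_idx <- sample(a_idx, round(0.6 * length(a_idx)))
  se <- GenomicRanges::GRanges(
    seqnames = c(ann$chrom[cov_idx], sample(paste0("chr", 1:22),
                                            length(cov_idx), replace = TRUE)),
    ranges = IRanges::IRanges(
      start = pmax(1L, c(ann$pos[cov_idx] - 1000L,
                         sample.int(2e8, length(cov_idx)))),
      width = 2000L))
  se <- GenomicRanges::reduce(se)

  list(beta = beta, sheet = sheet, truth = tumor_truth, stages = stages,
       carrier = carrier, genes = genes,
       expr_tumor = expr_tumor, expr_ref = expr_ref,
       regions = list(synthetic_SE = se))
}

#' Simulate a complete dataset (reference plus tumors)
#'
#' @param config `sim_config`.
#' @return list with `reference`, `tumors`, combined `sheet`, combined
#'   `beta` (reference and tumor columns, including decoy probes) and
#'   `annotation`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ref <- simulate_reference(config)
  tum <- simulate_tumors(config, ref)
  decoys <- setdiff(ref$annotation$probe_id, rownames(tum$beta))
  tum_full <- rbind(tum$beta,
                    matrix(stats::runif(length(decoys) * ncol(tum$beta)),
                           length(decoys), ncol(tum$beta),
                           dimnames = list(decoys, colnames(tum$beta))))
  list(reference = ref, tumors = tum,
       sheet = rbind(ref$sheet, tum$sheet),
       beta = cbind(ref$beta, tum_full[rownames(ref$beta), , drop = FALSE]),
       annotation = ref$annotation)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"))
  write_tsv(sim$sheet, file.path(dir, "samples.tsv"))
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(sim$tumors$genes[, c("gene_id", "chrom", "tss", "strand")],
            file.path(dir, "genes.tsv"))
  write_expression(sim$tumors$expr_tumor, file.path(dir, "expr_tumor.tsv"))
  write_expression(sim$tumors$expr_ref, file.path(dir, "expr_ref.tsv"))
  for (nm in names(sim$tumors$regions))
    write_regions(sim$tumors$regions[[nm]], file.path(dir,
                                                      paste0(nm, ".bed")))
  write_tsv(sim$reference$truth, file.path(dir, "truth_reference.tsv"))
  write_tsv(sim$tumors$truth, file.path(dir, "truth_tumors.tsv"))
  write_tsv(data.frame(sample_id = names(sim$tumors$stages),
                       stage = as.numeric(sim$tumors$stages)),
            file.path(dir, "truth_stages.tsv"))
  invisible(dir)
}
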