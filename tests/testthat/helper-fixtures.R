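# Shared fixtures built in code.

# small but complete synthetic scenario for fast unit tests
small_config <- function(seed = 42L, ...) {
  defaults <- list(n_probes = 3000L, n_tumors = 12L,
                   planted_counts = c(A = 80L, B = 10L, C = 60L, D = 10L),
                   n_corr_genes = 15L, n_null_genes = 60L, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# reference sheet with k subpopulations x d donors (no beta values)
make_sheet <- function(k = 4L, d = 2L, tumors = 0L) {
  pops <- sprintf("S%02d", seq_len(k))
  ref <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(sample_id = sprintf("%s_d%d", pops[i], seq_len(d)),
               role = "reference", subpopulation = pops[i], ordinal = i,
               stringsAsFactors = FALSE)))
  if (tumors > 0L)
    ref <- rbind(ref, data.frame(sample_id = sprintf("T%02d", seq_len(tumors)),
                                 role = "tumor", subpopulation = NA,
                                 ordinal = NA, stringsAsFactors = FALSE))
  ref
}

# noiseless linear reference continuum: probes exactly alpha + slope * stage
make_linear_reference <- function(n_probes = 200L, k = 6L, d = 3L,
                                  seed = 1L, noise_sd = 0) {
  set.seed(seed)
  sheet <- make_sheet(k, d)
  stages <- 100 * (seq_len(k) - 1) / (k - 1)
  mag <- runif(n_probes, 0.25, 0.7) * sample(c(-1, 1), n_probes, TRUE)
  base <- runif(n_probes, 0.03, 0.97 - abs(mag))
  alpha <- ifelse(mag > 0, base, base + abs(mag))
  slope <- mag / 100
  beta <- sapply(sheet$sample_id, function(sm) {
    st <- stages[sheet$ordinal[sheet$sample_id == sm]]
    pmin(pmax(alpha + slope * st + rnorm(n_probes, 0, noise_sd), 0), 1)
  })
  rownames(beta) <- sprintf("cg%06d", seq_len(n_probes))
  list(beta = beta, sheet = sheet, stages = setNames(stages,
                                                     sprintf("S%02d", seq_len(k))),
       alpha = alpha, slope = slope)
}

# random additive distance matrix from a random tree with positive lengths
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}
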