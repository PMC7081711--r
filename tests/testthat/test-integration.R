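# Promoter windows, miRNA promoter assignment, correlation, closest gene,
# enrichment, group expression comparison.

test_that("promoter windows follow the -2.5kb/+0.5kb strand-aware rule", {
  genes <- data.frame(gene_id = c("g_plus", "g_minus"),
                      chrom = "chr1", tss = 100000L,
                      strand = c("+", "-"))
  w <- promoter_windows(genes)
  expect_equal(w$start[1], 97500); expect_equal(w$end[1], 100500)
  expect_equal(w$start[2], 99500); expect_equal(w$end[2], 102500)
  # strand flip mirrors the window about the TSS
  expect_equal(w$start[2] - genes$tss[2], -(w$end[1] - genes$tss[1]))
  expect_error(promoter_windows(data.frame(gene_id = "g", chrom = "chr1",
                                           tss = 5L, strand = ".")),
               "unknown strand")
})

test_that("probe-to-promoter assignment matches a brute-force scan", {
  set.seed(61)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:25),
                      chrom = sample(c("chr1", "chr2"), 25, TRUE),
                      tss = sample.int(5e5, 25),
                      strand = sample(c("+", "-"), 25, TRUE))
  ann <- data.frame(probe_id = sprintf("cg%03d", 1:400),
                    chrom = sample(c("chr1", "chr2"), 400, TRUE),
                    pos = sample.int(5e5, 400),
                    snp = FALSE, sex_chrom = FALSE)
  w <- promoter_windows(genes, ann)
  for (i in seq_len(nrow(w))) {
    want <- ann$probe_id[ann$chrom == w$chrom[i] &
                           ann$pos >= w$start[i] & ann$pos <= w$end[i]]
    got <- strsplit(w$probe_ids[i], ",", fixed = TRUE)[[1L]]
    expect_setequal(got, want)
  }
})

test_that("miRNA promoter assignment respects the 100-kb upstream window", {
  seg <- function(s, e) GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(s, e))
  segs <- list(c(seg(30000, 42000), seg(150000, 152000),
                 seg(300000, 301000)),
               c(seg(29000, 41000), seg(149000, 153000),
                 seg(300200, 300800)))
  mir <- data.frame(mirna_id = c("mirP", "mirM"),
                    chrom = "chr1", tss = c(102000L, 201000L),
                    strand = c("+", "-"))
  out <- assign_mirna_promoters(segs, mir)
  # + strand: segment ending 60kb upstream assigned; 300kb one is not
  p <- out[out$mirna_id == "mirP", ]
  expect_true(any(p$end == 41000))
  expect_false(any(p$start == 300200))
  # - strand: upstream means larger coordinates
  m <- out[out$mirna_id == "mirM", ]
  expect_true(any(m$start == 300200))
  expect_false(any(m$end == 41000))
  # intersection across sources trims to shared support
  expect_true(all(p$start >= 30000 & p$end <= 41000 |
                    p$start >= 150000))
  expect_error(assign_mirna_promoters(list(), mir), "empty segment")
})

test_that("miRNA assignment agrees with a brute-force distance scan", {
  set.seed(71)
  for (rep in 1:5) {
    k <- 30L
    s <- sort(sample.int(2e6, k))
    gr <- GenomicRanges::GRanges("chr3",
                                 IRanges::IRanges(s, s + sample.int(5000, k)))
    mir <- data.frame(mirna_id = sprintf("m%02d", 1:10), chrom = "chr3",
                      tss = sample.int(2e6, 10),
                      strand = sample(c("+", "-"), 10, TRUE))
    out <- assign_mirna_promoters(list(gr), mir, max_distance = 1e5)
    merged <- GenomicRanges::reduce(gr)
    ms <- GenomicRanges::start(merged); me <- GenomicRanges::end(merged)
    for (i in 1:10) {
      t <- mir$tss[i]
      hit <- if (mir$strand[i] == "+")
        (ms <= t & me >= t) | (me < t & t - me <= 1e5)
      else (ms <= t & me >= t) | (ms > t & ms - t <= 1e5)
      got <- out[out$mirna_id == mir$mirna_id[i], ]
      expect_setequal(got$start, ms[hit])
    }
  }
})

test_that("correlation matches closed-form oracles and excludes constants", {
  # perfect anticorrelation
  meth <- matrix(seq(0.1, 0.8, length.out = 8), 1,
                 dimnames = list("cg1", paste0("s", 1:8)))
  expr <- matrix(10 - 5 * meth[1, ], 1,
                 dimnames = list("g1", paste0("s", 1:8)))
  map <- data.frame(feature_id = "g1", probe_id = "cg1")
  out <- correlate(meth, expr, map, method = "pearson")
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_true(out$passes)
  # constant expression excluded but counted
  expr0 <- expr; expr0[1, ] <- 3
  out0 <- correlate(meth, expr0, map, method = "pearson")
  expect_true(out0$excluded); expect_false(out0$passes)

  # random pairs vs closed-form Pearson r and t-based p
  set.seed(83)
  n <- 15L
  meth <- matrix(runif(20 * n), 20,
                 dimnames = list(sprintf("cg%02d", 1:20),
                                 sprintf("s%02d", 1:n)))
  expr <- matrix(rnorm(20 * n), 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:n)))
  map <- data.frame(feature_id = sprintf("g%02d", 1:20),
                    probe_id = sprintf("cg%02d", 1:20))
  out <- correlate(meth, expr, map, method = "pearson")
  for (i in 1:20) {
    x <- meth[i, ]; y <- expr[i, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(out$r[i], r, tolerance = 1e-9)
    expect_equal(out$p_value[i], 2 * pt(-abs(tt), n - 2), tolerance = 1e-6)
  }
  # spearman: rank-transform oracle
  out_s <- correlate(meth, expr, map, method = "spearman")
  for (i in 1:20) {
    r <- cor(rank(meth[i, ]), rank(expr[i, ]))
    expect_equal(out_s$r[i], r, tolerance = 1e-9)
  }
})

test_that("closest gene assignment handles overlap, ties and empty chromosomes", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"),
                      chrom = "chr1", tss = c(1000L, 5000L, 9000L))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(4900, 2900, 20000),
                                                c(5100, 3100, 20100)))
  out <- closest_gene(gr, genes)
  expect_equal(out$gene_id[1], "gA"); expect_equal(out$distance[1], 0)
  # region equidistant (1900) from gB@1000 and gA@5000 -> smaller TSS wins
  expect_equal(out$gene_id[2], "gB"); expect_equal(out$distance[2], 1900)
  expect_equal(out$gene_id[3], "gC")
  out2 <- closest_gene(GenomicRanges::GRanges("chr9",
                                              IRanges::IRanges(1, 10)), genes)
  expect_true(is.na(out2$gene_id))

  set.seed(91)
  genes2 <- data.frame(gene_id = sprintf("g%03d", 1:50),
                       chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       tss = sample.int(1e6, 50))
  s <- sample.int(1e6, 30)
  gr2 <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 30, TRUE),
                                IRanges::IRanges(s, s + 500))
  out2 <- closest_gene(gr2, genes2)
  chr <- as.character(GenomicRanges::seqnames(gr2))
  for (i in 1:30) {
    g <- genes2[genes2$chrom == chr[i], ]
    d <- pmax(0, pmax(s[i] - g$tss, g$tss - (s[i] + 500)))
    best <- g[order(d, g$tss, g$gene_id), ][1, ]
    expect_identical(out2$gene_id[i], best$gene_id)
  }
})

test_that("region enrichment reproduces fold-change arithmetic and Fisher p", {
  # foreground 100 probes, 30 in set; background 10000 with 1000 in set
  ann <- data.frame(probe_id = sprintf("cg%05d", 1:10000),
                    chrom = "chr1", pos = seq_len(10000) * 1000L,
                    snp = FALSE, sex_chrom = FALSE)
  in_set <- seq_len(1000)            # first 1000 probes inside the region
  set_gr <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1, 1000 * 1000L + 1))
  fg <- c(sample(in_set, 30), sample(setdiff(seq_len(10000), in_set), 70))
  calls <- data.frame(probe_id = ann$probe_id,
                      class = factor(ifelse(seq_len(10000) %in% fg, "A",
                                            "none"),
                                     levels = c("A", "B", "C", "D", "none")))
  out <- region_enrichment(calls, ann, list(myset = set_gr), classes = "A")
  expect_equal(out$fold_change, 3.0, tolerance = 1e-12)
  expect_equal(out$log2_fc, log2(3), tolerance = 1e-12)
  # Fisher two-sided p from the hypergeometric mass oracle
  a <- 30; fgT <- 100; bgH <- 1000; bgT <- 10000
  tab <- c(a = a, b = fgT - a, c = bgH - a, d = (bgT - fgT) - (bgH - a))
  probs <- dhyper(0:fgT, tab["a"] + tab["c"], tab["b"] + tab["d"], fgT)
  p_or <- sum(probs[probs <= dhyper(a, tab["a"] + tab["c"],
                                    tab["b"] + tab["d"], fgT) *
                      (1 + 1e-7)])
  expect_equal(out$p_value, p_or, tolerance = 1e-6)

  # null case: fg proportion equals bg proportion
  fg_null <- c(sample(in_set, 10), sample(setdiff(seq_len(10000), in_set),
                                          90))
  calls2 <- data.frame(probe_id = ann$probe_id,
                       class = factor(ifelse(seq_len(10000) %in% fg_null,
                                             "A", "none"),
                                      levels = levels(calls$class)))
  out2 <- region_enrichment(calls2, ann, list(myset = set_gr),
                            classes = "A")
  expect_equal(out2$fold_change, 1.0, tolerance = 1e-12)
  expect_gte(out2$p_value, 0.99)

  # zero-hit foreground
  fg0 <- sample(setdiff(seq_len(10000), in_set), 50)
  calls3 <- data.frame(probe_id = ann$probe_id,
                       class = factor(ifelse(seq_len(10000) %in% fg0, "A",
                                             "none"),
                                      levels = levels(calls$class)))
  out3 <- region_enrichment(calls3, ann, list(myset = set_gr),
                            classes = "A")
  expect_equal(out3$fold_change, 0)
})

test_that("group expression comparison reproduces the exact rank-sum law", {
  e <- matrix(c(1, 2, 3, 10, 11, 12), 1,
              dimnames = list("g1", paste0("s", 1:6)))
  groups <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  out <- compare_target_expression(e, "g1", groups)
  # exhaustive enumeration over all 3-subsets of ranks
  ranks <- combn(6, 3)
  wstats <- apply(ranks, 2, sum) - 6    # W statistic of group 1
  obs <- sum(rank(e[1, ])[1:3]) - 6
  p_exact <- mean(abs(wstats - 4.5) >= abs(obs - 4.5))
  expect_equal(out$p_value, p_exact)    # = 0.1 for total separation
  expect_equal(out$p_value, 0.1)
  expect_equal(out$direction, "up")

  same <- matrix(rep(2, 6), 1, dimnames = dimnames(e))
  expect_equal(compare_target_expression(same, "g1", groups)$p_value, 1)

  set.seed(101)
  e2 <- matrix(rnorm(50 * 8), 50,
               dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  gr2 <- setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  out2 <- compare_target_expression(e2, rownames(e2), gr2)
  for (i in seq_len(50)) {
    x <- e2[i, 1:4]; y <- e2[i, 5:8]
    # exhaustive enumeration oracle
    pooled <- c(x, y); rk <- rank(pooled)
    combs <- combn(8, 4)
    ws <- apply(combs, 2, function(ix) sum(rk[ix])) - 10
    obs <- sum(rk[1:4]) - 10
    p_or <- mean(abs(ws - 8) >= abs(obs - 8) - 1e-9)
    expect_equal(out2$p_value[i], p_or, tolerance = 1e-9)
  }
})
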