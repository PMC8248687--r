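test_that("rpkm follows the closed form and its scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(5, 500, 2e6), 5)
  expect_error(rpkm(1, 0, 1e6), "positive")
  expect_error(rpkm(1, 100, 0), "positive")
  # linear in count, inverse-linear in length and library size
  expect_equal(rpkm(20, 1000, 1e6), 2 * rpkm(10, 1000, 1e6))
  expect_equal(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6) / 2)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
})

test_that("gene-body signal matches uniform expectations and the per-base oracle", {
  genes <- toy_genes(c(100, 1000), c(600, 1600))
  unif <- toy_track("chr1", 0, 2000, 3)
  gb <- gene_body_signal(unif, genes)
  expect_equal(gb$mean_density, c(3, 3))

  half <- toy_track("chr1", 100, 350, 2)   # covers half of gene 1 at 2v
  gb2 <- gene_body_signal(half, genes[1])
  expect_equal(gb2$mean_density, 1)

  set.seed(55)
  genes20 <- toy_genes(seq(0, 19) * 500, seq(0, 19) * 500 + sample(100:400, 20))
  st <- seq(0, 59) * 160
  trk <- toy_track("chr1", st, st + sample(10:150, 60, replace = TRUE),
                   runif(60, 0, 4))
  gb3 <- gene_body_signal(trk, genes20)
  for (i in seq_along(genes20)) {
    expect_equal(gb3$mean_density[i], per_base_gene_mean(trk, genes20[i]),
                 tolerance = 1e-9)
  }

  expect_warning(gene_body_signal(unif, toy_genes(0, 100, chrom = "chrX")),
                 "absent")
})

test_that("gene-body signal conserves mass over disjoint genes", {
  set.seed(56)
  genes <- toy_genes(seq(0, 9) * 1000, seq(0, 9) * 1000 + 800)
  trk <- toy_track("chr1", seq(0, 99) * 100, seq(0, 99) * 100 + 100,
                   runif(100, 0, 2))
  gb <- gene_body_signal(trk, genes)
  total <- sum(trk$score * width(trk))
  expect_lte(sum(gb$mean_density * width(genes)), total + 1e-9)
})

test_that("weighted tissue expression mixes fractions by composition", {
  expect_equal(unname(weighted_tissue_expression(c(g = 10), c(g = 0))), 6)
  expect_equal(unname(weighted_tissue_expression(c(g = 7), c(g = 7),
                                                 0.3, 0.7)), 7)
  expect_equal(unname(weighted_tissue_expression(c(g = 5), c(g = 99), 1, 0)), 5)
  expect_error(weighted_tissue_expression(c(g = 1), c(g = 1), 0.7, 0.4),
               "sum to 1")
  expect_warning(weighted_tissue_expression(c(a = 1), c(b = 1)), "only one")
})

test_that("percentile bins partition genes with remainder in the lowest bins", {
  x <- stats::setNames(runif(100), sprintf("g%03d", 1:100))
  pb <- percentile_bins(x, n_bins = 10)
  expect_equal(unname(table(pb$bin)), rep(10L, 10), ignore_attr = TRUE)
  expect_setequal(names(pb$bin), names(x))

  # 103 genes, 10 bins: three lowest bins get the extra gene
  y <- stats::setNames(runif(103), sprintf("g%03d", 1:103))
  pb2 <- percentile_bins(y, n_bins = 10)
  expect_equal(as.integer(table(pb2$bin)), c(11L, 11L, 11L, rep(10L, 7)))

  # companion equal to expression: strictly increasing bin means
  pb3 <- percentile_bins(x, companion = x, n_bins = 5)
  expect_true(all(diff(pb3$summary$mean_companion) > 0))

  z <- stats::setNames(rep(2, 10), letters[1:10])
  expect_warning(pb4 <- percentile_bins(z, n_bins = 3), "single bin")
  expect_true(all(pb4$bin == 1L))
})

test_that("gammaH2AX bin means rise with expression on synthetic data", {
  co <- perm_cohort(61, n_genes = 500, n_induced = 0, excess_delta = 1)
  pb <- percentile_bins(co$wexpr[names(co$signal)], co$signal, n_bins = 10)
  rho <- cor(pb$summary$bin, pb$summary$mean_companion, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("marker aggregate scores use geometric means and row Z-scores", {
  fpkm <- matrix(c(1, 10, 100, 2, 2, 2), nrow = 3,
                 dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  res <- marker_aggregate_score(fpkm, list(ct = c("m1", "m2", "m3")),
                                pseudocount = 0)
  expect_equal(unname(res$score["ct", "s1"]), 10)
  expect_equal(unname(res$score["ct", "s2"]), 2)
  expect_equal(unname(res$z["ct", "s1"]), 1)

  flat <- matrix(5, nrow = 2, ncol = 3,
                 dimnames = list(c("m1", "m2"), c("a", "b", "c")))
  res2 <- marker_aggregate_score(flat, list(ct = c("m1", "m2")), pseudocount = 0)
  expect_true(res2$degenerate[["ct"]])
  expect_true(all(is.nan(res2$z["ct", ])))

  ten <- matrix(c(10, 1, 1), nrow = 1, dimnames = list("m1", c("a", "b", "c")))
  res3 <- marker_aggregate_score(ten, list(ct = "m1"))
  expect_equal(unname(which.max(res3$z["ct", ])), 1L)

  expect_error(marker_aggregate_score(fpkm, list(bad = "nope")), "'bad'")
})

test_that("marker scores separate synthetic fractions by their own markers", {
  co <- perm_cohort(62, n_genes = 400, n_induced = 40, excess_delta = 1)
  fm <- co$expression$fpkm_mean
  naive <- fm[, c("NeuNpos_naive", "NeuNneg_naive")]
  # markers: genes most specific to each fraction in the naive condition
  spec <- log2((naive[, 1] + 0.1) / (naive[, 2] + 0.1))
  sets <- list(neuron = rownames(naive)[order(-spec)[1:20]],
               nonneuron = rownames(naive)[order(spec)[1:20]])
  res <- marker_aggregate_score(naive, sets)
  expect_equal(unname(which.max(res$z["neuron", ])), 1L)
  expect_equal(unname(which.max(res$z["nonneuron", ])), 2L)
})

test_that("aggregate profiles localise the apex and match hand-computed bins", {
  # triangular signal centred on the anchor midpoint
  anchors <- gr("chr1", 4990, 5010)
  tri <- toy_track("chr1", seq(4000, 5990, by = 10), seq(4010, 6000, by = 10),
                   1000 - abs(seq(4005, 5995, by = 10) - 5000))
  prof <- aggregate_profile(tri, anchors, flank = 1000, bin_width = 100)
  # the two central bins tie in exact arithmetic; either side of the summit
  expect_true(prof$apex %in% c(10L, 11L))

  flat <- toy_track("chr1", 0, 10000, 2)
  pf <- aggregate_profile(flat, anchors, flank = 500, bin_width = 50)
  expect_true(all(abs(pf$values - 2) < 1e-12))
  expect_equal(pf$apex, 1L)

  # single anchor, hand-built 4-bin window
  t4 <- toy_track("chr1", c(900, 950, 1000, 1050), c(950, 1000, 1050, 1100),
                  c(1, 2, 3, 4))
  a <- gr("chr1", 1000, 1002)  # midpoint 0-based 1000
  p4 <- aggregate_profile(t4, a, flank = 100, bin_width = 50)
  expect_equal(p4$values, c(1, 2, 3, 4))

  expect_warning(
    aggregate_profile(flat, c(anchors, gr("chrZ", 0, 10)), flank = 100,
                      bin_width = 50),
    "skipped")
})

test_that("length regression recovers exact linear relations", {
  genes <- toy_genes(seq(0, 4) * 10000, seq(0, 4) * 10000 + c(1000, 2000, 3000, 4000, 5000))
  pk <- granges(genes)
  mcols(pk)$name <- sprintf("p%d", 1:5)
  ann <- annotate_peaks_to_genes(pk, genes, min_frac = 0.5)
  fit <- length_regression(genes, pk, ann)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  # constant peak length: slope 0, r reported as 0
  pk2 <- gr("chr1", start(genes) - 1, start(genes) + 499)
  mcols(pk2)$name <- sprintf("p%d", 1:5)
  ann2 <- data.frame(peak = pk2$name, gene = genes$gene_id)
  fit2 <- length_regression(genes, pk2, ann2)
  expect_equal(fit2$slope, 0, tolerance = 1e-9)
  expect_equal(fit2$r, 0)

  # 5-point hand dataset against the normal equations
  x <- c(1000, 3000, 4500, 8000, 12000)
  y <- c(800, 2000, 5000, 6000, 9000)
  g5 <- toy_genes(seq(0, 4) * 20000, seq(0, 4) * 20000 + x)
  p5 <- gr("chr1", seq(0, 4) * 20000, seq(0, 4) * 20000 + y)
  mcols(p5)$name <- sprintf("p%d", 1:5)
  a5 <- data.frame(peak = p5$name, gene = g5$gene_id)
  fit5 <- length_regression(g5, p5, a5)
  ref <- ols_reference(x, y)
  expect_equal(fit5$slope, ref$slope, tolerance = 1e-12)
  expect_equal(fit5$intercept, ref$intercept, tolerance = 1e-9)

  expect_error(length_regression(g5[1:2], p5[1:2],
                                 a5[1:2, ]), "at least 3")
})

test_that("delta-delta-Ct fold changes follow the exponent rule", {
  expect_equal(delta_delta_ct(20, 20, 20, 20), 1)
  expect_equal(delta_delta_ct(20, 18, 22, 18), 4)
  expect_equal(delta_delta_ct(21, 18, 20, 18), 0.5)
  expect_error(delta_delta_ct(NA, 1, 1, 1))
})
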