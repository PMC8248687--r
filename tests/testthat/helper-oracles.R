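# Independent oracles and small fixture builders used across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

gr <- function(chrom, start0, end0, strand = "*") {
  # build a GRanges from 0-based half-open coordinates, as in BED
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
}

toy_genes <- function(starts0, ends0, strand = "+", chrom = "chr1",
                      ids = sprintf("G%03d", seq_along(starts0))) {
  g <- gr(chrom, starts0, ends0, strand)
  mcols(g)$gene_id <- ids
  mcols(g)$gene_name <- ids
  g
}

toy_track <- function(chrom, starts0, ends0, values) {
  t <- gr(chrom, starts0, ends0)
  mcols(t)$score <- values
  sort(t, ignore.strand = TRUE)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# universe and count those overlapping a fixed K-set by >= k elements.
hyper_upper_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Reference BH step-up, written independently of stats::p.adjust.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force log-odds score of one window.
pwm_window_score <- function(window_chars, pwm) {
  sum(vapply(seq_along(window_chars), function(i) {
    b <- window_chars[i]
    log2(pwm$probs[b, i] / pwm$background[b])
  }, numeric(1)))
}

# Per-base brute-force mean signal of a gene over a track.
per_base_gene_mean <- function(track, gene) {
  pos <- seq(start(gene), end(gene))
  val <- numeric(length(pos))
  tt <- track[as.character(seqnames(track)) == as.character(seqnames(gene))]
  for (i in seq_along(tt)) {
    sel <- pos >= start(tt)[i] & pos <= end(tt)[i]
    val[sel] <- tt$score[i]
  }
  mean(val)
}

# OLS by normal equations, independent of lm().
ols_reference <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Gene-level synthetic cohort for permutation tests: runs the full generator
# at the given conditions and returns what the test needs.
perm_cohort <- function(seed, n_genes, n_induced, excess_delta,
                        gamma_slope = 1) {
  cfg <- sim_config(n_genes = n_genes, n_induced = n_induced,
                    excess_delta = excess_delta, gamma_slope = gamma_slope,
                    seed = seed)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  trk <- simulate_gamma_track(cfg, ann, expr)
  gb <- gene_body_signal(trk$track, ann$genes)
  fm <- expr$fpkm_mean
  wexpr <- weighted_tissue_expression(
    stats::setNames(fm[, "NeuNpos_t30"], rownames(fm)),
    stats::setNames(fm[, "NeuNneg_t30"], rownames(fm)))
  list(cfg = cfg, annotation = ann, expression = expr, track = trk,
       signal = stats::setNames(gb$rpkm, gb$gene),
       wexpr = wexpr,
       universe = filter_expressed(fm),
       targets = intersect(expr$truth$induced_all, filter_expressed(fm)))
}
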