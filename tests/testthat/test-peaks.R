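test_that("flat tracks yield no peaks; a strong enriched region yields exactly one", {
  sizes <- c(chr1 = 100000)
  flat <- toy_track("chr1", 0, 100000, 1.0)
  expect_length(call_broad_peaks(flat, sizes, p_cutoff = 1e-5), 0)
  expect_length(call_broad_peaks(GRanges(), sizes), 0)

  # 1 kb region at 10x a 1 read/bp background
  enr <- toy_track("chr1", c(0, 50000, 51000), c(50000, 51000, 100000),
                   c(1, 10, 1))
  pk <- call_broad_peaks(enr, sizes, window = 200, p_cutoff = 1e-5)
  expect_equal(length(pk), 1L)
  expect_lte(start(pk), 50001)
  expect_gte(end(pk), 51000)
  expect_true(pk$score > 5)

  # independent exact Poisson tail oracle (regularised gamma identity):
  # enriched windows must pass the cutoff, background windows must not
  lambda <- sum(enr$score * width(enr)) / 100000 * 200
  p_upper <- function(x, lam) stats::pgamma(lam, shape = x, lower.tail = TRUE)
  expect_lte(p_upper(2000, lambda), 1e-5)
  expect_gt(p_upper(200, lambda), 1e-5)
})

test_that("peak merging respects max_gap across enriched regions", {
  sizes <- c(chr1 = 100000)
  two <- toy_track("chr1",
                   c(0, 20000, 21000, 24000, 25000),
                   c(20000, 21000, 24000, 25000, 100000),
                   c(1, 10, 1, 10, 1))
  apart <- call_broad_peaks(two, sizes, window = 200, p_cutoff = 1e-5,
                            max_gap = 1000)
  expect_equal(length(apart), 2L)
  joined <- call_broad_peaks(two, sizes, window = 200, p_cutoff = 1e-5,
                             max_gap = 4000)
  expect_equal(length(joined), 1L)
})

test_that("two-tier filter keeps relaxed extents with stringent support", {
  stringent <- gr("chr1", 100, 200)
  relaxed <- c(gr("chr1", 50, 400), gr("chr1", 500, 600))
  out <- two_tier_filter(stringent, relaxed)
  expect_equal(length(out), 1L)
  expect_equal(start(out) - 1L, 50L)
  expect_equal(end(out), 400L)
  expect_length(two_tier_filter(GRanges(), relaxed), 0)

  # subset of relaxed, monotone in the stringent set
  set.seed(12)
  rel <- gr("chr1", st <- sample(0:2000, 30) * 10, st * 10 + 500)
  str1 <- gr("chr1", sample(0:20000, 5), sample(20001:20500, 5))
  str2 <- c(str1, gr("chr1", 100, 5000))
  o1 <- two_tier_filter(str1, rel)
  o2 <- two_tier_filter(str2, rel)
  expect_true(all(as.character(o1) %in% as.character(rel)))
  expect_true(all(as.character(o1) %in% as.character(o2)))
})

test_that("peak-to-gene annotation applies the 50% rule boundary-inclusively", {
  genes <- toy_genes(c(500, 510), c(2000, 2000), ids = c("gIn", "gOut"))
  pk <- gr("chr1", 0, 1000)
  mcols(pk)$name <- "p1"
  ann <- annotate_peaks_to_genes(pk, genes[1], min_frac = 0.5)
  expect_equal(ann$gene, "gIn")
  expect_equal(ann$frac, 0.5)
  ann2 <- annotate_peaks_to_genes(pk, genes[2], min_frac = 0.5)
  expect_true(is.na(ann2$gene))

  # one peak inside two overlapping genes annotates to both
  both <- toy_genes(c(0, 100), c(5000, 6000), ids = c("gA", "gB"))
  inner <- gr("chr1", 1000, 2000)
  mcols(inner)$name <- "p2"
  ann3 <- annotate_peaks_to_genes(inner, both)
  expect_setequal(ann3$gene, c("gA", "gB"))

  # tiny min_frac recovers any-overlap intersection
  ann4 <- annotate_peaks_to_genes(pk, genes, min_frac = 1e-9)
  expect_setequal(ann4$gene, c("gIn", "gOut"))
})

test_that("nearest_gene assigns by TSS distance with deterministic tie-breaks", {
  genes <- toy_genes(c(1000, 5000), c(2000, 6000), strand = c("+", "-"),
                     ids = c("gA", "gB"))
  # site midpoint exactly on gA's TSS (0-based 1000)
  s1 <- gr("chr1", 990, 1011)
  mcols(s1)$name <- "s1"
  r1 <- nearest_gene(s1, genes)
  expect_equal(r1$gene, "gA")
  expect_equal(r1$distance, 0)

  # equidistant between gA TSS (1000) and gB TSS (5999): midpoint 3499.5 is
  # not integral, so use TSSs 1000 and 6000 via an unstranded second gene
  g2 <- toy_genes(c(1000, 6000), c(2000, 7000), ids = c("gA", "gB"))
  s2 <- gr("chr1", 3495, 3506)  # midpoint 0-based 3500, 2500 from both
  mcols(s2)$name <- "s2"
  expect_equal(nearest_gene(s2, g2)$gene, "gA")

  # single gene: every site maps to it; minus-strand sign convention
  gm <- toy_genes(1000, 2000, strand = "-", ids = "gM")   # TSS at 1999
  s3 <- c(gr("chr1", 2990, 3011), gr("chr1", 0, 11))
  mcols(s3)$name <- c("down", "up")
  r3 <- nearest_gene(s3, gm)
  expect_equal(r3$gene, c("gM", "gM"))
  # downstream of a minus-strand TSS means smaller coordinates
  expect_lt(r3$distance[1], 0)
  expect_gt(r3$distance[2], 0)
})

test_that("PWM scanning finds planted matches on both strands", {
  pwm <- pwm_from_consensus("ACGT")
  hits <- scan_pwm(c(s1 = "TTACGTTT"), pwm, threshold = 5)
  # ACGT is its own reverse complement, so the planted match scores on both
  # strands at the same forward offset
  expect_true(all(hits$offset == 2L))
  expect_true(any(hits$strand == "+"))

  # non-palindromic motif on the minus strand: revcomp(AAGG) = CCTT
  pwm2 <- pwm_from_consensus("AAGG")
  hits2 <- scan_pwm(c(s1 = "TTCCTTTT"), pwm2, threshold = 5)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 2L)

  expect_equal(nrow(scan_pwm(c(s1 = "ACGTACGT"), pwm, threshold = Inf)), 0L)
  # windows covering N (or any non-ACGT base) are skipped on both strands:
  # only the TACG window at offset 3 is scannable here
  amb <- scan_pwm(c(s1 = "ACNTACGX"), pwm, threshold = -100)
  expect_true(all(amb$offset == 3L))
  expect_equal(nrow(amb), 2L)

  bad <- pwm_from_consensus("ACGT")
  bad$probs["A", 1] <- 0
  bad$probs["C", 1] <- 0.99 + 0.01
  expect_error(scan_pwm(c(s1 = "ACGT"), bad, 0), "pseudocount")
})

test_that("PWM window scores equal the brute-force sum on random sequences", {
  set.seed(33)
  pwm <- pwm_from_consensus("AGAACATGTTCT", pseudocount = 0.02)
  seqs <- random_dna(50, 40)
  names(seqs) <- sprintf("r%02d", 1:50)
  hits <- scan_pwm(seqs, pwm, threshold = -Inf)
  expect_equal(nrow(hits), 50 * 2 * (40 - 12 + 1))
  m <- ncol(pwm$probs)
  for (i in sample(nrow(hits), 200)) {
    h <- hits[i, ]
    s <- seqs[[h$site_id]]
    win <- if (h$strand == "+") substr(s, h$offset + 1, h$offset + m) else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(s, h$offset + 1, h$offset + m))))
    expect_equal(h$score, pwm_window_score(strsplit(win, "")[[1]], pwm),
                 tolerance = 1e-12)
  }
})

test_that("scanning a sequence equals scanning its reverse complement with strands swapped", {
  set.seed(34)
  pwm <- pwm_from_consensus("GATTACA")
  seqs <- random_dna(10, 60)
  names(seqs) <- sprintf("r%02d", 1:10)
  fwd <- scan_pwm(seqs, pwm, threshold = -Inf)
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  rev <- scan_pwm(rc, pwm, threshold = -Inf)
  m <- ncol(pwm$probs)
  key <- function(df) paste(df$site_id, df$offset, df$strand,
                            round(df$score, 9))
  rev_mapped <- data.frame(site_id = rev$site_id,
                           offset = 60 - m - rev$offset,
                           strand = ifelse(rev$strand == "+", "-", "+"),
                           score = rev$score)
  expect_setequal(key(fwd), key(rev_mapped))
})

test_that("PWM files round-trip", {
  pwm <- pwm_from_consensus("ACGTAC", pseudocount = 0.03)
  f <- withr::local_tempfile()
  write_pwm(pwm, f)
  p2 <- read_pwm(f)
  expect_equal(p2$probs, pwm$probs, tolerance = 1e-6)
  expect_equal(p2$name, pwm$name)
})

test_that("surrogate caller recovers strongly enriched genes with no background peaks", {
  rec <- vapply(1:5, function(i) {
    co <- perm_cohort(i, n_genes = 300, n_induced = 30, excess_delta = 3)
    stringent <- call_broad_peaks(co$track$track, co$annotation$chrom_sizes,
                                  p_cutoff = 1e-5)
    relaxed <- call_broad_peaks(co$track$track, co$annotation$chrom_sizes,
                                p_cutoff = 0.1)
    pk <- two_tier_filter(stringent, relaxed)
    planted <- co$annotation$genes[
      co$annotation$genes$gene_id %in% co$expression$truth$induced_all]
    expect_equal(sum(as.character(seqnames(pk)) == "chrB1"), 0L)
    mean(IRanges::overlapsAny(planted, pk))
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})
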