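#' Call broad enrichment peaks with a Poisson window model
#'
#' A deliberately simple surrogate for a broad-peak caller: the genome is
#' tiled into fixed windows, the summed signal mass in each window is tested
#' against the genome-wide mean rate with a Poisson upper tail, and
#' significant windows within `max_gap` of each other are merged into peaks.
#' Peaks called externally (e.g. MACS2 broad peaks in BED form) can be used
#' anywhere this function's output is, via [read_bed()].
#'
#' @param track Signal-track `GRanges` (density per bp in `score`).
#' @param chrom_sizes Named numeric vector of chromosome sizes (bp).
#' @param window Window width in bp (default 200).
#' @param p_cutoff Poisson upper-tail p-value threshold, in (0, 1).
#' @param max_gap Significant windows closer than this are merged (default
#'   1000 bp).
#' @return `GRanges` of peaks with metadata `score` (-log10 of the best
#'   window p-value, capped at 1000), `mean_signal` (density) and `name`.
#' @export
call_broad_peaks <- function(track, chrom_sizes, window = 200L,
                             p_cutoff = 1e-5, max_gap = 1000L) {
  stopifnot(window > 0, p_cutoff > 0, p_cutoff < 1, max_gap >= 0)
  if (length(track) == 0L) return(empty_peaks())
  track <- validate_track(track)
  genome_len <- sum(chrom_sizes)
  total_mass <- sum(track$score * width(track))
  lambda <- total_mass / genome_len * window
  wins <- unlist(GenomicRanges::tile(
    GRanges(names(chrom_sizes), IRanges(1L, as.integer(chrom_sizes))),
    width = window))
  hits <- findOverlaps(wins, track, ignore.strand = TRUE)
  ovw <- width(pintersect(wins[queryHits(hits)], track[subjectHits(hits)]))
  mass_in <- tapply(ovw * track$score[subjectHits(hits)], queryHits(hits), sum)
  mass <- numeric(length(wins))
  mass[as.integer(names(mass_in))] <- mass_in
  # P(X >= mass) for Poisson X; fractional mass rounded up to the next count
  pv <- stats::ppois(ceiling(mass) - 1, lambda, lower.tail = FALSE)
  sig <- which(pv <= p_cutoff)
  if (length(sig) == 0L) return(empty_peaks())
  peaks <- merge_intervals(wins[sig], max_gap = max_gap)
  wp <- findOverlaps(peaks, wins[sig], ignore.strand = TRUE)
  best <- tapply(pv[sig][subjectHits(wp)], queryHits(wp), min)
  score <- pmin(-log10(pmax(unname(best), 1e-300)), 1000)
  pm <- findOverlaps(peaks, track, ignore.strand = TRUE)
  pmass <- tapply(width(pintersect(peaks[queryHits(pm)],
                                   track[subjectHits(pm)])) *
                    track$score[subjectHits(pm)],
                  queryHits(pm), sum)
  mean_signal <- numeric(length(peaks))
  mean_signal[as.integer(names(pmass))] <- pmass
  mean_signal <- mean_signal / width(peaks)
  mcols(peaks)$name <- sprintf("peak%05d", seq_along(peaks))
  mcols(peaks)$score <- score
  mcols(peaks)$mean_signal <- mean_signal
  peaks
}

empty_peaks <- function() {
  gr <- GRanges()
  mcols(gr)$name <- character(0)
  mcols(gr)$score <- numeric(0)
  mcols(gr)$mean_signal <- numeric(0)
  gr
}

#' Two-tier broad-peak filter
#'
#' Retains every relaxed-threshold peak that overlaps (by at least 1 bp) a
#' stringent-threshold peak, keeping the relaxed coordinates. This captures
#' the full extent of broad enrichment while requiring stringent confidence
#' somewhere within it.
#'
#' @param stringent Peaks called at the strict cutoff (`GRanges`).
#' @param relaxed Peaks called at the loose cutoff (`GRanges`).
#' @return The qualifying subset of `relaxed`.
#' @export
two_tier_filter <- function(stringent, relaxed) {
  subsetByOverlaps(relaxed, stringent, ignore.strand = TRUE)
}

#' Annotate peaks to genes by fractional overlap
#'
#' A peak is annotated to a gene when at least `min_frac` of the chosen
#' feature (`direction = "peak"`: the peak; `"gene"`: the gene) is covered by
#' the other, boundary inclusive. One peak may annotate to several genes.
#'
#' @param peaks `GRanges` of peaks (a `name` column is used as peak id when
#'   present).
#' @param genes `GRanges` with `gene_id`.
#' @param min_frac Minimum overlap fraction in (0, 1], default 0.5.
#' @param direction Which feature's length the fraction is measured against.
#' @return data.frame with one row per peak-gene assignment (`peak`, `gene`,
#'   `overlap_bp`, `frac`); peaks with no assignment appear once with
#'   `gene = NA` (intergenic).
#' @export
annotate_peaks_to_genes <- function(peaks, genes, min_frac = 0.5,
                                    direction = c("peak", "gene")) {
  stopifnot(min_frac > 0, min_frac <= 1)
  direction <- match.arg(direction)
  peak_id <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name else
    sprintf("peak%05d", seq_along(peaks))
  hits <- findOverlaps(peaks, genes, ignore.strand = TRUE)
  ov <- width(pintersect(granges(peaks)[queryHits(hits)],
                         granges(genes)[subjectHits(hits)],
                         ignore.strand = TRUE))
  denom <- if (direction == "peak") width(peaks)[queryHits(hits)] else
    width(genes)[subjectHits(hits)]
  frac <- ov / denom
  keep <- frac >= min_frac
  ann <- data.frame(peak = peak_id[queryHits(hits)[keep]],
                    gene = genes$gene_id[subjectHits(hits)[keep]],
                    overlap_bp = ov[keep], frac = frac[keep],
                    stringsAsFactors = FALSE)
  inter <- setdiff(peak_id, ann$peak)
  if (length(inter)) {
    ann <- rbind(ann, data.frame(peak = inter, gene = NA_character_,
                                 overlap_bp = 0L, frac = 0,
                                 stringsAsFactors = FALSE))
  }
  ann[order(match(ann$peak, peak_id)), , drop = FALSE]
}

#' Assign each site to its single nearest gene by TSS distance
#'
#' Distance is measured from the site midpoint to each gene's TSS on the
#' same chromosome and signed by gene strand, so positive distances lie
#' downstream of the TSS. Ties are broken by lexicographically smaller
#' `gene_id`. Sites on chromosomes with no annotated gene get `NA` with a
#' warning.
#'
#' @param sites `GRanges` of sites (`name` used as site id when present).
#' @param genes `GRanges` with `gene_id`; must be non-empty.
#' @return data.frame with `site`, `gene`, `distance` (bp, strand-signed).
#' @export
nearest_gene <- function(sites, genes) {
  stopifnot(length(genes) > 0)
  site_id <- if (!is.null(mcols(sites)$name)) mcols(sites)$name else
    sprintf("site%05d", seq_along(sites))
  tss <- gene_tss(genes)
  tss_pos <- start(tss)
  tss_chrom <- as.character(seqnames(tss))
  sgn <- ifelse(as.character(strand(genes)) == "-", -1, 1)
  ord <- order(genes$gene_id)
  mid <- start(sites) + floor((width(sites) - 1) / 2)
  s_chrom <- as.character(seqnames(sites))
  out <- data.frame(site = site_id, gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    cand <- ord[tss_chrom[ord] == s_chrom[i]]
    if (length(cand) == 0L) next
    d <- mid[i] - tss_pos[cand]
    j <- cand[which.min(abs(d))]   # ord is id-sorted, so ties pick smaller id
    out$gene[i] <- genes$gene_id[j]
    out$distance[i] <- (mid[i] - tss_pos[j]) * sgn[j]
  }
  if (anyNA(out$gene)) {
    warning(sum(is.na(out$gene)),
            " site(s) on chromosomes with no annotated gene; assigned NA")
  }
  out
}

#' Build a PWM from a consensus sequence
#'
#' Position probabilities put mass `1 - 3 * pseudocount` on the consensus
#' base and `pseudocount` elsewhere; background is uniform.
#'
#' @param consensus Character string over A/C/G/T.
#' @param pseudocount Off-consensus per-base probability (default 0.01).
#' @return A list of class `pwm` with `name`, `probs` (4 x width matrix,
#'   rows A/C/G/T) and `background`.
#' @export
pwm_from_consensus <- function(consensus, pseudocount = 0.01) {
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(cc %in% bases))
  probs <- matrix(pseudocount, nrow = 4, ncol = length(cc),
                  dimnames = list(bases, NULL))
  probs[cbind(match(cc, bases), seq_along(cc))] <- 1 - 3 * pseudocount
  new_pwm(consensus, probs)
}

new_pwm <- function(name, probs, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  rownames(probs) <- bases
  names(background) <- bases
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM column probabilities must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(name = name, probs = probs, background = background),
            class = "pwm")
}

#' Read a PWM from a plain-text matrix file
#'
#' Format: a `>name` header line followed by one row per motif position with
#' four whitespace-separated probabilities in A C G T order.
#'
#' @param path Path to the PWM file.
#' @return A `pwm` object (see [pwm_from_consensus()]).
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  stopifnot(length(lines) >= 2L, startsWith(lines[1], ">"))
  name <- sub("^>\\s*", "", lines[1])
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != 4L)) stop("PWM parse error: rows must have 4 columns")
  new_pwm(name, t(do.call(rbind, vals)))
}

#' Write a PWM to the plain-text matrix format
#'
#' @param pwm A `pwm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  lines <- c(paste0(">", pwm$name),
             apply(pwm$probs, 2, function(col)
               paste(format(col, digits = 6), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Scan sequences for PWM matches by log-odds score
#'
#' Every window on both strands is scored as
#' `sum_i log2(p_i(base_i) / bg(base_i))` (bits); windows containing N are
#' skipped. All windows at or above `threshold` are reported.
#'
#' @param sequences Named character vector or `DNAStringSet` over A/C/G/T/N.
#' @param pwm A `pwm` object; zero probabilities are an error (regularise
#'   with a pseudocount first, e.g. [pwm_from_consensus()]).
#' @param threshold Minimum log-odds score in bits.
#' @return data.frame of hits: `site_id`, `offset` (0-based window start on
#'   the forward sequence), `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold) {
  stopifnot(inherits(pwm, "pwm"), is.numeric(threshold), !is.na(threshold))
  if (any(pwm$probs == 0)) {
    stop("PWM contains zero probabilities; add a pseudocount ",
         "(see pwm_from_consensus) before scanning")
  }
  seqs <- as.character(sequences)
  if (!is.null(names(sequences))) names(seqs) <- names(sequences)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  lo <- log2(sweep(pwm$probs, 1, pwm$background, "/"))
  m <- ncol(lo)
  hits <- lapply(names(seqs), function(id) {
    s <- toupper(seqs[[id]])
    fw <- scan_one_strand(s, lo, m)
    rv <- scan_one_strand(revcomp_chr(s), lo, m)
    # a window at reverse-strand offset j covers forward offsets
    # (L - m - j) .. (L - 1 - j)
    L <- nchar(s)
    res <- rbind(
      if (length(fw$off)) data.frame(site_id = id, offset = fw$off,
                                     strand = "+", score = fw$score),
      if (length(rv$off)) data.frame(site_id = id, offset = L - m - rv$off,
                                     strand = "-", score = rv$score))
    res
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(site_id = character(0), offset = integer(0),
                       strand = character(0), score = numeric(0))
  }
  keep <- hits$score >= threshold
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Score every window of one strand; returns 0-based offsets passing nothing
# (filtering happens in the caller). Windows containing non-ACGT are dropped.
scan_one_strand <- function(s, lo, m) {
  L <- nchar(s)
  if (L < m) return(list(off = integer(0), score = numeric(0)))
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  n_win <- L - m + 1L
  sc <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (i in seq_len(m)) {
    b <- code[i:(i + n_win - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    sc <- sc + lo[cbind(b, i)]
  }
  list(off = which(ok) - 1L, score = sc[ok])
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
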