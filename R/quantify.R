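#' Reads (fragments) per kilobase per million
#'
#' `count / (length/1e3 * library_size/1e6)`; a zero count gives 0.
#'
#' @param count Read (fragment) count, vectorised.
#' @param feature_length Feature length in bp, > 0.
#' @param library_size Total mapped reads, > 0.
#' @return RPKM/FPKM density.
#' @export
rpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (feature_length / 1e3 * library_size / 1e6)
}

#' Quantify signal over gene bodies
#'
#' For each gene, sums `score x covered-bp` over the gene body and divides
#' by body length (mean density); the RPKM-equivalent treats the gene's
#' signal mass as its count and the total track mass as library size.
#'
#' @param track Signal-track `GRanges`.
#' @param genes `GRanges` with `gene_id`.
#' @return data.frame keyed by `gene`: `mass`, `mean_density`, `rpkm`.
#'   Genes on chromosomes absent from the track get 0 with one warning.
#' @export
gene_body_signal <- function(track, genes) {
  track <- validate_track(track)
  hits <- suppressWarnings(
    findOverlaps(granges(genes), granges(track), ignore.strand = TRUE))
  ov <- suppressWarnings(
    width(pintersect(granges(genes)[queryHits(hits)],
                     granges(track)[subjectHits(hits)],
                     ignore.strand = TRUE)))
  mass_in <- tapply(ov * track$score[subjectHits(hits)], queryHits(hits), sum)
  mass <- numeric(length(genes))
  mass[as.integer(names(mass_in))] <- mass_in
  missing_chrom <- !(as.character(seqnames(genes)) %in%
                       unique(as.character(seqnames(track))))
  if (any(missing_chrom)) {
    warning(sum(missing_chrom),
            " gene(s) on chromosomes absent from the track; signal set to 0")
  }
  total_mass <- sum(track$score * width(track))
  data.frame(gene = genes$gene_id,
             mass = mass,
             mean_density = mass / width(genes),
             rpkm = rpkm(mass, width(genes), max(total_mass, 1)),
             stringsAsFactors = FALSE)
}

#' Tissue-weighted expression across sorted fractions
#'
#' Whole-tissue expression estimated as `w_plus * FPKM+ + w_minus * FPKM-`
#' per gene, reflecting the approximate neuronal/non-neuronal composition of
#' bulk tissue (default 60/40).
#'
#' @param fpkm_plus,fpkm_minus Named numeric vectors of per-gene FPKM for
#'   the NeuN+ and NeuN- fractions. A gene present in only one vector is
#'   treated as 0 in the other, with a warning.
#' @param w_plus,w_minus Weights summing to 1 (defaults 0.6 / 0.4).
#' @return Named numeric vector over the union of genes.
#' @export
weighted_tissue_expression <- function(fpkm_plus, fpkm_minus,
                                       w_plus = 0.6, w_minus = 0.4) {
  if (abs(w_plus + w_minus - 1) > 1e-8) stop("weights must sum to 1")
  genes <- union(names(fpkm_plus), names(fpkm_minus))
  miss <- sum(!(genes %in% names(fpkm_plus))) +
    sum(!(genes %in% names(fpkm_minus)))
  if (miss > 0) {
    warning(miss, " gene(s) present in only one fraction; treated as 0 FPKM ",
            "in the other")
  }
  gp <- stats::setNames(numeric(length(genes)), genes)
  gm <- gp
  gp[names(fpkm_plus)] <- fpkm_plus
  gm[names(fpkm_minus)] <- fpkm_minus
  w_plus * gp + w_minus * gm
}

#' Quantile bins of expression with a companion-value summary
#'
#' Ranks genes by expression (ties broken by stable gene-id order) and
#' splits them into `n_bins` near-equal bins, any remainder going to the
#' lowest bins. Reports each gene's bin and the per-bin mean of a companion
#' value (e.g. gammaH2AX signal versus expression percentile).
#'
#' @param expression Named per-gene numeric vector (e.g. FPKM), non-empty.
#' @param companion Named per-gene numeric vector summarised within bins;
#'   defaults to the expression itself.
#' @param n_bins Number of bins, >= 2.
#' @return List with `bin` (named integer, 1 = lowest expression) and
#'   `summary` (data.frame: bin, n, mean_expression, mean_companion).
#' @export
percentile_bins <- function(expression, companion = expression, n_bins = 10L) {
  stopifnot(n_bins >= 2, length(expression) > 0)
  ids <- names(expression)
  if (length(unique(expression)) == 1L) {
    warning("all expression values identical; returning a single bin")
    bin <- stats::setNames(rep(1L, length(expression)), ids)
    return(list(bin = bin,
                summary = data.frame(bin = 1L, n = length(expression),
                                     mean_expression = expression[[1]],
                                     mean_companion = mean(companion[ids]))))
  }
  ord <- order(expression, ids)
  n <- length(expression)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  names(bin) <- ids
  comp <- companion[ids]
  summary <- data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    mean_expression = vapply(seq_len(n_bins), function(b)
      mean(expression[bin == b]), numeric(1)),
    mean_companion = vapply(seq_len(n_bins), function(b)
      mean(comp[bin == b]), numeric(1)))
  list(bin = bin, summary = summary)
}

#' Aggregate marker-gene scores per cell type with row Z-scores
#'
#' For each cell type's marker set, takes the geometric mean of
#' `FPKM + pseudocount` over the set's genes in each sample, then Z-scores
#' across samples within the cell-type row (population sd). Zero-variance
#' rows yield `NaN` Z-scores and are flagged rather than erroring.
#'
#' @param fpkm_table Numeric matrix/data.frame, genes x samples, rownames =
#'   gene ids.
#' @param marker_sets Named list of marker gene vectors; each set must have
#'   at least one gene present in the table.
#' @return List with `score` (geometric means, cell type x sample), `z`
#'   (row Z-scores) and `degenerate` (logical per row).
#' @export
marker_aggregate_score <- function(fpkm_table, marker_sets, pseudocount = 0.01) {
  fpkm_table <- as.matrix(fpkm_table)
  score <- t(vapply(names(marker_sets), function(ct) {
    g <- intersect(marker_sets[[ct]], rownames(fpkm_table))
    if (length(g) == 0L) {
      stop("marker set '", ct, "' has no genes present in the table")
    }
    exp(colMeans(log(fpkm_table[g, , drop = FALSE] + pseudocount)))
  }, numeric(ncol(fpkm_table))))
  mu <- rowMeans(score)
  sdev <- sqrt(rowMeans((score - mu)^2))
  z <- (score - mu) / sdev
  list(score = score, z = z, degenerate = sdev == 0)
}

#' Aggregate signal profile anchored at interval midpoints
#'
#' Averages track signal in fixed-width bins spanning
#' `[midpoint - flank, midpoint + flank)` around each anchor, then averages
#' across anchors. The apex is the bin of maximal mean signal (ties take the
#' lower index). Uncovered bases count as zero signal.
#'
#' @param track Signal-track `GRanges`.
#' @param anchors `GRanges` of anchor intervals (e.g. binding sites).
#' @param flank Half-window in bp; must be a multiple of `bin_width`.
#' @param bin_width Bin width in bp.
#' @return List of class `profile_matrix`: `values` (mean signal per bin),
#'   `matrix` (anchors x bins), `bin_mid` (bp offsets from the anchor
#'   midpoint), `apex` (1-based bin index), `n_anchors` used and
#'   `n_skipped` anchors on chromosomes absent from the track.
#' @export
aggregate_profile <- function(track, anchors, flank = 2000L, bin_width = 50L) {
  stopifnot(flank > 0, bin_width > 0, flank %% bin_width == 0)
  track <- validate_track(track)
  n_bins <- as.integer(2 * flank / bin_width)
  chroms <- unique(as.character(seqnames(track)))
  on_track <- as.character(seqnames(anchors)) %in% chroms
  n_skipped <- sum(!on_track)
  if (n_skipped > 0) {
    warning(n_skipped, " anchor(s) on chromosomes absent from the track; skipped")
  }
  anchors <- anchors[on_track]
  if (length(anchors) == 0L) stop("no usable anchors")
  mid <- start(anchors) + floor((width(anchors) - 1) / 2)
  bin_start <- rep(mid, each = n_bins) - flank +
    rep(seq_len(n_bins) - 1L, times = length(anchors)) * bin_width
  bins <- GRanges(rep(as.character(seqnames(anchors)), each = n_bins),
                  IRanges(start = pmax(bin_start, 1L),
                          end = pmax(bin_start, 1L) + bin_width - 1L))
  hits <- suppressWarnings(
    findOverlaps(bins, granges(track), ignore.strand = TRUE))
  ov <- suppressWarnings(
    width(pintersect(granges(bins)[queryHits(hits)],
                     granges(track)[subjectHits(hits)],
                     ignore.strand = TRUE)))
  mass_in <- tapply(ov * track$score[subjectHits(hits)], queryHits(hits), sum)
  mass <- numeric(length(bins))
  mass[as.integer(names(mass_in))] <- mass_in
  mat <- matrix(mass / bin_width, nrow = length(anchors), ncol = n_bins,
                byrow = TRUE)
  values <- colMeans(mat)
  structure(list(values = values, matrix = mat,
                 bin_mid = seq_len(n_bins) * bin_width - flank - bin_width / 2,
                 apex = which.max(values),
                 n_anchors = length(anchors), n_skipped = n_skipped),
            class = "profile_matrix")
}

#' Linear regression of peak length on gene length
#'
#' Ordinary least squares of annotated peak length against the length of
#' the gene each peak was assigned to, with the Pearson correlation.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param peaks `GRanges` of peaks (`name` = peak id).
#' @param annotation_map data.frame from [annotate_peaks_to_genes()].
#' @return List: `slope`, `intercept`, `r`, `n` pairs used.
#' @export
length_regression <- function(genes, peaks, annotation_map) {
  ann <- annotation_map[!is.na(annotation_map$gene), , drop = FALSE]
  peak_id <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name else
    sprintf("peak%05d", seq_along(peaks))
  x <- width(genes)[match(ann$gene, genes$gene_id)]
  y <- width(peaks)[match(ann$peak, peak_id)]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 annotated (gene, peak) pairs")
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0 || stats::sd(x) == 0) 0 else stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, n = length(x))
}

#' Relative fold change by the delta-delta-Ct method
#'
#' `2^-((Ct_target_s - Ct_ref_s) - (Ct_target_c - Ct_ref_c))`: target gene
#' Ct normalised against a reference gene (e.g. Hprt) in a stimulated
#' sample, relative to the same normalisation in a control sample.
#'
#' @param ct_target_s,ct_ref_s Target and reference Ct in the stimulated
#'   sample.
#' @param ct_target_c,ct_ref_c Target and reference Ct in the control
#'   sample.
#' @return Fold change (vectorised).
#' @export
delta_delta_ct <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  stopifnot(all(is.finite(c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c))))
  2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}
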