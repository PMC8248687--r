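#' Configuration for the synthetic dataset generator
#'
#' Bundles every generative knob with a validated default. The generator
#' emulates the statistical structure of a learning-induction experiment:
#' negative-binomial expression counts for two sorted nuclear fractions
#' (NeuN+ neuronal, NeuN- non-neuronal) at naive/10-min/30-min conditions,
#' a gammaH2AX signal track whose gene-body density rises with expression
#' and carries an injectable multiplicative excess at induced genes, and
#' regulatory binding sites with a planted motif.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of gene-bearing chromosomes.
#' @param n_background_chroms Extra chromosomes carrying only background
#'   signal (useful for false-positive checks on the peak caller).
#' @param gene_length_range Two-vector of min/max gene length (bp); lengths
#'   are drawn uniformly.
#' @param intergenic_gap_range Min/max intergenic gap (bp).
#' @param n_induced Number of stimulus-induced genes.
#' @param induction_log2fc Mean log2 fold-change of induced genes in
#'   stimulated conditions (0 = no induction anywhere).
#' @param induced_mix Proportions of induced genes that are neuron-only,
#'   shared, and non-neuron-only (must sum to 1).
#' @param fraction_weights Tissue composition weights `c(plus, minus)` used
#'   for the weighted whole-tissue expression scale; must sum to 1.
#' @param gamma_slope Strength of the expression -> gammaH2AX dependence
#'   (0 = signal independent of expression).
#' @param gamma_gene_sd Standard deviation (natural-log scale) of the
#'   per-gene biological variability of gammaH2AX density not explained by
#'   expression (0 = deterministic in expression).
#' @param excess_delta Multiplicative gammaH2AX excess at induced genes
#'   (1 = null, no excess beyond what expression predicts).
#' @param induction_propensity_mid,induction_propensity_scale Parameters of
#'   the logistic propensity (on log FPKM) with which genes are picked as
#'   induced: `plogis((log(FPKM) - log(mid)) / scale)`. Mirrors the
#'   expression dependence of differential-expression detection power, which
#'   is what shapes real upregulated-gene sets.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param n_reps Replicates per fraction x condition.
#' @param lib_size Target library size per sample (reads).
#' @param expr_meanlog,expr_sdlog Baseline per-gene FPKM is
#'   `rlnorm(meanlog, sdlog)`; the defaults give a median of ~2.7 FPKM and a
#'   dynamic range of several orders of magnitude.
#' @param base_density gammaH2AX read density (reads/bp) of a gene body at
#'   zero expression.
#' @param background_lambda Intergenic background read density (reads/bp).
#' @param track_bin Bin width (bp) of the emitted signal track.
#' @param background_chrom_size Size (bp) of each background-only chromosome.
#' @param max_chrom_size Upper bound on a laid-out chromosome; exceeded
#'   placement is an error.
#' @param n_sites Number of regulatory binding sites to simulate.
#' @param site_width Width (bp) of each site and its sequence.
#' @param site_tss_window Maximum distance (bp) of a site midpoint from the
#'   TSS it is planted near.
#' @param motif_consensus Consensus sequence of the planted motif.
#' @param plant_fraction Fraction of site sequences carrying the motif.
#' @param seed Integer RNG seed; every generator output is a deterministic
#'   function of the config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_chroms = 4L,
                       n_background_chroms = 1L,
                       gene_length_range = c(1000L, 10000L),
                       intergenic_gap_range = c(2000L, 10000L),
                       n_induced = 100L,
                       induction_log2fc = 2,
                       induced_mix = c(neuron = 0.6, shared = 0.1, nonneuron = 0.3),
                       induction_propensity_mid = 2,
                       induction_propensity_scale = 0.7,
                       fraction_weights = c(plus = 0.6, minus = 0.4),
                       gamma_slope = 1,
                       gamma_gene_sd = 0.6,
                       excess_delta = 1,
                       nb_dispersion = 0.05,
                       n_reps = 4L,
                       lib_size = 2e6,
                       expr_meanlog = 1,
                       expr_sdlog = 1.5,
                       base_density = 0.5,
                       background_lambda = 0.05,
                       track_bin = 200L,
                       background_chrom_size = 2e6,
                       max_chrom_size = Inf,
                       n_sites = 60L,
                       site_width = 200L,
                       site_tss_window = 500L,
                       motif_consensus = "AGAACATGTTCT",
                       plant_fraction = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_induced <= cfg$n_genes,
            length(cfg$gene_length_range) == 2L,
            cfg$gene_length_range[1] <= cfg$gene_length_range[2],
            cfg$excess_delta > 0, cfg$nb_dispersion > 0,
            cfg$plant_fraction >= 0, cfg$plant_fraction <= 1)
  if (abs(sum(cfg$fraction_weights) - 1) > 1e-8) {
    stop("fraction_weights must sum to 1")
  }
  if (abs(sum(cfg$induced_mix) - 1) > 1e-8) {
    stop("induced_mix must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# Stage-specific seeds derived from the config seed; kept within 32-bit range.
stage_seed <- function(cfg, stage) {
  offsets <- c(annotation = 101L, expression = 211L, track = 307L,
               sites = 401L)
  (as.integer(cfg$seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping genes sequentially along `n_chroms` chromosomes
#' with random intergenic gaps; gene lengths are uniform in
#' `gene_length_range`. Background-only chromosomes (no genes) are appended.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (a `GRanges` with `gene_id`, `gene_name`) and
#'   `chrom_sizes` (named numeric, bp).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg, "annotation"), {
    n <- cfg$n_genes
    if (n == 0L) {
      genes <- GRanges()
      mcols(genes)$gene_id <- character(0)
      mcols(genes)$gene_name <- character(0)
    } else {
      chrom_of <- sort(rep_len(seq_len(cfg$n_chroms), n))
      lens <- sample.int(cfg$gene_length_range[2] - cfg$gene_length_range[1] + 1L,
                         n, replace = TRUE) + cfg$gene_length_range[1] - 1L
      gaps <- sample.int(cfg$intergenic_gap_range[2] - cfg$intergenic_gap_range[1] + 1L,
                         n, replace = TRUE) + cfg$intergenic_gap_range[1] - 1L
      starts <- integer(n)
      for (ch in unique(chrom_of)) {
        idx <- which(chrom_of == ch)
        starts[idx] <- cumsum(c(gaps[idx[1]],
                                (lens[idx] + gaps[idx])[-length(idx)])) + 1L
      }
      genes <- GRanges(paste0("chr", chrom_of), IRanges(starts, width = lens),
                       strand = sample(c("+", "-"), n, replace = TRUE))
      mcols(genes)$gene_id <- sprintf("G%05d", seq_len(n))
      mcols(genes)$gene_name <- sprintf("Gene%05d", seq_len(n))
    }
    sizes <- numeric(0)
    for (ch in seq_len(cfg$n_chroms)) {
      nm <- paste0("chr", ch)
      on_ch <- genes[as.character(seqnames(genes)) == nm]
      sz <- if (length(on_ch)) max(end(on_ch)) + cfg$intergenic_gap_range[2] else
        cfg$background_chrom_size
      if (sz > cfg$max_chrom_size) {
        stop("cannot place ", length(on_ch), " genes on ", nm,
             " without exceeding max_chrom_size; use larger chromosomes ",
             "(raise max_chrom_size) or fewer genes")
      }
      sizes[nm] <- sz
    }
    for (b in seq_len(cfg$n_background_chroms)) {
      sizes[paste0("chrB", b)] <- cfg$background_chrom_size
    }
    list(genes = genes, chrom_sizes = sizes)
  })
}

#' Simulate expression counts, FPKM tables and differential-expression calls
#'
#' Baseline per-gene FPKM is log-normal; counts are negative-binomial around
#' `FPKM x length_kb x lib_size/1e6`. Induced genes are multiplied by
#' `2^log2FC` in the stimulated (10', 30') conditions of their designated
#' fraction(s); induced genes are drawn with a logistic detection-power-like
#' propensity in log expression, mirroring how padj-thresholded target sets
#' arise in real differential-expression analyses. DE tables carry the
#' moderated log2FC estimate and BH-adjusted p-value from a limma-trend fit
#' on log2 FPKM (naive vs stimulated, per fraction and time point).
#'
#' @param cfg A [sim_config()].
#' @param annotation Result of [simulate_annotation()].
#' @return List with `counts` (genes x samples), `fpkm` (per-sample FPKM),
#'   `fpkm_mean` (genes x fraction_condition means), `de` (list of
#'   data.frames per fraction: gene, log2fc, padj, fraction, timepoint) and
#'   `truth` (induced ids per fraction, baseline FPKM, excess flags).
#' @export
simulate_expression <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- annotation$genes
  n <- length(genes)
  ids <- genes$gene_id
  fractions <- c("NeuNpos", "NeuNneg")
  conditions <- c("naive", "t10", "t30")
  with_seed(stage_seed(cfg, "expression"), {
    fpkm0 <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    names(fpkm0) <- ids

    # induced genes sampled with a detection-power-like logistic propensity
    # in log expression: lowly expressed genes are rarely called induced
    propensity <- stats::plogis((log(fpkm0) - log(cfg$induction_propensity_mid)) /
                                  cfg$induction_propensity_scale)
    n_ind <- min(cfg$n_induced, n)
    induced_idx <- if (n_ind > 0) sort(sample(n, n_ind, prob = propensity)) else integer(0)
    mix_n <- round_half_up(cfg$induced_mix * n_ind)
    # rounding can over/undershoot by one; absorb in the first category
    mix_n[1] <- n_ind - sum(mix_n[-1])
    cat_lab <- rep(names(cfg$induced_mix), times = pmax(mix_n, 0))[seq_len(n_ind)]
    cat_lab <- sample(cat_lab)
    induced_plus <- induced_idx[cat_lab %in% c("neuron", "shared")]
    induced_minus <- induced_idx[cat_lab %in% c("nonneuron", "shared")]
    lfc_true <- stats::setNames(numeric(n), ids)
    if (n_ind > 0 && cfg$induction_log2fc != 0) {
      lfc_true[induced_idx] <- cfg$induction_log2fc *
        exp(stats::rnorm(n_ind, 0, 0.2))
    }

    len_kb <- width(genes) / 1000
    sample_names <- as.vector(outer(
      paste(rep(fractions, each = length(conditions)),
            rep(conditions, times = length(fractions)), sep = "_"),
      paste0("r", seq_len(cfg$n_reps)), paste, sep = "_"))
    counts <- matrix(0, nrow = n, ncol = length(sample_names),
                     dimnames = list(ids, sample_names))
    for (s in sample_names) {
      parts <- strsplit(s, "_", fixed = TRUE)[[1]]
      frac <- parts[1]; cond <- parts[2]
      fpkm_s <- fpkm0
      if (cond != "naive") {
        idx <- if (frac == "NeuNpos") induced_plus else induced_minus
        fpkm_s[idx] <- fpkm_s[idx] * 2^lfc_true[idx]
      }
      mu <- fpkm_s * len_kb * cfg$lib_size / 1e6
      counts[, s] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    }

    # median-of-ratios size factors: induction of a few high-expression
    # genes would otherwise deflate every other gene's FPKM in stimulated
    # samples (composition bias)
    pos <- rowSums(counts == 0) == 0
    geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(cl) median(cl / geo))
    lib_eff <- sf * mean(colSums(counts) / sf)
    fpkm <- sweep(sweep(counts, 1, len_kb, "/"), 2, lib_eff / 1e6, "/")
    grp <- sub("_r[0-9]+$", "", colnames(counts))
    fpkm_mean <- vapply(unique(grp), function(g) {
      rowMeans(fpkm[, grp == g, drop = FALSE])
    }, numeric(n))

    de <- lapply(fractions, function(frac) {
      do.call(rbind, lapply(c("t10", "t30"), function(tp) {
        sel <- grp %in% paste(frac, c("naive", tp), sep = "_")
        y <- log2(fpkm[, sel, drop = FALSE] + 0.1)
        stim <- factor(grp[sel] == paste(frac, tp, sep = "_"))
        fit <- limma::eBayes(limma::lmFit(y, stats::model.matrix(~stim)),
                             trend = TRUE)
        tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
        data.frame(gene = ids,
                   log2fc = tt$logFC,
                   pvalue = tt$P.Value,
                   padj = tt$adj.P.Val,
                   fraction = frac, timepoint = tp,
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    })
    names(de) <- fractions

    truth <- list(
      induced = list(NeuNpos = ids[induced_plus], NeuNneg = ids[induced_minus]),
      induced_all = ids[induced_idx],
      baseline_fpkm = fpkm0,
      true_log2fc = lfc_true,
      excess = stats::setNames(seq_len(n) %in% induced_idx, ids))
    list(counts = counts, fpkm = fpkm, fpkm_mean = fpkm_mean, de = de,
         truth = truth)
  })
}

#' Simulate a gammaH2AX signal track over the toy genome
#'
#' Gene-body read density is
#' `base_density * (1 + gamma_slope * log1p(weighted FPKM))`, multiplied by
#' a per-gene log-normal biological variability factor (`gamma_gene_sd`) and
#' by `excess_delta` at induced genes; intergenic regions sit at
#' `background_lambda`. The emitted track is binned at `track_bin` bp with
#' per-bin Poisson read counts converted back to densities; zero-count bins
#' are omitted.
#'
#' @param cfg A [sim_config()].
#' @param annotation Result of [simulate_annotation()].
#' @param expression Result of [simulate_expression()]; may be `NULL` when
#'   the annotation is empty.
#' @return List with `track` (signal `GRanges`) and `true_density` (named
#'   per-gene expected read density, reads/bp).
#' @export
simulate_gamma_track <- function(cfg, annotation, expression = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- annotation$genes
  sizes <- annotation$chrom_sizes
  with_seed(stage_seed(cfg, "track"), {
    genome <- GRanges(names(sizes), IRanges(1L, as.integer(sizes)))
    if (length(genes)) {
      w <- cfg$fraction_weights
      wfpkm <- w[[1]] * expression$fpkm_mean[, "NeuNpos_t30"] +
        w[[2]] * expression$fpkm_mean[, "NeuNneg_t30"]
      dens <- cfg$base_density * (1 + cfg$gamma_slope * log1p(wfpkm)) *
        exp(stats::rnorm(length(genes), 0, cfg$gamma_gene_sd))
      dens <- dens * ifelse(expression$truth$excess[genes$gene_id],
                            cfg$excess_delta, 1)
      names(dens) <- genes$gene_id
      tiles <- GenomicRanges::tile(granges(genes), width = cfg$track_bin)
      gene_bins <- unlist(tiles)
      per_bin_dens <- rep(unname(dens), lengths(tiles))
      bg <- GenomicRanges::setdiff(genome, granges(genes), ignore.strand = TRUE)
    } else {
      dens <- stats::setNames(numeric(0), character(0))
      gene_bins <- GRanges()
      per_bin_dens <- numeric(0)
      bg <- genome
    }
    bg <- bg[width(bg) > 0]
    bg_bins <- if (length(bg)) unlist(GenomicRanges::tile(bg, width = cfg$track_bin)) else GRanges()
    all_bins <- c(gene_bins, bg_bins)
    lam <- c(per_bin_dens, rep(cfg$background_lambda, length(bg_bins))) *
      width(all_bins)
    counts <- stats::rpois(length(all_bins), lam)
    keep <- counts > 0
    track <- all_bins[keep]
    mcols(track)$score <- counts[keep] / width(track)
    track <- GenomicRanges::sort(track, ignore.strand = TRUE)
    list(track = track, true_density = dens)
  })
}

#' Simulate regulatory binding sites with a planted motif
#'
#' Sites are placed with midpoints within `site_tss_window` bp of the TSS of
#' a designated gene subset (by default a seeded sample; the pipeline passes
#' the glia-induced genes). Each site carries a random uniform-base sequence;
#' `plant_fraction` of them have the consensus motif inserted at a random
#' offset on a random strand.
#'
#' @param cfg A [sim_config()].
#' @param annotation Result of [simulate_annotation()].
#' @param target_genes Optional character vector of gene ids to anchor sites
#'   near; defaults to a seeded sample of all genes.
#' @return List with `sites` (`GRanges`, `name` = site id,
#'   `planted` = logical), `pwm` (see [pwm_from_consensus()]) and
#'   `sequences` (`Biostrings::DNAStringSet` named by site id).
#' @export
simulate_binding_sites <- function(cfg, annotation, target_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- annotation$genes
  stopifnot(length(genes) > 0)
  with_seed(stage_seed(cfg, "sites"), {
    if (is.null(target_genes)) {
      target_genes <- sample(genes$gene_id, min(cfg$n_sites, length(genes)))
    }
    anchor <- genes[match(rep_len(target_genes, cfg$n_sites), genes$gene_id)]
    tss <- start(gene_tss(anchor))
    offs <- sample.int(2L * cfg$site_tss_window + 1L, cfg$n_sites,
                       replace = TRUE) - cfg$site_tss_window - 1L
    mid <- pmax(tss + offs, cfg$site_width)
    sites <- GRanges(seqnames(anchor),
                     IRanges(start = mid - floor(cfg$site_width / 2),
                             width = cfg$site_width))
    mcols(sites)$name <- sprintf("site%04d", seq_len(cfg$n_sites))
    mcols(sites)$anchor_gene <- anchor$gene_id

    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(cfg$n_sites), function(i) {
      paste(sample(bases, cfg$site_width, replace = TRUE), collapse = "")
    }, character(1))
    planted <- seq_len(cfg$n_sites) <=
      round_half_up(cfg$plant_fraction * cfg$n_sites)
    planted <- sample(planted)
    motif <- cfg$motif_consensus
    m <- nchar(motif)
    for (i in which(planted)) {
      at <- sample.int(cfg$site_width - m + 1L, 1L)
      ins <- if (stats::runif(1) < 0.5) motif else revcomp(motif)
      substr(seqs[i], at, at + m - 1L) <- ins
    }
    mcols(sites)$planted <- planted
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- sites$name
    list(sites = sites, pwm = pwm_from_consensus(motif), sequences = sequences)
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a full synthetic dataset to disk
#'
#' Runs every generator stage and writes GTF, count/FPKM/DE TSV tables,
#' bedGraph signal, BED sites, FASTA site sequences, the planted PWM and a
#' ground-truth JSON into `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the in-memory dataset (annotation, expression, track,
#'   sites) with a `paths` element naming every file written.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  trk <- simulate_gamma_track(cfg, ann, expr)
  sites <- simulate_binding_sites(cfg, ann,
                                  target_genes = expr$truth$induced$NeuNneg)
  p <- list(
    gtf = file.path(outdir, "genes.gtf"),
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    counts = file.path(outdir, "counts.tsv"),
    fpkm = file.path(outdir, "fpkm.tsv"),
    fpkm_mean = file.path(outdir, "fpkm_mean.tsv"),
    de_plus = file.path(outdir, "de_NeuNpos.tsv"),
    de_minus = file.path(outdir, "de_NeuNneg.tsv"),
    track = file.path(outdir, "gammaH2AX.bedgraph"),
    sites = file.path(outdir, "sites.bed"),
    fasta = file.path(outdir, "site_sequences.fa"),
    pwm = file.path(outdir, "motif.pwm"),
    truth = file.path(outdir, "ground_truth.json"))
  write_gtf_genes(ann$genes, p$gtf)
  utils::write.table(data.frame(names(ann$chrom_sizes), ann$chrom_sizes),
                     p$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_table(as.data.frame(expr$counts), p$counts, id_col = "gene")
  write_tsv_table(as.data.frame(expr$fpkm), p$fpkm, id_col = "gene")
  write_tsv_table(as.data.frame(expr$fpkm_mean), p$fpkm_mean, id_col = "gene")
  write_tsv_table(expr$de$NeuNpos, p$de_plus)
  write_tsv_table(expr$de$NeuNneg, p$de_minus)
  write_bedgraph(trk$track, p$track)
  write_bed(sites$sites, p$sites)
  Biostrings::writeXStringSet(sites$sequences, p$fasta)
  write_pwm(sites$pwm, p$pwm)
  jsonlite::write_json(
    list(induced = expr$truth$induced,
         induced_all = expr$truth$induced_all,
         excess_genes = names(expr$truth$excess)[expr$truth$excess],
         seed = cfg$seed),
    p$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, expression = expr, track = trk,
                 sites = sites, paths = p))
}
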