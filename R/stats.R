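#' Expressed-gene filter
#'
#' A gene counts as expressed when its FPKM is strictly greater than
#' `threshold` in at least one column (time point) of the table.
#'
#' @param fpkm_table Numeric matrix/data.frame, genes x conditions, rownames
#'   = gene ids.
#' @param threshold FPKM threshold (default 0.2).
#' @return Character vector of expressed gene ids.
#' @export
filter_expressed <- function(fpkm_table, threshold = 0.2) {
  stopifnot(threshold >= 0)
  fpkm_table <- as.matrix(fpkm_table)
  if (nrow(fpkm_table) == 0L) return(character(0))
  rownames(fpkm_table)[apply(fpkm_table > threshold, 1, any)]
}

#' Four-way differential grouping across nuclear fractions
#'
#' Classifies each gene by where its response occurs: up in the neuronal
#' fraction only, up in both, up in the non-neuronal fraction only, down
#' (significantly down somewhere and up nowhere), or not significant. "Up in
#' a fraction" means `padj < alpha` and `log2fc > 0` at any time point of
#' that fraction; a significant up-call outranks a down-call for the same
#' gene.
#'
#' @param de_plus,de_minus data.frames with columns `gene`, `log2fc`,
#'   `padj`, `timepoint` for the NeuN+ and NeuN- fractions.
#' @param gene_universe Character vector of genes to classify.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Named factor over `gene_universe` with levels `neuron_only_up`,
#'   `shared_up`, `nonneuron_only_up`, `down`, `ns`.
#' @export
classify_differential_grouping <- function(de_plus, de_minus, gene_universe,
                                           alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  check_de <- function(de, label) {
    if (anyDuplicated(de[, c("gene", "timepoint")])) {
      stop("duplicate (gene, timepoint) rows in ", label, " DE table")
    }
  }
  check_de(de_plus, "NeuN+"); check_de(de_minus, "NeuN-")
  call_dir <- function(de) {
    sig <- de$padj < alpha & !is.na(de$padj)
    list(up = unique(de$gene[sig & de$log2fc > 0]),
         down = unique(de$gene[sig & de$log2fc < 0]))
  }
  cp <- call_dir(de_plus); cm <- call_dir(de_minus)
  up_p <- gene_universe %in% cp$up
  up_m <- gene_universe %in% cm$up
  dn <- gene_universe %in% union(cp$down, cm$down)
  grp <- rep("ns", length(gene_universe))
  grp[dn] <- "down"
  grp[up_p & up_m] <- "shared_up"
  grp[up_p & !up_m] <- "neuron_only_up"
  grp[!up_p & up_m] <- "nonneuron_only_up"
  factor(stats::setNames(grp, gene_universe),
         levels = c("neuron_only_up", "shared_up", "nonneuron_only_up",
                    "down", "ns"))
}

#' Percentage of responsive genes regulated only in glia
#'
#' Over genes upregulated in at least one cell type, the percentage that are
#' up in at least one glial type (any column other than the neuronal one)
#' and not in neurons, rounded half-up to the nearest integer.
#'
#' @param up_table Logical matrix/data.frame, genes x cell types, with the
#'   neuronal column named by `neuron_col`; `TRUE` = upregulated.
#' @param neuron_col Name of the neuronal column (default "NeuNpos").
#' @return Integer percentage.
#' @export
glia_only_fraction <- function(up_table, neuron_col = "NeuNpos") {
  up_table <- as.matrix(up_table)
  stopifnot(neuron_col %in% colnames(up_table))
  any_up <- apply(up_table, 1, any)
  if (!any(any_up)) stop("no gene upregulated in any cell type; fraction undefined")
  glial <- up_table[, setdiff(colnames(up_table), neuron_col), drop = FALSE]
  glia_only <- apply(glial, 1, any) & !up_table[, neuron_col]
  as.integer(round_half_up(100 * sum(glia_only) / sum(any_up)))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether `|A intersect B|` is larger than expected for random draws
#' from the universe: upper-tail inclusive,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = |U|, K = |A|, n = |B|)`.
#' Genes outside the universe are dropped with a warning.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Non-empty character vector of gene ids.
#' @return List: `k` (overlap), `n_a`, `n_b`, `n_universe`, `p`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  a <- unique(set_a); b <- unique(set_b)
  dropped <- sum(!(a %in% universe)) + sum(!(b %in% universe))
  if (dropped > 0) {
    warning(dropped, " gene(s) outside the universe dropped")
  }
  a <- intersect(a, universe); b <- intersect(b, universe)
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  list(k = k, n_a = length(a), n_b = length(b),
       n_universe = length(universe), p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of a query gene list against each set of a
#' collection, over a background universe of expressed genes; sets and the
#' query are intersected with the background first, and BH correction is
#' applied across the tested sets.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Non-empty character vector: the expressed-gene universe.
#' @param p_cutoff Significance cutoff applied to the BH-adjusted q
#'   (default 0.01).
#' @param report_all Return all sets (`TRUE`) or only those with
#'   `q <= p_cutoff` (default).
#' @return data.frame: `set`, `k`, `set_size`, `query_size`, `universe_size`,
#'   `p`, `q`, `significant`; ordered by `p`.
#' @export
ora_gene_sets <- function(query, sets, background, p_cutoff = 0.01,
                          report_all = FALSE) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background universe")
  query <- intersect(unique(query), background)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(background) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, k = k, set_size = length(s),
               query_size = length(query),
               universe_size = length(background), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q <= p_cutoff
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  if (!report_all) res <- res[res$significant, , drop = FALSE]
  res
}

#' Expression-matched permutation test of break-signal excess
#'
#' Asks whether a target gene set (e.g. learning-upregulated genes) carries
#' more gammaH2AX signal than expected from its expression level alone.
#' Targets are divided into expression bins (quantiles of the *target*
#' expression distribution); each permutation draws, without replacement and
#' per bin, as many universe genes as there are targets in that bin, and the
#' null distribution is the mean signal of the pooled pseudo-target sets.
#' The empirical p-value is the fraction of permutations whose mean signal
#' reaches the observed target mean.
#'
#' @param targets Character vector of target gene ids; must be a subset of
#'   `universe`.
#' @param expression Named per-gene expression (weighted whole-tissue FPKM).
#' @param signal Named per-gene gammaH2AX RPKM.
#' @param universe Character vector of expressed gene ids.
#' @param n_bins Number of expression-matching bins (default 10).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param tail `"geq"` (inclusive, default) or `"gt"` for the comparison of
#'   null means against the observed mean.
#' @return List of class `permutation_result`: `observed_mean`,
#'   `null_means`, `expected_mean`, `p_value` (fraction rule),
#'   `p_value_plus1` (the `(k+1)/(n+1)` estimator), `matching` (per-bin
#'   counts and mean expression of targets vs null draws) and the echoed
#'   configuration.
#' @export
expression_matched_permutation <- function(targets, expression, signal,
                                           universe, n_bins = 10L,
                                           n_perm = 1000L, seed = 1L,
                                           tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  stopifnot(n_perm >= 1, n_bins >= 1)
  universe <- unique(universe)
  targets <- unique(targets)
  if (!all(targets %in% universe)) {
    stop("targets must be a subset of the expressed-gene universe")
  }
  if (n_bins > length(targets)) {
    stop("n_bins exceeds the number of target genes; use fewer bins")
  }
  stopifnot(all(universe %in% names(expression)),
            all(universe %in% names(signal)))
  expr_u <- expression[universe]
  sig_u <- signal[universe]

  edges <- stats::quantile(expression[targets],
                           probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7)
  inner <- unique(edges[-c(1, length(edges))])
  bin_u <- findInterval(expr_u, inner) + 1L   # 1 .. length(inner)+1
  bin_t <- bin_u[match(targets, universe)]
  tcount <- table(factor(bin_t, levels = seq_len(length(inner) + 1L)))
  ucount <- table(factor(bin_u, levels = seq_len(length(inner) + 1L)))
  short <- which(as.integer(ucount) < as.integer(tcount))
  if (length(short)) {
    stop("expression bin ", short[1], " has fewer universe genes (",
         ucount[short[1]], ") than required draws (", tcount[short[1]],
         "); use fewer bins")
  }

  used_bins <- which(as.integer(tcount) > 0)
  strata_sig <- lapply(used_bins, function(b) unname(sig_u[bin_u == b]))
  strata_expr <- lapply(used_bins, function(b) unname(expr_u[bin_u == b]))
  draws <- as.integer(tcount)[used_bins]
  n_target <- length(targets)

  observed_mean <- mean(signal[targets])
  null_means <- numeric(n_perm)
  null_expr_means <- numeric(n_perm)
  null_logexpr_means <- numeric(n_perm)
  strata_logexpr <- lapply(strata_expr, log1p)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      ssum <- 0; esum <- 0; lsum <- 0
      for (j in seq_along(used_bins)) {
        idx <- sample.int(length(strata_sig[[j]]), draws[j])
        ssum <- ssum + sum(strata_sig[[j]][idx])
        esum <- esum + sum(strata_expr[[j]][idx])
        lsum <- lsum + sum(strata_logexpr[[j]][idx])
      }
      null_means[i] <- ssum / n_target
      null_expr_means[i] <- esum / n_target
      null_logexpr_means[i] <- lsum / n_target
    }
  })
  k <- if (tail == "geq") sum(null_means >= observed_mean) else
    sum(null_means > observed_mean)
  tgt_logmean <- mean(log1p(expression[targets]))
  matching <- list(
    bin_target_counts = as.integer(tcount),
    bin_universe_counts = as.integer(ucount),
    target_mean_fpkm = mean(expression[targets]),
    null_mean_fpkm = mean(null_expr_means),
    relative_fpkm_difference =
      abs(mean(null_expr_means) - mean(expression[targets])) /
      mean(expression[targets]),
    # log-scale (geometric-mean-like) version: heavy-tailed FPKM makes the
    # arithmetic mean a single-gene-dominated diagnostic
    target_mean_log1p_fpkm = tgt_logmean,
    null_mean_log1p_fpkm = mean(null_logexpr_means),
    relative_log1p_fpkm_difference =
      abs(mean(null_logexpr_means) - tgt_logmean) / tgt_logmean)
  structure(list(observed_mean = observed_mean,
                 null_means = null_means,
                 expected_mean = mean(null_means),
                 p_value = k / n_perm,
                 p_value_plus1 = (k + 1) / (n_perm + 1),
                 matching = matching,
                 config = list(n_bins = n_bins, n_perm = n_perm, seed = seed,
                               tail = tail, n_targets = n_target,
                               n_universe = length(universe))),
            class = "permutation_result")
}

#' Observed-versus-expected summary of a permutation result
#'
#' @param result A `permutation_result` from
#'   [expression_matched_permutation()].
#' @return data.frame with one row: observed and expected (null) mean
#'   signal, their difference and ratio, both p-value estimators, and a
#'   `p_label` rendering `p = 0` as `"< 1/n_perm"`.
#' @export
observed_vs_expected_summary <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  n <- result$config$n_perm
  out <- data.frame(
    observed = result$observed_mean,
    expected = result$expected_mean,
    difference = result$observed_mean - result$expected_mean,
    ratio = result$observed_mean / result$expected_mean,
    p_value = result$p_value,
    p_value_plus1 = result$p_value_plus1,
    p_label = if (result$p_value == 0) paste0("< 1/", n) else
      format(result$p_value, digits = 4),
    stringsAsFactors = FALSE)
  attr(out, "null_breaks") <-
    pretty(c(result$null_means, result$observed_mean), n = 30)
  out
}
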