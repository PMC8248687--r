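pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = NULL,   # list of sim_config() overrides, or NULL when inputs given
    inputs = NULL,     # list of file paths for a pre-existing dataset
    quantify = list(weights = c(0.6, 0.4)),
    peaks = list(window = 200L, stringent_cutoff = 1e-5,
                 relaxed_cutoff = 0.1, max_gap = 1000L,
                 min_overlap_frac = 0.5),
    stats = list(n_bins = 10L, n_perm = 1000L, alpha = 0.05,
                 expressed_fpkm = 0.2, ora_cutoff = 0.01, tail = "geq"),
    profile = list(flank = 2000L, bin_width = 50L),
    motif = list(threshold_bits = 8))
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML config, fills defaults, and rejects unknown keys. The config
#' must contain either a `simulate:` block (generator overrides; `{}` for
#' all defaults) or an `inputs:` block of file paths.
#'
#' @param path Path to a YAML config file, or a list already in memory.
#' @return Normalised config list of class `run_config`.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else if (is.list(path)) path else stop("config must be a file path or list")
  defs <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; expected one of: ", paste(names(defs), collapse = ", "))
  }
  cfg <- defs
  for (k in names(raw)) {
    if (k %in% c("simulate", "inputs")) { cfg[[k]] <- raw[[k]]; next }
    if (is.list(defs[[k]])) {
      bad <- setdiff(names(raw[[k]]), names(defs[[k]]))
      if (length(bad)) {
        stop("unknown key(s) in '", k, "' block: ", paste(bad, collapse = ", "))
      }
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  if (!is.null(cfg$simulate)) {
    bad <- setdiff(names(cfg$simulate), names(formals(sim_config)))
    if (length(bad)) {
      stop("unknown key(s) in 'simulate' block: ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config requires a 'simulate' block (generator parameters, or {} ",
         "for defaults) or an 'inputs' block of file paths")
  }
  w <- as.numeric(cfg$quantify$weights)
  if (length(w) != 2L || abs(sum(w) - 1) > 1e-8) {
    stop("quantify$weights must be two numbers summing to 1")
  }
  cfg$quantify$weights <- w
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full break-mapping pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> peaks -> stats and writes
#' every intermediate plus `report.json` and `report.md` into `outdir`. A
#' `MANIFEST` file lists the completed stages; on a stage failure partial
#' artifacts and the manifest are retained.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list
#'   accepted by it).
#' @param outdir Output directory.
#' @return The report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note_stage <- function(s) {
    manifest <<- c(manifest, s)
    writeLines(manifest, file.path(outdir, "MANIFEST"))
    message("[breakscan] stage complete: ", s)
  }
  report <- list(package_version = as.character(utils::packageVersion("breakscan")),
                 seed = config$seed)

  ## ---- stage: data ----
  if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    ds <- simulate_dataset(scfg, file.path(outdir, "simulated"))
    genes <- ds$annotation$genes
    chrom_sizes <- ds$annotation$chrom_sizes
    fpkm_mean <- ds$expression$fpkm_mean
    de <- ds$expression$de
    track <- ds$track$track
    sites <- ds$sites$sites
    site_seqs <- ds$sites$sequences
    pwm <- ds$sites$pwm
    gene_sets <- c(
      list(induced_neuron = ds$expression$truth$induced$NeuNpos,
           induced_glia = ds$expression$truth$induced$NeuNneg),
      with_seed(config$seed + 7L, {
        lapply(stats::setNames(1:3, paste0("random_set_", 1:3)),
               function(i) sample(genes$gene_id, 50))
      }))
    gene_sets <- Filter(function(s) length(s) > 0, gene_sets)
    write_gmt(gene_sets, file.path(outdir, "simulated", "gene_sets.gmt"))
  } else {
    inp <- config$inputs
    genes <- read_gtf_genes(inp$gtf)
    track <- read_bedgraph(inp$track)
    cs <- utils::read.delim(inp$chrom_sizes, header = FALSE)
    chrom_sizes <- stats::setNames(cs[[2]], cs[[1]])
    fpkm_mean <- as.matrix(read_tsv_table(inp$fpkm_mean, row_names = TRUE))
    de <- list(NeuNpos = read_tsv_table(inp$de_plus),
               NeuNneg = read_tsv_table(inp$de_minus))
    sites <- if (!is.null(inp$sites)) read_bed(inp$sites) else NULL
    site_seqs <- if (!is.null(inp$fasta)) Biostrings::readDNAStringSet(inp$fasta) else NULL
    pwm <- if (!is.null(inp$pwm)) read_pwm(inp$pwm) else NULL
    gene_sets <- if (!is.null(inp$gmt)) read_gmt(inp$gmt) else NULL
  }
  report$n_genes <- length(genes)
  report$n_track_intervals <- length(track)
  note_stage("data")

  ## ---- stage: quantify ----
  gb <- gene_body_signal(track, genes)
  w <- config$quantify$weights
  wexpr <- weighted_tissue_expression(
    stats::setNames(fpkm_mean[, "NeuNpos_t30"], rownames(fpkm_mean)),
    stats::setNames(fpkm_mean[, "NeuNneg_t30"], rownames(fpkm_mean)),
    w[1], w[2])
  signal <- stats::setNames(gb$rpkm, gb$gene)
  pb <- percentile_bins(wexpr[gb$gene], signal, n_bins = config$stats$n_bins)
  write_tsv_table(gb, file.path(outdir, "gene_body_signal.tsv"))
  write_tsv_table(pb$summary, file.path(outdir, "expression_bins.tsv"))
  report$expression_bin_summary <- pb$summary
  note_stage("quantify")

  ## ---- stage: peaks ----
  pk <- config$peaks
  stringent <- call_broad_peaks(track, chrom_sizes, window = pk$window,
                                p_cutoff = pk$stringent_cutoff,
                                max_gap = pk$max_gap)
  relaxed <- call_broad_peaks(track, chrom_sizes, window = pk$window,
                              p_cutoff = pk$relaxed_cutoff,
                              max_gap = pk$max_gap)
  peaks <- two_tier_filter(stringent, relaxed)
  ann <- annotate_peaks_to_genes(peaks, genes, min_frac = pk$min_overlap_frac)
  peak_genes <- unique(ann$gene[!is.na(ann$gene)])
  write_bed(peaks, file.path(outdir, "peaks_two_tier.bed"))
  write_tsv_table(ann, file.path(outdir, "peak_gene_annotation.tsv"))
  report$peaks <- list(n_stringent = length(stringent),
                       n_relaxed = length(relaxed),
                       n_two_tier = length(peaks),
                       n_peak_genes = length(peak_genes))
  lr <- tryCatch(length_regression(genes, peaks, ann), error = function(e) NULL)
  report$length_regression <- lr[c("slope", "intercept", "r", "n")]
  if (!is.null(sites) && !is.null(site_seqs) && !is.null(pwm)) {
    hits <- scan_pwm(site_seqs, pwm, threshold = config$motif$threshold_bits)
    ng <- nearest_gene(sites, genes)
    prof <- aggregate_profile(track, sites, flank = config$profile$flank,
                              bin_width = config$profile$bin_width)
    write_tsv_table(hits, file.path(outdir, "motif_hits.tsv"))
    write_tsv_table(ng, file.path(outdir, "site_nearest_gene.tsv"))
    write_tsv_table(data.frame(bin_mid = prof$bin_mid, mean = prof$values),
                    file.path(outdir, "site_profile.tsv"))
    report$motif <- list(n_sites = length(sites),
                         n_sites_with_hit = length(unique(hits$site_id)),
                         n_hits = nrow(hits),
                         profile_apex_bin = prof$apex,
                         profile_apex_bp = prof$bin_mid[prof$apex])
  }
  note_stage("peaks")

  ## ---- stage: stats ----
  st <- config$stats
  universe <- filter_expressed(fpkm_mean, threshold = st$expressed_fpkm)
  grouping <- classify_differential_grouping(de$NeuNpos, de$NeuNneg,
                                             universe, alpha = st$alpha)
  report$differential_grouping <- as.list(table(grouping))
  up_plus_sig <- function(tp) {
    d <- de$NeuNpos
    unique(d$gene[d$padj < st$alpha & !is.na(d$padj) & d$log2fc > 0 &
                    d$timepoint == tp])
  }
  report$overlap_tests <- list()
  report$permutation <- list()
  for (tp in intersect(c("t10", "t30"), unique(de$NeuNpos$timepoint))) {
    up <- intersect(up_plus_sig(tp), universe)
    if (length(up) >= 2) {
      ov <- hypergeometric_overlap(peak_genes, up, universe)
      report$overlap_tests[[tp]] <- ov
    }
    if (length(up) >= st$n_bins) {
      pr <- expression_matched_permutation(
        up, wexpr, signal, universe, n_bins = st$n_bins,
        n_perm = st$n_perm, seed = config$seed, tail = st$tail)
      report$permutation[[tp]] <- c(
        as.list(observed_vs_expected_summary(pr)),
        list(matching = pr$matching))
      jsonlite::write_json(unclass(pr),
                           file.path(outdir, paste0("permutation_", tp, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(gene_sets)) {
    up_all <- intersect(unique(de$NeuNpos$gene[de$NeuNpos$padj < st$alpha &
                                                 !is.na(de$NeuNpos$padj) &
                                                 de$NeuNpos$log2fc > 0]),
                        universe)
    ora <- ora_gene_sets(up_all, gene_sets, universe,
                         p_cutoff = st$ora_cutoff, report_all = TRUE)
    write_tsv_table(ora, file.path(outdir, "ora.tsv"))
    report$ora <- ora
  }
  note_stage("stats")

  ## ---- report ----
  cfg_path <- file.path(outdir, "config_normalized.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  report$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  note_stage("report")
  invisible(report)
}

render_report_md <- function(report) {
  num <- function(x) format(x, digits = 6)
  lines <- c(
    "# breakscan run report", "",
    paste0("- package version: ", report$package_version),
    paste0("- seed: ", report$seed),
    paste0("- genes: ", report$n_genes),
    "", "## Peaks",
    paste0("- stringent / relaxed / two-tier: ", report$peaks$n_stringent,
           " / ", report$peaks$n_relaxed, " / ", report$peaks$n_two_tier),
    paste0("- genes with an annotated peak: ", report$peaks$n_peak_genes),
    "", "## Differential grouping",
    vapply(names(report$differential_grouping), function(k)
      paste0("- ", k, ": ", report$differential_grouping[[k]]), character(1)))
  if (length(report$permutation)) {
    lines <- c(lines, "", "## Expression-matched permutation test")
    for (tp in names(report$permutation)) {
      p <- report$permutation[[tp]]
      lines <- c(lines, paste0(
        "- ", tp, ": observed ", num(p$observed), " vs expected ",
        num(p$expected), " (ratio ", num(p$ratio), "), p ", p$p_label,
        " [", p$p_value, "; (k+1)/(n+1) = ", num(p$p_value_plus1), "]"))
    }
  }
  lines
}
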