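#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   reduce findOverlaps pintersect resize mcols mcols<- sort GRangesList
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqlevels<-
NULL

# Coordinate convention: GRanges (1-based, closed) everywhere inside the
# package; BED/bedGraph (0-based, half-open) are converted at the I/O
# boundary. Interval lengths, overlap lengths and merge gaps are identical
# under either convention.

#' Read a BED file of genomic intervals
#'
#' Reads BED3+ into a `GRanges`. Columns 4-6 (name, score, strand) are kept
#' when present. Coordinates are converted from BED 0-based half-open to the
#' 1-based closed convention `GRanges` uses, so a BED line `chr1 0 100`
#' becomes `chr1:1-100` (width 100).
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A `GRanges`, with metadata columns `name` and `score` if the file
#'   has them.
#' @details Malformed lines (fewer than 3 fields, non-integer coordinates,
#'   `end <= start`, negative start) raise an error naming the line number.
#'   Empty files yield an empty `GRanges`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(s) | !is.finite(e) | s != floor(s) | e != floor(e))
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(e <= s | s < 0)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L],
         ": requires 0 <= start < end, got [", s[bad[1L]], ", ", e[bad[1L]], ")")
  }
  strand <- rep("*", length(lines))
  if (all(nf >= 6L)) {
    strand6 <- vapply(fields, `[[`, character(1), 6L)
    strand <- ifelse(strand6 %in% c("+", "-"), strand6, "*")
  }
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = strand)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 5L)) {
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5L)))
  }
  gr
}

#' Write intervals to BED
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are written as
#'   BED columns 4-5 when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  has_name <- !is.null(mcols(gr)$name)
  has_score <- !is.null(mcols(gr)$score)
  if (has_name || has_score) {
    df$name <- if (has_name) mcols(gr)$name else "."
  }
  if (has_score) {
    df$score <- mcols(gr)$score
    st <- as.character(strand(gr))
    if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Keeps only rows with feature type `gene` (ensembl dialect) and returns one
#' range per gene spanning TSS to TES (introns and exons). GTF 1-based
#' inclusive coordinates map directly onto the `GRanges` convention.
#'
#' @param path Path to a GTF file.
#' @return `GRanges` with metadata columns `gene_id` and `gene_name`
#'   (`gene_name` falls back to `gene_id` when absent).
#' @export
read_gtf_genes <- function(path) {
  stopifnot(file.exists(path))
  gtf <- rtracklayer::import(path, format = "gtf")
  genes <- gtf[!is.na(gtf$type) & as.character(gtf$type) == "gene"]
  if (length(genes) == 0L) {
    gr <- GRanges()
    mcols(gr)$gene_id <- character(0)
    mcols(gr)$gene_name <- character(0)
    return(gr)
  }
  if (is.null(genes$gene_id) || anyNA(genes$gene_id)) {
    stop("GTF parse error: gene row missing required gene_id attribute")
  }
  out <- granges(genes)
  mcols(out)$gene_id <- as.character(genes$gene_id)
  gn <- if (!is.null(genes$gene_name)) as.character(genes$gene_name) else NA_character_
  mcols(out)$gene_name <- ifelse(is.na(gn), as.character(genes$gene_id), gn)
  out
}

#' Write gene models as ensembl-dialect GTF gene rows
#'
#' @param genes `GRanges` with `gene_id` (and optionally `gene_name`)
#'   metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path) {
  stopifnot(!is.null(genes$gene_id))
  nm <- if (!is.null(genes$gene_name)) genes$gene_name else genes$gene_id
  st <- as.character(strand(genes))
  st[st == "*"] <- "."
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', genes$gene_id, nm)
  lines <- sprintf("%s\tbreakscan\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(seqnames(genes)), start(genes), end(genes),
                   st, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Strand-aware transcription start sites
#'
#' Returns the 5' end of each gene model as a width-1 `GRanges`; for `-`
#' strand genes this is the rightmost base, for `+` or unstranded genes the
#' leftmost.
#'
#' @param genes `GRanges` of gene bodies.
#' @return Width-1 `GRanges`, metadata preserved.
#' @export
gene_tss <- function(genes) {
  resize(genes, width = 1L, fix = "start", ignore.strand = FALSE)
}

#' Read a bedGraph signal track
#'
#' A signal track is a `GRanges` with a non-negative numeric `score`
#' (signal density per base) whose intervals are sorted and non-overlapping
#' within each chromosome.
#'
#' @param path Path to a bedGraph file.
#' @return A sorted `GRanges` with `score`.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  validate_track(gr)
}

#' Write a signal track to bedGraph
#'
#' @param track Signal-track `GRanges` (see [read_bedgraph()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_track(track)
  df <- data.frame(as.character(seqnames(track)), start(track) - 1L,
                   end(track), track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a signal track
#'
#' Checks the signal-track invariants: numeric `score`, no negative values,
#' no overlapping intervals within a chromosome. Returns the track sorted.
#'
#' @param track A `GRanges` with a `score` metadata column.
#' @return The sorted track.
#' @export
validate_track <- function(track) {
  if (is.null(track$score)) stop("signal track requires a 'score' column")
  if (any(track$score < 0)) stop("signal track values must be non-negative")
  track <- GenomicRanges::sort(track, ignore.strand = TRUE)
  if (!IRanges::isDisjoint(granges(track))) {
    stop("signal track intervals overlap within a chromosome")
  }
  track
}

#' Overlap length between two sets of intervals, elementwise
#'
#' Vectorised over pairs (shorter argument recycled). Strand is ignored;
#' intervals on different chromosomes overlap by 0 bp.
#'
#' @param a,b `GRanges` of equal (or recyclable) length.
#' @return Integer vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  pmax(ov, 0L)
}

#' Merge intervals within a gap tolerance
#'
#' Two intervals are merged iff the gap between them is at most `max_gap`
#' bases (gap 0 = abutting). Strand-blind. With `max_gap = 0` the union of
#' covered bases is preserved.
#'
#' @param gr `GRanges`.
#' @param max_gap Non-negative gap tolerance in bp.
#' @return Sorted, non-overlapping `GRanges`.
#' @export
merge_intervals <- function(gr, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  reduce(gr, min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
}

#' Read a GMT gene-set collection
#'
#' Format: one set per line, tab-separated `name`, `description`, members.
#' Duplicate genes within a set are dropped; empty sets are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("GMT parse error: line with fewer than 3 fields (name, description, >=1 gene)")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (any(lengths(sets) == 0L)) stop("GMT parse error: empty gene set")
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
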