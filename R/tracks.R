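#' Per-base signal track for one strand
#'
#' A minimal container for PRO-seq-like single-nucleotide coverage: a vector
#' of non-negative counts along one synthetic chromosome, one strand.
#' Coordinates are 0-based half-open throughout the package (the BED /
#' bedGraph convention): the count at 0-based position `i` is stored at R
#' index `i + 1`.
#'
#' @param counts Numeric vector of non-negative per-base counts.
#' @param chrom Chromosome name; default `"chrS"`.
#' @param strand `"+"` or `"-"` (informational).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(counts, chrom = "chrS", strand = "+") {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("track counts must be finite and non-negative", call. = FALSE)
  structure(list(chrom = chrom, strand = strand, counts = as.numeric(counts)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s (%s strand), %d bp, %g total counts\n",
              x$chrom, x$strand, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write a signal track as bedGraph
#'
#' Zero runs are omitted, equal-count neighbours are merged into one
#' interval; intervals are 0-based half-open. Counts are written as plain
#' (non-negative) values on both strands.
#'
#' @param track A [signal_track()].
#' @param path Output path (`.bedgraph`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  runs <- rle(track$counts)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = runs$values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a signal track
#'
#' Negative scores (a dialect some PRO-seq pipelines use to encode the minus
#' strand) are converted to their absolute value with a warning.
#'
#' @param path Path to a bedGraph file.
#' @param genome_length Length of the chromosome; intervals beyond it are an
#'   error.
#' @param chrom Expected chromosome name; other sequences are an error.
#' @param strand Strand label to attach to the returned track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, genome_length, chrom = "chrS", strand = "+") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  counts <- numeric(genome_length)
  if (length(gr)) {
    bad <- as.character(GenomicRanges::seqnames(gr)) != chrom
    if (any(bad))
      stop(path, ": unexpected chromosome(s) ",
           paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                 collapse = ", "), call. = FALSE)
    if (max(GenomicRanges::end(gr)) > genome_length)
      stop(path, ": interval extends beyond genome length ", genome_length,
           call. = FALSE)
    score <- S4Vectors::mcols(gr)$score
    if (any(score < 0)) {
      warning(path, ": negative bedGraph scores interpreted as ",
              "minus-strand magnitudes (absolute value taken)", call. = FALSE)
      score <- abs(score)
    }
    cov <- IRanges::coverage(IRanges::ranges(gr), weight = score,
                             width = genome_length)
    counts <- as.numeric(cov)
  }
  signal_track(counts, chrom = chrom, strand = strand)
}

#' Write gene annotations as BED6
#'
#' One record per gene spanning pause-window start to body-window end (on
#' the genome), `name` = gene id, `score` = 1 for perturbation-target genes
#' and 0 otherwise, and the gene strand.
#'
#' @param genes Gene annotation data.frame from [generate_genes()].
#' @param path Output path (`.bed`).
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  span_start <- pmin(genes$pause_start, genes$body_start)
  span_end <- pmax(genes$pause_end, genes$body_end)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = span_start + 1L, end = span_end),
    strand = genes$strand,
    name = genes$gene_id,
    score = as.integer(genes$is_target)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED6 gene annotations
#'
#' Reconstructs the TSS and the pause/body windows from the gene span and
#' strand: the TSS is the 5' end of the record, the pause window is
#' `[TSS, TSS + l_p)` and the body window `[TSS + body_offset,
#' TSS + body_offset + l_b)` in the direction of transcription (coordinates
#' 0-based half-open).
#'
#' @param path Path to a BED6 file written by [write_genes_bed()].
#' @param l_p Pause-window length (bp).
#' @param body_offset Distance from the TSS to the body-window start (bp).
#' @param l_b Body-window length (bp).
#' @return A gene annotation data.frame in the layout of [generate_genes()].
#' @export
read_genes_bed <- function(path, l_p = 100, body_offset = 500, l_b = 10000) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) stop(path, ": no gene records", call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop(path, ": gene records must carry an explicit +/- strand",
         call. = FALSE)
  start0 <- GenomicRanges::start(gr) - 1L  # back to 0-based
  end0 <- GenomicRanges::end(gr)
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  mk_windows(data.frame(
    gene_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = as.integer(tss),
    strand = strand,
    is_target = if (!is.null(S4Vectors::mcols(gr)$score))
      S4Vectors::mcols(gr)$score > 0 else FALSE,
    stringsAsFactors = FALSE
  ), l_p = l_p, body_offset = body_offset, l_b = l_b)
}

# internal: attach 0-based half-open pause/body windows to a gene table
mk_windows <- function(genes, l_p, body_offset, l_b) {
  plus <- genes$strand == "+"
  genes$pause_start <- ifelse(plus, genes$tss, genes$tss - l_p + 1L)
  genes$pause_end <- genes$pause_start + l_p
  genes$body_start <- ifelse(plus, genes$tss + body_offset,
                             genes$tss - body_offset - l_b + 1L)
  genes$body_end <- genes$body_start + l_b
  genes$l_p <- l_p
  genes$l_b <- l_b
  genes
}
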