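#' Depth-normalized read density in a genomic window
#'
#' Sums the counts in the 0-based half-open interval `[start, end)` and
#' divides by the window length and the library scale factor, giving counts
#' per bp (per million mapped reads when `scale` is a CPM factor).
#'
#' @param track A [signal_track()].
#' @param start,end Window coordinates, 0-based half-open; must lie within
#'   the track.
#' @param scale Library scale factor; default 1 (raw counts per bp).
#' @return The window density.
#' @examples
#' tr <- signal_track(rep(3, 100))
#' window_density(tr, 0, 100)  # 3
#' @export
window_density <- function(track, start, end, scale = 1) {
  stopifnot(inherits(track, "signal_track"))
  if (start < 0 || end > length(track$counts) || start >= end)
    stop("window [", start, ", ", end, ") out of track bounds [0, ",
         length(track$counts), ")", call. = FALSE)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  sum(track$counts[(start + 1):end]) / (end - start) / scale
}

#' Library scale factor for a pair of strand tracks
#'
#' Counts-per-million scaling: total mapped counts over both strands
#' divided by 1e6.
#'
#' @param tracks A list with `plus` and `minus` [signal_track()]s.
#' @return The CPM scale factor (total counts / 1e6).
#' @export
library_scale <- function(tracks) {
  (sum(tracks$plus$counts) + sum(tracks$minus$counts)) / 1e6
}

#' Per-gene pause and body densities, and pause indices
#'
#' Summarizes a pair of strand tracks over each gene's pause and body
#' windows: raw counts, depth-normalized densities (counts per bp per scale
#' unit) and the pause index (pause density / body density). Each gene is
#' read from the track matching its strand.
#'
#' @param tracks A list with `plus` and `minus` [signal_track()]s for one
#'   condition.
#' @param genes Gene annotation data.frame ([generate_genes()] or
#'   [read_genes_bed()]).
#' @param condition Label stored in the `condition` column.
#' @param scale `"cpm"` (default: total-count CPM via [library_scale()]),
#'   `"none"`, or an explicit positive number.
#' @return A data.frame of class `density_summary` with one row per gene:
#'   `gene_id`, `condition`, `pause_count`, `body_count`, `pause_density`,
#'   `body_density`, `pause_index` (`NA` where the body window is empty),
#'   and the `scale` factor used. Window lengths are attached as attributes
#'   `l_p` and `l_b`.
#' @export
summarize_densities <- function(tracks, genes, condition = "A",
                                scale = "cpm") {
  if (is.null(tracks$plus) || is.null(tracks$minus))
    stop("tracks must supply both 'plus' and 'minus' strands", call. = FALSE)
  sf <- if (identical(scale, "cpm")) library_scale(tracks)
        else if (identical(scale, "none")) 1
        else as.numeric(scale)
  if (!is.finite(sf) || sf <= 0)
    stop("invalid library scale factor: ", sf, call. = FALSE)
  n <- nrow(genes)
  pause_count <- body_count <- numeric(n)
  for (i in seq_len(n)) {
    tr <- if (genes$strand[i] == "+") tracks$plus else tracks$minus
    pause_count[i] <- sum(tr$counts[(genes$pause_start[i] + 1):genes$pause_end[i]])
    body_count[i] <- sum(tr$counts[(genes$body_start[i] + 1):genes$body_end[i]])
  }
  l_p <- genes$pause_end - genes$pause_start
  l_b <- genes$body_end - genes$body_start
  pause_density <- pause_count / l_p / sf
  body_density <- body_count / l_b / sf
  out <- data.frame(
    gene_id = genes$gene_id, condition = condition,
    pause_count = pause_count, body_count = body_count,
    pause_density = pause_density, body_density = body_density,
    pause_index = ifelse(body_density > 0, pause_density / body_density,
                         NA_real_),
    scale = sf, l_p = l_p, l_b = l_b,
    stringsAsFactors = FALSE
  )
  class(out) <- c("density_summary", "data.frame")
  out
}

#' Composite (metagene) profile around the TSS
#'
#' Averages depth-normalized per-base density across genes as a function of
#' position relative to the TSS, with minus-strand genes flipped so that
#' downstream is positive.
#'
#' @inheritParams summarize_densities
#' @param upstream Bases upstream of the TSS to include; default 500.
#' @param downstream Bases downstream (inclusive of the TSS base); default
#'   2000.
#' @return A data.frame of class `composite_profile`: `pos` (bp relative to
#'   TSS, `-upstream .. downstream - 1`), `density` (mean normalized
#'   density) and attribute `n_genes`.
#' @export
composite_profile <- function(tracks, genes, upstream = 500,
                              downstream = 2000, scale = "cpm") {
  if (nrow(genes) == 0) stop("empty gene set", call. = FALSE)
  sf <- if (identical(scale, "cpm")) library_scale(tracks)
        else if (identical(scale, "none")) 1
        else as.numeric(scale)
  pos <- seq(-upstream, downstream - 1)
  acc <- numeric(length(pos))
  for (i in seq_len(nrow(genes))) {
    tr <- if (genes$strand[i] == "+") tracks$plus else tracks$minus
    if (genes$strand[i] == "+") {
      idx <- genes$tss[i] + pos + 1  # 0-based genomic -> 1-based index
    } else {
      idx <- genes$tss[i] - pos + 1
    }
    if (min(idx) < 1 || max(idx) > length(tr$counts))
      stop("composite span exceeds track bounds for gene ",
           genes$gene_id[i], call. = FALSE)
    acc <- acc + tr$counts[idx]
  }
  out <- data.frame(pos = pos, density = acc / nrow(genes) / sf)
  attr(out, "n_genes") <- nrow(genes)
  class(out) <- c("composite_profile", "data.frame")
  out
}

#' Between-condition fold changes of pause and body densities
#'
#' For each gene, computes log2 fold changes (condition B over A) of the
#' pause and body densities with a pseudocount added to the window counts
#' before density conversion, plus the pause-index change
#' `delta_pause_index = pause log2FC - body log2FC`. Swapping A and B
#' negates every record.
#'
#' @param summary_a,summary_b [summarize_densities()] outputs for the two
#'   conditions; gene sets must match.
#' @param pseudocount Count added to each window before the density
#'   conversion; default 0.25.
#' @return A data.frame of class `fold_change`: `gene_id`, `lfc_pause`,
#'   `lfc_body`, `delta_pause_index`, plus the pseudocounted densities
#'   `pause_density_a`, `pause_density_b`, `body_density_a`,
#'   `body_density_b` used to compute them.
#' @export
compare_conditions <- function(summary_a, summary_b, pseudocount = 0.25) {
  if (!identical(summary_a$gene_id, summary_b$gene_id))
    stop("condition summaries cover different gene sets", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  dens <- function(s)
    list(p = (s$pause_count + pseudocount) / s$l_p / s$scale,
         b = (s$body_count + pseudocount) / s$l_b / s$scale)
  da <- dens(summary_a); db <- dens(summary_b)
  out <- data.frame(
    gene_id = summary_a$gene_id,
    lfc_pause = log2(db$p / da$p),
    lfc_body = log2(db$b / da$b),
    pause_density_a = da$p, pause_density_b = db$p,
    body_density_a = da$b, body_density_b = db$b,
    stringsAsFactors = FALSE
  )
  out$delta_pause_index <- out$lfc_pause - out$lfc_body
  class(out) <- c("fold_change", "data.frame")
  out
}
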