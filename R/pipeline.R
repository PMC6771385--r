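#' Run the synthetic-data analysis pipeline end to end
#'
#' Generates (or reuses) a two-condition synthetic dataset, writes it to
#' disk in standard formats, re-reads the files, quantifies per-gene pause
#' and body densities in both conditions, computes between-condition fold
#' changes, and classifies the mechanism behind each gene's density change.
#' All randomness derives from `config$seed`, so a rerun with the same
#' configuration reproduces every output byte for byte.
#'
#' Outputs written to `outdir`: the dataset files of [write_dataset()],
#' `densities.tsv` (both conditions), `foldchange.tsv`, `mechanisms.tsv`,
#' and `run_info.json` (a provenance record echoing the configuration, the
#' seed and the package version).
#'
#' @param config A [synth_config()].
#' @param outdir Output directory; created if absent.
#' @param scale Library normalization passed to [summarize_densities()];
#'   default `"cpm"`.
#' @param tol Log2 no-change band for [classify_mechanism()]; default 0.2.
#' @param pseudocount Pseudocount for [compare_conditions()]; default 0.25.
#' @param resume If `TRUE` and the dataset files already exist in `outdir`,
#'   skip generation and quantify the existing files.
#' @return Invisibly, a list with `genes`, `summary_a`, `summary_b`, `fc`,
#'   `mechanisms`, and `outdir`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_genes = 12, seed = 7)
#' res <- run_pipeline(cfg, outdir = tempfile("pipeline"))
#' table(res$mechanisms$call)
#' }
#' @export
run_pipeline <- function(config, outdir, scale = "cpm", tol = 0.2,
                         pseudocount = 0.25, resume = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c("genes.bed", "condA_plus.bedgraph", "condA_minus.bedgraph",
             "condB_plus.bedgraph", "condB_minus.bedgraph")
  have_all <- all(file.exists(file.path(outdir, files)))
  slot <- config$body_offset + config$l_b + config$spacing
  margin <- config$l_p + config$spacing
  genome_length <- if (is.null(config$genome_length))
    margin + config$n_genes * slot + margin else config$genome_length

  if (!resume || !have_all) {
    dataset <- generate_dataset(config)
    write_dataset(dataset, outdir)
  }
  genes <- read_genes_bed(file.path(outdir, "genes.bed"),
                          l_p = config$l_p, body_offset = config$body_offset,
                          l_b = config$l_b)
  rd <- function(cond) list(
    plus = read_bedgraph(file.path(outdir, paste0("cond", cond, "_plus.bedgraph")),
                         genome_length, chrom = config$chrom, strand = "+"),
    minus = read_bedgraph(file.path(outdir, paste0("cond", cond, "_minus.bedgraph")),
                          genome_length, chrom = config$chrom, strand = "-"))
  tracks_a <- rd("A"); tracks_b <- rd("B")
  summary_a <- summarize_densities(tracks_a, genes, condition = "A",
                                   scale = scale)
  summary_b <- summarize_densities(tracks_b, genes, condition = "B",
                                   scale = scale)
  fc <- compare_conditions(summary_a, summary_b, pseudocount = pseudocount)
  mech <- classify_mechanism(fc, tol = tol)

  wtsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(rbind(summary_a, summary_b), "densities.tsv")
  wtsv(fc, "foldchange.tsv")
  wtsv(mech, "mechanisms.tsv")
  jsonlite::write_json(
    list(package = "pauseflux",
         version = as.character(utils::packageVersion("pauseflux")),
         seed = config$seed,
         config = unclass(config)[setdiff(names(config), "meanlog")],
         meanlog = as.list(config$meanlog),
         normalization = scale, tol = tol, pseudocount = pseudocount),
    file.path(outdir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(genes = genes, summary_a = summary_a, summary_b = summary_b,
                 fc = fc, mechanisms = mech, outdir = outdir))
}
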