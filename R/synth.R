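#' Configuration for the synthetic nascent-transcription generator
#'
#' Describes a synthetic PRO-seq-like experiment on one artificial
#' chromosome: a set of genes with per-gene rate constants drawn from
#' log-normal distributions, a reference condition A, and a perturbed
#' condition B in which one rate constant of a fixed fraction of "target"
#' genes is multiplied by a fold change. Per-base counts are Poisson around
#' the model's steady-state expectation scaled by the sequencing depth `D`.
#'
#' @param n_genes Number of genes (>= 1). Default 200.
#' @param fraction_targets Fraction of genes carrying the perturbation in
#'   condition B. Default 0.3.
#' @param perturb_parameter Rate constant perturbed in targets; default
#'   `"k_pre"`.
#' @param perturb_fold Fold change applied to that constant; default 1.6
#'   (a 60% increase in premature pause release).
#' @param depth Sequencing depth `D`: expected counts per unit model density
#'   per bp. Default 100.
#' @param meanlog,sdlog Named log-normal location (log scale) and common
#'   log-sd for the per-gene rate constants. Defaults: constants centred on
#'   `k_init = 1`, `k_pre = 0.5`, `k_rel = 0.5`, `k_term = 1` with
#'   `sdlog = 0.25` (moderate gene-to-gene variability).
#' @param l_p,l_b Pause-window and body-window lengths (bp); defaults 100
#'   and 10000.
#' @param body_offset Gap between TSS and body-window start (bp); default
#'   500, so pause signal is never counted in the body window.
#' @param profile_mode `"flat"` (piecewise-constant expected density:
#'   `D * p_ss` across the pause window, `D * b_ss` across the body) or
#'   `"waveform"` (the smooth pause-peak curve of [waveform_density()]).
#' @param tau Waveform decay constant (bp), used only in waveform mode.
#' @param chrom Chromosome name; default `"chrS"`.
#' @param spacing Intergenic gap between gene slots (bp); default 2000.
#' @param genome_length Optional explicit chromosome length; by default just
#'   large enough for the layout. Supplying a value too small for `n_genes`
#'   is a layout error in [generate_genes()].
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   seed.
#' @return An object of class `synth_config` (a named list).
#' @seealso [generate_genes()], [generate_dataset()]
#' @export
synth_config <- function(n_genes = 200, fraction_targets = 0.3,
                         perturb_parameter = "k_pre", perturb_fold = 1.6,
                         depth = 100,
                         meanlog = log(c(k_init = 1, k_pre = 0.5,
                                         k_rel = 0.5, k_term = 1)),
                         sdlog = 0.25,
                         l_p = 100, l_b = 10000, body_offset = 500,
                         profile_mode = c("flat", "waveform"), tau = 25,
                         chrom = "chrS", spacing = 2000,
                         genome_length = NULL, seed = 1L) {
  profile_mode <- match.arg(profile_mode)
  perturb_parameter <- match.arg(perturb_parameter,
                                 c("k_init", "k_pre", "k_rel", "k_term"))
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (fraction_targets < 0 || fraction_targets > 1)
    stop("fraction_targets must be in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (perturb_fold <= 0) stop("perturb_fold must be > 0", call. = FALSE)
  stopifnot(all(c("k_init", "k_pre", "k_rel", "k_term") %in% names(meanlog)))
  structure(list(
    n_genes = as.integer(n_genes), fraction_targets = fraction_targets,
    perturb_parameter = perturb_parameter, perturb_fold = perturb_fold,
    depth = depth, meanlog = meanlog, sdlog = sdlog,
    l_p = l_p, l_b = l_b, body_offset = body_offset,
    profile_mode = profile_mode, tau = tau,
    chrom = chrom, spacing = spacing, genome_length = genome_length,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# internal: run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Lay out synthetic genes and draw their rate parameters
#'
#' Places `n_genes` non-overlapping genes head-to-tail along the synthetic
#' chromosome, alternating strands, each occupying a slot of
#' `body_offset + l_b` bp plus the configured intergenic spacing. Per-gene
#' rate constants are drawn from the configured log-normal distributions,
#' and a deterministic (seeded) sample of genes is flagged `is_target`.
#'
#' @param config A [synth_config()].
#' @return A list with elements
#'   `genes` (data.frame: `gene_id`, `chrom`, `tss`, `strand`,
#'   `pause_start`, `pause_end`, `body_start`, `body_end`, `is_target`,
#'   one row per gene; window coordinates 0-based half-open),
#'   `params` (list of per-gene reference [rate_params()]),
#'   `params_b` (per-gene condition-B parameters: perturbed for targets,
#'   identical otherwise), and `genome_length`.
#' @export
generate_genes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  slot <- config$body_offset + config$l_b + config$spacing
  margin <- config$l_p + config$spacing  # room for minus-strand pause windows
  needed <- margin + n * slot + margin
  genome_length <- if (is.null(config$genome_length)) needed
                   else config$genome_length
  if (genome_length < needed)
    stop("layout error: ", n, " genes need ", needed,
         " bp but genome_length is ", genome_length, call. = FALSE)
  with_seed(config$seed, {
    strand <- rep(c("+", "-"), length.out = n)
    slot_start <- margin + (seq_len(n) - 1L) * slot
    # TSS at the 5' end of the slot's transcribed span
    tss <- ifelse(strand == "+", slot_start,
                  slot_start + config$body_offset + config$l_b - 1L)
    genes <- mk_windows(data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n)),
      chrom = config$chrom, tss = as.integer(tss), strand = strand,
      is_target = FALSE, stringsAsFactors = FALSE
    ), l_p = config$l_p, body_offset = config$body_offset, l_b = config$l_b)
    n_targets <- round(config$fraction_targets * n)
    genes$is_target[sample.int(n, n_targets)] <- TRUE
    draw <- function(key) stats::rlnorm(n, meanlog = config$meanlog[[key]],
                                        sdlog = config$sdlog)
    k <- data.frame(k_init = draw("k_init"), k_pre = draw("k_pre"),
                    k_rel = draw("k_rel"), k_term = draw("k_term"))
    params <- lapply(seq_len(n), function(i)
      rate_params(k$k_init[i], k$k_pre[i], k$k_rel[i], k$k_term[i],
                  l_p = config$l_p, l_b = config$l_b))
    params_b <- lapply(seq_len(n), function(i)
      if (genes$is_target[i])
        perturb_params(params[[i]], config$perturb_parameter,
                       config$perturb_fold)
      else params[[i]])
    list(genes = genes, params = params, params_b = params_b,
         genome_length = genome_length)
  })
}

#' Expected per-base counts for one gene
#'
#' Converts a gene's steady-state model densities into an expected count at
#' every base of its transcribed span. In `"flat"` mode the expectation is
#' `depth * p_ss` across the pause window, `depth * b_ss` across the body
#' window and 0 in the gap, so the pause window integrates to
#' `depth * p_ss * l_p` and the body to `depth * b_ss * l_b`. In
#' `"waveform"` mode the expectation follows the calibrated
#' [waveform_density()] curve (peak `depth * p_ss`, plateau
#' `depth * b_ss`) as a function of distance from the TSS.
#'
#' @param gene One row of the gene annotation data.frame.
#' @param params The gene's [rate_params()].
#' @param depth Sequencing depth `D` (>= 0).
#' @param mode `"flat"` or `"waveform"`.
#' @param tau Waveform decay constant (bp), waveform mode only.
#' @return A list with `start` (0-based genomic start of the covered span),
#'   `values` (expected count per base, in genomic orientation), and
#'   `strand`.
#' @export
expected_profile <- function(gene, params, depth,
                             mode = c("flat", "waveform"), tau = 25) {
  mode <- match.arg(mode)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  ss <- steady_state(params)
  l_p <- gene$pause_end - gene$pause_start
  l_b <- gene$body_end - gene$body_start
  # distance from the TSS to the body-window start, in transcription direction
  body_off <- if (gene$strand == "+") gene$body_start - gene$tss
              else gene$tss - (gene$body_end - 1L)
  span <- body_off + l_b  # TSS .. body end
  if (mode == "flat") {
    rel <- numeric(span)  # index i -> distance (i-1) bp downstream of TSS
    rel[seq_len(l_p)] <- depth * ss$p_ss
    rel[body_off + seq_len(l_b)] <- depth * ss$b_ss
  } else {
    if (ss$p_ss <= ss$b_ss)
      stop("waveform mode needs p_ss > b_ss", call. = FALSE)
    d <- seq_len(span) - 1
    pkb <- solve_pk_body(ss$b_ss, pk_pause = ss$p_ss, tau = tau)
    rel <- depth * waveform_density(d, tau = tau, pk_pause = ss$p_ss,
                                    pk_body = pkb)
  }
  if (gene$strand == "+") {
    list(start = gene$tss, values = rel, strand = "+")
  } else {
    list(start = gene$body_start, values = rev(rel), strand = "-")
  }
}

#' Draw Poisson counts for a set of expected profiles
#'
#' Each base receives an independent Poisson draw around its expectation;
#' counts are accumulated into a plus-strand and a minus-strand
#' [signal_track()] according to each gene's orientation. Fixing the seed
#' fixes the tracks exactly.
#'
#' @param profiles List of profiles from [expected_profile()].
#' @param genome_length Chromosome length (bp).
#' @param seed Optional integer seed for the draws (`NULL` uses the current
#'   RNG stream).
#' @param chrom Chromosome name.
#' @param noiseless If `TRUE`, skip the Poisson draw and store the
#'   expectations themselves (useful for exactness tests).
#' @return A list with `plus` and `minus` [signal_track()]s.
#' @export
sample_counts <- function(profiles, genome_length, seed = NULL,
                          chrom = "chrS", noiseless = FALSE) {
  draw_all <- function() {
    plus <- numeric(genome_length)
    minus <- numeric(genome_length)
    for (pr in profiles) {
      idx <- pr$start + seq_along(pr$values)  # 0-based start -> 1-based index
      if (min(idx) < 1 || max(idx) > genome_length)
        stop("profile extends beyond the genome", call. = FALSE)
      vals <- if (noiseless) pr$values
              else stats::rpois(length(pr$values), pr$values)
      if (pr$strand == "+") plus[idx] <- plus[idx] + vals
      else minus[idx] <- minus[idx] + vals
    }
    list(plus = signal_track(plus, chrom = chrom, strand = "+"),
         minus = signal_track(minus, chrom = chrom, strand = "-"))
  }
  if (is.null(seed)) draw_all() else with_seed(seed, draw_all())
}

#' Generate a full two-condition synthetic dataset
#'
#' Runs the generator end to end: gene layout and per-gene parameters,
#' expected profiles for the reference condition A and the perturbed
#' condition B, and Poisson count tracks for both. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param noiseless If `TRUE`, tracks carry the exact expectations instead
#'   of Poisson draws.
#' @return A list with `genes`, `params`, `params_b`, `genome_length`,
#'   `truth` (per-gene data.frame of reference and condition-B steady
#'   states), and `tracks` = `list(A = list(plus, minus), B = ...)`.
#' @export
generate_dataset <- function(config, noiseless = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  layout <- generate_genes(config)
  prof <- function(params_list)
    lapply(seq_len(config$n_genes), function(i)
      expected_profile(layout$genes[i, ], params_list[[i]], config$depth,
                       mode = config$profile_mode, tau = config$tau))
  prof_a <- prof(layout$params)
  prof_b <- prof(layout$params_b)
  tracks <- list(
    A = sample_counts(prof_a, layout$genome_length,
                      seed = config$seed + 1000L, chrom = config$chrom,
                      noiseless = noiseless),
    B = sample_counts(prof_b, layout$genome_length,
                      seed = config$seed + 2000L, chrom = config$chrom,
                      noiseless = noiseless)
  )
  truth <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
    ssa <- steady_state(layout$params[[i]])
    ssb <- steady_state(layout$params_b[[i]])
    data.frame(gene_id = layout$genes$gene_id[i],
               is_target = layout$genes$is_target[i],
               p_ss_a = ssa$p_ss, b_ss_a = ssa$b_ss, pi_a = ssa$pause_index,
               p_ss_b = ssb$p_ss, b_ss_b = ssb$b_ss, pi_b = ssb$pause_index)
  }))
  c(layout, list(truth = truth, tracks = tracks, config = config))
}

#' Write a synthetic dataset to disk
#'
#' Emits `genes.bed` (BED6), `condA_plus.bedgraph`, `condA_minus.bedgraph`,
#' `condB_plus.bedgraph`, `condB_minus.bedgraph` and `truth.tsv` into
#' `outdir`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genes_bed(dataset$genes, file.path(outdir, "genes.bed"))
  for (cond in c("A", "B")) for (str in c("plus", "minus"))
    write_bedgraph(dataset$tracks[[cond]][[str]],
                   file.path(outdir, sprintf("cond%s_%s.bedgraph", cond, str)))
  utils::write.table(dataset$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Synthetic protein-degradation time course
#'
#' Samples the one-phase decay curve
#' `y(t) = (y0 - plateau) * exp(-k t) + plateau` on a regular grid --
#' by default every 15 min over 4 h (17 points, 0-240 min inclusive), the
#' sampling scheme of an auxin-degradation Western-blot series -- and adds
#' Gaussian noise.
#'
#' @param y0 Signal at time 0; must exceed `plateau`.
#' @param plateau Asymptotic signal (>= 0).
#' @param k Decay rate constant (per min, >= 0).
#' @param t_max Last time point (min); default 240.
#' @param dt Sampling interval (min); default 15.
#' @param noise_sd Gaussian noise standard deviation; default 0.
#' @param seed Optional integer seed.
#' @return A data.frame of class `decay_timecourse` with columns `time` and
#'   `signal`; the generating parameters are attached as attribute
#'   `"truth"`.
#' @examples
#' tc <- generate_decay_timecourse(1, 0.1, 0.02)
#' nrow(tc)  # 17
#' @export
generate_decay_timecourse <- function(y0, plateau, k, t_max = 240, dt = 15,
                                      noise_sd = 0, seed = NULL) {
  if (y0 <= plateau || plateau < 0 || k < 0)
    stop("need y0 > plateau >= 0 and k >= 0", call. = FALSE)
  times <- seq(0, t_max, by = dt)
  curve <- (y0 - plateau) * exp(-k * times) + plateau
  make <- function() {
    sig <- curve + if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd)
                   else 0
    out <- data.frame(time = times, signal = sig)
    attr(out, "truth") <- c(y0 = y0, plateau = plateau, k = k)
    class(out) <- c("decay_timecourse", "data.frame")
    out
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}
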