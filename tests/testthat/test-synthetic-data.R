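small_config <- function(...) {
  synth_config(n_genes = 6, fraction_targets = 0.5, depth = 100, seed = 101,
               ...)
}

test_that("gene layout is deterministic, non-overlapping and strand-aware", {
  cfg <- small_config()
  a <- generate_genes(cfg)
  b <- generate_genes(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(vapply(a$params, `[[`, numeric(1), "k_init"),
                   vapply(b$params, `[[`, numeric(1), "k_init"))

  g <- a$genes
  expect_equal(nrow(g), 6)
  expect_equal(sum(g$is_target), 3)  # round(0.5 * 6), fixed by the seed
  # windows: correct lengths, pause before body along the strand, no overlap
  expect_true(all(g$pause_end - g$pause_start == 100))
  expect_true(all(g$body_end - g$body_start == 10000))
  plus <- g$strand == "+"
  expect_true(all(g$body_start[plus] - g$pause_end[plus] == 400))
  expect_true(all(g$pause_start[!plus] - g$body_end[!plus] == 400))
  # genes stay inside the genome and do not collide
  spans <- cbind(pmin(g$pause_start, g$body_start),
                 pmax(g$pause_end, g$body_end))
  ord <- order(spans[, 1])
  expect_true(all(spans[ord, 1][-1] >= spans[ord, 2][-nrow(g)]))
  expect_true(all(spans >= 0 & spans <= a$genome_length))
})

test_that("a too-small genome is a layout error", {
  cfg <- synth_config(n_genes = 10, genome_length = 5000, seed = 1)
  expect_error(generate_genes(cfg), "layout error")
})

test_that("flat-mode expectations integrate to the steady-state totals", {
  cfg <- small_config()
  layout <- generate_genes(cfg)
  pp <- example_params()
  for (i in c(1, 2)) {  # one plus- and one minus-strand gene
    gene <- layout$genes[i, ]
    prof <- expected_profile(gene, pp, depth = 100, mode = "flat")
    tr <- numeric(layout$genome_length)
    tr[prof$start + seq_along(prof$values)] <- prof$values
    pause_total <- sum(tr[(gene$pause_start + 1):gene$pause_end])
    body_total <- sum(tr[(gene$body_start + 1):gene$body_end])
    expect_equal(pause_total, 100 * 1.0 * 100)   # D * p_ss * l_p
    expect_equal(body_total, 100 * 0.005 * 10000)  # D * b_ss * l_b
    # nothing outside the gene's windows
    expect_equal(sum(tr), pause_total + body_total)
    # density ratio equals the pause index for any depth
    prof2 <- expected_profile(gene, pp, depth = 7, mode = "flat")
    expect_equal(max(prof2$values) / min(prof2$values[prof2$values > 0]), 200)
  }
  # zero depth silences everything
  prof0 <- expected_profile(layout$genes[1, ], pp, depth = 0)
  expect_true(all(prof0$values == 0))
})

test_that("waveform-mode expectation carries the calibrated curve", {
  cfg <- small_config(profile_mode = "waveform")
  layout <- generate_genes(cfg)
  gene <- layout$genes[1, ]
  pp <- example_params()
  prof <- expected_profile(gene, pp, depth = 100, mode = "waveform", tau = 25)
  expect_equal(prof$values[1], 0)  # zero at the TSS
  expect_equal(max(prof$values), 100 * 1.0, tolerance = 1e-3)
  expect_equal(prof$values[length(prof$values)], 100 * 0.005,
               tolerance = 1e-3)
})

test_that("Poisson sampling is seeded, unbiased and respects zeros", {
  cfg <- small_config()
  layout <- generate_genes(cfg)
  prof <- lapply(seq_len(6), function(i)
    expected_profile(layout$genes[i, ], layout$params[[i]], cfg$depth))
  t1 <- sample_counts(prof, layout$genome_length, seed = 5)
  t2 <- sample_counts(prof, layout$genome_length, seed = 5)
  expect_identical(t1$plus$counts, t2$plus$counts)
  expect_identical(t1$minus$counts, t2$minus$counts)

  # zero expectation -> zero counts
  zero <- sample_counts(list(list(start = 10, values = numeric(50),
                                  strand = "+")),
                        genome_length = 100, seed = 1)
  expect_true(all(zero$plus$counts == 0))

  # pause-window totals across replicate draws: mean within 3 SE of truth
  gene <- layout$genes[1, ]
  expected_total <- sum(prof[[1]]$values[seq_len(100)])
  totals <- vapply(1:50, function(s) {
    tr <- sample_counts(prof[1], layout$genome_length, seed = s)
    sum(tr$plus$counts[(gene$pause_start + 1):gene$pause_end])
  }, numeric(1))
  se <- sqrt(expected_total / 50)  # Poisson variance = mean
  expect_lt(abs(mean(totals) - expected_total), 3 * se)
})

test_that("bedGraph write/read round trip preserves every count", {
  cfg <- small_config()
  ds <- generate_dataset(cfg)
  path <- tempfile(fileext = ".bedgraph")
  on.exit(unlink(path))
  write_bedgraph(ds$tracks$A$plus, path)
  back <- read_bedgraph(path, ds$genome_length, chrom = "chrS")
  expect_identical(back$counts, ds$tracks$A$plus$counts)
  expect_equal(sum(back$counts), sum(ds$tracks$A$plus$counts))
})

test_that("negative bedGraph scores are folded to magnitudes with a warning", {
  path <- tempfile(fileext = ".bedgraph")
  on.exit(unlink(path))
  writeLines(c("chrS\t0\t5\t-3", "chrS\t10\t12\t4"), path)
  expect_warning(tr <- read_bedgraph(path, 20), "minus-strand")
  expect_equal(sum(tr$counts), 3 * 5 + 4 * 2)
  expect_true(all(tr$counts >= 0))
})

test_that("full dataset generation is reproducible and labels truth", {
  cfg <- small_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$tracks$A$plus$counts, d2$tracks$A$plus$counts)
  expect_identical(d1$tracks$B$minus$counts, d2$tracks$B$minus$counts)
  expect_identical(d1$truth, d2$truth)
  # non-targets share reference and perturbed steady states; targets do not
  tg <- d1$truth$is_target
  expect_true(all(d1$truth$p_ss_a[!tg] == d1$truth$p_ss_b[!tg]))
  expect_true(all(d1$truth$p_ss_a[tg] != d1$truth$p_ss_b[tg]))
  # +60% premature release leaves the pause index untouched in truth
  expect_equal(d1$truth$pi_a, d1$truth$pi_b)
})

test_that("decay time course follows the one-phase curve", {
  tc <- generate_decay_timecourse(1.0, 0.1, 0.02)
  expect_equal(nrow(tc), 17)  # 0..240 min at 15-min intervals
  expect_equal(tc$time, seq(0, 240, 15))
  expect_equal(tc$signal[1], 1.0)
  expect_equal(tc$signal[17], 0.9 * exp(-4.8) + 0.1, tolerance = 1e-12)
  expect_equal(tc$signal[17], 0.10740, tolerance = 1e-4)
  # the noiseless curve crosses halfway to the plateau at ln(2)/k
  t_half <- log(2) / 0.02
  expect_equal(t_half, 34.66, tolerance = 1e-3)
  y_half <- (1.0 - 0.1) * exp(-0.02 * t_half) + 0.1
  expect_equal(y_half, 0.1 + (1.0 - 0.1) / 2)

  # degenerate no-decay case and determinism of the noisy series
  flat <- generate_decay_timecourse(1, 0.1, 0, noise_sd = 0)
  expect_true(all(flat$signal == 1))
  n1 <- generate_decay_timecourse(1, 0.1, 0.02, noise_sd = 0.05, seed = 3)
  n2 <- generate_decay_timecourse(1, 0.1, 0.02, noise_sd = 0.05, seed = 3)
  expect_identical(n1$signal, n2$signal)
  expect_error(generate_decay_timecourse(0.5, 0.6, 0.02), "y0 > plateau")
})
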