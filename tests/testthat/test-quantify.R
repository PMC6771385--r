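test_that("window density is counts per bp per scale unit", {
  tr <- signal_track(c(rep(3, 100), numeric(100)))
  expect_equal(window_density(tr, 0, 100), 3.0)  # 300 counts over 100 bp
  expect_equal(window_density(tr, 0, 100, scale = 2), 1.5)
  expect_equal(window_density(tr, 100, 200), 0)  # empty window
  expect_error(window_density(tr, 150, 250), "out of track bounds")
  expect_error(window_density(tr, -1, 10), "out of track bounds")
  expect_error(window_density(tr, 10, 10), "out of track bounds")
})

test_that("noiseless tracks return the model densities exactly", {
  cfg <- synth_config(n_genes = 6, fraction_targets = 0.5, seed = 102)
  ds <- generate_dataset(cfg, noiseless = TRUE)
  s <- summarize_densities(ds$tracks$A, ds$genes, scale = "none")
  # pause density = D * p_ss and body density = D * b_ss, both strands
  expect_equal(s$pause_density, cfg$depth * ds$truth$p_ss_a)
  expect_equal(s$body_density, cfg$depth * ds$truth$b_ss_a)
  expect_equal(s$pause_index, ds$truth$pi_a)
})

test_that("summaries are invariant across identical conditions", {
  cfg <- synth_config(n_genes = 4, fraction_targets = 0, seed = 103)
  ds <- generate_dataset(cfg)
  sa <- summarize_densities(ds$tracks$A, ds$genes, condition = "A")
  sa2 <- summarize_densities(ds$tracks$A, ds$genes, condition = "A")
  expect_identical(sa, sa2)
  expect_error(summarize_densities(list(plus = ds$tracks$A$plus),
                                   ds$genes), "both")
})

test_that("an initiation increase raises pause and body but not the index", {
  cfg <- synth_config(n_genes = 60, fraction_targets = 1,
                      perturb_parameter = "k_init", perturb_fold = 1.25,
                      seed = 104)
  ds <- generate_dataset(cfg)
  sa <- summarize_densities(ds$tracks$A, ds$genes, "A", scale = "none")
  sb <- summarize_densities(ds$tracks$B, ds$genes, "B", scale = "none")
  fc <- compare_conditions(sa, sb)
  # every gene perturbed: mean fold changes sit at log2(1.25) within noise
  expect_lt(abs(mean(fc$lfc_pause) - log2(1.25)), 0.02)
  expect_lt(abs(mean(fc$lfc_body) - log2(1.25)), 0.02)
  # pause index unchanged within a 3-SE band
  dpi <- fc$delta_pause_index
  expect_lt(abs(mean(dpi)), 3 * stats::sd(dpi) / sqrt(length(dpi)))
})

test_that("composite profile averages normalized per-base density", {
  cfg <- synth_config(n_genes = 4, fraction_targets = 0, seed = 105)
  ds <- generate_dataset(cfg, noiseless = TRUE)
  one <- ds$genes[1, , drop = FALSE]
  prof1 <- composite_profile(ds$tracks$A, one, upstream = 100,
                             downstream = 1000, scale = "none")
  # single gene: the profile is that gene's own oriented track segment
  tr <- ds$tracks$A$plus$counts
  expect_equal(prof1$density,
               tr[one$tss + prof1$pos + 1])
  # flat mode: pause bases at D*p_ss, upstream at zero
  expect_true(all(prof1$density[prof1$pos < 0] == 0))
  expect_equal(prof1$density[prof1$pos == 50],
               cfg$depth * ds$truth$p_ss_a[1])

  # averaging identical genes reproduces the single-gene profile
  idential_genes <- ds$genes[rep(1, 5), ]
  prof5 <- composite_profile(ds$tracks$A, idential_genes, upstream = 100,
                             downstream = 1000, scale = "none")
  expect_equal(prof5$density, prof1$density)
  expect_error(composite_profile(ds$tracks$A, ds$genes[0, ]), "empty")
})

test_that("minus-strand genes are flipped so downstream is positive", {
  cfg <- synth_config(n_genes = 2, fraction_targets = 0, seed = 106)
  ds <- generate_dataset(cfg, noiseless = TRUE)
  minus <- ds$genes[ds$genes$strand == "-", , drop = FALSE]
  prof <- composite_profile(ds$tracks$A, minus, upstream = 100,
                            downstream = 1000, scale = "none")
  expect_true(all(prof$density[prof$pos < 0] == 0))
  expect_equal(prof$density[prof$pos == 10],
               cfg$depth * steady_state(ds$params[[2]])$p_ss)
})

test_that("waveform-mode composite matches the rendered curve in expectation", {
  cfg <- synth_config(n_genes = 6, fraction_targets = 0, seed = 107,
                      profile_mode = "waveform", tau = 25)
  ds <- generate_dataset(cfg, noiseless = TRUE)
  g1 <- ds$genes[1, , drop = FALSE]
  prof <- composite_profile(ds$tracks$A, g1, upstream = 0,
                            downstream = 2000, scale = "none")
  ss <- steady_state(ds$params[[1]])
  curve <- render_condition_profiles(list(x = ss), tau = 25, length = 1999)
  expect_equal(prof$density, cfg$depth * curve$x, tolerance = 1e-10)
})

test_that("fold changes are zero for identical conditions and antisymmetric", {
  cfg <- synth_config(n_genes = 6, fraction_targets = 0.5, seed = 108)
  ds <- generate_dataset(cfg)
  sa <- summarize_densities(ds$tracks$A, ds$genes, "A", scale = "none")
  sb <- summarize_densities(ds$tracks$B, ds$genes, "B", scale = "none")
  self <- compare_conditions(sa, sa)
  expect_true(all(self$lfc_pause == 0))
  expect_true(all(self$lfc_body == 0))
  expect_true(all(self$delta_pause_index == 0))
  ab <- compare_conditions(sa, sb)
  ba <- compare_conditions(sb, sa)
  expect_equal(ab$lfc_pause, -ba$lfc_pause)
  expect_equal(ab$lfc_body, -ba$lfc_body)
  expect_equal(ab$delta_pause_index, -ba$delta_pause_index)
  expect_error(compare_conditions(sa, sb[rev(seq_len(nrow(sb))), ]),
               "different gene sets")
})

test_that("noiseless fold changes equal the closed-form scaling exactly", {
  cfg <- synth_config(n_genes = 4, fraction_targets = 1,
                      perturb_parameter = "k_init", perturb_fold = 1.25,
                      seed = 109)
  ds <- generate_dataset(cfg, noiseless = TRUE)
  sa <- summarize_densities(ds$tracks$A, ds$genes, "A", scale = "none")
  sb <- summarize_densities(ds$tracks$B, ds$genes, "B", scale = "none")
  fc <- compare_conditions(sa, sb, pseudocount = 0)
  expect_equal(fc$lfc_pause, rep(log2(1.25), 4), tolerance = 1e-12)
  expect_equal(fc$lfc_body, rep(log2(1.25), 4), tolerance = 1e-12)
  expect_equal(fc$delta_pause_index, rep(0, 4), tolerance = 1e-12)
})
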