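test_that("the config validates phenotype probabilities and efficiency", {
  expect_error(synth_config(phenotype_probs = c(normal = 1)), "named")
  expect_error(synth_config(phenotype_probs = c(normal = 0.5, elongated = 0.2,
                                                bubble = 0.2, bipolar = 0.2,
                                                exploded = 0.2)), "sum to 1")
  expect_error(synth_config(efficiency = 0.95,
                            phenotype_probs = c(normal = 0.5, elongated = 0.1,
                                                bubble = 0.2, bipolar = 0.1,
                                                exploded = 0.1)),
               "cannot exceed")
})

test_that("identical seed and config give bit-identical stacks and truth", {
  cfg <- tiny_config(seed = 77)
  g1 <- generate_timelapse(cfg)
  g2 <- generate_timelapse(cfg)
  expect_identical(g1$timelapse$frames, g2$timelapse$frames)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_timelapse(tiny_config(seed = 78))
  expect_false(identical(g1$timelapse$frames, g3$timelapse$frames))
})

test_that("zero efficiency yields a cohort where nothing ever divides", {
  cfg <- tiny_config(seed = 55, efficiency = 0)
  gen <- generate_timelapse(cfg)
  sc <- score_timelapse(gen$timelapse, classify = FALSE)
  ars <- sc$tracks$measures$aspect_ratio
  expect_true(all(ars < 3.0))
  expect_equal(germination_efficiency(sc$records)$efficiency, 0)
})

test_that("generated spores satisfy the frame-0 spore criteria by construction", {
  gen <- generate_timelapse(tiny_config(seed = 66))
  tr <- link_tracks(gen$timelapse)
  sel <- select_spores(tr)
  rec <- match_truth_to_records(sel, tr, gen$truth)
  truth_spores <- rec$truth_type %in% "spore"
  expect_true(all(rec$is_spore[truth_spores]))
  expect_true(all(rec$starting_ar[truth_spores] < 1.4))
  # and debris never sneaks in as a spore
  expect_true(all(!rec$is_spore[rec$truth_type %in% "debris"]))
})

test_that("overcrowded configurations raise a placement error", {
  expect_error(generate_timelapse(synth_config(seed = 1, n_spores = 60L,
                                               grid = c(160L, 160L))),
               "placement error")
})

test_that("noise-free CFU viability equals the exponential decay exactly", {
  cfg <- synth_config(seed = 10, cfu_poisson = FALSE, cfu_batch_sdlog = 0)
  gen <- generate_cfu_dataset(cfg)
  viab <- cfu_viability(gen$cfu)
  for (cond in names(cfg$cfu_lambda)) {
    v <- viab[viab$condition == cond, ]
    expect_equal(v$viability, exp(-cfg$cfu_lambda[[cond]] * v$day),
                 tolerance = 1e-12)
  }
  expect_true(all(viab$viability[viab$day == 0] == 1))
})

test_that("Poisson counting noise shows up but keeps day-0 normalization", {
  gen <- generate_cfu_dataset(synth_config(seed = 11))
  viab <- cfu_viability(gen$cfu)
  expect_true(all(viab$viability[viab$day == 0] == 1))
  expect_true(any(viab$viability != round(viab$viability, 3)) ||
                length(unique(viab$viability)) > length(unique(viab$day)))
})

test_that("stress datasets reflect their configured survival fractions", {
  cfg <- synth_config(seed = 12, stress_n0 = 2000)
  gen <- generate_stress_dataset(cfg)
  for (smp in names(cfg$stress_survival_true)) {
    d <- gen$assay[gen$assay$sample == smp, ]
    sv <- stress_survival(d)
    expect_equal(sv$n_replicates, cfg$stress_replicates)
    expect_lt(abs(sv$mean_percent / 100 - cfg$stress_survival_true[[smp]]),
              4 * sqrt(cfg$stress_survival_true[[smp]] / cfg$stress_n0 / 5) + 0.01)
  }
})

test_that("boundary jitter leaves classification mostly intact", {
  cfg <- tiny_config(seed = 88, jitter_px = 1)
  out <- run_synthetic_cohort(cfg)
  sp <- out$records[out$records$is_spore & !is.na(out$records$truth_phenotype), ]
  expect_gt(nrow(sp), 3)
  expect_gte(mean(sp$phenotype == sp$truth_phenotype), 0.8)
})

test_that("the fallback threshold segmenter recovers objects from grayscale", {
  cfg <- tiny_config(seed = 91, debris_n = 0L)
  gen <- generate_timelapse(cfg)
  gray <- render_brightfield(gen$timelapse, seed = 5)
  seg <- segment_threshold(gray, cfg$pixel_size_um, cfg$frame_interval_min)
  # same number of objects as the ground-truth mask at a few frames
  for (k in c(1L, 40L, 90L)) {
    n_true <- length(setdiff(unique(as.vector(gen$timelapse$frames[[k]])), 0L))
    n_seg <- length(setdiff(unique(as.vector(seg$frames[[k]])), 0L))
    expect_lte(abs(n_seg - n_true), 1L)
  }
})
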