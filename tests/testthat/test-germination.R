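# helper: build a minimal track_set by hand from per-track AR/area series
fake_tracks <- function(series, dt = 10, px = 0.15) {
  rows <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    n <- length(s$ar)
    fr <- if (is.null(s$first)) 0L else s$first
    data.frame(track_id = i, frame = seq.int(fr, length.out = n),
               label = i, pixel_count = s$area / px^2,
               area_um2 = s$area, aspect_ratio = s$ar,
               major_axis_um = 2 * sqrt(s$area / pi) * sqrt(s$ar),
               minor_axis_um = 2 * sqrt(s$area / pi) / sqrt(s$ar),
               centroid_row = 10 * i, centroid_col = 10 * i)
  }))
  rows$time_min <- rows$frame * dt
  rows$interpolated <- FALSE
  structure(list(measures = rows, events = germlapse:::.empty_events(),
                 pixel_size_um = px, frame_interval_min = dt,
                 n_frames = max(rows$frame) + 1L, dim = c(100L, 100L)),
            class = "track_set")
}

test_that("spore selection applies the strict AR < 1.4 rule at frame 0", {
  tr <- fake_tracks(list(
    list(ar = rep(1.39, 10), area = rep(8, 10)),           # kept
    list(ar = rep(1.40, 10), area = rep(8, 10)),           # boundary: excluded
    list(ar = rep(1.10, 8), area = rep(8, 8), first = 3L), # late arrival
    list(ar = rep(1.05, 10), area = rep(0.5, 10))))        # tiny debris
  sel <- select_spores(tr)
  expect_equal(sel$is_spore, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sel$exclude_reason,
               c(NA, "ar_t0_above_threshold", "not_present_t0", "below_min_area"))
  # selection + exclusion partitions the track set exactly
  expect_equal(sum(sel$is_spore) + sum(sel$excluded), nrow(sel))
  # the area floor is optional
  sel0 <- select_spores(tr, min_area_um2 = 0)
  expect_true(sel0$is_spore[4L])
})

test_that("first division is the first frame with AR strictly above threshold", {
  ar <- c(rep(1, 40), 3.2, 3.4, 3.6)
  dv <- call_first_division(ar, ar_threshold = 3.0, interval_min = 10)
  expect_equal(dv$frame, 40L)
  expect_equal(dv$time_min, 400)
  expect_null(call_first_division(rep(2.9, 100), interval_min = 10))
  expect_null(call_first_division(c(1, 2, 3), interval_min = 10))  # 3.0 not > 3.0
  expect_error(call_first_division(ar, ar_threshold = 1), "parameter")
})

test_that("lowering the division threshold never delays any called division", {
  cfg <- tiny_config(seed = 21)
  gen <- generate_timelapse(cfg)
  tr <- link_tracks(gen$timelapse)
  sel <- select_spores(tr)
  for (tid in sel$track_id[sel$is_spore]) {
    d <- tr$measures[tr$measures$track_id == tid, ]
    calls <- lapply(c(2.0, 2.5, 3.0, 3.5), function(th)
      call_first_division(d$aspect_ratio, d$frame, th, 10))
    tms <- vapply(calls, function(x) if (is.null(x)) 1e9 else x$time_min, 0)
    expect_true(all(diff(tms) >= 0))
  }
})

test_that("germination efficiency returns the ratio with its counts", {
  rec <- data.frame(is_spore = rep(c(TRUE, FALSE), c(100, 7)),
                    germinated = rep(c(TRUE, FALSE, FALSE), c(60, 40, 7)))
  ge <- germination_efficiency(rec)
  expect_equal(ge$efficiency, 0.6)
  expect_equal(ge$n_germinated, 60L)
  expect_equal(ge$n_scored, 100L)
  rec0 <- data.frame(is_spore = rep(TRUE, 50), germinated = rep(FALSE, 50))
  expect_equal(germination_efficiency(rec0)$efficiency, 0)
  expect_error(germination_efficiency(rec[rec$is_spore == FALSE, ]),
               "no scored spores")
})

test_that("starting areas subset correctly and both modes agree when all germinate", {
  rec <- data.frame(is_spore = c(TRUE, TRUE, TRUE, FALSE),
                    germinated = c(TRUE, TRUE, TRUE, FALSE),
                    starting_area_um2 = c(8, 9, 10, 2))
  expect_equal(sort(starting_area(rec)), sort(starting_area(rec, TRUE)))
  rec$germinated[2L] <- FALSE
  expect_equal(starting_area(rec, TRUE), c(8, 10))
})

test_that("population curves give hand-checked means and zero SE for clones", {
  tr <- fake_tracks(list(list(ar = rep(1, 5), area = rep(8, 5)),
                         list(ar = rep(1, 5), area = rep(10, 5))))
  rec <- data.frame(track_id = 1:2, is_spore = TRUE)
  pc <- population_curves(tr, rec)
  expect_equal(pc$area_mean, rep(9, 5))
  expect_equal(pc$area_se, rep(1, 5))
  tr2 <- fake_tracks(list(list(ar = rep(1.2, 5), area = rep(8, 5)),
                          list(ar = rep(1.2, 5), area = rep(8, 5))))
  pc2 <- population_curves(tr2, rec)
  expect_true(all(pc2$area_se == 0))
  expect_true(all(pc2$ar_se == 0))
})

test_that("a constant-shape dormant spore has no swelling window", {
  expect_null(detect_swelling_window(rep(8, 60), rep(1.02, 60), 10))
  expect_error(detect_swelling_window(rep(8, 60), rep(1, 60), 10,
                                      smooth_frames = 4), "parameter")
})

test_that("swelling windows recover generator phase boundaries within 2 frames", {
  cfg <- tiny_config(seed = 31)
  out <- run_synthetic_cohort(cfg, n_fields = 2L)
  sp <- out$records[out$records$is_spore &
                      out$records$truth_phenotype %in% "normal", ]
  expect_gt(nrow(sp), 4)
  derr_start <- abs(sp$swelling_start_min - sp$truth_swell_start_min) / 10
  derr_end <- abs(sp$swelling_end_min - sp$truth_swell_end_min) / 10
  expect_true(all(derr_start <= 2))
  expect_true(all(derr_end <= 2))
})

test_that("a delayed-lag cohort starts swelling later than a prompt cohort", {
  prompt <- run_synthetic_cohort(tiny_config(seed = 41, lag_median_min = 100))
  delayed <- run_synthetic_cohort(tiny_config(seed = 41, lag_median_min = 300))
  ms <- function(o) mean(o$records$swelling_start_min[o$records$is_spore],
                         na.rm = TRUE)
  expect_lt(ms(prompt), ms(delayed))
})
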