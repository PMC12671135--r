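test_that("a rasterized disc is measured as circular with the right area", {
  m <- draw_disc(c(64L, 64L), c(32, 32), 15)
  om <- measure_object(m, 1L, 0.1)
  expect_lt(abs(om$aspect_ratio - 1), 0.02)
  expect_lt(abs(om$area_um2 - pi * 1.5^2), 0.05 * pi * 1.5^2)
  expect_equal(om$aspect_ratio, om$major_axis_um / om$minor_axis_um,
               tolerance = 1e-9)
})

test_that("a solid rectangle's AR equals its side ratio exactly", {
  m <- matrix(0L, 40, 50)
  m[11:20, 11:40] <- 1L  # 10 x 30
  om <- measure_object(m, 1L, 0.1)
  expect_equal(om$aspect_ratio, 3, tolerance = 1e-9)
})

test_that("degenerate and missing labels are handled", {
  m <- matrix(0L, 8, 8); m[4, 4] <- 7L
  om <- measure_object(m, 7L, 0.2)
  expect_equal(om$aspect_ratio, 1)
  expect_equal(om$area_um2, 0.04)
  expect_error(measure_object(m, 3L, 0.2), "not found")
})

test_that("measurements agree with a brute-force covariance oracle", {
  # capsule: 10 um tip-to-tip, 3 um wide at 0.05 um/px
  cap <- draw_capsule(c(320L, 320L), c(160, 90), c(160, 230), 30)
  om <- measure_object(cap, 1L, 0.05)
  or <- oracle_moments(cap, 1L, 0.05)
  expect_equal(om$aspect_ratio, or$aspect_ratio, tolerance = 1e-6)
  expect_equal(om$area_um2, or$area_um2, tolerance = 1e-12)
  # and on 100 random blobs
  set.seed(7)
  for (i in 1:100) {
    b <- random_blob()
    om <- measure_object(b, 1L, 0.1)
    or <- oracle_moments(b, 1L, 0.1)
    expect_equal(om$aspect_ratio, or$aspect_ratio, tolerance = 1e-6)
    expect_equal(om$major_axis_um, or$major_axis_um, tolerance = 1e-6)
  }
})

test_that("AR is invariant under rotation and translation", {
  set.seed(8)
  dim <- c(300L, 300L)
  for (ang in c(0, 17, 45, 63, 90, 131) * pi / 180) {
    d <- 110 * c(cos(ang), sin(ang))
    shift <- runif(2, -15, 15)
    p1 <- c(150, 150) - d / 2 + shift
    m <- draw_capsule(dim, p1, p1 + d, 25)
    ar <- measure_object(m, 1L, 0.1)$aspect_ratio
    if (ang == 0) ar0 <- ar
    expect_lt(abs(ar - ar0), 0.02)
    expect_gte(ar, 1)
  }
})

test_that("one drifting disc yields exactly one full-length track", {
  tl <- drifting_disc_tl(n = 50L)
  tr <- link_tracks(tl)
  expect_equal(length(unique(tr$measures$track_id)), 1L)
  expect_equal(sort(tr$measures$frame), 0:49)
})

test_that("two disjoint discs never swap identities", {
  frames <- lapply(0:19, function(k) {
    m <- draw_disc(c(80L, 80L), c(20, 20 + 0.4 * k), 7)
    draw_disc(c(80L, 80L), c(60, 60 - 0.4 * k), 7, label = 2L, into = m)
  })
  tr <- link_tracks(time_lapse(frames, 10, 0.1))
  expect_equal(length(unique(tr$measures$track_id)), 2L)
  m <- tr$measures
  t1 <- m[m$track_id == 1L, ]
  expect_true(all(abs(t1$centroid_row - 20) < 1))  # track 1 stays the top disc
})

test_that("a split keeps the parent id on the centroid-containing fragment", {
  dim <- c(100L, 120L)
  frames <- c(
    lapply(1:40, function(k) draw_capsule(dim, c(50, 30), c(50, 90), 12)),
    lapply(1:10, function(k) {
      m <- draw_capsule(dim, c(50, 30), c(50, 57), 12)          # left half
      draw_capsule(dim, c(50, 63), c(50, 90), 12, 2L, into = m) # right half
    }))
  tr <- link_tracks(time_lapse(frames, 10, 0.1))
  expect_equal(length(unique(tr$measures$track_id)), 2L)
  expect_equal(tr$events$frame, 40L)
  expect_equal(tr$events$n_fragments, 2L)
  # parent centroid was at col 60; it continues into the fragment holding it
  parent <- tr$measures[tr$measures$track_id == 1L, ]
  expect_equal(max(parent$frame), 49L)
  child <- tr$measures[tr$measures$track_id == 2L, ]
  expect_equal(min(child$frame), 40L)
})

test_that("tracking conserves foreground pixel counts per frame", {
  cfg <- tiny_config(seed = 5)
  gen <- generate_timelapse(cfg)
  tr <- link_tracks(gen$timelapse)
  m <- tr$measures
  for (k in c(0L, 30L, 60L, 99L)) {
    expect_equal(sum(m$pixel_count[m$frame == k]),
                 sum(gen$timelapse$frames[[k + 1L]] > 0L))
  }
})

test_that("a single globally-perturbed frame is flagged and repaired", {
  tl <- drifting_disc_tl(n = 60L, drift = c(0, 0))
  frames <- lapply(seq_along(tl$frames) - 1L, function(k) {
    r <- if (k == 30L) 8 * sqrt(0.5) else 8  # area halved at frame 30
    draw_disc(c(64L, 64L), c(24, 24), r + 0.02 * k)
  })
  # several parallel tracks so the median is meaningful
  big <- lapply(frames, function(f) {
    m <- matrix(0L, 200L, 64L)
    m[1:64, ] <- f
    m[69:132, ] <- ifelse(f > 0L, 2L, 0L)
    m[137:200, ] <- ifelse(f > 0L, 3L, 0L)
    m
  })
  tl2 <- time_lapse(big, 10, 0.1)
  tr <- link_tracks(tl2)
  truth_area <- measure_frame(frames[[31]] * 0L + draw_disc(c(64L, 64L), c(24, 24), 8 + 0.02 * 30), 0.1)$area_um2
  fl <- flag_focus_loss(tr)
  expect_equal(fl$flagged_frames, 30L)
  expect_false(fl$excluded)
  rep30 <- fl$tracks$measures[fl$tracks$measures$frame == 30L, ]
  expect_true(all(rep30$interpolated))
  expect_true(all(abs(rep30$area_um2 - truth_area) / truth_area < 0.01))
})

test_that("more than five consecutive perturbed frames exclude the stack", {
  mk <- function(bad) lapply(0:59, function(k) {
    r <- if (k %in% bad) 8 * sqrt(0.5) else 8
    m <- matrix(0L, 200L, 64L)
    d <- draw_disc(c(64L, 64L), c(24, 24), r)
    m[1:64, ] <- d; m[69:132, ] <- 2L * d; m[137:200, ] <- 3L * d
    m
  })
  tr8 <- link_tracks(time_lapse(mk(30:37), 10, 0.1))  # 8 > 5 consecutive
  expect_true(flag_focus_loss(tr8)$excluded)
  tr0 <- link_tracks(time_lapse(mk(integer()), 10, 0.1))
  fl0 <- flag_focus_loss(tr0)
  expect_equal(fl0$flagged_frames, integer())
  expect_false(fl0$excluded)
})
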