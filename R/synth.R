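# Seeded synthetic-data generator: time-lapse mask stacks, an FM4-64-like
# fluorescence channel, CFU longevity tables and acute-stress assays, all
# with full per-object ground truth.
#
# Kinematics are continuous in time and sampled at frame times, then
# rasterized, so the ground truth is independent of the pixel grid. A
# germinating cell is a swollen disc body (radius rs) plus an axial capsule
# tube (half-width ro, hemispherical cap); truth aspect ratios come from 1-D
# quadrature of the continuous shape's half-width profile.

#' Synthetic-data generator configuration
#'
#' Defaults emulate the published study conditions: imaging every 10 minutes
#' for 1,200 minutes; starting spore areas around 8 µm² (true spores are
#' ~7–9 µm²); division near AR 3.1; normal outgrowths of ~4.5–5 µm at the
#' first division, elongated ones longer than 6 µm (up to 20 µm); vacuole
#' body retention of 64% in healthy young spores; CFU decay rates such that
#' viability halves by day 10 at the 37 °C analog and by day 80 at the 4 °C
#' analog; three CFU replicates and five stress replicates.
#'
#' `efficiency` is the probability that a spore completes the first division
#' (reaches AR > 3). Bubble and exploded attempts are additional failure
#' modes: a spore attempts germination with probability
#' `efficiency / P(normal, elongated or bipolar)` and the attempt's phenotype
#' follows `phenotype_probs`, so phenotype fractions among attempts follow
#' `phenotype_probs` exactly and the fraction of spores that divide equals
#' `efficiency`.
#'
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @param n_spores spores per field of view.
#' @param grid mask dimensions in pixels (rows, cols).
#' @param pixel_size_um,frame_interval_min,n_frames calibration and length.
#' @param starting_area_mean_um2,starting_area_sd_um2 frame-0 spore area (µm²).
#' @param efficiency probability of completing the first division.
#' @param lag_median_min,lag_sdlog dormancy lag, lognormal (minutes).
#' @param swell_rate_um2_min,swell_duration_min isotropic swelling phase.
#' @param outgrowth_rate_um_min polarized tube elongation rate (µm/min).
#' @param tube_halfwidth_um,tube_halfwidth_sd germ-tube half-width (µm).
#' @param ar_division truth threshold for the first division (AR > 3.0).
#' @param division_ar_target AR at which the mask physically splits (3.1).
#' @param phenotype_probs named probabilities over the five attempt classes.
#' @param elongated_length_range outgrowth length at the (late) split of
#'   elongated cells (µm).
#' @param debris_n,debris_radius_range transient background debris per field.
#' @param jitter_px boundary jitter amplitude in pixels (0 = noise-free).
#' @param puncta_n,puncta_sigma_um,puncta_amp_range,fluor_bg,fluor_noise_sd,
#'   body_fraction_true fluorescence channel parameters; each vacuole punctum
#'   is placed in the spore body with probability `body_fraction_true`.
#' @param cfu_n0,cfu_days,cfu_lambda,cfu_replicates,cfu_batch_sdlog,
#'   cfu_dilution,cfu_poisson CFU longevity table parameters; `cfu_lambda` is
#'   a named per-condition decay rate (per day).
#' @param stress_replicates,stress_n0,stress_survival_true acute-stress assay
#'   parameters; `stress_survival_true` is a named per-sample survival
#'   fraction.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_spores = 25L,
                         grid = c(896L, 896L),
                         pixel_size_um = 0.18,
                         frame_interval_min = 10,
                         n_frames = 120L,
                         starting_area_mean_um2 = 8,
                         starting_area_sd_um2 = 0.8,
                         efficiency = 0.9,
                         lag_median_min = 150,
                         lag_sdlog = 0.35,
                         swell_rate_um2_min = 0.02,
                         swell_duration_min = 180,
                         outgrowth_rate_um_min = 0.02,
                         tube_halfwidth_um = 1.0,
                         tube_halfwidth_sd = 0.05,
                         ar_division = 3.0,
                         division_ar_target = 3.1,
                         phenotype_probs = c(normal = 0.85, elongated = 0.05,
                                             bubble = 0.04, bipolar = 0.03,
                                             exploded = 0.03),
                         elongated_length_range = c(6, 20),
                         debris_n = 5L,
                         debris_radius_range = c(0.25, 0.8),
                         jitter_px = 0,
                         puncta_n = 12L,
                         puncta_sigma_um = 0.25,
                         puncta_amp_range = c(150, 400),
                         fluor_bg = 100,
                         fluor_noise_sd = 5,
                         body_fraction_true = 0.64,
                         cfu_n0 = 300,
                         cfu_days = c(0, 5, 10, 20, 40, 60, 80),
                         cfu_lambda = c("4C" = log(2) / 80,
                                        "37C" = log(2) / 10),
                         cfu_replicates = 3L,
                         cfu_batch_sdlog = 0.1,
                         cfu_dilution = 1,
                         cfu_poisson = TRUE,
                         stress_replicates = 5L,
                         stress_n0 = 200,
                         stress_survival_true = c("25C" = 0.60,
                                                  "37C" = 0.15,
                                                  "42C" = 0.03)) {
  cfg <- as.list(environment())
  pp <- cfg$phenotype_probs
  need <- c("normal", "elongated", "bubble", "bipolar", "exploded")
  if (!setequal(names(pp), need))
    stop("phenotype_probs must be named: ", paste(need, collapse = ", "))
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-8)
    stop("phenotype_probs must be nonnegative and sum to 1")
  cfg$phenotype_probs <- pp[need]
  p_success <- sum(pp[c("normal", "elongated", "bipolar")])
  if (p_success <= 0 && cfg$efficiency > 0)
    stop("efficiency > 0 requires positive normal/elongated/bipolar probability")
  if (cfg$efficiency > p_success + 1e-12)
    stop("efficiency (", cfg$efficiency, ") cannot exceed the probability of ",
         "division-completing phenotypes (", round(p_success, 3), ")")
  stopifnot(cfg$efficiency >= 0, cfg$efficiency <= 1,
            cfg$pixel_size_um > 0, cfg$frame_interval_min > 0,
            cfg$n_frames >= 2, cfg$swell_rate_um2_min >= 0,
            cfg$outgrowth_rate_um_min > 0, all(cfg$cfu_lambda > 0))
  class(cfg) <- "synth_config"
  cfg
}

# --- continuous-shape truth ------------------------------------------------

# half-width profile of disc body (rs) + axial tube (half-width ro, length
# parameterized by protrusion lam beyond the body) (+ optional mirrored tube)
.profile_bounds <- function(rs, ro, lam) {
  a <- sqrt(max(rs^2 - ro^2, 0))
  ell <- max(0, lam + rs - a - ro)
  c(a = a, ell = ell, tip = a + ell + ro)
}

.shape_ar <- function(rs, ro, lam, ro2 = 0, lam2 = 0, du = 0.004) {
  b1 <- .profile_bounds(rs, ro, lam)
  lo <- -rs
  if (ro2 > 0) {
    b2 <- .profile_bounds(rs, ro2, lam2)
    lo <- -b2[["tip"]]
  }
  u <- seq(lo, b1[["tip"]], by = du)
  h <- sqrt(pmax(rs^2 - u^2, 0))
  tube <- u >= b1[["a"]] & u <= b1[["a"]] + b1[["ell"]]
  h[tube] <- pmax(h[tube], ro)
  capz <- u > b1[["a"]] + b1[["ell"]]
  h[capz] <- pmax(h[capz], sqrt(pmax(ro^2 - (u[capz] - b1[["a"]] - b1[["ell"]])^2, 0)))
  if (ro2 > 0) {
    um <- -u
    tube2 <- um >= b2[["a"]] & um <= b2[["a"]] + b2[["ell"]]
    h[tube2] <- pmax(h[tube2], ro2)
    capz2 <- um > b2[["a"]] + b2[["ell"]]
    h[capz2] <- pmax(h[capz2],
                     sqrt(pmax(ro2^2 - (um[capz2] - b2[["a"]] - b2[["ell"]])^2, 0)))
  }
  A <- sum(2 * h) * du
  ub <- sum(2 * h * u) * du / A
  vu <- sum(2 * h * u^2) * du / A - ub^2
  vv <- sum((2 / 3) * h^3) * du / A
  sqrt(max(vu, vv) / min(vu, vv))
}

# time at which the continuous AR crosses `target`, for tube(s) elongating
# linearly from t_out; returns Inf if not reached before t_max
.solve_ar_time <- function(target, rs, ro, g1, t_out, ro2 = 0, g2 = 0,
                           t_max = 5000) {
  f <- function(t) {
    .shape_ar(rs, ro, g1 * (t - t_out),
              ro2 = ro2, lam2 = if (ro2 > 0) g2 * (t - t_out) else 0) - target
  }
  if (f(t_max) < 0) return(Inf)
  uniroot(f, c(t_out + 1e-6, t_max), tol = 1e-3)$root
}

# --- rasterization ---------------------------------------------------------

.raster_grid <- function(center, extent, px, dim) {
  # pixel centers: x = (col - 0.5) px, y = (row - 0.5) px
  r0 <- max(1L, floor((center[2L] - extent) / px))
  r1 <- min(dim[1L], ceiling((center[2L] + extent) / px) + 1L)
  c0 <- max(1L, floor((center[1L] - extent) / px))
  c1 <- min(dim[2L], ceiling((center[1L] + extent) / px) + 1L)
  if (r1 < r0 || c1 < c0) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  list(rows = rows, cols = cols,
       x = matrix((cols - 0.5) * px, length(rows), length(cols), byrow = TRUE),
       y = matrix((rows - 0.5) * px, length(rows), length(cols)))
}

# linear indices of a disc
.pixels_disc <- function(center, r, px, dim) {
  g <- .raster_grid(center, r + 2 * px, px, dim)
  if (is.null(g)) return(integer())
  inside <- (g$x - center[1L])^2 + (g$y - center[2L])^2 <= r^2
  ij <- which(inside, arr.ind = TRUE)
  (g$cols[ij[, 2L]] - 1L) * dim[1L] + g$rows[ij[, 1L]]
}

# linear indices of a germinating cell; returns a list of 1 or 2 pixel sets
# (2 after the mask splits at the septum, with a background gap between)
.pixels_cell <- function(center, theta, rs, ro, lam, ro2 = 0, lam2 = 0,
                         px, dim, split = FALSE, gap_um = NULL) {
  b1 <- .profile_bounds(rs, ro, lam)
  lo <- if (ro2 > 0) .profile_bounds(rs, ro2, lam2)[["tip"]] else rs
  extent <- max(b1[["tip"]], lo)
  g <- .raster_grid(center, extent + 2 * px, px, dim)
  if (is.null(g)) return(list(integer()))
  dx <- g$x - center[1L]; dy <- g$y - center[2L]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- u^2 + v^2 <= rs^2
  T1 <- b1[["a"]] + b1[["ell"]]
  inside <- inside | (u >= b1[["a"]] & u <= T1 & abs(v) <= ro)
  inside <- inside | (u > T1 & (u - T1)^2 + v^2 <= ro^2)
  if (ro2 > 0) {
    b2 <- .profile_bounds(rs, ro2, lam2)
    T2 <- b2[["a"]] + b2[["ell"]]
    um <- -u
    inside <- inside | (um >= b2[["a"]] & um <= T2 & abs(v) <= ro2)
    inside <- inside | (um > T2 & (um - T2)^2 + v^2 <= ro2^2)
  }
  lin <- function(m) {
    ij <- which(m, arr.ind = TRUE)
    (g$cols[ij[, 2L]] - 1L) * dim[1L] + g$rows[ij[, 1L]]
  }
  if (!split) return(list(lin(inside)))
  if (is.null(gap_um)) gap_um <- 1.6 * px
  u_s <- (-lo + b1[["tip"]]) / 2
  list(lin(inside & u < u_s - gap_um / 2),
       lin(inside & u > u_s + gap_um / 2))
}

.apply_jitter <- function(idx, dim, jitter_px) {
  if (jitter_px <= 0 || !length(idx)) return(idx)
  p <- 0.25 * min(jitter_px, 1)
  nr <- dim[1L]
  neigh <- c(-1L, 1L, -nr, nr)
  inset <- logical(prod(dim))
  inset[idx] <- TRUE
  nb <- outer(idx, neigh, "+")
  ok <- nb >= 1L & nb <= prod(dim)
  boundary <- idx[rowSums(matrix(!inset[pmax(nb, 1L)] & ok, nrow = length(idx))) > 0L]
  cand <- unique(nb[ok & !inset[pmax(nb, 1L)]])
  drop <- boundary[runif(length(boundary)) < p]
  add <- cand[runif(length(cand)) < p]
  sort(unique(c(setdiff(idx, drop), add)))
}

# --- time-lapse generation -------------------------------------------------

#' Generate a synthetic germination time-lapse with ground truth
#'
#' Rasterizes each spore as a disc placed without overlap; spores stay
#' dormant until their lag, swell isotropically, then extend a polarized
#' capsule outgrowth in a random direction (two antiparallel outgrowths for
#' bipolar cells; continued circular swelling with a low-AR split for bubble
#' cells; area collapse into fragments for exploded cells). The mask splits
#' into two labels shortly after the AR-3 crossing (near the division AR
#' target of 3.1). Debris specks appear and disappear at random frames.
#'
#' @param config a [synth_config()].
#' @return List with `timelapse` (a [time_lapse()]) and `truth` (data frame
#'   with one row per object: type, frame-0 centroid in pixels, true starting
#'   area, attempt flag, phenotype, lag, swelling boundaries, continuous
#'   division time, division and split frames, outgrowth length at division).
#' @export
generate_timelapse <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  px <- cfg$pixel_size_um
  dim <- as.integer(cfg$grid)
  W <- dim[2L] * px; H <- dim[1L] * px
  dt <- cfg$frame_interval_min
  n <- cfg$n_spores
  pp <- cfg$phenotype_probs
  p_success <- sum(pp[c("normal", "elongated", "bipolar")])
  p_attempt <- if (p_success > 0) cfg$efficiency / p_success else 0

  sp <- vector("list", n)
  for (i in seq_len(n)) {
    A0 <- max(rnorm(1, cfg$starting_area_mean_um2, cfg$starting_area_sd_um2), 4)
    r0 <- sqrt(A0 / pi)
    attempt <- runif(1) < p_attempt
    phen <- if (attempt) sample(names(pp), 1L, prob = pp) else "not_germinated"
    lag <- rlnorm(1, log(cfg$lag_median_min), cfg$lag_sdlog)
    t_out <- lag + cfg$swell_duration_min
    A1 <- A0 + cfg$swell_rate_um2_min * cfg$swell_duration_min
    rs <- sqrt(A1 / pi)
    g <- cfg$outgrowth_rate_um_min
    s <- list(A0 = A0, r0 = r0, rs = rs, attempt = attempt, phen = phen,
              lag = lag, t_out = t_out, theta = runif(1, 0, 2 * pi),
              ro = NA_real_, ro2 = 0, g1 = g, g2 = 0,
              t_div = Inf, t_split = Inf, t_explode = Inf,
              lam_div = NA_real_, lam_max = 0, extent = r0)
    if (phen %in% c("normal", "elongated", "bipolar")) {
      if (phen == "elongated") {
        s$ro <- 0.995 * rs
      } else {
        s$ro <- min(max(rnorm(1, cfg$tube_halfwidth_um, cfg$tube_halfwidth_sd),
                        0.85), 0.9 * rs)
      }
      if (phen == "bipolar") { s$ro2 <- s$ro; s$g2 <- g * runif(1, 0.6, 1.0) }
      s$t_div <- .solve_ar_time(cfg$ar_division, rs, s$ro, s$g1, t_out,
                                ro2 = s$ro2, g2 = s$g2)
      t31 <- .solve_ar_time(cfg$division_ar_target, rs, s$ro, s$g1, t_out,
                            ro2 = s$ro2, g2 = s$g2)
      s$t_split <- max(t31, s$t_div + 2.1 * dt)
      if (phen == "elongated") {
        L <- runif(1, cfg$elongated_length_range[1L], cfg$elongated_length_range[2L])
        s$t_split <- max(s$t_split, t_out + L / g)
      }
      s$lam_div <- s$g1 * (s$t_div - t_out)
      s$lam_max <- s$g1 * (s$t_split - t_out)
      s$extent <- rs + s$lam_max
      if (phen == "bipolar")
        s$extent <- rs + max(s$lam_max, s$g2 * (s$t_split - t_out))
    } else if (phen == "bubble") {
      s$t_split <- t_out + runif(1, 60, 180)
      s$rs_final <- sqrt((A0 + cfg$swell_rate_um2_min * (s$t_split - lag)) / pi)
      s$extent <- s$rs_final
    } else if (phen == "exploded") {
      s$t_explode <- lag + runif(1, 0.5, 1.1) * cfg$swell_duration_min
      nf <- sample(3:5, 1L)
      rx <- sqrt((A0 + cfg$swell_rate_um2_min *
                    max(0, min(s$t_explode, t_out) - lag)) / pi)
      ang <- runif(nf, 0, 2 * pi); rad <- runif(nf, 0, 0.6 * rx)
      s$frag_dx <- rad * cos(ang); s$frag_dy <- rad * sin(ang)
      s$frag_r <- runif(nf, 0.3, 0.5)
      s$extent <- rx + 0.5
    } else {
      s$extent <- r0  # dormant
    }
    sp[[i]] <- s
  }

  # non-overlap placement by rejection sampling on final extents
  centers <- matrix(NA_real_, n, 2L)
  R <- vapply(sp, function(s) s$extent + 0.6, 0)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (2 * (R[i] + 1) >= min(W, H))
      stop("placement error: a spore's final extent (", round(R[i], 1),
           " um) does not fit the field; enlarge `grid`")
    for (att in seq_len(2000L)) {
      cx <- runif(1, R[i] + 1, W - R[i] - 1)
      cy <- runif(1, R[i] + 1, H - R[i] - 1)
      if (i == 1L || all(sqrt((centers[seq_len(i - 1L), 1L] - cx)^2 +
                              (centers[seq_len(i - 1L), 2L] - cy)^2) >=
                         R[i] + R[seq_len(i - 1L)] + 0.5)) {
        centers[i, ] <- c(cx, cy); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("placement error: cannot place ", n, " spores without overlap; ",
           "enlarge `grid` or reduce `n_spores`")
  }
  for (i in seq_len(n)) sp[[i]]$center <- centers[i, ]

  # debris: transient specks away from the cells
  deb <- list()
  if (cfg$debris_n > 0) {
    for (j in seq_len(cfg$debris_n)) {
      rd <- runif(1, cfg$debris_radius_range[1L], cfg$debris_radius_range[2L])
      for (att in seq_len(500L)) {
        cx <- runif(1, rd + 1, W - rd - 1); cy <- runif(1, rd + 1, H - rd - 1)
        if (all(sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2) >=
                R + rd + 0.5)) break
        cx <- NA
      }
      if (is.na(cx)) next
      deb[[length(deb) + 1L]] <- list(
        center = c(cx, cy), r = rd,
        from = sample(seq_len(cfg$n_frames - 3L), 1L),
        life = sample(2:10, 1L))
    }
  }

  explode_persist <- 2L
  frames <- vector("list", cfg$n_frames)
  for (k in seq_len(cfg$n_frames)) {
    t <- (k - 1L) * dt
    mk <- matrix(0L, dim[1L], dim[2L])
    lab <- 0L
    for (i in seq_len(n)) {
      s <- sp[[i]]
      pieces <- NULL
      if (t >= s$t_explode) {
        kx <- ceiling(s$t_explode / dt)  # first frame index (0-based) >= t_explode
        if ((k - 1L) < kx + explode_persist) {
          pieces <- lapply(seq_along(s$frag_r), function(q)
            .pixels_disc(s$center + c(s$frag_dx[q], s$frag_dy[q]),
                         s$frag_r[q], px, dim))
        } else pieces <- list()
      } else if (s$phen == "bubble" && t * (1 + 1e-12) >= s$t_split) {
        pieces <- .pixels_cell(s$center, s$theta, s$rs_final, 0.999 * s$rs_final,
                               0, px = px, dim = dim, split = TRUE)
      } else if (t < s$lag || !s$attempt) {
        pieces <- list(.pixels_disc(s$center, s$r0, px, dim))
      } else if (t < s$t_out || s$phen %in% c("bubble", "exploded")) {
        tsw <- if (s$phen == "bubble") t else min(t, s$t_out)
        rt <- sqrt((s$A0 + cfg$swell_rate_um2_min * (tsw - s$lag)) / pi)
        pieces <- list(.pixels_disc(s$center, rt, px, dim))
      } else {
        lam1 <- min(s$g1 * (t - s$t_out), s$lam_max)
        lam2 <- if (s$ro2 > 0) min(s$g2 * (t - s$t_out),
                                   s$g2 * (s$t_split - s$t_out)) else 0
        pieces <- .pixels_cell(s$center, s$theta, s$rs, s$ro, lam1,
                               ro2 = s$ro2, lam2 = lam2, px = px, dim = dim,
                               split = t * (1 + 1e-12) >= s$t_split)
      }
      for (pz in pieces) {
        pz <- .apply_jitter(pz, dim, cfg$jitter_px)
        if (length(pz)) { lab <- lab + 1L; mk[pz] <- lab }
      }
    }
    for (d in deb) {
      if ((k - 1L) >= d$from && (k - 1L) < d$from + d$life) {
        pz <- .apply_jitter(.pixels_disc(d$center, d$r, px, dim), dim, cfg$jitter_px)
        if (length(pz)) { lab <- lab + 1L; mk[pz] <- lab }
      }
    }
    frames[[k]] <- mk
  }

  truth_sp <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- sp[[i]]
    t_end <- (cfg$n_frames - 1L) * dt
    divided <- is.finite(s$t_div) && s$t_div < t_end
    data.frame(
      object_id = i, type = "spore",
      center_row_px = s$center[2L] / px + 0.5,
      center_col_px = s$center[1L] / px + 0.5,
      starting_area_um2 = s$A0,
      attempt = s$attempt, phenotype = s$phen,
      lag_min = s$lag,
      swell_start_min = if (s$attempt) s$lag else NA_real_,
      swell_end_min = if (!s$attempt || s$phen == "not_germinated") NA_real_
        else if (s$phen == "bubble") s$t_split
        else min(s$t_out, s$t_explode),
      divides = divided,
      division_time_cont_min = if (divided) s$t_div else NA_real_,
      division_frame = if (divided) floor(s$t_div / dt) + 1L else NA_integer_,
      split_frame = if (is.finite(s$t_split) && s$t_split <= t_end)
        ceiling(s$t_split / dt) else NA_integer_,
      outgrowth_len_div_um = s$lam_div,
      explode_frame = if (is.finite(s$t_explode))
        ceiling(s$t_explode / dt) else NA_integer_,
      tube_halfwidth_um = s$ro,
      theta = s$theta,
      body_fraction_true = NA_real_)
  }))
  if (length(deb)) {
    truth_deb <- do.call(rbind, lapply(seq_along(deb), function(j) {
      d <- deb[[j]]
      data.frame(
        object_id = n + j, type = "debris",
        center_row_px = d$center[2L] / px + 0.5,
        center_col_px = d$center[1L] / px + 0.5,
        starting_area_um2 = pi * d$r^2,
        attempt = FALSE, phenotype = NA_character_,
        lag_min = NA_real_, swell_start_min = NA_real_, swell_end_min = NA_real_,
        divides = FALSE, division_time_cont_min = NA_real_,
        division_frame = NA_integer_, split_frame = NA_integer_,
        outgrowth_len_div_um = NA_real_, explode_frame = NA_integer_,
        tube_halfwidth_um = NA_real_, theta = NA_real_,
        body_fraction_true = NA_real_)
    }))
    truth_sp <- rbind(truth_sp, truth_deb)
  }
  rownames(truth_sp) <- NULL

  tl <- time_lapse(frames, dt, px,
                   metadata = list(synthetic = TRUE, seed = cfg$seed))
  attr(tl, "spore_models") <- sp
  list(timelapse = tl, truth = truth_sp)
}

#' Generate an FM4-64-like fluorescence channel
#'
#' At and after each divided spore's division frame, places Gaussian vacuole
#' puncta; each punctum lies in the spore body with probability
#' `body_fraction_true`, otherwise in the outgrowth tube. Dormant spores take
#' up no dye. A constant background plus Gaussian noise is added everywhere.
#'
#' @param gen output of [generate_timelapse()] (list with `timelapse`,
#'   `truth`).
#' @param config the same [synth_config()].
#' @return `gen` with the fluorescence channel attached to `timelapse` and a
#'   `body_fraction_true` column filled in `truth` (realized punctum fraction
#'   per spore).
#' @export
generate_fluorescence <- function(gen, config) {
  stopifnot(inherits(config, "synth_config"))
  tl <- gen$timelapse
  truth <- gen$truth
  sp <- attr(tl, "spore_models")
  if (is.null(sp)) stop("missing truth: generate the time-lapse first")
  cfg <- config
  set.seed(cfg$seed + 500000L)
  px <- tl$pixel_size_um
  dim <- dim(tl$frames[[1L]])
  dt <- tl$frame_interval_min
  sig <- cfg$puncta_sigma_um
  puncta <- list()
  for (i in seq_along(sp)) {
    s <- sp[[i]]
    divided <- is.finite(s$t_div) && s$t_div < (length(tl$frames) - 1L) * dt
    if (!divided) next
    m <- max(3 * sig + 0.15, 0.4)
    n_body <- rbinom(1L, cfg$puncta_n, cfg$body_fraction_true)
    pos <- matrix(NA_real_, cfg$puncta_n, 2L)
    for (q in seq_len(cfg$puncta_n)) {
      if (q <= n_body) {  # inside the body disc, margin from the edge
        rr <- sqrt(runif(1)) * max(s$rs - m, 0.2)
        aa <- runif(1, 0, 2 * pi)
        duv <- c(rr * cos(aa), rr * sin(aa))
      } else {            # along the tube, margin from body and tip
        u <- runif(1, s$rs + m, max(s$rs + m + 0.05, s$rs + s$lam_div - m))
        v <- runif(1, -1, 1) * max(s$ro - m, 0.05)
        duv <- c(u * cos(s$theta) - v * sin(s$theta),
                 u * sin(s$theta) + v * cos(s$theta))
      }
      pos[q, ] <- s$center + duv
    }
    amp <- runif(cfg$puncta_n, cfg$puncta_amp_range[1L], cfg$puncta_amp_range[2L])
    k_div <- floor(s$t_div / dt) + 1L
    puncta[[length(puncta) + 1L]] <- list(pos = pos, amp = amp, from = k_div)
    truth$body_fraction_true[truth$object_id == i] <- n_body / cfg$puncta_n
  }
  fl <- vector("list", length(tl$frames))
  for (k in seq_along(fl)) {
    f <- matrix(cfg$fluor_bg, dim[1L], dim[2L]) +
      matrix(rnorm(prod(dim), 0, cfg$fluor_noise_sd), dim[1L], dim[2L])
    for (pset in puncta) {
      if ((k - 1L) < pset$from) next
      for (q in seq_len(nrow(pset$pos))) {
        ctr <- pset$pos[q, ]
        g <- .raster_grid(ctr, 4 * sig, px, dim)
        if (is.null(g)) next
        add <- pset$amp[q] *
          exp(-(((g$x - ctr[1L])^2 + (g$y - ctr[2L])^2) / (2 * sig^2)))
        f[g$rows, g$cols] <- f[g$rows, g$cols] + add
      }
    }
    fl[[k]] <- pmax(f, 0)
  }
  tl$fluorescence <- fl
  gen$timelapse <- tl
  gen$truth <- truth
  gen
}

# --- plate-count generators ------------------------------------------------

#' Generate a CFU longevity dataset with ground truth
#'
#' True viability decays exponentially, `S(t) = exp(-lambda_T t)`, with a
#' per-condition rate; each replicate carries a lognormal batch multiplier
#' constant over time, and plate counts are Poisson around
#' `N0 * S(t) * batch`. With the default rates, viability halves by day 10 in
#' the 37 °C analog and by day 80 in the 4 °C analog.
#'
#' @param config a [synth_config()].
#' @return List with `cfu` (data frame: condition, day, replicate, dilution,
#'   count) and `truth` (per-condition lambda; per-replicate batch
#'   multipliers).
#' @export
generate_cfu_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed + 600000L)
  rows <- list(); bt <- list()
  for (cond in names(cfg$cfu_lambda)) {
    lam <- cfg$cfu_lambda[[cond]]
    for (r in seq_len(cfg$cfu_replicates)) {
      batch <- rlnorm(1, 0, cfg$cfu_batch_sdlog)
      mu <- cfg$cfu_n0 * exp(-lam * cfg$cfu_days) * batch * cfg$cfu_dilution
      cnt <- if (cfg$cfu_poisson) rpois(length(mu), mu) else mu
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, day = cfg$cfu_days, replicate = r,
        dilution = cfg$cfu_dilution, count = cnt)
      bt[[length(bt) + 1L]] <- data.frame(condition = cond, replicate = r,
                                          lambda = lam, batch = batch)
    }
  }
  list(cfu = do.call(rbind, rows), truth = do.call(rbind, bt))
}

#' Generate an acute-stress assay dataset with ground truth
#'
#' Per sample, `stress_replicates` plate pairs with Poisson counts around
#' `stress_n0` (untreated) and `stress_n0 * survival` (treated).
#'
#' @param config a [synth_config()].
#' @param stressor label for the stress applied (`"heat"` or `"UV"`).
#' @return List with `assay` (data frame: sample, stressor, replicate,
#'   cfu_untreated, cfu_treated) and `truth` (per-sample true survival).
#' @export
generate_stress_dataset <- function(config, stressor = "heat") {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed + 700000L)
  rows <- list()
  for (smp in names(cfg$stress_survival_true)) {
    sv <- cfg$stress_survival_true[[smp]]
    u <- rpois(cfg$stress_replicates, cfg$stress_n0)
    tr <- rpois(cfg$stress_replicates, cfg$stress_n0 * sv)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = smp, stressor = stressor,
      replicate = seq_len(cfg$stress_replicates),
      cfu_untreated = u, cfu_treated = tr)
  }
  list(assay = do.call(rbind, rows),
       truth = data.frame(sample = names(cfg$stress_survival_true),
                          survival_true = unname(cfg$stress_survival_true)))
}

# --- cohort runner and truth matching --------------------------------------

#' Match ground-truth objects to scored records
#'
#' Joins generator truth to records by nearest frame-0 centroid (within
#' `max_dist_px` pixels).
#'
#' @param records scored records (from [score_spores()] / [score_timelapse()]).
#' @param tracks the matching `track_set`.
#' @param truth generator truth data frame.
#' @param max_dist_px matching radius in pixels (default 3).
#' @return `records` with `truth_*` columns appended (NA where unmatched).
#' @export
match_truth_to_records <- function(records, tracks, truth, max_dist_px = 3) {
  m <- tracks$measures
  f0 <- m[m$frame == 0L, ]
  add <- data.frame(
    truth_id = rep(NA_integer_, nrow(records)),
    truth_type = NA_character_, truth_attempt = NA,
    truth_phenotype = NA_character_, truth_divides = NA,
    truth_division_frame = NA_integer_,
    truth_division_time_cont_min = NA_real_,
    truth_swell_start_min = NA_real_, truth_swell_end_min = NA_real_,
    truth_outgrowth_len_div_um = NA_real_,
    truth_body_fraction = NA_real_)
  for (i in seq_len(nrow(records))) {
    r0 <- f0[f0$track_id == records$track_id[i], ]
    if (!nrow(r0)) next
    d2 <- (truth$center_row_px - r0$centroid_row)^2 +
      (truth$center_col_px - r0$centroid_col)^2
    j <- which.min(d2)
    if (!length(j) || d2[j] > max_dist_px^2) next
    add$truth_id[i] <- truth$object_id[j]
    add$truth_type[i] <- truth$type[j]
    add$truth_attempt[i] <- truth$attempt[j]
    add$truth_phenotype[i] <- truth$phenotype[j]
    add$truth_divides[i] <- truth$divides[j]
    add$truth_division_frame[i] <- truth$division_frame[j]
    add$truth_division_time_cont_min[i] <- truth$division_time_cont_min[j]
    add$truth_swell_start_min[i] <- truth$swell_start_min[j]
    add$truth_swell_end_min[i] <- truth$swell_end_min[j]
    add$truth_outgrowth_len_div_um[i] <- truth$outgrowth_len_div_um[j]
    add$truth_body_fraction[i] <- truth$body_fraction_true[j]
  }
  cbind(records, add)
}

#' Generate and score a multi-field synthetic cohort
#'
#' Real experiments image several fields of view; cohorts larger than one
#' field's capacity are generated as multiple fields with consecutive
#' sub-seeds and pooled. Each field is generated, scored with
#' [score_timelapse()], matched to truth, and discarded before the next.
#'
#' @param config a [synth_config()]; `config$seed + field - 1` seeds field
#'   `field`.
#' @param n_fields number of fields of view.
#' @param thresholds scoring thresholds.
#' @param fluorescence also generate the FM4-64 channel and measure vacuole
#'   partitions.
#' @return List with pooled `records` (with `field` and `truth_*` columns),
#'   `truth`, `vacuole` (if requested), and `n_spores_truth`.
#' @export
run_synthetic_cohort <- function(config, n_fields = 1L,
                                 thresholds = default_thresholds(),
                                 fluorescence = FALSE) {
  recs <- list(); truths <- list(); vac <- list()
  for (f in seq_len(n_fields)) {
    cfg <- config
    cfg$seed <- config$seed + (f - 1L)
    gen <- generate_timelapse(cfg)
    if (fluorescence) gen <- generate_fluorescence(gen, cfg)
    sc <- score_timelapse(gen$timelapse, thresholds)
    if (sc$excluded) next
    rec <- match_truth_to_records(sc$records, sc$tracks, gen$truth)
    rec$field <- f
    recs[[length(recs) + 1L]] <- rec
    gt <- gen$truth; gt$field <- f
    truths[[length(truths) + 1L]] <- gt
    if (fluorescence) {
      v <- vacuole_partition(gen$timelapse, sc$tracks, sc$records)
      if (nrow(v)) { v$field <- f; vac[[length(vac) + 1L]] <- v }
    }
  }
  list(records = do.call(rbind, recs),
       truth = do.call(rbind, truths),
       vacuole = if (fluorescence) do.call(rbind, vac) else NULL,
       n_spores_truth = sum(vapply(truths, function(t) sum(t$type == "spore"), 0)))
}

# --- grayscale rendering and fallback segmentation -------------------------

#' Render a brightfield-like grayscale stack from label masks
#'
#' Dark cells on a bright field with Gaussian noise, for exercising the
#' bundled threshold-based fallback segmenter.
#'
#' @param tl a [time_lapse()].
#' @param cell_level,bg_level gray levels in \[0, 1\].
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return List of numeric matrices in \[0, 1\].
#' @export
render_brightfield <- function(tl, cell_level = 0.45, bg_level = 0.9,
                               noise_sd = 0.03, seed = 1L) {
  set.seed(seed)
  lapply(tl$frames, function(f) {
    img <- ifelse(f > 0L, cell_level, bg_level) +
      matrix(rnorm(length(f), 0, noise_sd), nrow(f), ncol(f))
    pmin(pmax(img, 0), 1)
  })
}

#' Threshold-based fallback segmentation
#'
#' Otsu threshold per frame (dark objects on a bright background) followed by
#' connected-component labeling. A minimal stand-in for an external segmenter
#' when only grayscale images are available; any segmenter producing label
#' masks can feed the pipeline instead.
#'
#' @param images list of grayscale matrices in \[0, 1\].
#' @param pixel_size_um,frame_interval_min calibration for the returned
#'   [time_lapse()].
#' @param min_px drop components smaller than this (default 9).
#' @return A [time_lapse()] of label masks.
#' @export
segment_threshold <- function(images, pixel_size_um, frame_interval_min,
                              min_px = 9L) {
  frames <- lapply(images, function(img) {
    thr <- EBImage::otsu(EBImage::Image(img))
    lab <- EBImage::bwlabel(matrix(as.integer(img < thr), nrow(img), ncol(img)))
    lab <- matrix(as.integer(lab), nrow(img), ncol(img))
    if (min_px > 0L) {
      tb <- tabulate(lab)
      drop <- which(tb < min_px)
      if (length(drop)) lab[lab %in% drop] <- 0L
    }
    lab
  })
  time_lapse(frames, frame_interval_min, pixel_size_um)
}
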