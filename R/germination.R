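# Turning tracks into scored spore records: spore selection, first-division
# calling, germination efficiency, starting areas, population curves, and
# swelling-window detection.

#' Select spore tracks
#'
#' Keeps exactly the tracks that (a) are present at time point zero and
#' (b) have an aspect ratio strictly below `ar_max` at frame 0 — these are
#' circular and therefore likely spores. Optionally a starting-area floor
#' excludes small round debris (true spores are ~7–9 µm²). All other tracks
#' are excluded with a reason.
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param ar_max strict AR threshold at frame 0 (default 1.4).
#' @param min_area_um2 minimum starting area in µm² (default 3; set 0 to
#'   disable).
#' @return Data frame with one row per track: `track_id, first_frame,
#'   starting_area_um2, starting_ar, is_spore, excluded, exclude_reason`.
#'   `excluded` is `!is_spore`; the three outcomes partition the track set.
#' @export
select_spores <- function(tracks, ar_max = 1.4, min_area_um2 = 3) {
  ts <- track_summary(tracks)
  reason <- rep(NA_character_, nrow(ts))
  reason[ts$first_frame != 0] <- "not_present_t0"
  reason[ts$first_frame == 0 & ts$starting_ar >= ar_max] <- "ar_t0_above_threshold"
  reason[ts$first_frame == 0 & ts$starting_ar < ar_max &
           ts$starting_area_um2 < min_area_um2] <- "below_min_area"
  data.frame(
    track_id = ts$track_id,
    first_frame = ts$first_frame,
    starting_area_um2 = ifelse(ts$first_frame == 0, ts$starting_area_um2, NA_real_),
    starting_ar = ifelse(ts$first_frame == 0, ts$starting_ar, NA_real_),
    is_spore = is.na(reason),
    excluded = !is.na(reason),
    exclude_reason = reason)
}

#' Call the time of first division from an aspect-ratio series
#'
#' The first division is the first frame at which the object's AR strictly
#' exceeds `ar_threshold` (default 3.0; germinating cells reach an average AR
#' of about 3.1 at division). Division times are quantized to frame times.
#'
#' @param ar numeric AR series of one track.
#' @param frames 0-based frame indices matching `ar` (default contiguous from 0).
#' @param ar_threshold strict AR threshold (> 1).
#' @param interval_min minutes per frame.
#' @return `NULL` if AR never exceeds the threshold, else a list with
#'   `frame` (0-based) and `time_min` (`frame * interval_min`).
#' @examples
#' ar <- c(rep(1, 39), 3.2, 3.4)
#' call_first_division(ar, interval_min = 10)$time_min  # 390 (frame 39 0-based)
#' @export
call_first_division <- function(ar, frames = seq_along(ar) - 1L,
                                ar_threshold = 3.0, interval_min = 10) {
  if (!is.numeric(ar_threshold) || ar_threshold <= 1)
    stop("parameter error: `ar_threshold` must exceed 1")
  hit <- which(ar > ar_threshold)
  if (!length(hit)) return(NULL)
  f <- frames[hit[1L]]
  list(frame = as.integer(f), time_min = f * interval_min)
}

#' Germination efficiency
#'
#' The number of scored spores that successfully underwent the first division
#' before the end of the time-lapse, divided by the total spores scored.
#'
#' @param records spore records from [score_spores()].
#' @return List with `efficiency`, `n_germinated`, `n_scored` (numerator and
#'   denominator are kept for Fisher tests across conditions).
#' @export
germination_efficiency <- function(records) {
  sp <- records[records$is_spore, , drop = FALSE]
  if (!nrow(sp)) stop("undefined ratio: no scored spores")
  list(efficiency = mean(sp$germinated),
       n_germinated = sum(sp$germinated),
       n_scored = nrow(sp))
}

#' Starting areas of scored spores
#'
#' Frame-0 areas (µm²) of all scored spores, or only of the spores that went
#' on to complete the first division.
#'
#' @param records spore records from [score_spores()].
#' @param germinated_only restrict to spores that germinated.
#' @return Numeric vector of areas in µm².
#' @export
starting_area <- function(records, germinated_only = FALSE) {
  sp <- records[records$is_spore, , drop = FALSE]
  if (germinated_only) sp <- sp[sp$germinated, , drop = FALSE]
  sp$starting_area_um2
}

#' Population mean curves of area and aspect ratio
#'
#' Per-frame mean and standard error (sample SD / sqrt(n)) of area and AR over
#' the scored spores still tracked at that frame. Interpolated (gap) frames
#' contribute their interpolated values; excluded tracks are omitted.
#'
#' @param tracks a `track_set`.
#' @param records spore records; only rows with `is_spore` are used.
#' @return Data frame: `frame, time_min, n, area_mean, area_se, ar_mean, ar_se`.
#' @export
population_curves <- function(tracks, records) {
  ids <- records$track_id[records$is_spore]
  m <- tracks$measures
  m <- m[m$track_id %in% ids, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(frame = integer(), time_min = numeric(), n = integer(),
                      area_mean = numeric(), area_se = numeric(),
                      ar_mean = numeric(), ar_se = numeric()))
  se <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  sp <- split(m, m$frame)
  out <- data.frame(
    frame = as.integer(names(sp)),
    n = vapply(sp, nrow, 0L),
    area_mean = vapply(sp, function(d) mean(d$area_um2), 0),
    area_se = vapply(sp, function(d) se(d$area_um2), 0),
    ar_mean = vapply(sp, function(d) mean(d$aspect_ratio), 0),
    ar_se = vapply(sp, function(d) se(d$aspect_ratio), 0))
  out$time_min <- out$frame * tracks$frame_interval_min
  rownames(out) <- NULL
  out[order(out$frame),
      c("frame", "time_min", "n", "area_mean", "area_se", "ar_mean", "ar_se")]
}

#' Detect the swelling window of one spore
#'
#' Swelling is an increase in cell area without an increase in aspect ratio
#' (no departure from circularity). After centered moving-average smoothing,
#' frames qualify when the area slope exceeds `area_slope_min` (a fraction of
#' the starting area per frame) while the AR slope stays below `ar_slope_max`
#' per frame. The longest contiguous qualifying run of at least `min_run`
#' frames is returned; its endpoints are shifted by `floor(smooth_frames/2)`
#' frames to undo the look-ahead of the centered filter on one-sided ramps,
#' and the window never extends past the called division.
#'
#' @param area,ar numeric series of one track (same length).
#' @param interval_min minutes per frame.
#' @param frames 0-based frame indices matching the series.
#' @param smooth_frames odd moving-average width >= 3 (default 5).
#' @param area_slope_min minimum area slope, as a fraction of starting area
#'   per frame (default 0.005, i.e. 0.5%).
#' @param ar_slope_max maximum AR slope per frame (default 0.005).
#' @param division_frame optional 0-based called division frame.
#' @param min_run minimum qualifying run length in frames (default 3).
#' @return `NULL` if no qualifying run, else `c(start_min, end_min)`.
#' @export
detect_swelling_window <- function(area, ar, interval_min,
                                   frames = seq_along(area) - 1L,
                                   smooth_frames = 5L,
                                   area_slope_min = 0.005,
                                   ar_slope_max = 0.005,
                                   division_frame = NA,
                                   min_run = 3L) {
  if (smooth_frames < 3L || smooth_frames %% 2L == 0L)
    stop("parameter error: `smooth_frames` must be odd and >= 3")
  n <- length(area)
  if (n < smooth_frames + 2L) return(NULL)
  w <- rep(1 / smooth_frames, smooth_frames)
  as_ <- stats::filter(area, w, sides = 2)
  rs_ <- stats::filter(ar, w, sides = 2)
  # centered slope per frame of the smoothed series
  slope <- function(y) c(NA, (y[-(1:2)] - y[1:(n - 2L)]) / 2, NA)
  sa <- slope(as.numeric(as_))
  sr <- slope(as.numeric(rs_))
  thr_a <- area_slope_min * area[1L]
  ok <- !is.na(sa) & !is.na(sr) & sa > thr_a & sr < ar_slope_max
  if (!is.na(division_frame)) ok <- ok & frames <= division_frame
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  # Undo the filter's look-ahead on one-sided ramps. The start detector
  # (area slope crossing a threshold) fires ~1 frame later than the raw
  # half-window anticipation; the end detector (AR slope violation) fires as
  # soon as any AR rise enters the look-ahead, a frame earlier.
  half <- smooth_frames %/% 2L
  f_start <- frames[starts[best]] + half - 1L
  f_end <- frames[ends[best]] + half + 1L
  if (!is.na(division_frame)) f_end <- min(f_end, division_frame)
  f_end <- min(f_end, frames[n])
  if (f_end <= f_start) return(NULL)
  c(start_min = f_start * interval_min, end_min = f_end * interval_min)
}

#' Score spore records from tracks
#'
#' Applies spore selection, first-division calling and swelling-window
#' detection to every track, producing one record per track. Phenotype
#' classification is added separately by [classify_spores()].
#'
#' @param tracks a `track_set` from [link_tracks()] (after
#'   [flag_focus_loss()] if focus repair is wanted).
#' @param thresholds a [default_thresholds()] list.
#' @return Data frame with one row per track: the [select_spores()] columns
#'   plus `division_frame`, `division_time_min`, `germinated`,
#'   `swelling_start_min`, `swelling_end_min`, and `phenotype` (`NA` until
#'   classified).
#' @export
score_spores <- function(tracks, thresholds = default_thresholds()) {
  thr <- thresholds
  rec <- select_spores(tracks, ar_max = thr$ar_spore_max,
                       min_area_um2 = thr$min_spore_area_um2)
  m <- tracks$measures
  rec$division_frame <- NA_integer_
  rec$division_time_min <- NA_real_
  rec$germinated <- FALSE
  rec$swelling_start_min <- NA_real_
  rec$swelling_end_min <- NA_real_
  for (i in which(rec$is_spore)) {
    d <- m[m$track_id == rec$track_id[i], , drop = FALSE]
    dv <- call_first_division(d$aspect_ratio, d$frame,
                              ar_threshold = thr$ar_division,
                              interval_min = tracks$frame_interval_min)
    if (!is.null(dv)) {
      rec$division_frame[i] <- dv$frame
      rec$division_time_min[i] <- dv$time_min
      rec$germinated[i] <- TRUE
    }
    sw <- detect_swelling_window(
      d$area_um2, d$aspect_ratio, tracks$frame_interval_min, d$frame,
      smooth_frames = thr$swell_smooth_frames,
      area_slope_min = thr$swell_area_slope_min,
      ar_slope_max = thr$swell_ar_slope_max,
      division_frame = if (is.null(dv)) NA else dv$frame)
    if (!is.null(sw)) {
      rec$swelling_start_min[i] <- sw[["start_min"]]
      rec$swelling_end_min[i] <- sw[["end_min"]]
    }
  }
  rec$phenotype <- NA_character_
  rec
}

#' Run the full scoring pipeline on one time-lapse
#'
#' Links tracks, flags/repairs focus loss, scores spore records, classifies
#' outgrowth phenotypes and computes population curves.
#'
#' @param tl a [time_lapse()].
#' @param thresholds a [default_thresholds()] list.
#' @param classify run [classify_spores()] (needs the masks; default TRUE).
#' @return An object of class `germ_scoring`: list with `records`, `tracks`,
#'   `curves`, `flagged_frames`, `excluded` and `thresholds`. If more than
#'   `focus_max_run` consecutive frames lost focus, `excluded` is `TRUE` and
#'   `records`/`curves` are `NULL`.
#' @export
score_timelapse <- function(tl, thresholds = default_thresholds(),
                            classify = TRUE) {
  thr <- thresholds
  tracks <- link_tracks(tl, iou_min = thr$iou_min,
                        fragment_overlap_min = thr$fragment_overlap_min)
  fl <- flag_focus_loss(tracks, rel_dev_max = thr$focus_rel_dev_max,
                        max_run = thr$focus_max_run)
  if (fl$excluded) {
    return(structure(
      list(records = NULL, tracks = tracks, curves = NULL,
           flagged_frames = fl$flagged_frames, excluded = TRUE,
           thresholds = thr),
      class = "germ_scoring"))
  }
  tracks <- fl$tracks
  rec <- score_spores(tracks, thr)
  if (classify) rec <- classify_spores(tl, tracks, rec, thr)
  structure(
    list(records = rec, tracks = tracks,
         curves = population_curves(tracks, rec),
         flagged_frames = fl$flagged_frames, excluded = FALSE,
         thresholds = thr),
    class = "germ_scoring")
}

#' @export
print.germ_scoring <- function(x, ...) {
  if (x$excluded) {
    cat("germ_scoring: stack EXCLUDED (focus lost for more than",
        x$thresholds$focus_max_run, "time points)\n")
    return(invisible(x))
  }
  eff <- try(germination_efficiency(x$records), silent = TRUE)
  cat("germ_scoring:", nrow(x$records), "tracks,",
      sum(x$records$is_spore), "spores scored\n")
  if (!inherits(eff, "try-error"))
    cat(sprintf("  germination efficiency: %d/%d = %.3f\n",
                eff$n_germinated, eff$n_scored, eff$efficiency))
  if (length(x$flagged_frames))
    cat("  focus-flagged frames:", paste(x$flagged_frames, collapse = ", "), "\n")
  if (any(!is.na(x$records$phenotype))) {
    pf <- try(phenotype_fractions(x$records), silent = TRUE)
    if (!inherits(pf, "try-error"))
      cat("  phenotypes:", paste(sprintf("%s %.0f%%", pf$phenotype, pf$percent),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}
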