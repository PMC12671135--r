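# Rule-based classification of outgrowth phenotypes. The original study
# classified these by eye; every quantitative rule here (50% area collapse for
# "exploded", 120 degrees separation for "bipolar", AR < 1.6 at division for
# "bubble", outgrowth > 6 um for "elongated") is this package's
# operationalization, validated against the synthetic generator's ground
# truth. All thresholds are configurable via default_thresholds().

#' Phenotype labels
#'
#' The five outgrowth classes plus `not_germinated`. If a spore is both
#' bipolar and elongated it is counted as bipolar (the classification order
#' enforces the tie-break).
#' @return Character vector of the six labels.
#' @export
phenotype_levels <- function() {
  c("normal", "elongated", "bubble", "bipolar", "exploded", "not_germinated")
}

# maximal disc centered on the frame-0 centroid that fits inside the mask:
# the spore body. Everything else is outgrowth.
.fit_body <- function(mask, label, c0_row, c0_col) {
  idx <- which(mask == label)
  if (!length(idx)) stop("measurement error: label ", label, " absent from mask")
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  r0 <- max(min(r) - 2L, 1L); r1 <- min(max(r) + 2L, nr)
  c0_ <- max(min(cc) - 2L, 1L); c1 <- min(max(cc) + 2L, ncol(mask))
  sub <- mask[r0:r1, c0_:c1]
  bg <- which(sub != label)
  br <- (bg - 1L) %% nrow(sub) + r0
  bc <- (bg - 1L) %/% nrow(sub) + c0_
  r_body <- sqrt(min((br - c0_row)^2 + (bc - c0_col)^2))
  dist2 <- (r - c0_row)^2 + (cc - c0_col)^2
  body <- idx[dist2 <= r_body^2 + 1e-9]
  list(body_idx = body, r_body_px = r_body,
       obj_idx = idx, obj_row = r, obj_col = cc)
}

#' Measure outgrowths of one object
#'
#' Fits the spore body as the disc of maximal radius centered on the frame-0
#' centroid that fits inside the mask, takes the remaining object pixels as
#' outgrowth, and summarizes each connected outgrowth component: its length
#' (maximal distance from the body boundary, µm), its direction (unit vector
#' from the body center to the component centroid) and pixel count. Components
#' shorter than `min_len_um` or smaller than `min_px` (rasterization slivers
#' hugging the body boundary) are dropped.
#'
#' @param mask integer label mask at the frame of interest (at or just before
#'   the called division, or the last frame if none).
#' @param label object label in `mask`.
#' @param centroid_row,centroid_col the track's frame-0 centroid (pixels).
#' @param pixel_size_um micrometres per pixel edge.
#' @param min_len_um,min_px outgrowth size floors (defaults 1 µm, 5 px).
#' @return List with `features` (data frame: `n_px, length_um, dir_row,
#'   dir_col`, one row per outgrowth), `n_outgrowths`, `body_idx` (linear
#'   pixel indices of the body), `body_radius_um`.
#' @export
measure_outgrowths <- function(mask, label, centroid_row, centroid_col,
                               pixel_size_um, min_len_um = 1.0, min_px = 5L) {
  fit <- .fit_body(mask, label, centroid_row, centroid_col)
  out <- setdiff(fit$obj_idx, fit$body_idx)
  feats <- data.frame(n_px = integer(), length_um = numeric(),
                      dir_row = numeric(), dir_col = numeric())
  if (length(out)) {
    nr <- nrow(mask)
    r <- (out - 1L) %% nr + 1L
    cc <- (out - 1L) %/% nr + 1L
    r0 <- min(r); c0_ <- min(cc)
    bin <- matrix(0L, max(r) - r0 + 1L, max(cc) - c0_ + 1L)
    bin[cbind(r - r0 + 1L, cc - c0_ + 1L)] <- 1L
    labm <- EBImage::bwlabel(bin)
    comp <- labm[cbind(r - r0 + 1L, cc - c0_ + 1L)]
    for (cid in sort(unique(comp))) {
      sel <- comp == cid
      d <- sqrt((r[sel] - centroid_row)^2 + (cc[sel] - centroid_col)^2)
      len <- (max(d) - fit$r_body_px) * pixel_size_um
      v <- c(mean(r[sel]) - centroid_row, mean(cc[sel]) - centroid_col)
      v <- v / sqrt(sum(v^2))
      feats <- rbind(feats, data.frame(n_px = sum(sel), length_um = len,
                                       dir_row = v[1L], dir_col = v[2L]))
    }
    feats <- feats[feats$length_um >= min_len_um & feats$n_px >= min_px, ,
                   drop = FALSE]
    rownames(feats) <- NULL
  }
  list(features = feats, n_outgrowths = nrow(feats),
       body_idx = fit$body_idx,
       body_radius_um = fit$r_body_px * pixel_size_um)
}

# largest pairwise angle (degrees) between outgrowth direction vectors
.max_pair_angle <- function(feats) {
  n <- nrow(feats)
  if (n < 2L) return(0)
  best <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    dot <- feats$dir_row[i] * feats$dir_row[j] +
      feats$dir_col[i] * feats$dir_col[j]
    best <- max(best, acos(pmin(pmax(dot, -1), 1)) * 180 / pi)
  }
  best
}

#' Classify outgrowth phenotypes of scored spores
#'
#' Applies the decision rules, in order, to every scored spore:
#' \enumerate{
#'   \item \strong{exploded} — the track's area collapses by more than
#'     `exploded_collapse_frac` within two frames and the object disappears or
#'     fragments into more than two pieces (spores that disintegrate during
#'     germination);
#'   \item \strong{bipolar} — at least two outgrowths with directions
#'     separated by more than `bipolar_min_angle_deg` (growth from both ends);
#'     a spore that is both bipolar and elongated counts as bipolar;
#'   \item \strong{bubble} — a division event (mask split) while the cell is
#'     still circular, AR at division below `bubble_ar_max`;
#'   \item \strong{elongated} — maximal outgrowth length strictly above
#'     `elongated_min_um` (6 µm; normal outgrowths are ~4.5 µm);
#'   \item \strong{normal} — any other completed germination attempt.
#' }
#' Spores with no division event and no explosion are `not_germinated`.
#' Outgrowth features are measured at the called division frame, or just
#' before the mask split, or at the last frame.
#'
#' @param tl the [time_lapse()] (masks are needed for outgrowth geometry).
#' @param tracks a `track_set`.
#' @param records spore records from [score_spores()].
#' @param thresholds a [default_thresholds()] list.
#' @return `records` with the `phenotype` column filled for scored spores.
#' @export
classify_spores <- function(tl, tracks, records,
                            thresholds = default_thresholds()) {
  thr <- thresholds
  m <- tracks$measures
  ts <- track_summary(tracks)
  nK <- tracks$n_frames
  for (i in which(records$is_spore)) {
    tid <- records$track_id[i]
    d <- m[m$track_id == tid, , drop = FALSE]
    s <- ts[ts$track_id == tid, ]
    a <- d$area_um2
    n <- nrow(d)
    collapse <- FALSE
    if (n >= 2L)
      collapse <- any(a[-1L] / a[-n] < thr$exploded_collapse_frac, na.rm = TRUE)
    if (!collapse && n >= 3L)
      collapse <- any(a[-(1:2)] / a[1:(n - 2L)] < thr$exploded_collapse_frac,
                      na.rm = TRUE)
    disappears <- s$last_frame < nK - 1L
    has_split <- !is.na(s$split_frame)
    frag_gt2 <- has_split && s$split_fragments > 2L
    germinated <- records$germinated[i]

    if (collapse && (disappears || frag_gt2)) {
      records$phenotype[i] <- "exploded"
      next
    }
    if (!germinated && !has_split) {
      records$phenotype[i] <- "not_germinated"
      next
    }
    meas_frame <- if (germinated) records$division_frame[i]
                  else s$split_frame - 1L
    row <- d[d$frame == meas_frame, , drop = FALSE]
    if (!nrow(row)) row <- d[which.max(d$frame[d$frame < meas_frame]), , drop = FALSE]
    og <- measure_outgrowths(
      tl$frames[[row$frame + 1L]], row$label,
      d$centroid_row[1L], d$centroid_col[1L], tl$pixel_size_um,
      min_len_um = thr$outgrowth_min_len_um, min_px = thr$outgrowth_min_px)
    ar_div <- row$aspect_ratio
    records$phenotype[i] <-
      if (og$n_outgrowths >= 2L &&
          .max_pair_angle(og$features) > thr$bipolar_min_angle_deg) {
        "bipolar"
      } else if (has_split && ar_div < thr$bubble_ar_max && !germinated) {
        "bubble"
      } else if (og$n_outgrowths >= 1L &&
                 max(og$features$length_um) > thr$elongated_min_um) {
        "elongated"
      } else {
        "normal"
      }
  }
  records
}

#' Phenotype counts and percentages among germination attempts
#'
#' Attempts are spores whose phenotype is one of the five outgrowth classes
#' (completed divisions, circular "bubble" splits, and explosions);
#' `not_germinated` spores are excluded. Percentages sum to 100; raw counts
#' are retained for Fisher tests between conditions.
#'
#' @param records classified spore records.
#' @param warn_n warn when the number of attempts is at or below this floor
#'   (default 50, the study's per-sample minimum).
#' @return Data frame `phenotype, count, percent` (five rows, fixed order),
#'   with attribute `n_attempts`.
#' @export
phenotype_fractions <- function(records, warn_n = 50L) {
  lv <- setdiff(phenotype_levels(), "not_germinated")
  ph <- records$phenotype[records$is_spore & !is.na(records$phenotype)]
  ph <- ph[ph %in% lv]
  if (!length(ph)) stop("undefined: no germination attempts to tally")
  if (length(ph) <= warn_n)
    warning("only ", length(ph), " outgrowths scored (recommended > ", warn_n, ")")
  cnt <- table(factor(ph, levels = lv))
  out <- data.frame(phenotype = lv, count = as.integer(cnt),
                    percent = 100 * as.integer(cnt) / length(ph))
  attr(out, "n_attempts") <- length(ph)
  out
}
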