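# Equivalent-ellipse morphometry and frame-to-frame tracking of label masks.
#
# Moments treat each pixel as a unit square (covariance of pixel centers plus
# 1/12 per axis), so the ellipse axes of a solid axis-aligned rectangle scale
# exactly with its sides and a single pixel has AR = 1.

.moments_from_sums <- function(n, sr, sc, srr, scc, src, pixel_size_um) {
  mr <- sr / n
  mc <- sc / n
  vrr <- srr / n - mr^2 + 1 / 12
  vcc <- scc / n - mc^2 + 1 / 12
  vrc <- src / n - mr * mc
  disc <- sqrt(((vrr - vcc) / 2)^2 + vrc^2)
  l1 <- pmax((vrr + vcc) / 2 + disc, 1e-12)
  l2 <- pmax((vrr + vcc) / 2 - disc, 1e-12)
  data.frame(
    pixel_count   = n,
    area_um2      = n * pixel_size_um^2,
    aspect_ratio  = sqrt(l1 / l2),
    major_axis_um = 4 * sqrt(l1) * pixel_size_um,
    minor_axis_um = 4 * sqrt(l2) * pixel_size_um,
    centroid_row  = mr,
    centroid_col  = mc)
}

#' Measure every object in one label mask
#'
#' @param mask integer label matrix (0 = background).
#' @param pixel_size_um micrometres per pixel edge.
#' @return Data frame with one row per label: `label, pixel_count, area_um2,
#'   aspect_ratio, major_axis_um, minor_axis_um, centroid_row, centroid_col`.
#'   Centroids are in (real-valued) pixel coordinates; everything else is in
#'   physical units.
#' @seealso [measure_object()] for a single label.
#' @export
measure_frame <- function(mask, pixel_size_um) {
  if (pixel_size_um <= 0) stop("calibration error: `pixel_size_um` must be positive")
  idx <- which(mask > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), pixel_count = numeric(),
                      area_um2 = numeric(), aspect_ratio = numeric(),
                      major_axis_um = numeric(), minor_axis_um = numeric(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  lab <- mask[idx]
  nr <- nrow(mask)
  r <- as.numeric((idx - 1L) %% nr + 1L)
  cc <- as.numeric((idx - 1L) %/% nr + 1L)
  S <- rowsum(cbind(1, r, cc, r * r, cc * cc, r * cc), lab)
  out <- .moments_from_sums(S[, 1L], S[, 2L], S[, 3L], S[, 4L], S[, 5L],
                            S[, 6L], pixel_size_um)
  cbind(data.frame(label = as.integer(rownames(S))), out)
}

#' Measure one object with an equivalent second-moment ellipse
#'
#' Fits the ellipse having the same normalized second central moments as the
#' object's pixel set. The aspect ratio (AR) is the ratio of the long to the
#' short axis of that ellipse; AR = 1 is a circle. A single-pixel object has
#' AR exactly 1 (degenerate moments).
#'
#' @inheritParams measure_frame
#' @param label positive integer label present in `mask`.
#' @return A one-row data frame as in [measure_frame()] (without `label`).
#' @examples
#' m <- matrix(0L, 40, 40); m[11:20, 6:35] <- 1L  # 10 x 30 rectangle
#' measure_object(m, 1L, 0.1)$aspect_ratio        # exactly 3
#' @export
measure_object <- function(mask, label, pixel_size_um) {
  fm <- measure_frame(mask, pixel_size_um)
  row <- fm[fm$label == label, , drop = FALSE]
  if (!nrow(row)) stop("label ", label, " not found in mask")
  row$label <- NULL
  rownames(row) <- NULL
  row
}

.empty_events <- function() {
  data.frame(track_id = integer(), frame = integer(), n_fragments = integer())
}

#' Link objects across frames into tracks
#'
#' Greedy one-to-one matching between consecutive frames by maximal
#' intersection-over-union (IoU) of pixel overlap; matches with IoU below
#' `iou_min` are rejected and unmatched objects start new tracks. When one
#' object splits into two or more pieces (a division), the fragment containing
#' the parent's last centroid inherits the track id, the other fragments start
#' new tracks, and a split event (frame, fragment count) is recorded. Spores
#' move little between 10-minute frames, so overlap matching suffices.
#'
#' @param tl a [time_lapse()].
#' @param iou_min minimum IoU to accept a match (default 0.3).
#' @param fragment_overlap_min minimum fraction of a new object's pixels inside
#'   the parent for it to count as a fragment of a split (default 0.5).
#' @return A `track_set`: list with `measures` (long data frame: `track_id,
#'   frame, time_min, label, pixel_count, area_um2, aspect_ratio,
#'   major_axis_um, minor_axis_um, centroid_row, centroid_col, interpolated`),
#'   `events` (split events: `track_id, frame, n_fragments`), and the
#'   calibration (`pixel_size_um`, `frame_interval_min`, `n_frames`, `dim`).
#' @export
link_tracks <- function(tl, iou_min = 0.3, fragment_overlap_min = 0.5) {
  stopifnot(inherits(tl, "time_lapse"))
  K <- length(tl$frames)
  px <- tl$pixel_size_um
  meas <- lapply(tl$frames, measure_frame, pixel_size_um = px)

  next_id <- 1L
  rows <- vector("list", K)
  events <- list()

  # frame 0: every object starts a track
  m0 <- meas[[1L]]
  trk_of <- integer(0)
  if (nrow(m0)) {
    trk_of <- seq_len(nrow(m0))
    names(trk_of) <- m0$label
    next_id <- nrow(m0) + 1L
    rows[[1L]] <- cbind(data.frame(track_id = unname(trk_of), frame = 0L), m0)
  }

  for (k in 2:K) {
    prev <- tl$frames[[k - 1L]]
    cur  <- tl$frames[[k]]
    mp <- meas[[k - 1L]]
    mc_ <- meas[[k]]
    frame0 <- k - 1L  # 0-based index of `cur`

    cur_track <- integer(nrow(mc_))          # 0 = unassigned
    names(cur_track) <- mc_$label
    prev_done <- logical(nrow(mp))
    names(prev_done) <- mp$label

    idx <- which(prev > 0L & cur > 0L)
    if (length(idx) && nrow(mp) && nrow(mc_)) {
      p <- as.numeric(prev[idx]); cl <- as.numeric(cur[idx])
      base <- max(cl) + 1
      code <- p * base + cl
      agg <- rowsum(rep.int(1, length(code)), code)
      codes <- as.numeric(rownames(agg))
      plab <- floor(codes / base)
      clab <- codes - plab * base
      inter <- agg[, 1L]
      pa <- mp$pixel_count[match(plab, mp$label)]
      ca <- mc_$pixel_count[match(clab, mc_$label)]
      iou <- inter / (pa + ca - inter)
      frac <- inter / ca

      # splits first: a parent with >= 2 substantial fragments
      for (pl in unique(plab)) {
        sel <- which(plab == pl & frac >= fragment_overlap_min)
        if (length(sel) < 2L) next
        tid <- trk_of[as.character(pl)]
        prow <- mp[mp$label == pl, ]
        pr <- as.integer(round(prow$centroid_row))
        pc <- as.integer(round(prow$centroid_col))
        pr <- min(max(pr, 1L), nrow(cur)); pc <- min(max(pc, 1L), ncol(cur))
        frag_labs <- clab[sel]
        keep <- if (cur[pr, pc] %in% frag_labs) {
          cur[pr, pc]
        } else {
          fr <- mc_[match(frag_labs, mc_$label), ]
          frag_labs[which.min((fr$centroid_row - prow$centroid_row)^2 +
                              (fr$centroid_col - prow$centroid_col)^2)]
        }
        cur_track[as.character(keep)] <- tid
        for (fl in setdiff(frag_labs, keep)) {
          cur_track[as.character(fl)] <- next_id
          next_id <- next_id + 1L
        }
        prev_done[as.character(pl)] <- TRUE
        events[[length(events) + 1L]] <-
          data.frame(track_id = tid, frame = frame0,
                     n_fragments = length(sel))
      }

      # greedy one-to-one IoU matching for the rest
      ord <- order(-iou)
      for (i in ord) {
        if (iou[i] < iou_min) break
        pl <- as.character(plab[i]); cl2 <- as.character(clab[i])
        if (prev_done[pl] || cur_track[cl2] != 0L) next
        cur_track[cl2] <- trk_of[pl]
        prev_done[pl] <- TRUE
      }
    }

    # remaining objects in `cur` start new tracks
    un <- which(cur_track == 0L)
    if (length(un)) {
      cur_track[un] <- seq.int(next_id, length.out = length(un))
      next_id <- next_id + length(un)
    }
    if (nrow(mc_))
      rows[[k]] <- cbind(data.frame(track_id = unname(cur_track), frame = frame0), mc_)
    trk_of <- cur_track
  }

  measures <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(measures)) {
    measures <- cbind(data.frame(track_id = integer(), frame = integer()),
                      measure_frame(matrix(0L, 1, 1), px))
  }
  measures$time_min <- measures$frame * tl$frame_interval_min
  measures$interpolated <- FALSE
  measures <- measures[order(measures$track_id, measures$frame), ]
  rownames(measures) <- NULL
  ev <- if (length(events)) do.call(rbind, events) else .empty_events()
  structure(
    list(measures = measures, events = ev, pixel_size_um = px,
         frame_interval_min = tl$frame_interval_min, n_frames = K,
         dim = dim(tl$frames[[1L]])),
    class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks over %d frames (%d split events)\n",
              length(unique(x$measures$track_id)), x$n_frames, nrow(x$events)))
  invisible(x)
}

#' Per-track summary
#'
#' @param tracks a `track_set`.
#' @return Data frame with one row per track: `track_id, first_frame,
#'   last_frame, n_obs, starting_area_um2, starting_ar`, plus the first split
#'   event (`split_frame`, `split_fragments`, `NA` if none).
#' @export
track_summary <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  m <- tracks$measures
  sp <- split(seq_len(nrow(m)), m$track_id)
  out <- data.frame(
    track_id = as.integer(names(sp)),
    first_frame = vapply(sp, function(i) min(m$frame[i]), 0),
    last_frame = vapply(sp, function(i) max(m$frame[i]), 0),
    n_obs = lengths(sp))
  first_i <- vapply(sp, function(i) i[which.min(m$frame[i])], 0L)
  out$starting_area_um2 <- m$area_um2[first_i]
  out$starting_ar <- m$aspect_ratio[first_i]
  ev <- tracks$events
  if (nrow(ev)) {
    ev <- ev[order(ev$track_id, ev$frame), ]
    ev <- ev[!duplicated(ev$track_id), ]
    j <- match(out$track_id, ev$track_id)
    out$split_frame <- ev$frame[j]
    out$split_fragments <- ev$n_fragments[j]
  } else {
    out$split_frame <- NA_integer_
    out$split_fragments <- NA_integer_
  }
  rownames(out) <- NULL
  out
}

#' Flag and repair transient focus loss
#'
#' A focus failure makes every object's apparent area dip or spike in the
#' same frame, so detection uses a population statistic — the *median* over
#' tracks of each frame's relative area deviation — which is robust to
#' single-cell events such as explosions or divisions. Two tests are applied:
#'
#' * **Exclusion test (long outages).** Each frame is compared against the
#'   midpoint of its track's areas `max_run + 1` frames away on either side
#'   (anchors that a tolerable outage cannot contaminate on both sides at
#'   once). If the frames whose median relative deviation exceeds
#'   `rel_dev_max` form a run longer than `max_run`, focus was lost for too
#'   many consecutive time points and the whole stack is excluded.
#' * **Spike test (repairable glitches).** Each frame is compared against a
#'   per-track running median over the surrounding `2 (max_run + 1)` frames
#'   (excluding the frame itself), which is immune to outages of up to
#'   `max_run + 1` frames. Frames whose median relative deviation exceeds
#'   `rel_dev_max` are flagged, repaired by per-track linear interpolation
#'   between the nearest unflagged frames, and recorded as gaps
#'   (`interpolated = TRUE`).
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param rel_dev_max median relative deviation threshold (default 0.3).
#' @param max_run longest tolerated run of consecutive flagged frames
#'   (default 5; more than five lost time points excludes the stack).
#' @return List with `tracks` (repaired `track_set`), `flagged_frames`
#'   (0-based frame indices) and `excluded` (logical).
#' @export
flag_focus_loss <- function(tracks, rel_dev_max = 0.3, max_run = 5L) {
  stopifnot(inherits(tracks, "track_set"))
  m <- tracks$measures
  K <- tracks$n_frames
  ids <- sort(unique(m$track_id))
  if (!length(ids) || K < 3L)
    return(list(tracks = tracks, flagged_frames = integer(), excluded = FALSE))

  A <- matrix(NA_real_, length(ids), K)
  A[cbind(match(m$track_id, ids), m$frame + 1L)] <- m$area_um2
  h <- max_run + 1L
  med_dev <- function(dev) {
    if (all(is.na(dev))) NA_real_ else median(dev, na.rm = TRUE)
  }

  # exclusion test: anchors h frames away cannot both sit inside a tolerable
  # outage, so a sustained level shift longer than max_run stands out
  shift_dev <- rep(NA_real_, K)
  for (j in seq_len(K)) {
    l <- j - h; r <- j + h
    base <- if (l >= 1L && r <= K) (A[, l] + A[, r]) / 2
            else if (l >= 1L) A[, l]
            else if (r <= K) A[, r]
            else next
    shift_dev[j] <- med_dev(abs(A[, j] - base) / base)
  }
  over <- !is.na(shift_dev) & shift_dev > rel_dev_max
  runs <- rle(over)
  if (any(runs$values & runs$lengths > max_run))
    return(list(tracks = tracks, flagged_frames = integer(),
                excluded = TRUE))

  # spike test: per-track running median excluding the frame itself
  flagged <- logical(K)
  for (j in seq_len(K)) {
    w <- setdiff(max(1L, j - h):min(K, j + h), j)
    base <- apply(A[, w, drop = FALSE], 1L, median, na.rm = TRUE)
    D <- med_dev(abs(A[, j] - base) / base)
    flagged[j] <- !is.na(D) && D > rel_dev_max
  }
  flagged_frames <- which(flagged) - 1L
  if (!length(flagged_frames))
    return(list(tracks = tracks, flagged_frames = flagged_frames,
                excluded = FALSE))

  # repair: per-track linear interpolation across flagged frames
  cols <- c("area_um2", "aspect_ratio", "major_axis_um", "minor_axis_um",
            "centroid_row", "centroid_col")
  good <- which(!flagged)
  for (tid in ids) {
    ri <- which(m$track_id == tid)
    fr <- m$frame[ri] + 1L
    bad <- ri[fr %in% (flagged_frames + 1L)]
    for (b in bad) {
      j <- m$frame[b] + 1L
      gl <- intersect(good[good < j], fr)
      gr <- intersect(good[good > j], fr)
      if (!length(gl) || !length(gr)) next
      l <- max(gl); r <- min(gr)
      il <- ri[match(l, fr)]; ir <- ri[match(r, fr)]
      w <- (j - l) / (r - l)
      for (cn in cols)
        m[b, cn] <- m[il, cn] * (1 - w) + m[ir, cn] * w
      m$interpolated[b] <- TRUE
    }
  }
  tracks$measures <- m
  list(tracks = tracks, flagged_frames = flagged_frames, excluded = FALSE)
}
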