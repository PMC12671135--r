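#' Construct a time-lapse of label masks
#'
#' Bundles an ordered sequence of integer label masks with its physical
#' calibration. A label mask is a 2-D integer matrix where 0 is background and
#' each positive value is one connected object; labels are *not* assumed
#' stable across frames (tracking assigns identity, see [link_tracks()]).
#' The time of frame `k` is `k * frame_interval_min` with `k` 0-based, so
#' "time point zero" is the first frame.
#'
#' @param frames list of integer matrices, all with identical dimensions.
#' @param frame_interval_min positive scalar, minutes between frames.
#' @param pixel_size_um positive scalar, micrometres per pixel edge.
#' @param fluorescence optional list of numeric matrices (same length and
#'   shape as `frames`), e.g. an FM4-64 channel.
#' @param metadata free-form named list (sample id, storage condition, ...).
#'
#' @return An object of class `time_lapse`.
#' @examples
#' m <- matrix(0L, 16, 16); m[6:10, 6:10] <- 1L
#' tl <- time_lapse(list(m, m), frame_interval_min = 10, pixel_size_um = 0.2)
#' tl
#' @export
time_lapse <- function(frames, frame_interval_min, pixel_size_um,
                       fluorescence = NULL, metadata = list()) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("`frames` must be a list of at least two label masks")
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
      frame_interval_min <= 0)
    stop("`frame_interval_min` must be a positive scalar (minutes)")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("calibration error: `pixel_size_um` must be a positive scalar")
  dims <- dim(frames[[1L]])
  if (is.null(dims) || length(dims) != 2L)
    stop("each frame must be a 2-D matrix")
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!identical(dim(f), dims))
      stop("structural error: frame ", i, " has a different shape")
    if (anyNA(f) || any(f < 0))
      stop("label masks must be nonnegative integers without NA")
    if (!is.integer(f)) frames[[i]] <- matrix(as.integer(f), dims[1L], dims[2L])
  }
  if (!is.null(fluorescence)) {
    if (!is.list(fluorescence) || length(fluorescence) != length(frames))
      stop("`fluorescence` must match `frames` in length")
    for (f in fluorescence) {
      if (!identical(dim(f), dims))
        stop("structural error: fluorescence frame shape mismatch")
      if (anyNA(f) || any(f < 0))
        stop("fluorescence must be nonnegative and free of NA")
    }
  }
  structure(
    list(frames = frames,
         frame_interval_min = as.numeric(frame_interval_min),
         pixel_size_um = as.numeric(pixel_size_um),
         fluorescence = fluorescence,
         metadata = metadata),
    class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf(
    "time_lapse: %d frames of %d x %d px (%.3g um/px), every %g min (%g min total)\n",
    length(x$frames), d[1L], d[2L], x$pixel_size_um, x$frame_interval_min,
    (length(x$frames) - 1L) * x$frame_interval_min))
  if (!is.null(x$fluorescence)) cat("  with paired fluorescence channel\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a time-lapse
#' @param tl a [time_lapse()].
#' @return Integer frame count.
#' @export
n_frames <- function(tl) length(tl$frames)

#' Frame times in minutes
#' @param tl a [time_lapse()].
#' @return Numeric vector, `(0:(n-1)) * frame_interval_min`.
#' @export
frame_times <- function(tl) (seq_along(tl$frames) - 1) * tl$frame_interval_min

#' Convert a pixel count to a physical area
#'
#' @param pixel_count nonnegative integer(s), number of pixels in an object.
#' @param pixel_size_um positive scalar, micrometres per pixel edge.
#' @return Area(s) in square micrometres: `pixel_count * pixel_size_um^2`.
#' @examples
#' to_physical(100, 0.1)  # 1 um^2
#' @export
to_physical <- function(pixel_count, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("calibration error: `pixel_size_um` must be positive")
  if (any(pixel_count < 0)) stop("`pixel_count` must be nonnegative")
  pixel_count * pixel_size_um^2
}

#' Default analysis thresholds
#'
#' One place for every tunable cut-off of the scoring pipeline. The spore
#' selection and division thresholds follow the published aspect-ratio rules
#' (round spores have AR < 1.4 at the first frame; the first division is the
#' first frame with AR > 3); the remaining values parameterize steps that the
#' original study performed by eye and that this package algorithmizes.
#'
#' @return Named list of thresholds:
#' \describe{
#'   \item{ar_spore_max}{spores must have AR strictly below this at frame 0 (1.4).}
#'   \item{min_spore_area_um2}{starting-area floor excluding small round debris
#'     (3 µm²; real spores are ~7–9 µm²). Set to 0 to disable.}
#'   \item{ar_division}{strict AR threshold calling the first division (3.0).}
#'   \item{iou_min}{minimum intersection-over-union accepting a frame-to-frame
#'     match during tracking (0.3).}
#'   \item{fragment_overlap_min}{fraction of a new object's pixels that must lie
#'     inside the parent for it to count as a division/fragmentation product (0.5).}
#'   \item{focus_rel_dev_max}{median relative area deviation above which a frame
#'     is flagged as a focus failure (0.3).}
#'   \item{focus_max_run}{longest tolerated run of flagged frames; more than
#'     this many consecutive flagged frames excludes the stack (5).}
#'   \item{swell_smooth_frames}{centered moving-average width for swelling
#'     detection (5, odd).}
#'   \item{swell_area_slope_min}{minimum area slope as a fraction of starting
#'     area per frame (0.005).}
#'   \item{swell_ar_slope_max}{maximum AR slope per frame during swelling (0.005).}
#'   \item{elongated_min_um}{outgrowths strictly longer than this are
#'     "elongated" (6 µm).}
#'   \item{bipolar_min_angle_deg}{minimum angular separation between outgrowth
#'     directions for "bipolar" (120).}
#'   \item{bubble_ar_max}{AR at division below which a mask split is a
#'     "bubble" division (1.6).}
#'   \item{exploded_collapse_frac}{area collapse fraction within two frames
#'     marking an explosion (0.5).}
#'   \item{outgrowth_min_len_um, outgrowth_min_px}{size floors for counting an
#'     outgrowth component (suppress rasterization slivers).}
#' }
#' @export
default_thresholds <- function() {
  list(
    ar_spore_max          = 1.4,
    min_spore_area_um2    = 3,
    ar_division           = 3.0,
    iou_min               = 0.3,
    fragment_overlap_min  = 0.5,
    focus_rel_dev_max     = 0.3,
    focus_max_run         = 5L,
    swell_smooth_frames   = 5L,
    swell_area_slope_min  = 0.005,
    swell_ar_slope_max    = 0.005,
    elongated_min_um      = 6,
    bipolar_min_angle_deg = 120,
    bubble_ar_max         = 1.6,
    exploded_collapse_frac = 0.5,
    outgrowth_min_len_um  = 1.0,
    outgrowth_min_px      = 5L
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration holding the physical calibration and any
#' threshold overrides, and merges it over [default_thresholds()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. Recognized top-level
#'   keys: `pixel_size_um`, `frame_interval_min`, `seed`, and `thresholds`
#'   (a mapping of [default_thresholds()] names).
#' @return A list with elements `pixel_size_um`, `frame_interval_min`, `seed`
#'   (possibly `NULL`) and `thresholds` (complete list).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml or .json file: ", path)
  thr <- default_thresholds()
  if (!is.null(cfg$thresholds)) {
    unknown <- setdiff(names(cfg$thresholds), names(thr))
    if (length(unknown))
      stop("unknown threshold name(s): ", paste(unknown, collapse = ", "))
    thr[names(cfg$thresholds)] <- cfg$thresholds
  }
  list(pixel_size_um = cfg$pixel_size_um,
       frame_interval_min = cfg$frame_interval_min,
       seed = cfg$seed,
       thresholds = thr)
}
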