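#' Write a time-lapse to multi-page TIFF
#'
#' Label masks are stored as 16-bit pages (values `mask/65535`), so label ids
#' up to 65535 round-trip exactly. The optional fluorescence channel is stored
#' as 32-bit float pages scaled by `fluor_scale`.
#'
#' @param tl a [time_lapse()].
#' @param mask_path output path for the mask stack (`.tif`).
#' @param fluor_path optional output path for the fluorescence stack.
#' @param fluor_scale divisor applied to fluorescence intensities before
#'   writing (TIFF float pages hold values in \[0, 1\]).
#' @return Invisibly, the mask path.
#' @seealso [read_timelapse_tiff()]
#' @export
write_timelapse_tiff <- function(tl, mask_path, fluor_path = NULL,
                                 fluor_scale = 65535) {
  stopifnot(inherits(tl, "time_lapse"))
  if (any(vapply(tl$frames, max, 0) > 65535))
    stop("label ids above 65535 cannot be stored in 16-bit TIFF")
  pages <- lapply(tl$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, mask_path, bits.per.sample = 16L, reduce = FALSE)
  if (!is.null(fluor_path)) {
    if (is.null(tl$fluorescence)) stop("time-lapse has no fluorescence channel")
    fp <- lapply(tl$fluorescence, function(f) pmin(pmax(f / fluor_scale, 0), 1))
    tiff::writeTIFF(fp, fluor_path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(mask_path)
}

#' Read a time-lapse from multi-page TIFF
#'
#' Inverse of [write_timelapse_tiff()]. The physical calibration is not stored
#' in the TIFF and must be supplied (the pixel size of the original microscopy
#' is a required user input).
#'
#' @param mask_path path to a multi-page mask TIFF written by
#'   [write_timelapse_tiff()] (or any 8/16-bit label stack).
#' @param pixel_size_um,frame_interval_min physical calibration, see
#'   [time_lapse()].
#' @param fluor_path optional fluorescence stack path.
#' @param fluor_scale scale used when the fluorescence stack was written.
#' @param metadata free-form named list.
#' @return A [time_lapse()].
#' @export
read_timelapse_tiff <- function(mask_path, pixel_size_um, frame_interval_min,
                                fluor_path = NULL, fluor_scale = 65535,
                                metadata = list()) {
  pages <- tiff::readTIFF(mask_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
  fluor <- NULL
  if (!is.null(fluor_path)) {
    fp <- tiff::readTIFF(fluor_path, all = TRUE)
    if (!is.list(fp)) fp <- list(fp)
    fluor <- lapply(fp, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      p * fluor_scale
    })
  }
  time_lapse(frames, frame_interval_min, pixel_size_um,
             fluorescence = fluor, metadata = metadata)
}

#' Read a colony-forming-unit (CFU) longevity table
#'
#' Expected CSV columns: `condition` (e.g. storage temperature / medium key),
#' `day` (nonnegative storage day), `replicate`, `dilution` (plated dilution
#' factor, e.g. 1e-3), `count` (colonies on the plate).
#'
#' @param path CSV path.
#' @return A data frame with the columns above, checked for schema and types.
#' @seealso [cfu_viability()]
#' @export
read_cfu_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "day", "replicate", "dilution", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CFU table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("`count` must be nonnegative integers")
  if (any(df$day < 0)) stop("`day` must be nonnegative")
  if (any(df$dilution <= 0)) stop("`dilution` must be positive")
  df[need]
}

#' Per-replicate normalized viability from CFU counts
#'
#' Counts are corrected for dilution (`count / dilution`) and each replicate
#' is divided by its own day-0 value, so viability at day 0 is exactly 1 per
#' replicate. Values above 1 at later days are possible (counting noise) and
#' are not clipped. Per-replicate normalization preserves replicate
#' independence for the downstream AUC t-test.
#'
#' @param cfu a data frame as returned by [read_cfu_csv()].
#' @return A data frame `condition, replicate, day, viability`, ordered by
#'   condition, replicate, day.
#' @export
cfu_viability <- function(cfu) {
  key <- interaction(cfu$condition, cfu$replicate, drop = TRUE)
  out <- lapply(split(cfu, key), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    if (anyDuplicated(d$day)) stop("duplicate days within a replicate")
    if (d$day[1L] != 0) stop("day 0 must be present for every replicate")
    corrected <- d$count / d$dilution
    if (corrected[1L] <= 0) stop("day-0 count must be positive to normalize")
    data.frame(condition = d$condition, replicate = d$replicate,
               day = d$day, viability = corrected / corrected[1L])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate, out$day), , drop = FALSE]
}

#' Read an acute-stress assay table
#'
#' Expected CSV columns: `sample`, `stressor` (`"UV"` or `"heat"`),
#' `replicate`, `cfu_untreated`, `cfu_treated`.
#'
#' @param path CSV path.
#' @return Schema-checked data frame.
#' @seealso [stress_survival()]
#' @export
read_stress_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "stressor", "replicate", "cfu_untreated", "cfu_treated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("stress table missing column(s): ", paste(miss, collapse = ", "))
  counts <- c(df$cfu_untreated, df$cfu_treated)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("CFU counts must be nonnegative integers")
  df[need]
}

# fixed-format number rendering so that re-running a pipeline on identical
# inputs yields byte-identical CSV output
.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
}

.write_fixed_csv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], .fmt_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export tracked morphometry to CSV
#'
#' Writes one row per track and frame with physical-unit measures
#' (`track_id, frame, time_min, area_um2, aspect_ratio, centroid_row,
#' centroid_col, interpolated`). Numbers use a fixed format so identical
#' inputs give byte-identical files.
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
export_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  m <- tracks$measures
  .write_fixed_csv(m[, c("track_id", "frame", "time_min", "area_um2",
                         "aspect_ratio", "centroid_row", "centroid_col",
                         "interpolated")], path)
}

#' Export spore records to CSV
#'
#' @param records a spore-record data frame (see [score_spores()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
export_records <- function(records, path) {
  cols <- c("track_id", "is_spore", "starting_area_um2", "starting_ar",
            "division_frame", "division_time_min", "germinated",
            "swelling_start_min", "swelling_end_min", "phenotype",
            "excluded", "exclude_reason")
  .write_fixed_csv(records[, intersect(cols, names(records))], path)
}
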