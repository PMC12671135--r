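# Partitioning of vacuole (FM4-64) fluorescence between the spore body and
# the germ-tube outgrowth at the first division.

#' Partition fluorescence between spore body and outgrowth
#'
#' Subtracts the background (median intensity outside all objects) from every
#' in-object pixel, clamping at zero, and returns the fraction of the total
#' remaining object signal that lies inside the spore body. The fraction is
#' invariant to multiplying the frame by a positive constant and to adding a
#' spatially constant offset (the outside median removes it exactly).
#'
#' @param fluor numeric fluorescence matrix, aligned with `mask`.
#' @param mask integer label mask of the same frame.
#' @param label object label.
#' @param body_idx linear pixel indices of the spore body; must be a subset of
#'   the object's pixels (see [measure_outgrowths()]).
#' @return List with `body_fraction` and `outgrowth_fraction`
#'   (`= 1 - body_fraction` exactly), both in \[0, 1\].
#' @export
partition_signal <- function(fluor, mask, label, body_idx) {
  if (!identical(dim(fluor), dim(mask)))
    stop("geometry error: fluorescence frame not aligned with mask")
  obj <- which(mask == label)
  if (!length(obj)) stop("geometry error: label ", label, " absent from mask")
  if (length(setdiff(body_idx, obj)))
    stop("geometry error: body pixels outside the object")
  bg <- median(fluor[mask == 0L])
  vals <- pmax(fluor[obj] - bg, 0)
  total <- sum(vals)
  if (total <= 0)
    stop("undefined fraction: zero total in-object signal after background subtraction")
  bf <- sum(pmax(fluor[body_idx] - bg, 0)) / total
  list(body_fraction = bf, outgrowth_fraction = 1 - bf)
}

#' Vacuole partition for every germinated spore in a time-lapse
#'
#' For each spore that completed the first division, fits the spore body at
#' the division frame (the same maximal-disc geometry used for phenotype
#' classification) and partitions the FM4-64 signal with [partition_signal()].
#'
#' @param tl a [time_lapse()] with a fluorescence channel.
#' @param tracks a `track_set`.
#' @param records scored spore records.
#' @return Data frame `track_id, frame, body_fraction, outgrowth_fraction`
#'   with one row per germinated spore (spores whose partition is undefined,
#'   e.g. no dye signal, are dropped with a warning).
#' @export
vacuole_partition <- function(tl, tracks, records) {
  if (is.null(tl$fluorescence))
    stop("time-lapse has no fluorescence channel")
  m <- tracks$measures
  out <- list()
  for (i in which(records$is_spore & records$germinated)) {
    tid <- records$track_id[i]
    d <- m[m$track_id == tid, , drop = FALSE]
    fr <- records$division_frame[i]
    row <- d[d$frame == fr, , drop = FALSE]
    if (!nrow(row)) next
    mask <- tl$frames[[fr + 1L]]
    og <- measure_outgrowths(mask, row$label, d$centroid_row[1L],
                             d$centroid_col[1L], tl$pixel_size_um)
    ps <- tryCatch(
      partition_signal(tl$fluorescence[[fr + 1L]], mask, row$label, og$body_idx),
      error = function(e) NULL)
    if (is.null(ps)) {
      warning("spore track ", tid, ": undefined vacuole fraction, dropped")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      track_id = tid, frame = fr,
      body_fraction = ps$body_fraction,
      outgrowth_fraction = ps$outgrowth_fraction)
  }
  if (!length(out))
    return(data.frame(track_id = integer(), frame = integer(),
                      body_fraction = numeric(), outgrowth_fraction = numeric()))
  do.call(rbind, out)
}

#' Cohort summary of vacuole asymmetry
#'
#' @param measurements data frame from [vacuole_partition()] (or any data
#'   frame with a `body_fraction` column).
#' @param warn_n warn when fewer than this many spores are measured
#'   (default 30, the study's per-sample minimum).
#' @return List with `mean_body_fraction`, `se` (standard error across
#'   spores), `n`, and the per-spore `fractions`.
#' @export
asymmetry_cohort_summary <- function(measurements, warn_n = 30L) {
  x <- measurements$body_fraction
  if (length(x) < 2L) stop("need at least two measurements")
  if (length(x) <= warn_n)
    warning("only ", length(x), " spores measured (recommended > ", warn_n, ")")
  list(mean_body_fraction = mean(x), se = sd(x) / sqrt(length(x)),
       n = length(x), fractions = x)
}
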