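# Three-step FAIMS preprocessing:
#   (1) combine the positive and negative ion planes into one DF-specific
#       matrix (element-wise maximum by default),
#   (2) optionally subtract a paired environmental blank (processed through
#       the same polarity combination), clamping negatives to zero,
#   (3) crop to the informative CF window and drop the terminal points, then
#       collapse to a separation chromatogram (SC): the maximum over CF at
#       each retained time point.

#' One dispersion-field-specific ion-intensity matrix
#'
#' @param df_voltage dispersion field (45, 55 or 65 V).
#' @param cf_axis CF axis in volts.
#' @param time_axis time axis in seconds.
#' @param intensity CF-by-time matrix in pA.
#' @param provenance one of "raw-combined", "blank-subtracted", "cropped".
#' @param sample_id originating sample.
#' @return a `df_matrix` object.
#' @export
df_matrix <- function(df_voltage, cf_axis, time_axis, intensity,
                      provenance = "raw-combined",
                      sample_id = NA_character_) {
  if (nrow(intensity) != length(cf_axis) ||
      ncol(intensity) != length(time_axis))
    stop("intensity shape inconsistent with axes", call. = FALSE)
  if (any(intensity < 0))
    stop("negative intensity in df_matrix", call. = FALSE)
  structure(list(df_voltage = as.integer(df_voltage),
                 cf_axis = as.numeric(cf_axis),
                 time_axis = as.numeric(time_axis),
                 intensity = intensity, provenance = provenance,
                 sample_id = sample_id),
            class = "df_matrix")
}

#' Combine positive and negative ion planes
#'
#' Element-wise maximum of the two polarity matrices (shape-preserving); a
#' summation mode is available via `rule = "sum"`.
#'
#' @param pos,neg equal-shape CF-by-time matrices.
#' @param rule "max" (default) or "sum".
#' @return combined matrix of the same shape.
#' @export
combine_polarities <- function(pos, neg, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  if (!all(dim(pos) == dim(neg)))
    stop("polarity matrices must have identical shapes", call. = FALSE)
  if (rule == "max") pmax(pos, neg) else pos + neg
}

#' Subtract a paired environmental blank
#'
#' Element-wise subtraction of the blank plane, clamped at zero so the
#' non-negativity invariant required by downstream peak detection holds.
#'
#' @param sample,blank `df_matrix` objects with the same DF voltage and
#'   shape.
#' @return blank-subtracted `df_matrix`.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "df_matrix"), inherits(blank, "df_matrix"))
  if (sample$df_voltage != blank$df_voltage)
    stop(sprintf("cannot subtract DF %d blank from DF %d sample",
                 blank$df_voltage, sample$df_voltage), call. = FALSE)
  if (!all(dim(sample$intensity) == dim(blank$intensity)))
    stop("sample and blank shapes differ", call. = FALSE)
  df_matrix(sample$df_voltage, sample$cf_axis, sample$time_axis,
            pmax(sample$intensity - blank$intensity, 0),
            provenance = "blank-subtracted", sample_id = sample$sample_id)
}

#' Crop a DF matrix to the informative window
#'
#' Retains CF rows whose axis value lies in the closed interval `cf_keep`
#' and drops the last `terminal_points` time columns. With the instrument
#' defaults (512 CF points spanning \[-6, 6\] V, 3460 time points) the
#' default crop of \[-3, 3\] V and 60 terminal points yields a 256 x 3400
#' matrix. The fraction of discarded cells below `baseline_max` is attached
#' as attribute `baseline_fraction` (a diagnostic for how much of the
#' removed region is bare baseline).
#'
#' @param m a `df_matrix`.
#' @param cf_keep closed CF retention interval in volts.
#' @param terminal_points number of trailing time points to drop.
#' @param baseline_max baseline diagnostic threshold in pA.
#' @return cropped `df_matrix`.
#' @export
crop_matrix <- function(m, cf_keep = c(-3, 3), terminal_points = 60L,
                        baseline_max = 0.0104) {
  stopifnot(inherits(m, "df_matrix"))
  if (cf_keep[1] < -6 || cf_keep[2] > 6 || cf_keep[1] > cf_keep[2])
    stop("cf_keep must be an interval within [-6, 6] V", call. = FALSE)
  if (terminal_points >= length(m$time_axis))
    stop("terminal_points must be smaller than the time axis", call. = FALSE)
  keep_rows <- which(m$cf_axis >= cf_keep[1] & m$cf_axis <= cf_keep[2])
  keep_cols <- seq_len(length(m$time_axis) - terminal_points)
  if (!length(keep_rows) || !length(keep_cols))
    stop("crop produced an empty matrix", call. = FALSE)
  n_dropped <- length(m$intensity) - length(keep_rows) * length(keep_cols)
  frac <- if (n_dropped > 0) {
    drop_mask <- matrix(TRUE, nrow(m$intensity), ncol(m$intensity))
    drop_mask[keep_rows, keep_cols] <- FALSE
    mean(m$intensity[drop_mask] < baseline_max)
  } else NA_real_
  out <- df_matrix(m$df_voltage, m$cf_axis[keep_rows],
                   m$time_axis[keep_cols],
                   m$intensity[keep_rows, keep_cols, drop = FALSE],
                   provenance = "cropped", sample_id = m$sample_id)
  attr(out, "baseline_fraction") <- frac
  out
}

#' Collapse a DF matrix to its separation chromatogram
#'
#' The SC value at each time point is the maximum intensity over all
#' retained CF rows at that point.
#'
#' @param m a (typically cropped) `df_matrix`.
#' @return a `separation_chromatogram`: list with `df_voltage`, `time_axis`,
#'   `intensity`, `sample_id`.
#' @export
collapse_to_chromatogram <- function(m) {
  stopifnot(inherits(m, "df_matrix"))
  structure(list(df_voltage = m$df_voltage, time_axis = m$time_axis,
                 intensity = apply(m$intensity, 2, max),
                 sample_id = m$sample_id),
            class = "separation_chromatogram")
}

combined_df_matrices <- function(run, rule = "max") {
  lapply(stats::setNames(c("45", "55", "65"), c("45", "55", "65")),
         function(df)
           df_matrix(as.integer(df), run$cf_axis, run$time_axis,
                     combine_polarities(run$matrices[[df]]$pos,
                                        run$matrices[[df]]$neg, rule = rule),
                     sample_id = run$sample_id))
}

#' Preprocess one run to its three separation chromatograms
#'
#' Per DF setting: combine polarities, optionally subtract the paired blank
#' (processed identically through polarity combination), crop, and collapse.
#'
#' @param run a `faims_run` (breath sample).
#' @param blank the paired blank `faims_run`, required unless `mode` is
#'   "none".
#' @param mode blank-subtraction mode: "none", "room_air" or "air_filter"
#'   (the mode is informational; the blank actually passed is used).
#' @param cf_keep,terminal_points crop parameters, see [crop_matrix()].
#' @param rule polarity combination rule.
#' @return named list of three `separation_chromatogram`s ("45", "55",
#'   "65").
#' @export
preprocess_run <- function(run, blank = NULL,
                           mode = c("none", "room_air", "air_filter"),
                           cf_keep = c(-3, 3), terminal_points = 60L,
                           rule = "max") {
  mode <- match.arg(mode)
  if (mode != "none" && is.null(blank))
    stop(sprintf("blank subtraction mode '%s' requires a blank run", mode),
         call. = FALSE)
  if (mode == "none" && !is.null(blank))
    blank <- NULL
  sample_mats <- combined_df_matrices(run, rule = rule)
  blank_mats <- if (!is.null(blank)) combined_df_matrices(blank, rule = rule)
  lapply(sample_mats, function(m) {
    step <- "combine_polarities"
    tryCatch({
      if (!is.null(blank_mats)) {
        step <- "subtract_blank"
        m <- subtract_blank(m, blank_mats[[as.character(m$df_voltage)]])
      }
      step <- "crop_matrix"
      m <- crop_matrix(m, cf_keep = cf_keep,
                       terminal_points = terminal_points)
      step <- "collapse_to_chromatogram"
      collapse_to_chromatogram(m)
    }, error = function(e)
      stop(sprintf("preprocessing step %s failed for DF %d: %s",
                   step, m$df_voltage, conditionMessage(e)), call. = FALSE))
  })
}
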