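# Molecular features (MF): intensity-thresholded chromatographic peaks on a
# separation chromatogram. An MF is a local maximum strictly above the
# detection threshold (default 0.5 pA, above the 0.391 pA background-air
# maximum), with a retention window extending outward to the first point
# that falls below the threshold or is a local minimum.

#' Detect molecular features on a separation chromatogram
#'
#' Local maxima strictly above `threshold`, at least `min_separation` time
#' points apart (when two candidate maxima are closer, the more intense one
#' wins; ties go to the earlier index). Plateau maxima are assigned to the
#' first plateau index.
#'
#' @param sc a `separation_chromatogram`.
#' @param threshold detection threshold in pA.
#' @param min_separation minimum distance between retained peaks, in time
#'   points.
#' @return data.frame with columns `rt_index` (1-based), `rt_start`,
#'   `rt_end`, `peak_max`, `peak_area`, sorted by `rt_index`. Zero rows when
#'   nothing crosses the threshold.
#' @export
detect_features <- function(sc, threshold = 0.5, min_separation = 5L) {
  stopifnot(inherits(sc, "separation_chromatogram"))
  x <- sc$intensity
  n <- length(x)
  if (n == 0L) stop("empty chromatogram", call. = FALSE)
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  cand <- which(x > threshold & x > left & x >= right)
  if (!length(cand))
    return(data.frame(rt_index = integer(), rt_start = integer(),
                      rt_end = integer(), peak_max = numeric(),
                      peak_area = numeric()))
  # enforce min_separation: greedy by decreasing intensity, earlier index
  # first on ties
  ord <- cand[order(-x[cand], cand)]
  kept <- integer()
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_separation))
      kept <- c(kept, i)
  kept <- sort(kept)
  windows <- t(vapply(kept, function(i)
    feature_window(x, i, threshold), integer(2)))
  out <- data.frame(rt_index = kept, rt_start = windows[, 1],
                    rt_end = windows[, 2], peak_max = x[kept])
  out$peak_area <- vapply(seq_len(nrow(out)), function(r)
    integrate_peak(sc, out[r, ]), 0)
  out
}

# walk outward from peak index i; stop at the first index that is below the
# threshold or a local minimum
feature_window <- function(x, i, threshold) {
  n <- length(x)
  is_stop <- function(j) {
    if (x[j] < threshold) return(TRUE)
    lo <- if (j > 1L) x[j - 1L] else Inf
    hi <- if (j < n) x[j + 1L] else Inf
    x[j] <= lo && x[j] <= hi
  }
  start <- i
  while (start > 1L && !is_stop(start - 1L)) start <- start - 1L
  if (start > 1L) start <- start - 1L
  end <- i
  while (end < n && !is_stop(end + 1L)) end <- end + 1L
  if (end < n) end <- end + 1L
  c(start, end)
}

#' Assign four-character MF identifiers
#'
#' Identifiers encode the DF setting in the first two characters and the
#' retention-order rank (zero-padded) in the last two, e.g. "4501" for the
#' first peak at DF 45 V. Features are sorted by retention index internally.
#'
#' @param features data.frame from [detect_features()].
#' @param df_voltage dispersion field (45, 55 or 65).
#' @return the features with an `id` column, in retention order.
#' @export
assign_feature_ids <- function(features, df_voltage) {
  if (!df_voltage %in% DF_SETTINGS)
    stop("df_voltage must be one of 45, 55, 65", call. = FALSE)
  if (nrow(features) > 99L)
    stop("MF identifier space exhausted: more than 99 features in one DF",
         call. = FALSE)
  features <- features[order(features$rt_index), , drop = FALSE]
  features$id <- sprintf("%d%02d", df_voltage, seq_len(nrow(features)))
  rownames(features) <- NULL
  features
}

#' Integrate a feature's peak area
#'
#' Trapezoidal integral of the chromatogram over the feature's retention
#' window, using the physical time-axis spacing; a single-point window has
#' area zero.
#'
#' @param sc a `separation_chromatogram`.
#' @param feature one feature row (needs `rt_start`, `rt_end`).
#' @return peak area in pA s.
#' @export
integrate_peak <- function(sc, feature) {
  idx <- feature$rt_start:feature$rt_end
  if (length(idx) < 2L) return(0)
  pracma::trapz(sc$time_axis[idx], sc$intensity[idx])
}

#' Match features across samples by retention time
#'
#' Greedy nearest-retention-time matching: samples are scanned in order;
#' each feature joins the existing column whose running mean retention index
#' is nearest and within `rt_tolerance` (one feature per column per sample),
#' otherwise it opens a new column.
#'
#' @param feature_lists named list (by sample id) of feature data.frames
#'   from one DF pipeline.
#' @param rt_tolerance maximum retention-index distance, in time points.
#' @return list with `rt_consensus` (mean retention index per column, in
#'   retention order), `peak_max` and `peak_area` (sample-by-column
#'   matrices, NA where a sample lacks the feature).
#' @export
match_features <- function(feature_lists, rt_tolerance = 10L) {
  cols <- list()  # each: list(rts = numeric(), by_sample = named list)
  for (sid in names(feature_lists)) {
    fl <- feature_lists[[sid]]
    if (!nrow(fl)) next
    fl <- fl[order(fl$rt_index), , drop = FALSE]
    taken <- rep(FALSE, length(cols))
    for (r in seq_len(nrow(fl))) {
      rt <- fl$rt_index[r]
      best <- 0L; best_d <- Inf
      for (ci in seq_along(cols)) {
        if (taken[ci]) next
        d <- abs(mean(cols[[ci]]$rts) - rt)
        if (d <= rt_tolerance && d < best_d) { best <- ci; best_d <- d }
      }
      if (best == 0L) {
        cols[[length(cols) + 1L]] <- list(rts = rt, vals = list())
        taken <- c(taken, TRUE)
        best <- length(cols)
      } else {
        cols[[best]]$rts <- c(cols[[best]]$rts, rt)
        taken[best] <- TRUE
      }
      cols[[best]]$vals[[sid]] <- c(max = fl$peak_max[r],
                                    area = fl$peak_area[r])
    }
  }
  samples <- names(feature_lists)
  k <- length(cols)
  peak_max <- matrix(NA_real_, length(samples), k,
                     dimnames = list(samples, NULL))
  peak_area <- peak_max
  rt_consensus <- vapply(cols, function(cc) mean(cc$rts), 0)
  for (ci in seq_len(k))
    for (sid in names(cols[[ci]]$vals)) {
      peak_max[sid, ci] <- cols[[ci]]$vals[[sid]]["max"]
      peak_area[sid, ci] <- cols[[ci]]$vals[[sid]]["area"]
    }
  ord <- order(rt_consensus)
  list(rt_consensus = rt_consensus[ord],
       peak_max = peak_max[, ord, drop = FALSE],
       peak_area = peak_area[, ord, drop = FALSE])
}

#' Build a subject-level feature table from per-sample chromatograms
#'
#' Detects features on every sample's three separation chromatograms,
#' matches them within each DF, assigns four-character identifiers from the
#' consensus retention order, and averages technical replicates per subject.
#'
#' @param sc_sets named list (by sample id) of per-DF chromatogram lists as
#'   returned by [preprocess_run()].
#' @param manifest cohort manifest rows for those samples (breath rows).
#' @param threshold,min_separation see [detect_features()].
#' @param rt_tolerance see [match_features()].
#' @return a `feature_table`: list with `peak_max`/`peak_area`
#'   (subject-by-MF matrices, replicate-averaged, NA-aware), `features`
#'   (data.frame id, df_voltage, rt_consensus) and `subjects` (data.frame
#'   subject_id, stage, cirrhosis, ncph).
#' @export
build_feature_table <- function(sc_sets, manifest, threshold = 0.5,
                                min_separation = 5L, rt_tolerance = 10L) {
  stopifnot(all(names(sc_sets) %in% manifest$sample_id))
  blocks_max <- list(); blocks_area <- list(); feat_info <- list()
  for (df in c("45", "55", "65")) {
    fl <- lapply(sc_sets, function(s)
      detect_features(s[[df]], threshold = threshold,
                      min_separation = min_separation))
    matched <- match_features(fl, rt_tolerance = rt_tolerance)
    k <- length(matched$rt_consensus)
    ids <- if (k) sprintf("%s%02d", df, seq_len(k)) else character()
    if (k > 99L)
      stop("MF identifier space exhausted in DF ", df, call. = FALSE)
    colnames(matched$peak_max) <- ids
    colnames(matched$peak_area) <- ids
    blocks_max[[df]] <- matched$peak_max
    blocks_area[[df]] <- matched$peak_area
    feat_info[[df]] <- data.frame(id = ids,
                                  df_voltage = as.integer(df),
                                  rt_consensus = matched$rt_consensus,
                                  stringsAsFactors = FALSE)
  }
  sample_max <- do.call(cbind, blocks_max)
  sample_area <- do.call(cbind, blocks_area)
  info <- do.call(rbind, feat_info)
  rownames(info) <- NULL
  # replicate-average per subject
  mrows <- manifest[match(rownames(sample_max), manifest$sample_id), ]
  subj <- unique(mrows[, c("subject_id", "stage", "cirrhosis", "ncph")])
  subj <- subj[order(subj$subject_id), , drop = FALSE]
  rownames(subj) <- NULL
  agg <- function(m) {
    out <- matrix(NA_real_, nrow(subj), ncol(m),
                  dimnames = list(subj$subject_id, colnames(m)))
    for (i in seq_len(nrow(subj))) {
      rows <- which(mrows$subject_id == subj$subject_id[i])
      v <- m[rows, , drop = FALSE]
      out[i, ] <- colMeans(v, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  structure(list(peak_max = agg(sample_max), peak_area = agg(sample_area),
                 features = info, subjects = subj),
            class = "feature_table")
}

#' Area under the ROC curve for one feature
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' exceeds a random negative, ties counted one half.
#'
#' @param values numeric scores; NA pairs are dropped.
#' @param labels logical or 0/1 class labels (TRUE/1 = positive).
#' @return AUC in \[0, 1\].
#' @export
feature_auc <- function(values, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("feature_auc() requires both classes", call. = FALSE)
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group comparison statistics per molecular feature
#'
#' For each MF and value layer (peak max and peak area): group means,
#' percent difference relative to the control mean, a one-tailed Welch
#' t-test p-value (alternative: disease greater than control by default),
#' the feature's AUC, and whether the per-stage means increase strictly
#' from stage 0 to 3.
#'
#' @param table a `feature_table`.
#' @param control_stages stages forming the control group (default stage 0).
#' @param direction "greater" tests disease > control, "less" the reverse.
#' @return data.frame (class `mf_stats`) with one row per (id, layer).
#' @export
compare_groups <- function(table, control_stages = 0L,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "feature_table"))
  is_control <- table$subjects$stage %in% control_stages
  if (!any(is_control) || all(is_control))
    stop("both groups must be non-empty", call. = FALSE)
  stages <- table$subjects$stage
  rows <- list()
  for (layer in c("peak_max", "peak_area")) {
    m <- table[[layer]]
    for (id in colnames(m)) {
      v <- m[, id]
      ctrl <- v[is_control & !is.na(v)]
      dis <- v[!is_control & !is.na(v)]
      mean_c <- mean(ctrl); mean_d <- mean(dis)
      pct <- if (mean_c != 0) abs(mean_d - mean_c) / mean_c * 100 else NA_real_
      p <- one_tailed_welch(dis, ctrl, direction)
      auc <- feature_auc(v, !is_control)
      stage_means <- vapply(0:3, function(s) {
        vv <- v[stages == s & !is.na(v)]
        if (length(vv)) mean(vv) else NA_real_
      }, 0)
      trend <- !anyNA(stage_means) && all(diff(stage_means) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, layer = layer, mean_control = mean_c, mean_disease = mean_d,
        pct_diff = pct, p_value = p, auc = auc, stage_trend = trend,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mf_stats", class(out))
  out
}

# Welch two-sample one-tailed t-test; degenerate zero-variance cases follow
# the direction of the mean difference, p = 0.5 when the means are equal
one_tailed_welch <- function(disease, control, direction = "greater") {
  if (length(disease) < 2L || length(control) < 2L ||
      (stats::sd(disease) == 0 && stats::sd(control) == 0)) {
    dd <- mean(disease) - mean(control)
    if (dd == 0) return(0.5)
    hit <- (direction == "greater") == (dd > 0)
    return(if (hit) .Machine$double.eps else 1)
  }
  stats::t.test(disease, control, alternative = direction,
                var.equal = FALSE)$p.value
}

#' Select candidate biomarker features
#'
#' Applies the percent-difference, p-value, AUC and (optionally) stage-trend
#' filters to group-comparison statistics for one value layer.
#'
#' @param stats an `mf_stats` data.frame from [compare_groups()].
#' @param layer "peak_max" or "peak_area".
#' @param min_pct minimum percent difference between groups.
#' @param max_p maximum one-tailed p-value.
#' @param min_auc minimum AUC (set to 0 to disable).
#' @param require_stage_trend keep only features whose stage means increase
#'   strictly from stage 0 to 3.
#' @return character vector of selected MF ids, ordered by decreasing AUC.
#' @export
select_candidates <- function(stats, layer = "peak_max", min_pct = 30,
                              max_p = 0.05, min_auc = 0.7,
                              require_stage_trend = FALSE) {
  s <- stats[stats$layer == layer, , drop = FALSE]
  keep <- !is.na(s$pct_diff) & s$pct_diff > min_pct & s$p_value < max_p &
    s$auc > min_auc
  if (require_stage_trend) keep <- keep & s$stage_trend
  s <- s[keep, , drop = FALSE]
  s$id[order(-s$auc)]
}
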