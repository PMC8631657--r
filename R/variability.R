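# Replicate variability via fixed-length embeddings and Euclidean mean
# distance (EMD): each DF-specific matrix is pooled into a deterministic
# 2048-value block-mean embedding (a plug-in stand-in for a pretrained CNN
# feature extractor), and dissimilarity between runs is the average
# pairwise Euclidean distance between embeddings, averaged over the three
# DF planes.

#' Embed a DF matrix as a fixed-length vector
#'
#' Partitions the matrix, read row-major, into `length` contiguous blocks
#' (as equal as divisibility allows) and emits each block's mean.
#' Deterministic; identical matrices give identical embeddings.
#'
#' @param m a `df_matrix` or a plain numeric matrix.
#' @param length embedding length (default 2048).
#' @param method embedding method; "block_mean" is the only built-in, but
#'   a function `(matrix) -> numeric(length)` may be supplied instead.
#' @return numeric vector of length `length`.
#' @export
embed_matrix <- function(m, length = 2048L, method = "block_mean") {
  intensity <- if (inherits(m, "df_matrix")) m$intensity else m
  n_cells <- base::length(intensity)
  if (n_cells == 0L) stop("empty matrix", call. = FALSE)
  if (is.function(method)) return(method(intensity))
  if (length > n_cells)
    stop(sprintf("embedding length %d exceeds the cell count %d",
                 length, n_cells), call. = FALSE)
  if (!identical(method, "block_mean"))
    stop("unknown embedding method", call. = FALSE)
  v <- as.numeric(t(intensity))  # row-major order
  bounds <- round(seq(0, n_cells, length.out = length + 1L))
  vapply(seq_len(length), function(i)
    mean(v[(bounds[i] + 1L):bounds[i + 1L]]), 0)
}

#' Mean pairwise Euclidean distance
#'
#' @param vectors list (or matrix rows) of equal-length numeric vectors.
#' @return arithmetic mean of Euclidean distances over all unordered pairs.
#' @export
pairwise_emd <- function(vectors) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1)
  if (length(vectors) < 2L)
    stop("pairwise_emd() needs at least two vectors", call. = FALSE)
  len <- lengths(vectors)
  if (any(len != len[1]))
    stop("embedding length mismatch", call. = FALSE)
  mean(stats::dist(do.call(rbind, vectors)))
}

run_embeddings <- function(run, length = 2048L, method = "block_mean") {
  mats <- combined_df_matrices(run)
  lapply(mats, function(m) embed_matrix(m, length = length, method = method))
}

emd_across_dfs <- function(emb_list) {
  # emb_list: list of per-run embeddings, each a per-DF list
  dfs <- names(emb_list[[1]])
  mean(vapply(dfs, function(df)
    pairwise_emd(lapply(emb_list, `[[`, df)), 0))
}

#' Replicate-variability report
#'
#' Quantifies within-technical (same subject, same day), within-biological
#' (same subject across days, first technical replicate per day) and
#' between-subject (one run per subject) variability as mean pairwise EMD
#' over run embeddings, each computed per DF plane and averaged over the
#' three planes. Groups with fewer than two members are omitted with a
#' warning.
#'
#' @param cohort output of [generate_cohort()] (needs `runs`, `manifest`).
#' @param length embedding length.
#' @param method embedding method, see [embed_matrix()].
#' @return list with `within_technical`, `within_biological`,
#'   `between_subject` (mean EMD, NA when not computable), `by_group`
#'   (data.frame of per-group EMDs) and `ordering_ok` (between-subject EMD
#'   exceeds both within-subject levels).
#' @export
variability_report <- function(cohort, length = 2048L,
                               method = "block_mean") {
  m <- cohort$manifest[cohort$manifest$sample_type == "breath", ,
                       drop = FALSE]
  emb <- lapply(m$sample_id, function(sid)
    run_embeddings(cohort$runs[[sid]], length = length, method = method))
  names(emb) <- m$sample_id

  group_emd <- function(ids) {
    if (length(ids) < 2L) return(NA_real_)
    emd_across_dfs(emb[ids])
  }

  rows <- list()
  # within-technical: (subject, day) groups
  singletons <- character()
  for (key in unique(paste(m$subject_id, m$day))) {
    ids <- m$sample_id[paste(m$subject_id, m$day) == key]
    if (length(ids) < 2L) {
      singletons <- c(singletons, key)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      level = "within_technical", group = key, n = length(ids),
      emd = group_emd(ids), stringsAsFactors = FALSE)
  }
  if (length(singletons))
    warning(sprintf("%d group(s) with < 2 technical replicates omitted: %s",
                    length(singletons),
                    paste(utils::head(singletons, 3), collapse = ", ")),
            call. = FALSE)
  # within-biological: per subject across days, first replicate each day
  for (subj in unique(m$subject_id)) {
    ms <- m[m$subject_id == subj & m$replicate == 1L, , drop = FALSE]
    if (nrow(ms) < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      level = "within_biological", group = subj, n = nrow(ms),
      emd = group_emd(ms$sample_id), stringsAsFactors = FALSE)
  }
  # between-subject: first run of each subject
  first_run <- m$sample_id[!duplicated(m$subject_id)]
  if (length(first_run) >= 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      level = "between_subject", group = "all", n = length(first_run),
      emd = group_emd(first_run), stringsAsFactors = FALSE)
  by_group <- do.call(rbind, rows)
  level_mean <- function(lv) {
    v <- by_group$emd[by_group$level == lv]
    if (length(v)) mean(v) else NA_real_
  }
  wt <- level_mean("within_technical")
  wb <- level_mean("within_biological")
  bs <- level_mean("between_subject")
  ordering_ok <- !is.na(bs) &&
    all(bs > c(wt, wb)[!is.na(c(wt, wb))])
  list(within_technical = wt, within_biological = wb,
       between_subject = bs, by_group = by_group,
       ordering_ok = ordering_ok)
}
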