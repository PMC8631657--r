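# On-disk format for raw FAIMS runs.
#
# One directory per run:
#   metadata.txt             flat "key: value" lines
#   df{45,55,65}_{pos,neg}.csv
# Each matrix file is UTF-8 comma-delimited text: first row is the time axis
# in seconds (leading empty cell), first column is the CF axis in volts,
# body is ion intensity in pA. Numbers carry 6 significant digits; the
# round-trip guarantee is exactness at that precision.

#' Construct a raw FAIMS run
#'
#' Bundles the six per-channel ion-intensity matrices (3 dispersion fields x
#' 2 polarities) of one analytical run with its axes and collection metadata,
#' and validates the instrument invariants: matching shapes, strictly
#' increasing CF axis spanning \[-6, 6\] V, intensities within \[0, 10\] pA.
#'
#' @param sample_id,subject_id identifiers.
#' @param sample_type one of "breath", "room_air", "air_filter".
#' @param day,replicate collection-day and technical-replicate indices.
#' @param run_duration_s analytical run time in seconds.
#' @param cf_axis compensation-field axis in volts (strictly increasing).
#' @param time_axis retention-time axis in seconds.
#' @param matrices nested list `matrices[["45"]]$pos` ... of CF-by-time
#'   matrices.
#' @return a validated `faims_run` object.
#' @export
faims_run <- function(sample_id, subject_id, sample_type, day, replicate,
                      run_duration_s, cf_axis, time_axis, matrices) {
  run <- structure(list(sample_id = sample_id, subject_id = subject_id,
                        sample_type = sample_type, day = day,
                        replicate = replicate,
                        run_duration_s = run_duration_s,
                        cf_axis = as.numeric(cf_axis),
                        time_axis = as.numeric(time_axis),
                        matrices = matrices),
                   class = "faims_run")
  validate_faims_run(run)
  run
}

#' Validate a FAIMS run against the instrument invariants
#'
#' @param run a `faims_run`.
#' @return the run, invisibly; stops with a descriptive error otherwise.
#' @export
validate_faims_run <- function(run) {
  if (!run$sample_type %in% c("breath", "room_air", "air_filter"))
    stop("sample_type must be breath, room_air or air_filter", call. = FALSE)
  cf <- run$cf_axis
  if (any(diff(cf) <= 0))
    stop("non-monotone CF axis", call. = FALSE)
  if (min(cf) < -6 || max(cf) > 6)
    stop("CF axis must lie within [-6, 6] V", call. = FALSE)
  shape <- c(length(cf), length(run$time_axis))
  for (df in c("45", "55", "65")) {
    for (pol in c("pos", "neg")) {
      m <- run$matrices[[df]][[pol]]
      if (is.null(m))
        stop(sprintf("missing matrix df%s_%s", df, pol), call. = FALSE)
      if (!all(dim(m) == shape))
        stop(sprintf("matrix df%s_%s shape %dx%d does not match axes %dx%d",
                     df, pol, nrow(m), ncol(m), shape[1], shape[2]),
             call. = FALSE)
      bad <- which(m < 0 | m > 10)
      if (length(bad)) {
        cell <- arrayInd(bad[1], dim(m))
        stop(sprintf(
          "matrix df%s_%s intensity %.4g pA at cell (%d, %d) outside [0, 10]",
          df, pol, m[bad[1]], cell[1], cell[2]), call. = FALSE)
      }
    }
  }
  invisible(run)
}

matrix_files <- function() {
  f <- expand.grid(pol = c("pos", "neg"), df = c("45", "55", "65"),
                   stringsAsFactors = FALSE)
  sprintf("df%s_%s.csv", f$df, f$pol)
}

fmt6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

#' Write a FAIMS run to a run directory
#'
#' @param run a validated `faims_run`.
#' @param path directory to create (must not exist or be empty-safe).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  validate_faims_run(run)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop(sprintf("cannot create run directory '%s'", path), call. = FALSE)
  meta <- c(sample_id = run$sample_id, subject_id = run$subject_id,
            sample_type = run$sample_type, day = run$day,
            replicate = run$replicate,
            run_duration_s = fmt6(run$run_duration_s))
  writeLines(paste0(names(meta), ": ", meta),
             file.path(path, "metadata.txt"))
  for (df in c("45", "55", "65")) {
    for (pol in c("pos", "neg")) {
      m <- run$matrices[[df]][[pol]]
      file <- file.path(path, sprintf("df%s_%s.csv", df, pol))
      header <- paste(c("", fmt6(run$time_axis)), collapse = ",")
      body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(fmt6(run$cf_axis[i]), fmt6(m[i, ])), collapse = ","),
        "")
      writeLines(c(header, body), file)
    }
  }
  invisible(path)
}

read_matrix_file <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L) abort_format(file, "fewer than two lines")
  split_num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  time_axis <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(time_axis)) abort_format(file, "non-numeric time axis")
  rows <- lapply(lines[-1], function(l) suppressWarnings(split_num(l)))
  ncol_expect <- length(time_axis) + 1L
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_expect)
      abort_format(file, sprintf("row %d has %d fields, expected %d",
                                 i + 1L, length(rows[[i]]), ncol_expect))
    if (anyNA(rows[[i]]))
      abort_format(file, sprintf("non-numeric value in row %d", i + 1L))
  }
  mat <- do.call(rbind, rows)
  cf_axis <- mat[, 1]
  m <- mat[, -1, drop = FALSE]
  if (any(diff(cf_axis) <= 0)) abort_format(file, "non-monotone CF axis")
  bad <- which(m < 0 | m > 10)
  if (length(bad)) {
    cell <- arrayInd(bad[1], dim(m))
    abort_format(file, sprintf(
      "intensity %.4g pA at cell (%d, %d) outside [0, 10]",
      m[bad[1]], cell[1], cell[2]))
  }
  list(cf_axis = cf_axis, time_axis = time_axis, intensity = m)
}

#' Read a FAIMS run directory
#'
#' @param path directory written by [write_run()] or conforming to the
#'   documented text format.
#' @return a validated `faims_run`.
#' @export
read_run <- function(path) {
  meta_file <- file.path(path, "metadata.txt")
  if (!file.exists(meta_file)) abort_format(meta_file, "missing")
  kv <- strsplit(readLines(meta_file), ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = ": "), ""), vapply(kv, `[`, "", 1))
  mats <- list()
  cf_axis <- NULL; time_axis <- NULL; first_file <- NULL
  for (df in c("45", "55", "65")) {
    mats[[df]] <- list()
    for (pol in c("pos", "neg")) {
      file <- file.path(path, sprintf("df%s_%s.csv", df, pol))
      if (!file.exists(file)) abort_format(file, "missing matrix file")
      parsed <- read_matrix_file(file)
      if (is.null(cf_axis)) {
        cf_axis <- parsed$cf_axis; time_axis <- parsed$time_axis
        first_file <- file
      } else if (!isTRUE(all.equal(cf_axis, parsed$cf_axis)) ||
                 !isTRUE(all.equal(time_axis, parsed$time_axis))) {
        abort_format(file, sprintf("axes differ from '%s'", first_file))
      }
      mats[[df]][[pol]] <- parsed$intensity
    }
  }
  faims_run(sample_id = meta[["sample_id"]],
            subject_id = meta[["subject_id"]],
            sample_type = meta[["sample_type"]],
            day = as.integer(meta[["day"]]),
            replicate = as.integer(meta[["replicate"]]),
            run_duration_s = as.numeric(meta[["run_duration_s"]]),
            cf_axis = cf_axis, time_axis = time_axis, matrices = mats)
}

#' Validate a tree of run directories
#'
#' Applies the format validation of [read_run()] to every subdirectory of
#' `root` and collects per-run diagnostics instead of stopping at the first
#' failure.
#'
#' @param root directory whose immediate subdirectories are run directories.
#' @return data.frame with columns `run`, `ok`, `message`.
#' @export
validate_run_tree <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  res <- lapply(dirs, function(d) {
    msg <- tryCatch({ read_run(d); "" }, error = function(e) conditionMessage(e))
    data.frame(run = basename(d), ok = msg == "", message = msg,
               stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(run = character(), ok = logical(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
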