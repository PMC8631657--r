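# Synthetic FAIMS cohort generator.
#
# Signal model: each volatile compound produces a separable 2-D Gaussian in
# (compensation field, retention time) on every matrix it appears in.
# Baseline noise is i.i.d. half-normal per cell, capped at the instrument's
# maximum baseline intensity, so rendered baselines never cross the
# molecular-feature threshold. All intensities are clipped to the detector
# range [0, 10] pA.

DF_SETTINGS <- c(45L, 55L, 65L)
POLARITIES <- c("positive", "negative")
PEAK_KINDS <- c("endogenous", "marker", "environmental", "background")

#' Describe one synthetic VOC peak
#'
#' A peak is a separable 2-D Gaussian localized in compensation field (CF)
#' and retention time, attached to one dispersion-field (DF) setting and one
#' ion polarity.
#'
#' @param rt_center retention-time center as a 0-based time index.
#' @param rt_sigma Gaussian width along the time axis, in time points.
#' @param cf_center CF center in volts, within \[-6, 6\].
#' @param cf_sigma Gaussian width along the CF axis, in volts.
#' @param amplitude peak amplitude in pA, within \[0, 10\].
#' @param df_setting dispersion field, one of 45, 55, 65 (volts).
#' @param polarity "positive" or "negative" ion channel.
#' @param kind one of "endogenous" (subject biology), "marker"
#'   (stage-amplified disease signal), "environmental" (shared between breath
#'   and paired blanks, removed by blank subtraction), "background"
#'   (instrument air background, present everywhere, sub-threshold).
#' @param stage_multiplier for marker peaks, a length-4 vector of per-stage
#'   amplitude multipliers (stages 0-3), each >= 1. Ignored for other kinds.
#' @return a `peak_spec` object.
#' @export
peak_spec <- function(rt_center, rt_sigma, cf_center, cf_sigma, amplitude,
                      df_setting, polarity = c("positive", "negative"),
                      kind = c("endogenous", "marker", "environmental",
                               "background"),
                      stage_multiplier = NULL) {
  polarity <- match.arg(polarity)
  kind <- match.arg(kind)
  if (!is.numeric(rt_center) || length(rt_center) != 1L || rt_center < 0)
    abort_config("rt_center", "must be a single non-negative time index")
  if (!is.numeric(rt_sigma) || rt_sigma <= 0)
    abort_config("rt_sigma", "must be > 0")
  if (!is.numeric(cf_center) || cf_center < -6 || cf_center > 6)
    abort_config("cf_center", "must lie in [-6, 6] V")
  if (!is.numeric(cf_sigma) || cf_sigma <= 0)
    abort_config("cf_sigma", "must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude > 10)
    abort_config("amplitude", "must lie in the detector range [0, 10] pA")
  if (!df_setting %in% DF_SETTINGS)
    abort_config("df_setting", "must be one of 45, 55, 65")
  if (kind == "marker") {
    stage_multiplier <- stage_multiplier %||% rep(1, 4)
    if (length(stage_multiplier) != 4L || any(stage_multiplier < 1))
      abort_config("stage_multiplier",
                   "must be 4 per-stage multipliers, each >= 1")
  } else {
    stage_multiplier <- rep(1, 4)
  }
  structure(list(rt_center = rt_center, rt_sigma = rt_sigma,
                 cf_center = cf_center, cf_sigma = cf_sigma,
                 amplitude = amplitude, df_setting = as.integer(df_setting),
                 polarity = polarity, kind = kind,
                 stage_multiplier = stage_multiplier),
            class = "peak_spec")
}

#' Default synthetic peak library
#'
#' A fixed arrangement of VOC peaks emulating the qualitative structure of
#' the study's instrument output: well-separated endogenous peaks on each DF
#' plane, one stage-amplified marker peak per DF, one environmental peak per
#' DF shared with paired blank runs, and one sub-threshold background peak
#' per DF (below the 0.5 pA feature threshold). Fewer peaks are placed at
#' DF 65 V, mirroring the sparser feature counts observed at that setting.
#' Retention centers are expressed as fractions of the time axis so the
#' library scales with `time_points`.
#'
#' @param time_points number of time points of the target grid.
#' @param stage_effect length-4 per-stage amplitude multipliers applied to
#'   marker peaks.
#' @return list of `peak_spec`.
#' @export
default_peak_library <- function(time_points = 3460L,
                                 stage_effect = c(1, 1.3, 1.6, 2)) {
  rs <- max(3, round(0.004 * time_points))  # peak width in time points
  pk <- function(frac, cf, amp, df, pol, kind, sm = NULL)
    peak_spec(rt_center = round(frac * (time_points - 1)), rt_sigma = rs,
              cf_center = cf, cf_sigma = 0.35, amplitude = amp,
              df_setting = df, polarity = pol, kind = kind,
              stage_multiplier = sm)
  c(
    # DF 45 V: five endogenous, one marker, one environmental, one background
    list(pk(0.08, -1.6, 2.5, 45, "positive", "endogenous"),
         pk(0.18,  0.8, 1.8, 45, "negative", "endogenous"),
         pk(0.28, -0.4, 3.0, 45, "positive", "endogenous"),
         pk(0.38,  1.9, 1.2, 45, "negative", "endogenous"),
         pk(0.48, -2.3, 2.0, 45, "positive", "endogenous"),
         pk(0.60,  0.2, 1.5, 45, "positive", "marker", stage_effect),
         pk(0.72, -1.0, 1.0, 45, "positive", "environmental"),
         pk(0.85,  1.2, 0.35, 45, "positive", "background")),
    # DF 55 V: four endogenous, one marker, one environmental, one background
    list(pk(0.12,  1.4, 2.2, 55, "positive", "endogenous"),
         pk(0.24, -0.9, 1.6, 55, "negative", "endogenous"),
         pk(0.40,  0.3, 2.8, 55, "positive", "endogenous"),
         pk(0.55, -1.8, 1.3, 55, "negative", "endogenous"),
         pk(0.66,  0.9, 1.4, 55, "positive", "marker", stage_effect),
         pk(0.78, -0.3, 0.9, 55, "positive", "environmental"),
         pk(0.90,  2.0, 0.3, 55, "positive", "background")),
    # DF 65 V: two endogenous, one marker, one environmental, one background
    list(pk(0.15, -0.6, 1.8, 65, "positive", "endogenous"),
         pk(0.35,  1.1, 1.2, 65, "negative", "endogenous"),
         pk(0.58, -1.3, 1.3, 65, "positive", "marker", stage_effect),
         pk(0.75,  0.5, 0.8, 65, "positive", "environmental"),
         pk(0.88, -2.0, 0.3, 65, "positive", "background"))
  )
}

#' Cohort generation configuration
#'
#' Defaults reproduce the study conditions: stage counts 11/14/15/10
#' (n = 50), four technical replicate tubes per collection, 512 CF points
#' spanning \[-6, 6\] V by 3460 time points over a 2164.1 s run, baseline
#' noise capped at 0.0104 pA, background air peaks up to 0.391 pA, and a
#' run-time jitter of +/- 0.18 %.
#'
#' @param n_per_stage integer counts of subjects at stages 0-3.
#' @param n_technical_replicates tubes per collection day (>= 1).
#' @param n_biological_replicates collection days per subject (>= 1).
#' @param peaks list of `peak_spec` templates; defaults to
#'   [default_peak_library()] at the configured grid size.
#' @param stage_effect per-stage amplitude multipliers applied to marker
#'   peaks in the default library.
#' @param noise_sd half-normal baseline noise sd in pA.
#' @param baseline_max cap on baseline noise in pA.
#' @param background_max maximum background-peak amplitude in pA (validated).
#' @param rt_jitter_fraction per-sample uniform run-time jitter half-range.
#' @param subject_sd lognormal sd of between-subject amplitude variation
#'   (endogenous and marker peaks).
#' @param biological_sd lognormal sd of day-to-day amplitude variation.
#' @param cf_points,time_points grid dimensions (cf_points must be even).
#' @param run_duration_s nominal analytical run time in seconds.
#' @param n_ncph number of stage-3 subjects flagged as non-cirrhotic portal
#'   hypertension.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_per_stage = c(11L, 14L, 15L, 10L),
                          n_technical_replicates = 4L,
                          n_biological_replicates = 1L,
                          peaks = NULL,
                          stage_effect = c(1, 1.3, 1.6, 2),
                          noise_sd = 0.002,
                          baseline_max = 0.0104,
                          background_max = 0.391,
                          rt_jitter_fraction = 0.0018,
                          subject_sd = 0.3,
                          biological_sd = 0.15,
                          cf_points = 512L,
                          time_points = 3460L,
                          run_duration_s = 2164.1,
                          n_ncph = 0L,
                          seed = 1L) {
  if (length(n_per_stage) != 4L || any(n_per_stage < 0) ||
      any(n_per_stage != round(n_per_stage)))
    abort_config("n_per_stage", "must be 4 non-negative integer counts")
  if (n_technical_replicates < 1L)
    abort_config("n_technical_replicates", "must be >= 1")
  if (n_biological_replicates < 1L)
    abort_config("n_biological_replicates", "must be >= 1")
  if (cf_points %% 2L != 0L || cf_points < 2L)
    abort_config("cf_points", "must be even and >= 2")
  if (time_points < 2L) abort_config("time_points", "must be >= 2")
  if (baseline_max >= 0.5)
    abort_config("baseline_max",
                 "must stay below the 0.5 pA feature threshold")
  if (rt_jitter_fraction < 0)
    abort_config("rt_jitter_fraction", "must be >= 0")
  if (noise_sd < 0) abort_config("noise_sd", "must be >= 0")
  if (n_ncph > n_per_stage[4])
    abort_config("n_ncph", "cannot exceed the stage-3 count")
  peaks <- peaks %||% default_peak_library(time_points, stage_effect)
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    if (!inherits(p, "peak_spec"))
      abort_config("peaks", sprintf("element %d is not a peak_spec", i))
    if (p$rt_center > time_points - 1L)
      abort_config("peaks",
                   sprintf("element %d rt_center %d outside the time axis",
                           i, p$rt_center))
    if (p$kind == "background" && p$amplitude > background_max)
      abort_config("peaks",
                   sprintf("element %d background amplitude exceeds %.3f pA",
                           i, background_max))
  }
  structure(list(n_per_stage = as.integer(n_per_stage),
                 n_technical_replicates = as.integer(n_technical_replicates),
                 n_biological_replicates = as.integer(n_biological_replicates),
                 peaks = peaks, stage_effect = stage_effect,
                 noise_sd = noise_sd, baseline_max = baseline_max,
                 background_max = background_max,
                 rt_jitter_fraction = rt_jitter_fraction,
                 subject_sd = subject_sd, biological_sd = biological_sd,
                 cf_points = as.integer(cf_points),
                 time_points = as.integer(time_points),
                 run_duration_s = run_duration_s,
                 n_ncph = as.integer(n_ncph), seed = as.integer(seed)),
            class = "cohort_config")
}

faims_axes <- function(config) {
  list(cf = seq(-6, 6, length.out = config$cf_points),
       time = (seq_len(config$time_points) - 1) *
         (config$run_duration_s / config$time_points))
}

#' Render one ion-intensity matrix from peak specs
#'
#' Sums separable 2-D Gaussians over the CF-by-time grid, adds capped
#' half-normal baseline noise from the current RNG state (or `noise_seed`),
#' and clips to the detector range \[0, 10\] pA.
#'
#' @param peaks list of `peak_spec`, all matching `polarity`/`df_setting`.
#' @param config a `cohort_config` (grid size and noise settings).
#' @param polarity,df_setting the channel being rendered.
#' @param noise_seed optional seed for the noise draw.
#' @param rt_scale multiplicative retention-time stretch (run-time jitter).
#' @return CF-by-time numeric matrix in pA.
#' @export
render_matrix <- function(peaks, config, polarity, df_setting,
                          noise_seed = NULL, rt_scale = 1) {
  for (p in peaks)
    if (p$polarity != polarity || p$df_setting != df_setting)
      abort_config("peaks",
                   sprintf("peak with polarity %s / DF %d does not match the requested %s / DF %d plane",
                           p$polarity, p$df_setting, polarity, df_setting))
  cf_axis <- seq(-6, 6, length.out = config$cf_points)
  tt <- seq_len(config$time_points) - 1
  m <- matrix(0, nrow = config$cf_points, ncol = config$time_points)
  for (p in peaks) {
    rt <- p$rt_center * rt_scale
    m <- m + p$amplitude *
      outer(exp(-(cf_axis - p$cf_center)^2 / (2 * p$cf_sigma^2)),
            exp(-(tt - rt)^2 / (2 * p$rt_sigma^2)))
  }
  if (config$noise_sd > 0) {
    draw <- function() {
      noise <- abs(stats::rnorm(length(m), 0, config$noise_sd))
      m + pmin(noise, config$baseline_max)
    }
    m <- if (is.null(noise_seed)) draw() else with_seed(noise_seed, draw())
  }
  pmin(pmax(m, 0), 10)
}

# realized per-sample amplitude for one peak
realized_amplitude <- function(p, stage, subj_factor, bio_factor) {
  amp <- p$amplitude
  if (p$kind %in% c("endogenous", "marker"))
    amp <- amp * subj_factor * bio_factor
  if (p$kind == "marker") amp <- amp * p$stage_multiplier[stage + 1L]
  amp
}

render_run <- function(config, peaks_realized, sample_id, subject_id,
                       sample_type, day, replicate, rt_scale, duration) {
  axes <- faims_axes(config)
  mats <- list()
  for (df in DF_SETTINGS) {
    mats[[as.character(df)]] <- list()
    for (pol in POLARITIES) {
      sel <- Filter(function(p) p$df_setting == df && p$polarity == pol,
                    peaks_realized)
      key <- if (pol == "positive") "pos" else "neg"
      mats[[as.character(df)]][[key]] <-
        render_matrix(sel, config, pol, df, rt_scale = rt_scale)
    }
  }
  faims_run(sample_id = sample_id, subject_id = subject_id,
            sample_type = sample_type, day = day, replicate = replicate,
            run_duration_s = duration, cf_axis = axes$cf,
            time_axis = axes$time, matrices = mats)
}

#' Generate a synthetic breath cohort with paired blanks
#'
#' Produces one breath run per (subject, day, technical replicate), each with
#' a paired room-air and air-filter blank sharing the breath run's
#' environmental amplitudes and run-time jitter (so noiseless blank
#' subtraction removes environmental signal exactly), plus a manifest and a
#' ground-truth record. Deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with elements `runs` (named list of `faims_run`), `manifest`
#'   (data.frame: sample_id, subject_id, sample_type, stage, cirrhosis, ncph,
#'   day, replicate, room_air_id, air_filter_id, run_duration_s, excluded),
#'   `truth` (subjects, per-sample realized peak amplitudes, marker /
#'   environmental peak indices) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_subj <- sum(config$n_per_stage)
  if (n_subj == 0L) abort_config("n_per_stage", "cohort is empty")
  peaks <- config$peaks
  marker_idx <- which(vapply(peaks, function(p) p$kind == "marker", TRUE))
  env_idx <- which(vapply(peaks, function(p) p$kind == "environmental", TRUE))
  bg_idx <- which(vapply(peaks, function(p) p$kind == "background", TRUE))
  varying <- which(vapply(peaks, function(p)
    p$kind %in% c("endogenous", "marker"), TRUE))

  with_seed(config$seed, {
    stages <- rep(0:3, times = config$n_per_stage)
    subject_id <- sprintf("SUBJ%03d", seq_len(n_subj))
    ncph <- rep(FALSE, n_subj)
    if (config$n_ncph > 0L) {
      s3 <- which(stages == 3L)
      ncph[s3[seq_len(config$n_ncph)]] <- TRUE
    }
    subjects <- data.frame(subject_id = subject_id, stage = stages,
                           cirrhosis = stages >= 1L & !ncph, ncph = ncph,
                           stringsAsFactors = FALSE)
    runs <- list()
    manifest <- list()
    amp_record <- list()
    for (si in seq_len(n_subj)) {
      subj_f <- rep(1, length(peaks))
      if (config$subject_sd > 0)
        subj_f[varying] <- stats::rlnorm(length(varying), 0, config$subject_sd)
      for (day in seq_len(config$n_biological_replicates)) {
        bio_f <- rep(1, length(peaks))
        if (config$biological_sd > 0 && config$n_biological_replicates > 1L)
          bio_f[varying] <- stats::rlnorm(length(varying), 0,
                                          config$biological_sd)
        for (rep_i in seq_len(config$n_technical_replicates)) {
          jit <- if (config$rt_jitter_fraction > 0)
            stats::runif(1, -config$rt_jitter_fraction,
                         config$rt_jitter_fraction) else 0
          duration <- config$run_duration_s * (1 + jit)
          amps <- vapply(seq_along(peaks), function(i)
            realized_amplitude(peaks[[i]], stages[si], subj_f[i], bio_f[i]),
            0)
          realized <- lapply(seq_along(peaks), function(i) {
            p <- peaks[[i]]; p$amplitude <- amps[i]; p
          })
          sid <- sprintf("%s_d%d_t%d", subject_id[si], day, rep_i)
          ra_id <- paste0(sid, "_roomair")
          af_id <- paste0(sid, "_airfilter")
          blank_peaks <- realized[c(env_idx, bg_idx)]
          runs[[sid]] <- render_run(config, realized, sid, subject_id[si],
                                    "breath", day, rep_i, 1 + jit, duration)
          runs[[ra_id]] <- render_run(config, blank_peaks, ra_id,
                                      subject_id[si], "room_air", day, rep_i,
                                      1 + jit, duration)
          runs[[af_id]] <- render_run(config, blank_peaks, af_id,
                                      subject_id[si], "air_filter", day,
                                      rep_i, 1 + jit, duration)
          manifest[[sid]] <- data.frame(
            sample_id = sid, subject_id = subject_id[si],
            sample_type = "breath", stage = stages[si],
            cirrhosis = subjects$cirrhosis[si], ncph = ncph[si],
            day = day, replicate = rep_i, room_air_id = ra_id,
            air_filter_id = af_id, run_duration_s = duration,
            excluded = FALSE, stringsAsFactors = FALSE)
          amp_record[[sid]] <- amps
        }
      }
    }
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    truth <- list(subjects = subjects,
                  amplitudes = do.call(rbind, amp_record),
                  marker_peaks = marker_idx,
                  environmental_peaks = env_idx,
                  background_peaks = bg_idx)
    list(runs = runs, manifest = manifest, truth = truth, config = config)
  })
}
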