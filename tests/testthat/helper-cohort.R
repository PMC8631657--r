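# Shared fixtures: reduced-grid cohort configurations (32 CF x 200 time
# points) keep cohort-level tests fast; single-run tests that check the
# instrument-shape contract use the full 512 x 3460 grid.

small_config <- function(..., seed = 42L) {
  defaults <- list(n_per_stage = c(2L, 2L, 2L, 2L),
                   n_technical_replicates = 2L,
                   cf_points = 32L, time_points = 200L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# a fully deterministic (noise-free, jitter-free, variation-free) config
noiseless_config <- function(...) {
  small_config(noise_sd = 0, rt_jitter_fraction = 0, subject_sd = 0,
               biological_sd = 0, ...)
}

# a cohort whose marker signal strongly separates the classes
separable_config <- function(..., seed = 11L) {
  small_config(n_per_stage = c(7L, 7L, 7L, 7L), n_technical_replicates = 1L,
               stage_effect = c(1, 4, 4, 7), subject_sd = 0.05,
               noise_sd = 0.002, seed = seed, ...)
}

# wrap a numeric vector as a separation chromatogram
sc_vec <- function(x, spacing = 1, df = 45L, sample_id = "S") {
  structure(list(df_voltage = df,
                 time_axis = (seq_along(x) - 1) * spacing,
                 intensity = as.numeric(x), sample_id = sample_id),
            class = "separation_chromatogram")
}

# minimal feature table around a value matrix (columns = MF ids)
toy_feature_table <- function(values, stages,
                              ids = sprintf("45%02d", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  colnames(values) <- ids
  rownames(values) <- sprintf("SUBJ%03d", seq_len(nrow(values)))
  subjects <- data.frame(subject_id = rownames(values), stage = stages,
                         cirrhosis = stages >= 1L, ncph = FALSE,
                         stringsAsFactors = FALSE)
  structure(list(peak_max = values, peak_area = values * 2,
                 features = data.frame(id = colnames(values),
                                       df_voltage = 45L,
                                       rt_consensus = seq_len(ncol(values)),
                                       stringsAsFactors = FALSE),
                 subjects = subjects),
            class = "feature_table")
}

# brute-force AUC oracle: explicit pair counting, ties one half
auc_bruteforce <- function(values, labels) {
  labels <- as.logical(labels)
  pos <- values[labels]; neg <- values[!labels]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
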