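test_that("rendered matrices follow the 2-D Gaussian signal model", {
  cfg <- small_config(noise_sd = 0)
  # empty peak list -> all zeros
  m0 <- render_matrix(list(), cfg, "positive", 45)
  expect_equal(dim(m0), c(32L, 200L))
  expect_true(all(m0 == 0))
  # single peak: maximum at (cf_center, rt_center); cf -6 + k*12/31 on-grid
  cf_axis <- seq(-6, 6, length.out = 32)
  p <- peak_spec(rt_center = 100, rt_sigma = 4, cf_center = cf_axis[18],
                 cf_sigma = 0.4, amplitude = 3, df_setting = 45,
                 polarity = "positive", kind = "endogenous")
  m1 <- render_matrix(list(p), cfg, "positive", 45)
  expect_equal(max(m1), 3)
  expect_equal(which(m1 == max(m1), arr.ind = TRUE)[1, ],
               c(row = 18L, col = 101L))
  # two overlapping peaks: grid max bounded by brute-force sum of the two
  # Gaussian surfaces evaluated over the whole grid
  q <- peak_spec(rt_center = 104, rt_sigma = 4, cf_center = cf_axis[18],
                 cf_sigma = 0.4, amplitude = 2, df_setting = 45,
                 polarity = "positive", kind = "endogenous")
  m2 <- render_matrix(list(p, q), cfg, "positive", 45)
  tt <- 0:199
  brute <- outer(exp(-(cf_axis - p$cf_center)^2 / (2 * p$cf_sigma^2)),
                 exp(-(tt - 100)^2 / (2 * 16))) * 3 +
    outer(exp(-(cf_axis - q$cf_center)^2 / (2 * q$cf_sigma^2)),
          exp(-(tt - 104)^2 / (2 * 16))) * 2
  expect_equal(m2, pmin(brute, 10), tolerance = 1e-12)
  expect_lte(max(m2), p$amplitude + q$amplitude)
  # polarity mismatch is rejected
  expect_error(render_matrix(list(p), cfg, "negative", 45), "polarity")
})

test_that("cohort generation is deterministic and honours the detector range", {
  cfg <- small_config(seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$runs, b$runs)
  for (r in a$runs[1:3])
    for (df in c("45", "55", "65"))
      for (pol in c("pos", "neg")) {
        m <- r$matrices[[df]][[pol]]
        expect_true(all(m >= 0 & m <= 10))
      }
  # each breath run has resolvable paired blanks
  expect_true(all(a$manifest$room_air_id %in% names(a$runs)))
  expect_true(all(a$manifest$air_filter_id %in% names(a$runs)))
})

test_that("noise-free same-stage subjects are identical", {
  cfg <- noiseless_config(n_per_stage = c(2L, 0L, 0L, 0L),
                          n_technical_replicates = 1L,
                          stage_effect = c(1, 1, 1, 1))
  co <- generate_cohort(cfg)
  ids <- co$manifest$sample_id
  expect_identical(co$runs[[ids[1]]]$matrices, co$runs[[ids[2]]]$matrices)
})

test_that("marker peak intensity increases strictly with stage (noiseless)", {
  cfg <- noiseless_config(n_per_stage = c(1L, 1L, 1L, 1L),
                          n_technical_replicates = 1L)
  co <- generate_cohort(cfg)
  marker <- cfg$peaks[[which(vapply(cfg$peaks, function(p)
    p$kind == "marker" && p$df_setting == 45L, TRUE))[1]]]
  maxima <- vapply(co$manifest$sample_id, function(sid) {
    m <- co$runs[[sid]]$matrices[["45"]][["pos"]]
    max(m[, marker$rt_center + 1L])
  }, 0)
  expect_identical(co$manifest$stage, 0:3)
  expect_true(all(diff(maxima) > 0))
})

test_that("noiseless blank subtraction removes environmental peaks exactly", {
  cfg <- noiseless_config(n_per_stage = c(1L, 0L, 0L, 0L),
                          n_technical_replicates = 1L)
  co <- generate_cohort(cfg)
  m <- co$manifest[1, ]
  breath <- co$runs[[m$sample_id]]
  blank <- co$runs[[m$room_air_id]]
  env <- cfg$peaks[vapply(cfg$peaks, function(p)
    p$kind %in% c("environmental", "background"), TRUE)]
  for (df in c("45", "55", "65")) {
    sample_m <- df_matrix(as.integer(df), breath$cf_axis, breath$time_axis,
                          combine_polarities(breath$matrices[[df]]$pos,
                                             breath$matrices[[df]]$neg))
    blank_m <- df_matrix(as.integer(df), blank$cf_axis, blank$time_axis,
                         combine_polarities(blank$matrices[[df]]$pos,
                                            blank$matrices[[df]]$neg))
    resid <- subtract_blank(sample_m, blank_m)
    for (p in env[vapply(env, function(p)
      p$df_setting == as.integer(df), TRUE)])
      expect_equal(resid$intensity[which.min(abs(resid$cf_axis -
                                                   p$cf_center)),
                                   p$rt_center + 1L],
                   0, tolerance = 1e-12)
  }
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(cohort_config(n_per_stage = c(1, 2, 3)), "n_per_stage")
  expect_error(cohort_config(cf_points = 33L), "cf_points")
  expect_error(cohort_config(baseline_max = 0.6), "baseline_max")
  expect_error(cohort_config(rt_jitter_fraction = -0.1),
               "rt_jitter_fraction")
  expect_error(peak_spec(10, 2, 7, 0.3, 1, 45), "cf_center")
  expect_error(peak_spec(10, 2, 0, 0.3, 12, 45), "amplitude")
  expect_error(peak_spec(10, 2, 0, 0.3, 1, 50), "df_setting")
  expect_error(peak_spec(10, 2, 0, 0.3, 1, 45, kind = "marker",
                         stage_multiplier = c(0.5, 1, 1, 1)),
               "stage_multiplier")
})
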