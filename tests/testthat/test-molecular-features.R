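test_that("detect_features thresholds local maxima with tie-breaking", {
  f <- detect_features(sc_vec(c(0, 0.6, 0, 1.2, 0)), min_separation = 1L)
  expect_equal(nrow(f), 2L)
  expect_equal(sort(f$peak_max), c(0.6, 1.2))
  # background-only trace stays below the 0.5 pA threshold
  bg <- detect_features(sc_vec(c(0.1, 0.391, 0.2, 0.3, 0.391, 0.1)))
  expect_equal(nrow(bg), 0L)
  # plateau resolves to the first plateau index
  pl <- detect_features(sc_vec(c(0, 0.7, 0.7, 0)), min_separation = 1L)
  expect_equal(pl$rt_index, 2L)
  # min_separation keeps the more intense of two close maxima
  x <- c(0, 0.8, 0.3, 1.5, 0)
  close_peaks <- detect_features(sc_vec(x), min_separation = 5L)
  expect_equal(close_peaks$peak_max, 1.5)
})

test_that("planted well-separated peaks are recovered with recall 1", {
  cfg <- noiseless_config(n_per_stage = c(1L, 0L, 0L, 0L),
                          n_technical_replicates = 1L)
  # 5 endogenous 2 pA peaks at well-separated centers, DF 45
  peaks <- lapply(seq(20, 180, by = 40), function(rt)
    peak_spec(rt, 3, 0.5 * (rt %% 3 - 1), 0.3, 2, 45, "positive",
              "endogenous"))
  cfg <- noiseless_config(n_per_stage = c(1L, 0L, 0L, 0L),
                          n_technical_replicates = 1L,
                          noise_sd = 0.001, peaks = peaks)
  co <- generate_cohort(cfg)
  scs <- preprocess_run(co$runs[[co$manifest$sample_id[1]]],
                        terminal_points = 10L)
  found <- detect_features(scs[["45"]])
  expect_equal(nrow(found), 5L)
  expect_true(all(vapply(seq(20, 180, by = 40), function(rt)
    any(abs(found$rt_index - (rt + 1L)) <= 2L), TRUE)))
  expect_equal(nrow(detect_features(scs[["65"]])), 0L)
})

test_that("feature ids encode DF and retention rank", {
  f <- data.frame(rt_index = c(120, 40), rt_start = c(115, 35),
                  rt_end = c(125, 45), peak_max = c(1, 2),
                  peak_area = c(5, 8))
  withid <- assign_feature_ids(f, 45L)
  expect_equal(withid$id, c("4501", "4502"))
  expect_equal(withid$rt_index, c(40, 120))  # sorted internally
  expect_equal(assign_feature_ids(f[1, ], 65L)$id, "6501")
  big <- data.frame(rt_index = 1:100, rt_start = 1:100, rt_end = 1:100,
                    peak_max = 1, peak_area = 1)
  expect_error(assign_feature_ids(big, 45L), "exhausted")
})

test_that("peak integration is trapezoidal on the physical time axis", {
  sc <- sc_vec(c(0, 1, 0))
  expect_equal(integrate_peak(sc, data.frame(rt_start = 1, rt_end = 3)), 1)
  flat <- sc_vec(c(1, 1, 1))
  expect_equal(integrate_peak(flat, data.frame(rt_start = 1, rt_end = 3)), 2)
  flat2 <- sc_vec(c(1, 1, 1), spacing = 0.6256)
  expect_equal(integrate_peak(flat2, data.frame(rt_start = 1, rt_end = 3)),
               1.2512)
  expect_equal(integrate_peak(sc, data.frame(rt_start = 2, rt_end = 2)), 0)
})

test_that("cross-sample matching brackets features by retention time", {
  fl <- function(idx, val = 1) data.frame(rt_index = idx, rt_start = idx - 2,
                                          rt_end = idx + 2, peak_max = val,
                                          peak_area = val * 3)
  near <- match_features(list(a = fl(100), b = fl(103)), rt_tolerance = 10L)
  expect_length(near$rt_consensus, 1L)
  far <- match_features(list(a = fl(100), b = fl(150)), rt_tolerance = 10L)
  expect_length(far$rt_consensus, 2L)
  expect_true(anyNA(far$peak_max))
})

test_that("replicate averaging yields subject-level means", {
  cfg <- noiseless_config(n_per_stage = c(2L, 0L, 2L, 0L),
                          n_technical_replicates = 3L)
  co <- generate_cohort(cfg)
  scs <- lapply(stats::setNames(co$manifest$sample_id,
                                co$manifest$sample_id), function(sid)
    preprocess_run(co$runs[[sid]], terminal_points = 10L))
  tab <- build_feature_table(scs, co$manifest)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab$peak_max), 4L)  # subjects, not samples
  # noiseless technical replicates agree exactly, so CV would be 0; the
  # subject mean equals any replicate's value
  one <- detect_features(scs[[co$manifest$sample_id[1]]][["45"]])
  expect_equal(unname(tab$peak_max[1, "4501"]), one$peak_max[1])
})

test_that("coefficient of variation matches hand-computed values", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3 * 100,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(c(10, 10, 10, 20)), 40)
  expect_error(coefficient_of_variation(5), "two values")
})

test_that("group comparison computes one-tailed Welch tests and AUC", {
  # identical distributions: percent difference 0, p = 0.5 convention
  same <- toy_feature_table(matrix(c(1, 1, 1, 1, 1, 1), 6), c(0, 0, 0, 1, 2, 3))
  s <- compare_groups(same)
  expect_equal(s$pct_diff[s$layer == "peak_max"], 0)
  expect_equal(s$p_value[s$layer == "peak_max"], 0.5)
  # control mean 1, disease mean 2 -> 100 %
  tab <- toy_feature_table(matrix(c(1, 1, 2, 2), 4), c(0, 0, 2, 3))
  s2 <- compare_groups(tab)
  expect_equal(s2$pct_diff[1], 100)
  # independent Welch oracle: manual statistic + pt()
  ctrl <- c(1.0, 1.1, 0.9); dis <- c(2.0, 2.1, 1.9)
  tab3 <- toy_feature_table(matrix(c(ctrl, dis), 6), c(0, 0, 0, 1, 2, 3))
  s3 <- compare_groups(tab3)
  se <- sqrt(var(dis) / 3 + var(ctrl) / 3)
  dfree <- se^4 / ((var(dis) / 3)^2 / 2 + (var(ctrl) / 3)^2 / 2)
  p_oracle <- stats::pt((mean(dis) - mean(ctrl)) / se, dfree,
                        lower.tail = FALSE)
  expect_equal(s3$p_value[s3$layer == "peak_max"], p_oracle,
               tolerance = 1e-10)
  expect_lt(s3$p_value[s3$layer == "peak_max"], 0.01)
  # stage trend flag: strictly increasing stage means
  tr <- toy_feature_table(matrix(c(1, 2, 3, 4), 4), c(0, 1, 2, 3))
  expect_true(all(compare_groups(tr)$stage_trend))
  ntr <- toy_feature_table(matrix(c(1, 3, 2, 4), 4), c(0, 1, 2, 3))
  expect_false(any(compare_groups(ntr)$stage_trend))
})

test_that("feature_auc equals brute-force pair counting", {
  expect_equal(feature_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(feature_auc(rep(3, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(feature_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_error(feature_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # property: oracle equivalence on random instances with ties
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    v <- sample(1:6, n, replace = TRUE)  # heavy ties
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(feature_auc(v, l), auc_bruteforce(v, l))
  }
  # independent library cross-check
  set.seed(77)
  v <- rnorm(30)
  l <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(feature_auc(v, l),
               as.numeric(pROC::auc(pROC::roc(l, v, quiet = TRUE,
                                              direction = "<"))))
})

test_that("candidate selection applies all active filters", {
  s <- data.frame(id = c("4501", "4502", "4503", "4504"),
                  layer = "peak_max",
                  mean_control = 1, mean_disease = 2,
                  pct_diff = c(35, 10, 40, 45),
                  p_value = c(0.01, 0.001, 0.001, 0.04),
                  auc = c(0.75, 0.9, 0.69, 0.80),
                  stage_trend = c(TRUE, TRUE, TRUE, FALSE))
  sel <- select_candidates(s)
  expect_setequal(sel, c("4501", "4504"))
  expect_equal(sel, c("4504", "4501"))  # descending AUC
  expect_equal(select_candidates(s, require_stage_trend = TRUE), "4501")
  expect_equal(select_candidates(s, min_auc = 0),
               c("4504", "4501", "4503"))
})
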