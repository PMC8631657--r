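test_that("polarity combination takes the element-wise maximum", {
  pos <- matrix(c(1.0, 0.0), 1)
  neg <- matrix(c(0.5, 0.3), 1)
  expect_equal(combine_polarities(pos, neg), matrix(c(1.0, 0.3), 1))
  expect_equal(combine_polarities(pos, pos * 0), pos)
  expect_equal(combine_polarities(pos, pos), pos)
  expect_equal(combine_polarities(pos, neg, rule = "sum"), pos + neg)
  expect_error(combine_polarities(pos, matrix(0, 2, 2)), "shape")
})

test_that("blank subtraction is element-wise and clamped at zero", {
  mk <- function(v, df = 45L)
    df_matrix(df, c(-1, 1), 0:1, matrix(v, 2, 2))
  expect_equal(subtract_blank(mk(0.8), mk(0.3))$intensity,
               matrix(0.5, 2, 2))
  expect_equal(subtract_blank(mk(0.2), mk(0.5))$intensity,
               matrix(0, 2, 2))
  s <- mk(0.7)
  expect_true(all(subtract_blank(s, s)$intensity == 0))
  expect_equal(subtract_blank(s, mk(0.3))$provenance, "blank-subtracted")
  expect_error(subtract_blank(mk(1), mk(1, df = 55L)), "DF 55")
})

test_that("default crop turns the instrument grid into 256 x 3400", {
  m <- df_matrix(45L, seq(-6, 6, length.out = 512),
                 (0:3459) * (2164.1 / 3460),
                 matrix(0.001, 512, 3460))
  cropped <- crop_matrix(m)
  expect_equal(dim(cropped$intensity), c(256L, 3400L))
  expect_true(all(cropped$cf_axis >= -3 & cropped$cf_axis <= 3))
  expect_equal(cropped$provenance, "cropped")
  # dropped region here is all baseline
  expect_equal(attr(cropped, "baseline_fraction"), 1)
})

test_that("crop retains the closed CF interval and drops terminal points", {
  m <- df_matrix(45L, c(-6, -2, 2, 6), 0:9, matrix(1, 4, 10))
  out <- crop_matrix(m, cf_keep = c(-3, 3), terminal_points = 1L)
  expect_equal(dim(out$intensity), c(2L, 9L))
  expect_equal(out$cf_axis, c(-2, 2))
  # identity crop
  id <- crop_matrix(m, cf_keep = c(-6, 6), terminal_points = 0L)
  expect_equal(id$intensity, m$intensity)
  # boundary values +-3 V are included (closed interval)
  m2 <- df_matrix(45L, c(-3, 0, 3), 0:4, matrix(1, 3, 5))
  expect_equal(crop_matrix(m2, terminal_points = 1L)$cf_axis, c(-3, 0, 3))
  expect_error(crop_matrix(m, cf_keep = c(4, 5), terminal_points = 0L),
               "empty")
})

test_that("chromatogram collapse takes the per-time-point CF maximum", {
  m <- df_matrix(45L, c(-1, 1), 0:1, matrix(c(1, 3, 2, 1), 2, 2))
  sc <- collapse_to_chromatogram(m)
  expect_equal(sc$intensity, c(3, 2))
  z <- collapse_to_chromatogram(df_matrix(45L, c(-1, 1), 0:2,
                                          matrix(0, 2, 3)))
  expect_true(all(z$intensity == 0))
  # max commutes with collapsing
  cfg <- small_config(n_per_stage = c(1L, 0L, 0L, 0L),
                      n_technical_replicates = 1L)
  run <- generate_cohort(cfg)$runs[[1]]
  comb <- combine_polarities(run$matrices[["45"]]$pos,
                             run$matrices[["45"]]$neg)
  dm <- df_matrix(45L, run$cf_axis, run$time_axis, comb)
  expect_equal(max(collapse_to_chromatogram(dm)$intensity), max(comb))
})

test_that("preprocess_run composes the three steps per DF", {
  cfg <- noiseless_config(n_per_stage = c(1L, 0L, 0L, 0L),
                          n_technical_replicates = 1L)
  co <- generate_cohort(cfg)
  m <- co$manifest[1, ]
  run <- co$runs[[m$sample_id]]
  blank <- co$runs[[m$room_air_id]]

  scs <- preprocess_run(run, terminal_points = 10L)
  expect_named(scs, c("45", "55", "65"))
  expect_length(scs[["45"]]$intensity, 190L)

  # all-zero blank is the identity
  zero_blank <- blank
  for (df in c("45", "55", "65"))
    for (pol in c("pos", "neg"))
      zero_blank$matrices[[df]][[pol]][] <- 0
  same <- preprocess_run(run, blank = zero_blank, mode = "room_air",
                         terminal_points = 10L)
  for (df in c("45", "55", "65"))
    expect_equal(same[[df]]$intensity, scs[[df]]$intensity)

  # real blank removes the environmental peak at its retention index while
  # leaving endogenous maxima untouched
  sub <- preprocess_run(run, blank = blank, mode = "room_air",
                        terminal_points = 10L)
  env45 <- cfg$peaks[[which(vapply(cfg$peaks, function(p)
    p$kind == "environmental" && p$df_setting == 45L, TRUE))[1]]]
  expect_equal(sub[["45"]]$intensity[env45$rt_center + 1L], 0,
               tolerance = 1e-12)
  endo45 <- cfg$peaks[[which(vapply(cfg$peaks, function(p)
    p$kind == "endogenous" && p$df_setting == 45L, TRUE))[1]]]
  expect_equal(sub[["45"]]$intensity[endo45$rt_center + 1L],
               scs[["45"]]$intensity[endo45$rt_center + 1L])

  # crop-then-collapse equals collapsing the cropped region directly
  comb <- combine_polarities(run$matrices[["45"]]$pos,
                             run$matrices[["45"]]$neg)
  dm <- df_matrix(45L, run$cf_axis, run$time_axis, comb)
  direct <- apply(crop_matrix(dm, terminal_points = 10L)$intensity, 2, max)
  expect_equal(scs[["45"]]$intensity, direct)

  expect_error(preprocess_run(run, mode = "room_air"), "requires a blank")
})
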