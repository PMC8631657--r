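# Cohorts here use the reduced 32 x 200 grid; the separable cohort plants a
# marker effect far above the noise floor so the classes are cleanly
# separated in chromatogram space.

paper_subjects <- data.frame(
  subject_id = sprintf("S%02d", 1:50),
  stage = rep(0:3, times = c(11, 14, 15, 10)))

test_that("stage-stratified split reproduces the study's training design", {
  split <- make_training_split(paper_subjects, per_stage = 6L, seed = 9L)
  expect_length(split$train, 24L)
  expect_length(split$validation, 26L)
  expect_length(intersect(split$train, split$validation), 0L)
  for (s in 0:3)
    expect_equal(sum(paper_subjects$stage[paper_subjects$subject_id %in%
                                            split$train] == s), 6L)
  expect_identical(split, make_training_split(paper_subjects, 6L, 9L))
  expect_false(identical(split,
                         make_training_split(paper_subjects, 6L, 10L)))
  expect_error(make_training_split(paper_subjects[1:45, ], 6L, 1L),
               "stage 3")
})

test_that("training is seeded, stratified, and leakage is caught", {
  cfg <- separable_config()
  co <- generate_cohort(cfg)
  x <- cohort_sc_matrix(co, mode = "none", terminal_points = 10L)
  tl <- task_labels(co$manifest, "cirrhosis_detection")
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  in_train <- tl$manifest$subject_id %in% split$train
  spec <- classifier_spec("gaussian_svm", seed = 5L)
  m1 <- train_classifier(x[in_train, ], tl$labels[in_train], spec)
  m2 <- train_classifier(x[in_train, ], tl$labels[in_train], spec)
  expect_identical(m1$cv, m2$cv)
  expect_error(train_classifier(x[1:7, ], c(TRUE, rep(FALSE, 6)), spec,
                                folds = 5L), "stratification")
  expect_error(
    evaluate_classifier(m1, x[!in_train, ], tl$labels[!in_train],
                        subject_ids = tl$manifest$subject_id[!in_train],
                        train_subject_ids = c(split$train,
                                              split$validation[1])),
    "leakage")
})

test_that("a separable cohort is classified perfectly by the Gaussian SVM", {
  cfg <- separable_config()
  co <- generate_cohort(cfg)
  x <- cohort_sc_matrix(co, mode = "none", terminal_points = 10L)
  tl <- task_labels(co$manifest, "cirrhosis_detection")
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  in_train <- tl$manifest$subject_id %in% split$train
  m <- train_classifier(x[in_train, ], tl$labels[in_train],
                        classifier_spec("gaussian_svm", seed = 5L))
  ev <- evaluate_classifier(m, x[!in_train, ], tl$labels[!in_train],
                            subject_ids =
                              tl$manifest$subject_id[!in_train],
                            train_subject_ids =
                              tl$manifest$subject_id[in_train])
  expect_equal(ev$per_sample$sensitivity, 1)
  expect_equal(ev$per_sample$specificity, 1)
  expect_equal(ev$per_subject$sensitivity, 1)
  expect_equal(ev$per_subject$specificity, 1)
  # confusion-matrix marginals equal validation class counts
  expect_equal(sum(ev$per_sample$confusion), sum(!in_train))
  expect_equal(colSums(ev$per_sample$confusion),
               c(pos = sum(tl$labels[!in_train]),
                 neg = sum(!tl$labels[!in_train])))
})

test_that("all four registry algorithms train and score in [0, 1]", {
  cfg <- separable_config()
  co <- generate_cohort(cfg)
  x <- cohort_sc_matrix(co, mode = "none", terminal_points = 10L)
  tl <- task_labels(co$manifest, "cirrhosis_detection")
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  in_train <- tl$manifest$subject_id %in% split$train
  for (algo in c("rus_boosted_trees", "subspace_knn", "gaussian_nb",
                 "gaussian_svm")) {
    m <- train_classifier(x[in_train, ], tl$labels[in_train],
                          classifier_spec(algo, seed = 5L))
    ev <- evaluate_classifier(m, x[!in_train, ], tl$labels[!in_train])
    expect_true(all(ev$scores >= 0 & ev$scores <= 1), label = algo)
    expect_gte(ev$per_sample$auc, 0.9)
    expect_length(m$cv$fold_auc, 5L)
  }
  expect_error(classifier_spec("logistic"), "algorithm must be one of")
})

test_that("model selection is strict at the AUC boundary", {
  fake <- function(auc, name) structure(
    list(spec = list(algorithm = name), cv = list(auc = auc)),
    class = "trained_classifier")
  models <- list(a = fake(0.71, "a"), b = fake(0.70, "b"),
                 c = fake(0.90, "c"))
  kept <- select_models(models, min_auc = 0.7)
  expect_equal(names(kept), c("c", "a"))  # strict, descending AUC
  expect_length(select_models(list(), 0.7), 0L)
})

test_that("blank-mode ablation reports one row per mode", {
  cfg <- separable_config(n_per_stage = c(7L, 7L, 7L, 7L))
  co <- generate_cohort(cfg)
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  tab <- ablate_blank_mode(co, classifier_spec("gaussian_svm", seed = 5L),
                           split, folds = 5L, terminal_points = 10L)
  expect_equal(tab$mode, c("none", "air_filter", "room_air"))
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})

test_that("tandem cascade routes samples detector-first", {
  cfg <- separable_config(stage_effect = c(1, 4, 4, 8))
  co <- generate_cohort(cfg)
  x <- cohort_sc_matrix(co, mode = "none", terminal_points = 10L)
  tl <- task_labels(co$manifest, "cirrhosis_detection")
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  in_train <- tl$manifest$subject_id %in% split$train
  detector <- train_classifier(x[in_train, ], tl$labels[in_train],
                               classifier_spec("gaussian_svm", seed = 5L))
  dis <- in_train & tl$manifest$stage >= 1L
  stager <- train_classifier(x[dis, ], tl$manifest$stage[dis] == 3L,
                             classifier_spec("gaussian_svm", seed = 5L),
                             folds = 3L)
  tm <- build_tandem(detector, stager)
  val <- !in_train
  pred <- predict_tandem(tm, x[val, , drop = FALSE])
  truth <- factor(ifelse(tl$manifest$stage[val] == 0L, "no_disease",
                         ifelse(tl$manifest$stage[val] == 3L,
                                "decompensated", "compensated")),
                  levels = levels(pred))
  # perfect components give perfect 3-class output
  expect_equal(mean(pred == truth), 1)
  expect_equal(unname(diag(table(pred, truth))),
               unname(as.vector(table(truth))))
  # any-disease sensitivity equals the detector's by construction
  det_pos <- score_algorithm(detector$fit, x[val, , drop = FALSE]) >= 0.5
  expect_equal(mean(pred[truth != "no_disease"] != "no_disease"),
               mean(det_pos[truth != "no_disease"]))
  # cutoff above every score: detector always negative -> all no_disease
  all_neg <- predict_tandem(tm, x[val, , drop = FALSE], cutoff = 1.1)
  expect_true(all(all_neg == "no_disease"))
  # feature-length mismatch is rejected
  stager_bad <- stager
  stager_bad$fit$p <- 10L
  expect_error(build_tandem(detector, stager_bad), "feature-length")
})

test_that("label-permuted training gives chance-level validation AUC", {
  cfg <- separable_config(n_per_stage = c(8L, 8L, 8L, 8L),
                          n_technical_replicates = 2L)
  co <- generate_cohort(cfg)
  x <- cohort_sc_matrix(co, mode = "none", terminal_points = 10L)
  tl <- task_labels(co$manifest, "cirrhosis_detection")
  split <- make_training_split(co$truth$subjects, per_stage = 6L, seed = 3L)
  in_train <- tl$manifest$subject_id %in% split$train
  set.seed(404)
  aucs <- replicate(20, {
    yperm <- sample(tl$labels[in_train])
    m <- train_classifier(x[in_train, ], yperm,
                          classifier_spec("gaussian_svm", seed = 5L),
                          folds = 2L)
    evaluate_classifier(m, x[!in_train, ],
                        tl$labels[!in_train])$per_sample$auc
  })
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
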