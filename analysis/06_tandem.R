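# Build the tandem cascade: a cirrhosis detector followed by a stage-3
# (decompensation) stager applied only to detector-positive samples, and
# report the 3-class confusion matrix on the validation subjects.

source("analysis/00_config.R")

cfg <- study_config()
cohort <- generate_cohort(cfg)
split <- make_training_split(cohort$truth$subjects, per_stage = 6L,
                             seed = SPLIT_SEED)
x <- cohort_sc_matrix(cohort, mode = "none",
                      terminal_points = TERMINAL_POINTS)
tl <- task_labels(cohort$manifest, "cirrhosis_detection")
x <- x[tl$manifest$sample_id, , drop = FALSE]
in_train <- tl$manifest$subject_id %in% split$train

detector <- train_classifier(x[in_train, ], tl$labels[in_train],
                             classifier_spec("rus_boosted_trees",
                                             seed = CLASSIFIER_SEED))
dis <- in_train & tl$manifest$stage >= 1L
stager <- train_classifier(x[dis, ], tl$manifest$stage[dis] == 3L,
                           classifier_spec("gaussian_svm",
                                           seed = CLASSIFIER_SEED))
tandem <- build_tandem(detector, stager)

val <- !in_train
pred <- predict_tandem(tandem, x[val, , drop = FALSE])
truth <- factor(ifelse(tl$manifest$stage[val] == 0L, "no_disease",
                       ifelse(tl$manifest$stage[val] == 3L,
                              "decompensated", "compensated")),
                levels = levels(pred))
conf <- table(pred = pred, truth = truth)
cat(sprintf("tandem 3-class accuracy: %.1f%%\n",
            100 * mean(pred == truth)))
print(conf)
write.csv(as.data.frame(conf), file.path(RESULTS_DIR,
                                         "tandem_confusion.csv"),
          row.names = FALSE)
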