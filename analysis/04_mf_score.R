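# Fit the MF score (logistic regression on the best stage-trending
# molecular feature), characterize its ROC, the 0.45 operating point, and
# the per-stage trend.

source("analysis/00_config.R")

cfg <- study_config()
cohort <- generate_cohort(cfg)
m <- cohort$manifest
scs <- lapply(stats::setNames(m$sample_id, m$sample_id), function(sid)
  preprocess_run(cohort$runs[[sid]], terminal_points = TERMINAL_POINTS))
tab <- build_feature_table(scs, m)

model <- fit_mf_score(tab)
cat(sprintf("MF score model: feature %s, intercept %.3f, coefficient %.3f\n",
            model$mf_ids, model$intercept, model$coefficients))

scores <- score_samples(model, tab)
report <- roc_and_operating_point(scores, tab$subjects$stage > 0L,
                                  cutoff = 0.45)
cat(sprintf("MF score AUC %.3f; at cutoff 0.45: sensitivity %.0f%%, specificity %.0f%%\n",
            report$auc, 100 * report$sensitivity,
            100 * report$specificity))

trend <- stage_trend(scores, tab$subjects$stage)
print(trend$by_stage)

write.csv(report$roc, file.path(RESULTS_DIR, "mf_score_roc.csv"),
          row.names = FALSE)
write.csv(trend$by_stage, file.path(RESULTS_DIR, "mf_score_by_stage.csv"),
          row.names = FALSE)
write.csv(data.frame(subject_id = names(scores), score = scores,
                     stage = tab$subjects$stage),
          file.path(RESULTS_DIR, "mf_scores.csv"), row.names = FALSE)
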