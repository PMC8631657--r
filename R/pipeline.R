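# End-to-end orchestration: simulate -> preprocess -> molecular features ->
# MF score -> classifiers (with blank-mode ablation) -> tandem ->
# variability, from one configuration object, with every intermediate
# available in the returned report and optionally serialized.

#' Pipeline parameters
#'
#' Collects the analysis constants: the 0.5 pA feature threshold, the
#' \[-3, 3\] V crop and 60 terminal points, 6 training subjects per stage,
#' 5-fold CV, strict AUC > 0.7 model selection, the 0.45 MF-score cutoff and
#' the 2048-value embedding length, plus the seeds of every stochastic
#' stage.
#'
#' @param threshold MF detection threshold in pA.
#' @param min_separation,rt_tolerance feature detection/matching windows in
#'   time points.
#' @param cf_keep,terminal_points crop parameters.
#' @param per_stage training subjects per stage.
#' @param folds CV folds.
#' @param min_auc strict CV-AUC selection bound.
#' @param cutoff MF-score operating cutoff.
#' @param embedding_length variability embedding length.
#' @param blank_mode blank-subtraction mode used for the feature/score/
#'   classifier branches ("none", "room_air" or "air_filter").
#' @param detector_algorithm,stager_algorithm tandem component algorithms.
#' @param split_seed,classifier_seed seeds for the split and the fits.
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(threshold = 0.5, min_separation = 5L,
                            rt_tolerance = 10L, cf_keep = c(-3, 3),
                            terminal_points = 60L, per_stage = 6L,
                            folds = 5L, min_auc = 0.7, cutoff = 0.45,
                            embedding_length = 2048L,
                            blank_mode = "none",
                            detector_algorithm = "rus_boosted_trees",
                            stager_algorithm = "gaussian_svm",
                            split_seed = 1L, classifier_seed = 1L) {
  structure(list(threshold = threshold, min_separation = min_separation,
                 rt_tolerance = rt_tolerance, cf_keep = cf_keep,
                 terminal_points = terminal_points, per_stage = per_stage,
                 folds = folds, min_auc = min_auc, cutoff = cutoff,
                 embedding_length = embedding_length,
                 blank_mode = blank_mode,
                 detector_algorithm = detector_algorithm,
                 stager_algorithm = stager_algorithm,
                 split_seed = split_seed,
                 classifier_seed = classifier_seed),
            class = "pipeline_params")
}

pipeline_stage <- function(stage, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param params a [pipeline_params()].
#' @param out_dir optional directory; when given, the manifest, feature
#'   table, MF statistics, score report, classifier metrics, tandem
#'   confusion matrix, EMD table and a JSON summary are written there.
#' @return a report list with elements `manifest`, `mf_counts`,
#'   `feature_table`, `mf_stats`, `selected_mf`, `mf_score`,
#'   `classifiers`, `ablation`, `tandem`, `variability`, `seeds`.
#' @export
run_pipeline <- function(config, params = pipeline_params(),
                         out_dir = NULL) {
  cohort <- pipeline_stage("simulate", generate_cohort(config))
  manifest <- cohort$manifest

  scs <- pipeline_stage("preprocess", {
    breath <- manifest$sample_id
    stats::setNames(lapply(seq_along(breath), function(i) {
      blank <- switch(params$blank_mode,
                      none = NULL,
                      room_air = cohort$runs[[manifest$room_air_id[i]]],
                      air_filter = cohort$runs[[manifest$air_filter_id[i]]])
      preprocess_run(cohort$runs[[breath[i]]], blank = blank,
                     mode = params$blank_mode, cf_keep = params$cf_keep,
                     terminal_points = params$terminal_points)
    }), breath)
  })

  table <- pipeline_stage("features",
    build_feature_table(scs, manifest, threshold = params$threshold,
                        min_separation = params$min_separation,
                        rt_tolerance = params$rt_tolerance))
  mf_counts <- vapply(c("45", "55", "65"), function(df)
    sum(table$features$df_voltage == as.integer(df)), 0L)

  stats <- pipeline_stage("stats", compare_groups(table))
  selected <- pipeline_stage("select",
    select_candidates(stats, min_pct = 30, max_p = 0.05,
                      min_auc = params$min_auc))

  mf_score <- pipeline_stage("score", {
    model <- fit_mf_score(table)
    scores <- score_samples(model, table)
    report <- roc_and_operating_point(scores, table$subjects$stage > 0L,
                                      cutoff = params$cutoff)
    trend <- stage_trend(scores, table$subjects$stage)
    list(model = model, scores = scores, report = report, trend = trend)
  })

  split <- pipeline_stage("split",
    make_training_split(cohort$truth$subjects,
                        per_stage = params$per_stage,
                        seed = params$split_seed))

  classifiers <- pipeline_stage("train", {
    tl <- task_labels(manifest, "cirrhosis_detection")
    x <- cohort_sc_matrix(cohort, mode = params$blank_mode,
                          cf_keep = params$cf_keep,
                          terminal_points = params$terminal_points)
    x <- x[tl$manifest$sample_id, , drop = FALSE]
    in_train <- tl$manifest$subject_id %in% split$train
    trained <- lapply(ALGORITHMS, function(algo)
      train_classifier(x[in_train, , drop = FALSE], tl$labels[in_train],
                       classifier_spec(algo, label_task =
                                         "cirrhosis_detection",
                                       seed = params$classifier_seed),
                       folds = params$folds))
    names(trained) <- ALGORITHMS
    kept <- select_models(trained, min_auc = params$min_auc)
    evaluated <- lapply(kept, function(m)
      evaluate_classifier(m, x[!in_train, , drop = FALSE],
                          tl$labels[!in_train],
                          subject_ids = tl$manifest$subject_id[!in_train],
                          train_subject_ids =
                            tl$manifest$subject_id[in_train]))
    list(x = x, task = tl, in_train = in_train, trained = trained,
         selected = kept, evaluated = evaluated)
  })

  ablation <- pipeline_stage("ablate",
    ablate_blank_mode(cohort,
                      classifier_spec(params$detector_algorithm,
                                      label_task = "cirrhosis_detection",
                                      seed = params$classifier_seed),
                      split, folds = params$folds,
                      cf_keep = params$cf_keep,
                      terminal_points = params$terminal_points))

  tandem <- pipeline_stage("tandem", {
    tl <- classifiers$task
    x <- classifiers$x
    in_train <- classifiers$in_train
    detector <- train_classifier(
      x[in_train, , drop = FALSE], tl$labels[in_train],
      classifier_spec(params$detector_algorithm,
                      label_task = "cirrhosis_detection",
                      seed = params$classifier_seed),
      folds = params$folds)
    dis_train <- in_train & tl$manifest$stage >= 1L
    stager <- train_classifier(
      x[dis_train, , drop = FALSE],
      tl$manifest$stage[dis_train] == 3L,
      classifier_spec(params$stager_algorithm,
                      label_task = "stage3_detection",
                      seed = params$classifier_seed),
      folds = min(params$folds,
                  min(table(tl$manifest$stage[dis_train] == 3L))))
    tm <- build_tandem(detector, stager)
    val <- !in_train
    pred <- predict_tandem(tm, x[val, , drop = FALSE])
    truth <- factor(ifelse(tl$manifest$stage[val] == 0L, "no_disease",
                           ifelse(tl$manifest$stage[val] == 3L,
                                  "decompensated", "compensated")),
                    levels = levels(pred))
    list(model = tm, confusion = table(pred = pred, truth = truth),
         accuracy = mean(pred == truth))
  })

  variability <- pipeline_stage("variability",
    variability_report(cohort, length = params$embedding_length))

  report <- list(manifest = manifest, mf_counts = mf_counts,
                 feature_table = table, mf_stats = stats,
                 selected_mf = selected, mf_score = mf_score,
                 classifiers = classifiers[c("trained", "selected",
                                             "evaluated")],
                 ablation = ablation, tandem = tandem,
                 variability = variability,
                 seeds = list(cohort = config$seed,
                              split = params$split_seed,
                              classifier = params$classifier_seed),
                 params = params)
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id =
                                rownames(report$feature_table$peak_max),
                              report$feature_table$peak_max,
                              check.names = FALSE),
                   file.path(out_dir, "feature_table_peak_max.csv"),
                   row.names = FALSE)
  utils::write.csv(report$mf_stats, file.path(out_dir, "mf_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ablation, file.path(out_dir, "ablation.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$tandem$confusion),
                   file.path(out_dir, "tandem_confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variability$by_group,
                   file.path(out_dir, "emd.csv"), row.names = FALSE)
  summary <- list(
    mf_counts = as.list(report$mf_counts),
    selected_mf = report$selected_mf,
    mf_score = list(auc = report$mf_score$report$auc,
                    cutoff = report$mf_score$report$cutoff,
                    sensitivity = report$mf_score$report$sensitivity,
                    specificity = report$mf_score$report$specificity),
    selected_classifiers = names(report$classifiers$selected),
    tandem_accuracy = report$tandem$accuracy,
    emd = list(within_technical = report$variability$within_technical,
               within_biological = report$variability$within_biological,
               between_subject = report$variability$between_subject),
    seeds = report$seeds)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
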