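# Supervised classification of full separation chromatograms: stage-
# stratified training split (6 subjects per stage by default), stratified
# 5-fold cross-validation, strict AUC > 0.7 model selection, independent
# validation on held-out subjects, blank-subtraction ablation, and tandem
# (cascade) staging.

#' Classifier specification
#'
#' @param algorithm one of "rus_boosted_trees", "subspace_knn",
#'   "gaussian_nb", "gaussian_svm".
#' @param params named list of algorithm hyperparameters (see the
#'   algorithm registry defaults).
#' @param label_task "cirrhosis_detection" (disease vs stage 0) or
#'   "stage3_detection" (decompensated vs stages 1-2, among diseased).
#' @param include_ncph whether non-cirrhotic portal-hypertension subjects
#'   are kept (as positives for detection) or dropped.
#' @param seed integer seed used for every stochastic step of the fit.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, params = list(),
                            label_task = c("cirrhosis_detection",
                                           "stage3_detection"),
                            include_ncph = FALSE, seed = 1L) {
  if (!algorithm %in% ALGORITHMS)
    stop("algorithm must be one of: ",
         paste(ALGORITHMS, collapse = ", "), call. = FALSE)
  label_task <- match.arg(label_task)
  structure(list(algorithm = algorithm, params = params,
                 label_task = label_task, include_ncph = include_ncph,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Stage-stratified training/validation split
#'
#' Draws `per_stage` subjects at random from each stage for training; the
#' remainder form the validation set. With the study's stage counts
#' (11/14/15/10) and the default of 6 per stage this gives 24 training and
#' 26 validation subjects.
#'
#' @param subjects data.frame with `subject_id` and `stage` columns.
#' @param per_stage training subjects per stage.
#' @param seed integer seed.
#' @param stages stages participating in the split (default 0-3).
#' @return list with `train` and `validation` subject-id vectors.
#' @export
make_training_split <- function(subjects, per_stage = 6L, seed = 1L,
                                stages = 0:3) {
  subjects <- subjects[subjects$stage %in% stages, , drop = FALSE]
  for (s in stages) {
    n_s <- sum(subjects$stage == s)
    if (n_s < per_stage)
      stop(sprintf(
        "stage %d has only %d subjects; %d required for the training split",
        s, n_s, per_stage), call. = FALSE)
  }
  with_seed(seed, {
    train <- unlist(lapply(stages, function(s)
      sample(subjects$subject_id[subjects$stage == s], per_stage)))
  })
  list(train = sort(train),
       validation = sort(setdiff(subjects$subject_id, train)))
}

stratified_folds <- function(y, folds) {
  if (min(table(y)) < folds)
    stop(sprintf(
      "stratification error: smallest class has %d samples for %d folds",
      min(table(y)), folds), call. = FALSE)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

classification_metrics <- function(scores, labels, cutoff = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
  list(confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("pos", "neg"),
                                          truth = c("pos", "neg"))),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       auc = if (tp + fn > 0 && tn + fp > 0)
         feature_auc(scores, labels) else NA_real_)
}

#' Train a chromatogram classifier with cross-validation
#'
#' Stratified k-fold cross-validation (pooled CV scores give the CV AUC and
#' confusion matrix) followed by a final fit on all training data. All
#' random draws (fold assignment, undersampling, subspaces) are governed by
#' `spec$seed`.
#'
#' @param x sample-by-feature matrix of separation-chromatogram intensities
#'   (rownames = sample ids).
#' @param labels logical labels aligned with rows of `x`.
#' @param spec a [classifier_spec()].
#' @param folds number of CV folds (>= 2).
#' @return a `trained_classifier`: list with `spec`, `fit`, `cv`
#'   (pooled metrics, per-fold AUC, fold assignment) and `n_train`.
#' @export
train_classifier <- function(x, labels, spec, folds = 5L) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.logical(labels)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  with_seed(spec$seed, {
    fold <- stratified_folds(labels, folds)
    cv_scores <- rep(NA_real_, length(labels))
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit_f <- fit_algorithm(x[tr, , drop = FALSE], labels[tr],
                             spec$algorithm, spec$params)
      cv_scores[!tr] <- score_algorithm(fit_f, x[!tr, , drop = FALSE])
      fold_auc[f] <- feature_auc(cv_scores[!tr], labels[!tr])
    }
    fit <- fit_algorithm(x, labels, spec$algorithm, spec$params)
    cv <- classification_metrics(cv_scores, labels)
    cv$fold_auc <- fold_auc
    cv$fold <- fold
    cv$scores <- cv_scores
    structure(list(spec = spec, fit = fit, cv = cv,
                   n_train = nrow(x),
                   train_samples = rownames(x)),
              class = "trained_classifier")
  })
}

#' Filter trained classifiers by cross-validated AUC
#'
#' Retains classifiers whose pooled CV AUC is strictly greater than
#' `min_auc`, ordered by decreasing AUC.
#'
#' @param trained list of `trained_classifier`.
#' @param min_auc strict lower bound on the pooled CV AUC.
#' @return filtered, reordered list (possibly empty).
#' @export
select_models <- function(trained, min_auc = 0.7) {
  aucs <- vapply(trained, function(m) m$cv$auc, 0)
  keep <- which(aucs > min_auc)
  trained[keep[order(-aucs[keep])]]
}

#' Evaluate a trained classifier on held-out samples
#'
#' Computes the confusion matrix, sensitivity, specificity and AUC on the
#' validation samples, and additionally per subject (majority score across a
#' subject's samples) when `subject_ids` is given. Training/validation
#' subject disjointness is asserted when both id sets are available.
#'
#' @param model a `trained_classifier`.
#' @param x validation sample-by-feature matrix.
#' @param labels validation labels.
#' @param subject_ids optional per-row subject ids of `x`.
#' @param train_subject_ids optional subject ids used in training; overlap
#'   with `subject_ids` raises a leakage error.
#' @return list with `per_sample` metrics, `per_subject` metrics (or NULL)
#'   and the validation `scores`.
#' @export
evaluate_classifier <- function(model, x, labels, subject_ids = NULL,
                                train_subject_ids = NULL) {
  stopifnot(inherits(model, "trained_classifier"))
  if (!is.null(subject_ids) && !is.null(train_subject_ids)) {
    overlap <- intersect(unique(subject_ids), unique(train_subject_ids))
    if (length(overlap))
      stop("leakage error: subjects present in both training and validation: ",
           paste(overlap, collapse = ", "), call. = FALSE)
  }
  labels <- as.logical(labels)
  scores <- score_algorithm(model$fit, x)
  per_sample <- classification_metrics(scores, labels)
  per_subject <- NULL
  if (!is.null(subject_ids)) {
    sscore <- tapply(scores, subject_ids, mean)
    slabel <- tapply(labels, subject_ids, function(v) v[1])
    per_subject <- classification_metrics(as.numeric(sscore),
                                          as.logical(slabel))
  }
  list(per_sample = per_sample, per_subject = per_subject, scores = scores)
}

#' Task labels for a cohort manifest
#'
#' @param manifest breath-sample manifest rows.
#' @param task "cirrhosis_detection" labels stage >= 1 positive (cirrhosis
#'   or portal hypertension); "stage3_detection" restricts to diseased
#'   subjects and labels stage 3 positive.
#' @param include_ncph if FALSE, non-cirrhotic portal-hypertension samples
#'   are dropped.
#' @return list with `manifest` (possibly filtered) and logical `labels`.
#' @export
task_labels <- function(manifest, task = c("cirrhosis_detection",
                                           "stage3_detection"),
                        include_ncph = FALSE) {
  task <- match.arg(task)
  m <- manifest[manifest$sample_type == "breath" & !manifest$excluded, ,
                drop = FALSE]
  if (!include_ncph) m <- m[!m$ncph, , drop = FALSE]
  if (task == "stage3_detection") m <- m[m$stage >= 1L, , drop = FALSE]
  labels <- if (task == "cirrhosis_detection") m$stage >= 1L
            else m$stage == 3L
  list(manifest = m, labels = labels)
}

#' Assemble the classifier feature matrix for a cohort
#'
#' Preprocesses every breath sample under the requested blank-subtraction
#' mode and concatenates its separation chromatograms (all three DF
#' settings by default) into one feature vector per sample.
#'
#' @param cohort output of [generate_cohort()] (or a compatible list with
#'   `runs` and `manifest`).
#' @param mode blank-subtraction mode: "none", "room_air" or "air_filter".
#' @param df_settings DF planes to concatenate, subset of c("45","55","65").
#' @param cf_keep,terminal_points crop parameters passed to
#'   [preprocess_run()].
#' @return sample-by-feature matrix with sample ids as rownames.
#' @export
cohort_sc_matrix <- function(cohort, mode = "none",
                             df_settings = c("45", "55", "65"),
                             cf_keep = c(-3, 3), terminal_points = 60L) {
  m <- cohort$manifest
  m <- m[m$sample_type == "breath", , drop = FALSE]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    run <- cohort$runs[[m$sample_id[i]]]
    blank <- switch(mode,
                    none = NULL,
                    room_air = cohort$runs[[m$room_air_id[i]]],
                    air_filter = cohort$runs[[m$air_filter_id[i]]])
    if (mode != "none" && is.null(blank))
      stop(sprintf("missing %s blank for sample %s", mode, m$sample_id[i]),
           call. = FALSE)
    scs <- preprocess_run(run, blank = blank, mode = mode,
                          cf_keep = cf_keep,
                          terminal_points = terminal_points)
    unlist(lapply(df_settings, function(df) scs[[df]]$intensity),
           use.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- m$sample_id
  out
}

#' Blank-subtraction ablation
#'
#' Trains and validates the same classifier specification under the three
#' blank-subtraction modes, reusing one training split, and tabulates the
#' validation metrics.
#'
#' @param cohort output of [generate_cohort()].
#' @param spec a [classifier_spec()].
#' @param split a [make_training_split()] result.
#' @param folds CV folds.
#' @param df_settings,cf_keep,terminal_points see [cohort_sc_matrix()].
#' @return data.frame with one row per mode: sensitivity, specificity, AUC
#'   (per-sample validation metrics).
#' @export
ablate_blank_mode <- function(cohort, spec, split, folds = 5L,
                              df_settings = c("45", "55", "65"),
                              cf_keep = c(-3, 3), terminal_points = 60L) {
  tl <- task_labels(cohort$manifest, spec$label_task, spec$include_ncph)
  rows <- lapply(c("none", "air_filter", "room_air"), function(mode) {
    x <- cohort_sc_matrix(cohort, mode = mode, df_settings = df_settings,
                          cf_keep = cf_keep,
                          terminal_points = terminal_points)
    x <- x[tl$manifest$sample_id, , drop = FALSE]
    in_train <- tl$manifest$subject_id %in% split$train
    model <- train_classifier(x[in_train, , drop = FALSE],
                              tl$labels[in_train], spec, folds = folds)
    ev <- evaluate_classifier(model, x[!in_train, , drop = FALSE],
                              tl$labels[!in_train],
                              subject_ids = tl$manifest$subject_id[!in_train],
                              train_subject_ids =
                                tl$manifest$subject_id[in_train])
    data.frame(mode = mode,
               sensitivity = ev$per_sample$sensitivity,
               specificity = ev$per_sample$specificity,
               auc = ev$per_sample$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine a disease detector and a stage-3 stager into a tandem model
#'
#' @param detector `trained_classifier` for disease vs no disease.
#' @param stager `trained_classifier` for decompensated (stage 3) vs
#'   compensated disease.
#' @return a `tandem_model`.
#' @export
build_tandem <- function(detector, stager) {
  stopifnot(inherits(detector, "trained_classifier"),
            inherits(stager, "trained_classifier"))
  if (detector$fit$p != stager$fit$p)
    stop(sprintf("feature-length mismatch: detector %d vs stager %d",
                 detector$fit$p, stager$fit$p), call. = FALSE)
  structure(list(detector = detector, stager = stager),
            class = "tandem_model")
}

#' Predict 3-class disease state with a tandem model
#'
#' Detector-negative samples are labelled "no_disease"; detector-positive
#' samples are sub-classified by the stager into "compensated" or
#' "decompensated". The stager is only ever applied to detector-positive
#' samples, so the tandem's any-disease sensitivity equals the detector's.
#'
#' @param tandem a `tandem_model`.
#' @param x sample-by-feature matrix.
#' @param cutoff score cutoff applied to both components.
#' @return factor with levels no_disease, compensated, decompensated.
#' @export
predict_tandem <- function(tandem, x, cutoff = 0.5) {
  stopifnot(inherits(tandem, "tandem_model"))
  det <- score_algorithm(tandem$detector$fit, x) >= cutoff
  out <- rep("no_disease", nrow(x))
  if (any(det)) {
    st <- score_algorithm(tandem$stager$fit,
                          x[det, , drop = FALSE]) >= cutoff
    out[det] <- ifelse(st, "decompensated", "compensated")
  }
  factor(out, levels = c("no_disease", "compensated", "decompensated"))
}
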