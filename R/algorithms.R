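# Classifier algorithm registry. Each algorithm provides fit(x, y, params)
# and a score method returning P(positive) in [0, 1]. The four entries are
# the ones reported in the study: random under-sampling boosted trees
# (RUSBT), subspace k-nearest neighbours (SKNN), Gaussian naive Bayes (GNB)
# and a "medium" Gaussian-kernel SVM (GSVM, kernel scale sqrt(p)).
#
# RUSBT and the random-subspace kNN ensemble are implemented here on top of
# rpart and class::knn; GNB and GSVM wrap e1071. Fits that draw random
# numbers (undersampling, subspace draws) consume the caller's RNG stream,
# so train_classifier()'s seed makes them reproducible.

ALGORITHMS <- c("rus_boosted_trees", "subspace_knn", "gaussian_nb",
                "gaussian_svm")

as_design <- function(x) {
  x <- as.matrix(x)
  colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  x
}

fit_algorithm <- function(x, y, algorithm, params = list()) {
  x <- as_design(x)
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  model <- switch(algorithm,
                  rus_boosted_trees = fit_rusbt(x, y, params),
                  subspace_knn = fit_sknn(x, y, params),
                  gaussian_nb = fit_gnb(x, y, params),
                  gaussian_svm = fit_gsvm(x, y, params),
                  stop(sprintf("unknown algorithm '%s'", algorithm),
                       call. = FALSE))
  structure(list(algorithm = algorithm, model = model, p = ncol(x)),
            class = "faims_classifier")
}

score_algorithm <- function(fit, x) {
  x <- as_design(x)
  if (ncol(x) != fit$p)
    stop(sprintf("feature-length mismatch: model expects %d, got %d",
                 fit$p, ncol(x)), call. = FALSE)
  switch(fit$algorithm,
         rus_boosted_trees = score_rusbt(fit$model, x),
         subspace_knn = score_sknn(fit$model, x),
         gaussian_nb = score_gnb(fit$model, x),
         gaussian_svm = score_gsvm(fit$model, x))
}

# ---- RUSBoost: AdaBoost.M1 with per-round random undersampling ----------

fit_rusbt <- function(x, y, params) {
  n_rounds <- params$n_rounds %||% 20L
  maxdepth <- params$maxdepth %||% 3L
  n <- nrow(x)
  w <- rep(1 / n, n)
  pos <- which(y); neg <- which(!y)
  n_bal <- min(length(pos), length(neg))
  learners <- list(); alphas <- numeric()
  for (t in seq_len(n_rounds)) {
    take <- function(idx) {
      if (length(idx) == n_bal) return(idx)
      pr <- w[idx]
      if (sum(pr) == 0) pr <- rep(1, length(idx))
      sample(idx, n_bal, prob = pr)
    }
    sel <- c(take(pos), take(neg))
    d <- data.frame(x[sel, , drop = FALSE],
                    .y = factor(y[sel], levels = c(FALSE, TRUE)))
    tree <- rpart::rpart(.y ~ ., data = d, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, minsplit = 2L, cp = 0,
                           xval = 0L))
    pred <- predict(tree, data.frame(x), type = "class") == "TRUE"
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
  }
  list(learners = learners, alphas = alphas, prior = mean(y))
}

score_rusbt <- function(model, x) {
  if (!length(model$learners))
    return(rep(model$prior, nrow(x)))
  votes <- vapply(model$learners, function(tree)
    as.numeric(predict(tree, data.frame(x), type = "class") == "TRUE"),
    numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  margin <- as.numeric(votes %*% model$alphas) / sum(model$alphas)
  pmin(pmax(margin, 0), 1)
}

# ---- Subspace kNN ensemble ----------------------------------------------

fit_sknn <- function(x, y, params) {
  n_learners <- params$n_learners %||% 30L
  k <- params$k %||% 3L
  subspace_size <- params$subspace_size %||%
    max(1L, ceiling(sqrt(ncol(x))))
  subspace_size <- min(subspace_size, ncol(x))
  subspaces <- lapply(seq_len(n_learners), function(i)
    sort(sample.int(ncol(x), subspace_size)))
  list(x = x, y = y, k = min(k, nrow(x)), subspaces = subspaces)
}

score_sknn <- function(model, x) {
  cl <- factor(model$y, levels = c(FALSE, TRUE))
  votes <- vapply(model$subspaces, function(fs) {
    pred <- class::knn(model$x[, fs, drop = FALSE],
                       x[, fs, drop = FALSE], cl, k = model$k,
                       prob = TRUE)
    pr <- attr(pred, "prob")
    ifelse(pred == "TRUE", pr, 1 - pr)
  }, numeric(nrow(x)))
  rowMeans(matrix(votes, nrow = nrow(x)))
}

# ---- Gaussian naive Bayes -----------------------------------------------

fit_gnb <- function(x, y, params) {
  sd_floor <- params$sd_floor %||% 1e-3
  nb <- e1071::naiveBayes(data.frame(x),
                          factor(y, levels = c(FALSE, TRUE)))
  # floor the per-class standard deviations: zero-variance features would
  # otherwise produce degenerate densities
  nb$tables <- lapply(nb$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], sd_floor)
    tb
  })
  list(nb = nb)
}

score_gnb <- function(model, x) {
  as.numeric(predict(model$nb, data.frame(x), type = "raw")[, "TRUE"])
}

# ---- Medium Gaussian SVM ------------------------------------------------

fit_gsvm <- function(x, y, params) {
  kernel_scale <- params$kernel_scale %||% sqrt(ncol(x))
  gamma <- 1 / (2 * kernel_scale^2)
  # intensities stay on the raw pA scale: baseline time points then
  # contribute essentially nothing to the kernel distance, which is what a
  # chromatogram similarity should reflect
  # inverse class weights keep the 0.5 score cutoff meaningful on the
  # imbalanced cohorts this design produces (disease : control ~ 3 : 1)
  wts <- if (isTRUE(params$weight_classes %||% TRUE)) "inverse" else NULL
  svm <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                    kernel = "radial", gamma = gamma,
                    cost = params$cost %||% 1, scale = FALSE,
                    class.weights = wts)
  list(svm = svm)
}

score_gsvm <- function(model, x) {
  pred <- predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 orients the decision value toward the class named first in the
  # column label "A/B": positive values favor A
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  d <- if (first == "TRUE") dv[, 1] else -dv[, 1]
  as.numeric(stats::plogis(d))
}
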