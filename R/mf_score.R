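# Molecular-feature score: a logistic-regression probability built from the
# selected MF intensities (default: the single stage-trending feature with
# the highest AUC). The fit is maximum likelihood with an optional weak L2
# penalty on the slopes so that near-separable small cohorts still yield a
# finite optimum.

#' Fit the MF-score logistic model
#'
#' @param table a `feature_table`.
#' @param labels logical per-subject class labels (TRUE = disease); default
#'   stage > 0.
#' @param mf_ids features to use; `NULL` picks the highest-AUC
#'   stage-trending peak-max feature via [compare_groups()] (falling back to
#'   the highest-AUC feature when none trends).
#' @param layer value layer to model, "peak_max" or "peak_area".
#' @param ridge L2 penalty weight on the slopes (0 = plain maximum
#'   likelihood).
#' @return an `mf_score_model`: list with `mf_ids`, `layer`, `intercept`,
#'   `coefficients`, `ridge`.
#' @export
fit_mf_score <- function(table, labels = NULL, mf_ids = NULL,
                         layer = "peak_max", ridge = 0) {
  stopifnot(inherits(table, "feature_table"))
  labels <- labels %||% (table$subjects$stage > 0L)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("fit_mf_score() requires both classes", call. = FALSE)
  if (is.null(mf_ids)) {
    stats <- compare_groups(table)
    s <- stats[stats$layer == layer, , drop = FALSE]
    cand <- s[s$stage_trend, , drop = FALSE]
    if (!nrow(cand)) cand <- s
    mf_ids <- cand$id[which.max(cand$auc)]
  }
  missing_ids <- setdiff(mf_ids, colnames(table[[layer]]))
  if (length(missing_ids))
    stop("mf_ids not present in the feature table: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  x <- table[[layer]][, mf_ids, drop = FALSE]
  if (anyNA(x))
    stop("selected features have missing subject values", call. = FALSE)
  fit <- ridge_logistic(x, labels, ridge)
  structure(list(mf_ids = mf_ids, layer = layer, intercept = fit$intercept,
                 coefficients = stats::setNames(fit$beta, mf_ids),
                 ridge = ridge),
            class = "mf_score_model")
}

# penalized logistic regression by BFGS on the (standardized) negative
# log-likelihood + 0.5 * ridge * |beta|^2; back-transformed to the raw scale
ridge_logistic <- function(x, y, ridge = 0, maxit = 500L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  p <- ncol(z)
  softplus <- function(e) ifelse(e > 30, e, log1p(exp(e)))
  negll <- function(par) {
    eta <- par[1] + z %*% par[-1]
    -sum(y * eta - softplus(eta)) + 0.5 * ridge * sum(par[-1]^2)
  }
  grad <- function(par) {
    pr <- stats::plogis(par[1] + z %*% par[-1])
    res <- as.numeric(pr - y)
    c(sum(res), as.numeric(crossprod(z, res)) + ridge * par[-1])
  }
  opt <- stats::optim(rep(0, p + 1L), negll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  beta_std <- opt$par[-1]
  beta <- beta_std / sdev
  intercept <- opt$par[1] - sum(beta * mu)
  list(intercept = intercept, beta = beta)
}

#' Score subjects with a fitted MF-score model
#'
#' @param model an `mf_score_model`.
#' @param table a `feature_table` containing the model's features.
#' @return named numeric vector of per-subject scores in \[0, 1\].
#' @export
score_samples <- function(model, table) {
  stopifnot(inherits(model, "mf_score_model"),
            inherits(table, "feature_table"))
  x <- table[[model$layer]]
  missing_ids <- setdiff(model$mf_ids, colnames(x))
  if (length(missing_ids))
    stop("feature table lacks model features: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  x <- x[, model$mf_ids, drop = FALSE]
  for (id in model$mf_ids) {
    bad <- which(is.na(x[, id]))
    if (length(bad))
      stop(sprintf("missing value of MF %s for subject %s", id,
                   rownames(x)[bad[1]]), call. = FALSE)
  }
  eta <- model$intercept + as.numeric(x %*% model$coefficients)
  stats::setNames(stats::plogis(eta), rownames(x))
}

#' Empirical ROC curve and operating point
#'
#' Builds the monotone step ROC curve from (0,0) to (1,1), its trapezoidal
#' AUC (equivalent to the rank AUC with ties counted one half), and the
#' sensitivity/specificity of the rule `score >= cutoff`.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels (TRUE = positive).
#' @param cutoff decision cutoff on the score scale.
#' @return a `score_report`: list with `roc` (data.frame fpr, tpr,
#'   threshold), `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `confusion` (2x2 table).
#' @export
roc_and_operating_point <- function(scores, labels, cutoff = 0.45) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes required", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fn <- n1 - tp
  fp <- sum(pred & !labels); tn <- n0 - fp
  structure(list(roc = roc, auc = auc, cutoff = cutoff,
                 sensitivity = tp / n1, specificity = tn / n0,
                 confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                    dimnames = list(pred = c("pos", "neg"),
                                                    truth = c("pos", "neg")))),
            class = "score_report")
}

#' Per-stage summary of the MF score
#'
#' Mean and standard deviation of the score at each disease stage (SD is NA
#' for singleton stages; empty stages are omitted with a warning), plus
#' optional Spearman rank correlations against external severity covariates
#' such as MELD or FIB-4.
#'
#' @param scores named numeric per-subject scores.
#' @param stages integer stages 0-3, aligned with `scores`.
#' @param covariates optional data.frame of per-subject severity scores.
#' @return list with `by_stage` (data.frame stage, n, mean, sd) and
#'   `covariate_cor` (named Spearman correlations, or NULL).
#' @export
stage_trend <- function(scores, stages, covariates = NULL) {
  stopifnot(all(stages %in% 0:3), length(scores) == length(stages))
  rows <- lapply(0:3, function(s) {
    v <- scores[stages == s]
    if (!length(v)) {
      warning(sprintf("stage %d has no subjects; omitted", s), call. = FALSE)
      return(NULL)
    }
    data.frame(stage = s, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  })
  by_stage <- do.call(rbind, rows)
  rownames(by_stage) <- NULL
  covariate_cor <- NULL
  if (!is.null(covariates))
    covariate_cor <- vapply(covariates, function(cv)
      stats::cor(scores, cv, method = "spearman", use = "complete.obs"), 0)
  list(by_stage = by_stage, covariate_cor = covariate_cor)
}
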