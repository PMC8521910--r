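# Subject-level MCI vs HC classification: univariate feature selection,
# per-fold standardization, leave-one-subject-out cross-validation with
# three classifiers, cascaded (stacked) designs with nested first stages,
# bootstrap ROC analysis and Youden-optimal operating points.

#' Assemble a subject-level feature table
#'
#' @param subject_id Character vector, one entry per subject (unique).
#' @param label Binary labels (MCI = 1, HC = 0).
#' @param features data.frame of numeric feature columns.
#' @return A `feature_table` data.frame with columns `subject_id`, `label`
#'   and the features.
#' @export
feature_table <- function(subject_id, label, features) {
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 (HC) or 1 (MCI)")
  out <- cbind(data.frame(subject_id = as.character(subject_id),
                          label = label, stringsAsFactors = FALSE),
               features)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_cols <- function(table) setdiff(names(table), c("subject_id", "label"))

#' Univariate feature selection
#'
#' Scores each feature by its one-way ANOVA F statistic against the binary
#' label (equal-variance two-sample test) and returns the top `k` features.
#' Constant features score 0 and rank last; a feature identical to the
#' label scores `Inf` and ranks first.
#'
#' @param table A [feature_table()].
#' @param k Number of features to keep (default: all, ranked).
#' @param features Candidate columns (default: all feature columns).
#' @return data.frame with `feature` and `score`, sorted by decreasing
#'   score, truncated to `k` rows.
#' @export
select_features <- function(table, k = NULL, features = feature_cols(table)) {
  if (length(features) < 1L) stop("no candidate features")
  if (length(unique(table$label)) < 2L) stop("both classes must be present")
  score1 <- function(x) {
    if (stats::sd(x) == 0) return(0)
    f <- tryCatch(stats::oneway.test(x ~ table$label, var.equal = TRUE)$statistic,
                  error = function(e) NA_real_)
    if (!is.finite(f)) {
      # zero within-group variance with distinct means: perfect separation
      gm <- tapply(x, table$label, mean)
      f <- if (length(unique(gm)) > 1L) Inf else 0
    }
    unname(f)
  }
  scores <- vapply(features, function(nm) score1(table[[nm]]), numeric(1))
  out <- data.frame(feature = features, score = scores,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, if (is.null(k)) nrow(out) else k)
}

#' Documented optimal feature sets per experiment
#'
#' The presets used by the three experiments: `exp1` (linguistic:
#' `nonstop, dvrst, HS, MDD`), `exp2` (keystroke: `B, R`), and the
#' first-stage sets of the fused experiment, `just_nlp`
#' (`nonstop, dvrst, MDD`) and `just_keys` (`B, R`).
#'
#' @param name One of `"exp1"`, `"exp2"`, `"just_nlp"`, `"just_keys"`.
#' @return Character vector of feature names.
#' @export
feature_preset <- function(name = c("exp1", "exp2", "just_nlp", "just_keys")) {
  switch(match.arg(name),
         exp1 = c("nonstop", "dvrst", "HS", "MDD"),
         exp2 = c("B", "R"),
         just_nlp = c("nonstop", "dvrst", "MDD"),
         just_keys = c("B", "R"))
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# Single fit + probability prediction. All three classifiers are fit
# prior-balanced: under leave-one-subject-out, removing a subject tilts the
# training-fold class prior against that subject's class, which biases
# every held-out score toward the opposite class and drags the null AUC
# well below 0.5. Balancing (case weights for logistic regression,
# stratified balanced bagging for the random forest, prior-corrected vote
# shares for k-NN) removes that artifact without touching the features.
fit_predict <- function(Xtr, ytr, Xte, classifier, k = 7L, ntree = 100L,
                        seed = 1L) {
  sc <- scale_fit(Xtr)
  Xtr <- scale_apply(Xtr, sc); Xte <- scale_apply(Xte, sc)
  n1 <- sum(ytr == 1L); n0 <- sum(ytr == 0L)
  if (classifier == "logistic_regression") {
    w <- ifelse(ytr == 1L, 0.5 / n1, 0.5 / n0) * (n0 + n1)
    if (ncol(Xtr) >= 2L) {
      # ridge-penalized fit (L2 strength 1.0); also tames quasi-separation
      # suppress glmnet's small-class advisory: single-digit class counts
      # are the normal regime for these cohorts
      fit <- suppressWarnings(
        glmnet::glmnet(Xtr, factor(ytr, levels = c(0, 1)),
                       family = "binomial", alpha = 0,
                       lambda = 1 / nrow(Xtr), weights = w,
                       standardize = FALSE))
      as.numeric(stats::predict(fit, newx = Xte, type = "response"))
    } else {
      d <- as.data.frame(Xtr); d$y <- ytr
      fit <- suppressWarnings(stats::glm(y ~ ., data = d,
                                         family = stats::binomial(),
                                         weights = w))
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(Xte), type = "response")))
    }
  } else if (classifier == "random_forest") {
    set.seed(seed)
    yf <- factor(ytr, levels = c(0, 1))
    m <- min(n0, n1)
    # probability forest: enlarged terminal nodes (~20% of the training
    # fold) smooth the vote-share surface, which with tens of subjects is
    # otherwise a jumpy near-0/1 step function
    fit <- randomForest::randomForest(x = Xtr, y = yf, ntree = ntree,
                                      strata = yf, sampsize = c(m, m),
                                      nodesize = max(5L, round(nrow(Xtr) / 5)))
    as.numeric(stats::predict(fit, newdata = Xte, type = "prob")[, "1"])
  } else if (classifier == "knn") {
    kk <- min(k, nrow(Xtr))
    pred <- class::knn(train = Xtr, test = Xte,
                       cl = factor(ytr, levels = c(0, 1)), k = kk, prob = TRUE)
    p_win <- attr(pred, "prob")
    p1 <- ifelse(pred == "1", p_win, 1 - p_win)
    pi1 <- n1 / (n0 + n1); pi0 <- 1 - pi1
    (p1 / pi1) / (p1 / pi1 + (1 - p1) / pi0)
  } else stop("unknown classifier: ", classifier)
}

#' Leave-one-subject-out cross-validated predictions
#'
#' Per fold: fit a scaler (zero mean, unit variance) and the classifier on
#' all subjects but one, then predict the held-out subject's probability of
#' MCI. Every subject is predicted by a model never trained on them.
#'
#' @param table A [feature_table()].
#' @param classifier `"logistic_regression"`, `"random_forest"` or
#'   `"knn"` (k = 7 by default).
#' @param features Feature columns to use (default: all).
#' @param k Neighbors for k-NN.
#' @param ntree Trees for the random forest.
#' @param seed Seed for stochastic classifiers (fixed per fold).
#' @return A `cv_predictions` data.frame: `subject_id`, `fold`, `label`,
#'   `prob`.
#' @export
loso_predict <- function(table,
                         classifier = c("logistic_regression",
                                        "random_forest", "knn"),
                         features = feature_cols(table),
                         k = 7L, ntree = 100L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (min(table(table$label)) < 3L) stop("need >= 3 subjects per class")
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$label
  n <- nrow(table)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    prob[i] <- fit_predict(X[-i, , drop = FALSE], y[-i],
                           X[i, , drop = FALSE], classifier,
                           k = k, ntree = ntree, seed = seed + i)
  }
  structure(data.frame(subject_id = table$subject_id, fold = seq_len(n),
                       label = y, prob = prob, stringsAsFactors = FALSE),
            class = c("cv_predictions", "data.frame"))
}

stage1_defs <- list(
  just_nlp = list(classifier = "logistic_regression",
                  features = c("nonstop", "dvrst", "MDD")),
  just_keys = list(classifier = "knn", features = c("B", "R")))

cascade_defs <- list(
  A = list(stage1 = "just_nlp", extra = "B", classifier = "random_forest"),
  B = list(stage1 = "just_keys", extra = c("dvrst", "nonstop", "MDD"),
           classifier = "knn"),
  C = list(stage1 = c("just_nlp", "just_keys"), extra = character(0),
           classifier = "random_forest"))

#' Cascaded (stacked) LOSO predictions
#'
#' First-stage models `just_nlp` (logistic regression on
#' `nonstop, dvrst, MDD`) and `just_keys` (k-NN on the `B` and `R`
#' indices) produce MCI probabilities; the cascade designs feed them, with
#' design-specific extra features, to a second-stage classifier:
#' * `A`: probabilities of just_nlp + `B` index, random forest;
#' * `B`: probabilities of just_keys + `dvrst, nonstop, MDD`, k-NN;
#' * `C`: probabilities of just_nlp + probabilities of just_keys, random
#'   forest;
#' * `just_nlp` / `just_keys`: the first-stage models on their own.
#'
#' When `nested = TRUE` (default), the second-stage training features for
#' each outer fold are first-stage probabilities produced out-of-fold by an
#' inner cross-validation confined to that outer training set, so no
#' first-stage model ever sees the subject it scores. The inner folds are
#' class-balanced: every first-stage fit leaves out one subject of each
#' class (the scored subject plus a rotating opposite-class partner), so
#' every fit has the same class composition. Without that, the held-out
#' subject's class is encoded in the calibration (and, for k-NN vote
#' shares, the exact discrete support) of their stacking feature relative
#' to the training rows' features, and a flexible second-stage learner
#' decodes it — on label-free data this drives the cascade AUC far below
#' 0.5. `nested = FALSE` skips the inner nesting: first-stage
#' probabilities are computed once by a single LOSO over the whole cohort
#' and then treated as fixed feature columns in the outer loop, so the
#' second stage trains on stacking features whose fits saw the held-out
#' subject. This leaky variant is kept only for the leakage regression
#' experiment; on label-free data it inflates the AUC.
#'
#' @param table A [feature_table()] holding both linguistic and index
#'   features.
#' @param design `"A"`, `"B"`, `"C"`, `"just_nlp"` or `"just_keys"`.
#' @param nested Use nested inner LOSO for first-stage probabilities.
#' @param seed,k,ntree As in [loso_predict()].
#' @return A `cv_predictions` data.frame.
#' @export
cascade_predict <- function(table,
                            design = c("A", "B", "C", "just_nlp", "just_keys"),
                            nested = TRUE, seed = 1L, k = 7L, ntree = 100L) {
  design <- match.arg(design)
  if (design %in% names(stage1_defs)) {
    def <- stage1_defs[[design]]
    missing_f <- setdiff(def$features, names(table))
    if (length(missing_f))
      stop("feature table lacks column(s): ", paste(missing_f, collapse = ", "))
    return(loso_predict(table, def$classifier, def$features,
                        k = k, ntree = ntree, seed = seed))
  }
  def <- cascade_defs[[design]]
  needed <- unique(c(unlist(lapply(stage1_defs[def$stage1], `[[`, "features")),
                     def$extra))
  missing_f <- setdiff(needed, names(table))
  if (length(missing_f))
    stop("feature table lacks column(s): ", paste(missing_f, collapse = ", "))

  y <- table$label
  n <- nrow(table)
  # rotating opposite-class partner: the next opposite-class subject by
  # index within the pool, wrapping around
  partner <- function(j, pool) {
    opp <- pool[y[pool] != y[j]]
    opp[which.max(opp > j)]
  }
  # leaky variant: stage-1 probabilities from one global LOSO, reused in
  # every outer fold
  s1_global <- NULL
  if (!nested) {
    s1_global <- vapply(def$stage1, function(m) {
      sd1 <- stage1_defs[[m]]
      loso_predict(table, sd1$classifier, sd1$features,
                   k = k, ntree = ntree, seed = seed)$prob
    }, numeric(n))
    colnames(s1_global) <- def$stage1
  }

  prob <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    # first-stage probabilities for the outer training subjects
    s1_tr <- matrix(NA_real_, length(tr), length(def$stage1),
                    dimnames = list(NULL, def$stage1))
    s1_te <- stats::setNames(numeric(length(def$stage1)), def$stage1)
    for (m in def$stage1) {
      sd1 <- stage1_defs[[m]]
      Xm <- as.matrix(table[, sd1$features, drop = FALSE])
      if (nested) {
        for (j in seq_along(tr)) {
          inner_tr <- setdiff(tr, c(tr[j], partner(tr[j], setdiff(tr, tr[j]))))
          s1_tr[j, m] <- fit_predict(Xm[inner_tr, , drop = FALSE], y[inner_tr],
                                     Xm[tr[j], , drop = FALSE],
                                     sd1$classifier, k = k, ntree = ntree,
                                     seed = seed + 37L * j)
        }
        outer_tr <- setdiff(tr, partner(i, tr))
        s1_te[[m]] <- fit_predict(Xm[outer_tr, , drop = FALSE], y[outer_tr],
                                  Xm[i, , drop = FALSE], sd1$classifier,
                                  k = k, ntree = ntree, seed = seed + i)
      } else {
        s1_tr[, m] <- s1_global[tr, m]
        s1_te[[m]] <- s1_global[i, m]
      }
    }
    Xtr2 <- cbind(s1_tr, as.matrix(table[tr, def$extra, drop = FALSE]))
    Xte2 <- matrix(c(s1_te, as.numeric(table[i, def$extra, drop = FALSE])),
                   nrow = 1)
    colnames(Xte2) <- colnames(Xtr2)
    prob[i] <- fit_predict(Xtr2, y[tr], Xte2, def$classifier,
                           k = k, ntree = ntree, seed = seed + i)
  }
  structure(data.frame(subject_id = table$subject_id, fold = seq_len(n),
                       label = y, prob = prob, stringsAsFactors = FALSE),
            class = c("cv_predictions", "data.frame"))
}

auc_of <- function(label, prob) {
  as.numeric(pROC::auc(response = label, predictor = prob,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Youden-optimal cut-off
#'
#' Maximizes J = sensitivity + specificity - 1 over all distinct score
#' thresholds (a score >= cutoff predicts MCI; `Inf` — predict nobody — is
#' also a candidate). Ties are broken toward the higher-specificity
#' operating point.
#'
#' @param preds A `cv_predictions` data.frame (`label`, `prob`).
#' @return List with `cutoff`, `specificity`, `sensitivity`, `youden`.
#' @export
youden_cutoff <- function(preds) {
  y <- preds$label; s <- preds$prob
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cand <- c(sort(unique(s)), Inf)
  best <- NULL
  for (t in cand) {
    pos <- s >= t
    se <- sum(pos & y == 1L) / sum(y == 1L)
    sp <- sum(!pos & y == 0L) / sum(y == 0L)
    j <- se + sp - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && sp > best$specificity))
      best <- list(cutoff = t, specificity = sp, sensitivity = se, youden = j)
  }
  best
}

#' Bootstrap ROC analysis of out-of-fold predictions
#'
#' Resamples subjects with replacement `n_boot` times (resamples containing
#' a single class are redrawn), computes the ROC AUC of each resample, and
#' reports the mean AUC with 2.5/97.5 percentile confidence bounds.
#' Accuracy, specificity and sensitivity are evaluated at the
#' Youden-optimal cut-off of the pooled predictions.
#'
#' @param preds A `cv_predictions` data.frame.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param classifier,features Optional labels recorded in the result.
#' @return An `experiment_result` list: `auc` (pooled), `mean_auc`,
#'   `auc_ci`, `accuracy`, `specificity`, `sensitivity`, `cutoff`,
#'   `n_bootstraps`, `n_subjects`, `classifier`, `features`.
#' @export
bootstrap_roc <- function(preds, n_boot = 1000L, seed = 1L,
                          classifier = NA_character_, features = character(0)) {
  y <- preds$label; s <- preds$prob
  if (min(table(y)) < 2L) stop("need >= 2 subjects per class")
  set.seed(seed)
  n <- length(y)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      ii <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[ii])) == 2L) break
    }
    aucs[b] <- auc_of(y[ii], s[ii])
  }
  yc <- youden_cutoff(preds)
  pos <- s >= yc$cutoff
  acc <- mean((pos & y == 1L) | (!pos & y == 0L))
  structure(list(auc = auc_of(y, s), mean_auc = mean(aucs),
                 auc_ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
                 accuracy = acc, specificity = yc$specificity,
                 sensitivity = yc$sensitivity, cutoff = yc$cutoff,
                 n_bootstraps = n_boot, n_subjects = n,
                 classifier = classifier, features = features),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.2f (bootstrap mean %.2f, 95%% CI %.2f-%.2f, %d resamples)\n",
    x$auc, x$mean_auc, x$auc_ci[1], x$auc_ci[2], x$n_bootstraps))
  cat(sprintf("accuracy %.2f, specificity %.2f, sensitivity %.2f at cutoff %.3g\n",
              x$accuracy, x$specificity, x$sensitivity, x$cutoff))
  if (!is.na(x$classifier))
    cat(sprintf("classifier: %s; features: %s\n", x$classifier,
                paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Pearson correlation with clinical scores
#'
#' @param values Per-subject model predictions or a feature column.
#' @param scores Paired clinical scores (MMSE, FUCAS or FRSSD).
#' @return List with `r`, `p` and `n`; `r` is `NA` when either vector has
#'   zero variance.
#' @export
clinical_correlation <- function(values, scores) {
  ok <- is.finite(values) & is.finite(scores)
  values <- values[ok]; scores <- scores[ok]
  if (length(values) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(values) == 0 || stats::sd(scores) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(values)))
  ct <- stats::cor.test(values, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}

#' Run one experiment end-to-end
#'
#' LOSO prediction (plain or cascaded) followed by bootstrap ROC analysis.
#'
#' @param table A [feature_table()].
#' @param design A cascade design name, or `NULL` to use
#'   `classifier`/`features` directly.
#' @param classifier,features For the non-cascaded route.
#' @param n_boot,seed Bootstrap settings.
#' @return An `experiment_result` with the predictions attached as
#'   attribute `predictions`.
#' @export
run_experiment <- function(table, design = NULL,
                           classifier = "logistic_regression",
                           features = feature_cols(table),
                           n_boot = 1000L, seed = 1L) {
  preds <- if (is.null(design))
    loso_predict(table, classifier, features, seed = seed)
  else cascade_predict(table, design, seed = seed)
  res <- bootstrap_roc(preds, n_boot = n_boot, seed = seed,
                       classifier = if (is.null(design)) classifier else design,
                       features = if (is.null(design)) features else character(0))
  attr(res, "predictions") <- preds
  res
}
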