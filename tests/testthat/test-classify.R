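make_table <- function(n_per_class = 10, delta = 0, p = 3, seed = 1,
                       prefix = "f") {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  X <- matrix(rnorm(n * p), n, p) + outer(y * delta, rep(1, p))
  colnames(X) <- paste0(prefix, seq_len(p))
  feature_table(sprintf("u%03d", seq_len(n)), y, as.data.frame(X))
}

test_that("univariate selection ranks label-associated features first", {
  tab <- make_table(n_per_class = 15, delta = 0, p = 4, seed = 2)
  tab$perfect <- as.numeric(tab$label)
  tab$constant <- 1
  sel <- select_features(tab)
  expect_identical(sel$feature[1], "perfect")
  expect_true(is.infinite(sel$score[1]))
  expect_identical(sel$feature[nrow(sel)], "constant")
  expect_equal(sel$score[nrow(sel)], 0)
  expect_identical(nrow(select_features(tab, k = 2)), 2L)

  # on pure noise no feature is preferred systematically
  set.seed(42)
  wins <- table(replicate(100, {
    t2 <- make_table(n_per_class = 100, delta = 0, p = 5,
                     seed = sample.int(1e6, 1))
    select_features(t2, k = 1)$feature
  }))
  expect_true(all(wins < 50))  # ~20 each under the uniform null

  # the documented experiment presets
  expect_identical(feature_preset("exp1"), c("nonstop", "dvrst", "HS", "MDD"))
  expect_identical(feature_preset("just_keys"), c("B", "R"))
})

test_that("LOSO predictions are out-of-fold, one per subject, and sane", {
  sep <- make_table(n_per_class = 8, delta = 6, seed = 3)
  for (clf in c("logistic_regression", "random_forest", "knn")) {
    preds <- loso_predict(sep, clf)
    expect_identical(nrow(preds), nrow(sep))
    expect_identical(preds$fold, seq_len(nrow(sep)))
    expect_identical(anyDuplicated(preds$subject_id), 0L)
    expect_equal(cogtype:::auc_of(preds$label, preds$prob), 1.0)
  }

  # permutation null: AUC near chance
  null_tab <- make_table(n_per_class = 100, delta = 0, seed = 4)
  preds <- loso_predict(null_tab, "logistic_regression")
  auc <- cogtype:::auc_of(preds$label, preds$prob)
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)

  expect_error(loso_predict(make_table(n_per_class = 2), "knn"), ">= 3")
})

test_that("per-fold scaling uses training-fold statistics only", {
  tab <- make_table(n_per_class = 6, delta = 0, seed = 5)
  tab$f1[1] <- 50  # held-out outlier must not shift its own fold's scaler
  Xtr <- as.matrix(tab[-1, c("f1", "f2", "f3")])
  sc_fold <- cogtype:::scale_fit(Xtr)
  sc_all <- cogtype:::scale_fit(as.matrix(tab[, c("f1", "f2", "f3")]))
  expect_gt(abs(sc_all$mu[["f1"]] - sc_fold$mu[["f1"]]), 1)
  scaled <- cogtype:::scale_apply(Xtr, sc_fold)
  expect_equal(unname(colMeans(scaled)), rep(0, 3))
  expect_equal(unname(apply(scaled, 2, sd)), rep(1, 3))
})

test_that("Youden cut-off equals the exhaustive threshold oracle", {
  oracle <- function(y, s) {
    best <- list(j = -Inf, sp = -1)
    for (t in c(sort(unique(s)), Inf)) {
      se <- mean(s[y == 1] >= t); sp <- mean(s[y == 0] < t)
      j <- se + sp - 1
      if (j > best$j + 1e-12 || (abs(j - best$j) <= 1e-12 && sp > best$sp))
        best <- list(j = j, sp = sp, se = se, t = t)
    }
    best
  }
  set.seed(6)
  for (rep in 1:50) {
    n <- sample(6:40, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    got <- youden_cutoff(data.frame(label = y, prob = s))
    want <- oracle(y, s)
    expect_equal(got$youden, want$j, tolerance = 1e-12)
    expect_equal(got$specificity, want$sp)
    expect_equal(got$sensitivity, want$se)
  }

  # separable scores: any cutoff in (0.2, 0.8] is perfect; ours picks 0.8
  sepa <- youden_cutoff(data.frame(label = c(0, 0, 1, 1),
                                   prob = c(0.1, 0.2, 0.8, 0.9)))
  expect_equal(sepa$youden, 1)
  expect_equal(sepa$cutoff, 0.8)

  # all scores equal: J = 0, tie resolved toward specificity
  flat <- youden_cutoff(data.frame(label = c(0, 1, 0, 1), prob = rep(0.5, 4)))
  expect_equal(flat$youden, 0)
  expect_equal(flat$specificity, 1)
  expect_equal(flat$sensitivity, 0)
})

test_that("bootstrap ROC handles degenerate and null score patterns", {
  ordered <- data.frame(label = rep(c(0L, 1L), each = 5),
                        prob = c(1:5, 6:10) / 10)
  r <- bootstrap_roc(ordered, n_boot = 200, seed = 1)
  expect_equal(r$mean_auc, 1.0)
  expect_equal(unname(r$auc_ci), c(1.0, 1.0))
  expect_equal(r$accuracy, 1.0)

  anti <- ordered; anti$prob <- rev(anti$prob)
  expect_equal(bootstrap_roc(anti, n_boot = 100, seed = 1)$mean_auc, 0.0)

  set.seed(8)
  null_preds <- data.frame(label = rep(c(0L, 1L), 100), prob = runif(200))
  rn <- bootstrap_roc(null_preds, n_boot = 400, seed = 2)
  expect_lt(rn$auc_ci[1], 0.5); expect_gt(rn$auc_ci[2], 0.5)

  # CI narrows with cohort size
  set.seed(9)
  mk <- function(n) data.frame(label = rep(c(0L, 1L), n / 2),
                               prob = rep(c(0L, 1L), n / 2) * 0.4 + runif(n))
  w20 <- diff(bootstrap_roc(mk(20), n_boot = 400, seed = 3)$auc_ci)
  w200 <- diff(bootstrap_roc(mk(200), n_boot = 400, seed = 3)$auc_ci)
  expect_lt(w200, w20)

  expect_error(bootstrap_roc(data.frame(label = c(0, 1), prob = c(0, 1))),
               ">= 2")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(10)
  y <- rep(c(0L, 1L), 30)
  s <- runif(60) + y * 0.3
  base <- cogtype:::auc_of(y, s)
  for (f in list(function(x) 3 * x - 1, exp, function(x) x^3,
                 function(x) 1 / (1 + exp(-5 * x)))) {
    expect_equal(cogtype:::auc_of(y, f(s)), base, tolerance = 1e-12)
  }
})

test_that("Pearson correlation with clinical scores behaves at the edges", {
  x <- seq(-3, 3, length.out = 20)
  expect_equal(clinical_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(clinical_correlation(x, -x)$r, -1.0)
  set.seed(11)
  null_r <- clinical_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(null_r$r), 0.1)
  expect_true(is.na(clinical_correlation(x, rep(2, 20))$r))
  expect_error(clinical_correlation(1:2, 2:3), ">= 3")
})

cascade_table <- function(n_per_class, delta_nlp = 0, delta_keys = 0,
                          seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  f <- function(delta) rnorm(n) + y * delta
  feature_table(sprintf("u%03d", seq_len(n)), y, data.frame(
    nonstop = f(delta_nlp), dvrst = f(-delta_nlp), MDD = f(-delta_nlp),
    HS = f(-delta_nlp), B = f(delta_keys), R = f(delta_keys)))
}

test_that("cascade designs wire the documented feature sets together", {
  tab <- cascade_table(10, delta_nlp = 4, delta_keys = 4, seed = 12)
  for (design in c("just_nlp", "just_keys", "A", "B", "C")) {
    preds <- cascade_predict(tab, design, seed = 1)
    expect_identical(nrow(preds), 20L)
    expect_identical(anyDuplicated(preds$subject_id), 0L)
    # strong effects in both modalities: near-perfect separation
    expect_gt(cogtype:::auc_of(preds$label, preds$prob), 0.9)
  }
  no_b <- tab; no_b$B <- NULL
  expect_error(cascade_predict(no_b, "A"), "B")
})

test_that("nested first stages avoid the leakage that in-sample scoring causes", {
  tab <- cascade_table(25, seed = 13)  # pure noise features
  nested <- bootstrap_roc(cascade_predict(tab, "C", nested = TRUE, seed = 2),
                          n_boot = 300, seed = 2)
  leaky <- bootstrap_roc(cascade_predict(tab, "C", nested = FALSE, seed = 2),
                         n_boot = 300, seed = 2)
  expect_lt(nested$auc_ci[1], 0.5)
  expect_gt(nested$auc_ci[2], 0.5)
  expect_gt(leaky$mean_auc, nested$mean_auc)
})
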