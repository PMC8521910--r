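test_that("typing sessions round-trip exactly through the dynamics equations", {
  set.seed(51)
  tp <- cogtype:::typing_params()
  for (rep in 1:50) {
    s <- simulate_typing_session(tp, "s", "u")
    d <- compute_dynamics(s)
    expect_identical(d$ht, attr(s, "true_ht"))
    expect_identical(d$ft, attr(s, "true_ft"))
  }

  # zero-variance draws collapse to the location parameter
  tp0 <- tp; tp0$ht_sdlog <- 0; tp0$pause_rate <- 0
  s0 <- compute_dynamics(simulate_typing_session(tp0, "s", "u"))
  expect_true(all(s0$ht == s0$ht[1]))
  expect_equal(s0$ht[1], round(1000 * exp(tp0$ht_meanlog)) / 1000)

  # determinism under a fixed seed
  set.seed(99); a <- simulate_typing_session(tp, "s", "u")
  set.seed(99); b <- simulate_typing_session(tp, "s", "u")
  expect_identical(a, b)
})

test_that("key-event counts straddle the QC bar and hold times match moments", {
  set.seed(52)
  tp <- cogtype:::typing_params()
  ns <- replicate(300, simulate_typing_session(tp, "s", "u")$n_keys)
  expect_gt(sum(ns <= 40), 0)
  expect_gt(sum(ns > 40), 0)

  # analytic log-normal mean, allowing for millisecond quantization
  hts <- numeric(0)
  while (length(hts) < 10000)
    hts <- c(hts, attr(simulate_typing_session(tp, "s", "u"), "true_ht"))
  expect_equal(mean(hts), exp(tp$ht_meanlog + tp$ht_sdlog^2 / 2),
               tolerance = 0.02)
})

test_that("severity dataset is monotone in severity and reproducible", {
  spec <- severity_generator_spec(n_subjects = 10, sessions_per_subject = 4,
                                  seed = 53)
  samp <- simulate_severity_dataset(spec)
  truth <- attr(samp, "truth")
  expect_true(all(truth$severity %in% 0:4))
  expect_true(all(vapply(samp, function(s)
    all(s$scores >= 0 & s$scores <= 4), logical(1))))

  mean_ht <- function(sev) {
    ids <- truth$subject_id[truth$severity == sev]
    mean(unlist(lapply(samp[vapply(samp, function(s)
      s$subject_id %in% ids, logical(1))], function(s) s$dynamics$ht)))
  }
  expect_gt(mean_ht(4), mean_ht(0))

  samp2 <- simulate_severity_dataset(spec)
  expect_identical(attr(samp2, "truth"), truth)
  expect_identical(samp2[[1]]$dynamics$ht, samp[[1]]$dynamics$ht)
})

test_that("generated documents are valid, tunable and parse back cleanly", {
  set.seed(54)
  lp <- cogtype:::linguistic_params()
  for (rep in 1:30) {
    doc <- simulate_document(lp, "d", "u")
    for (s in doc$sentences) expect_identical(sum(s$head == 0L), 1L)
  }

  # adjacency limit: tiny distance scale forces MDD = 1
  lp1 <- lp; lp1$mdd_scale <- 1e-6
  for (rep in 1:10)
    expect_equal(compute_mdd(simulate_document(lp1, "d", "u")), 1.0)

  # file round trip without warnings
  docs <- lapply(1:3, function(i) simulate_document(lp, paste0("d", i), "u7"))
  path <- tempfile(fileext = ".conllu")
  write_conllu(docs, path)
  expect_no_warning(back <- read_conllu(path))
  expect_length(back, 3)
  expect_identical(back[[2]]$subject_id, "u7")
  expect_equal(compute_mdd(back[[1]]), compute_mdd(docs[[1]]))
})

test_that("extracted noun ratio matches the tag-draw multinomial", {
  set.seed(55)
  lp <- cogtype:::linguistic_params()
  lp$pos_probs <- c(NOUN = 0.3, VERB = 0.25, PRON = 0.1, ADJ = 0.15,
                    ADV = 0.1, X = 0.1)
  nn <- 0; vrb <- 0
  for (i in 1:500) {
    doc <- simulate_document(lp, "d", "u")
    upos <- unlist(lapply(doc$sentences, `[[`, "upos"))
    nn <- nn + sum(upos == "NOUN"); vrb <- vrb + sum(upos == "VERB")
  }
  expect_equal(nn / (nn + vrb), 0.3 / 0.55, tolerance = 0.02 / (0.3 / 0.55))
})

test_that("the keystroke effect dial is calibrated in standardized units", {
  # a single 200-subject cohort measures d with SE ~ 0.15, so average the
  # measured effect over three independent cohorts to test the dial itself
  d_hat <- vapply(56:58, function(seed) {
    spec <- cohort_spec(n_mci = 100, n_hc = 100, sessions_per_subject = 6,
                        texts_per_subject = 1, d_ht_loc = 1, d_ht_scale = 0,
                        d_ft_loc = 0, d_zipf = 0, d_stop = 0, d_noun = 0,
                        d_pron = 0, d_mdd = 0, seed = seed)
    cohort <- simulate_cohort(spec)
    subj_mean <- vapply(split(cohort$sessions,
                              vapply(cohort$sessions, `[[`, "subject_id",
                                     FUN.VALUE = character(1))),
                        function(ss) mean(unlist(lapply(ss, function(s)
                          compute_dynamics(s)$ht))), numeric(1))
    grp <- cohort$labels$label[match(names(subj_mean),
                                     cohort$labels$subject_id)]
    (mean(subj_mean[grp == 1]) - mean(subj_mean[grp == 0])) /
      sqrt((var(subj_mean[grp == 1]) + var(subj_mean[grp == 0])) / 2)
  }, numeric(1))
  expect_gt(mean(d_hat), 0.8); expect_lt(mean(d_hat), 1.2)
})

test_that("cohort simulation writes self-consistent artifacts", {
  dir1 <- file.path(tempfile(), "a"); dir2 <- file.path(tempfile(), "b")
  spec <- cohort_spec(n_mci = 3, n_hc = 3, sessions_per_subject = 2,
                      texts_per_subject = 2, seed = 57)
  simulate_cohort(spec, dir = dir1)
  simulate_cohort(spec, dir = dir2)
  # identical bytes for identical seeds
  expect_identical(readLines(file.path(dir1, "sessions.jsonl")),
                   readLines(file.path(dir2, "sessions.jsonl")))
  f1 <- list.files(file.path(dir1, "conllu"))
  expect_length(f1, 6)
  for (f in f1)
    expect_identical(readLines(file.path(dir1, "conllu", f)),
                     readLines(file.path(dir2, "conllu", f)))

  # artifacts read back through the package's own readers
  sess <- read_sessions(file.path(dir1, "sessions.jsonl"))
  expect_length(sess, 12)
  docs <- do.call(c, lapply(file.path(dir1, "conllu", f1), read_conllu))
  expect_length(docs, 12)
  labels <- read.csv(file.path(dir1, "labels.csv"))
  expect_identical(sort(unique(labels$label)), c(0L, 1L))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  sw <- read_stopwords(file.path(dir1, "stopwords.txt"))
  expect_length(sw, 40)

  # refusal to clobber
  expect_error(simulate_cohort(spec, dir = dir1), "exists")
})

test_that("clinical scores track impairment in the documented directions", {
  cohort <- simulate_cohort(powered_cohort_spec(seed = 58))
  cl <- merge(cohort$clinical, cohort$labels, by = "subject_id")
  expect_lt(mean(cl$MMSE[cl$label == 1]), mean(cl$MMSE[cl$label == 0]))
  expect_gt(mean(cl$FRSSD[cl$label == 1]), mean(cl$FRSSD[cl$label == 0]))
})
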