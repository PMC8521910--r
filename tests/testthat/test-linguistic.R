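test_that("CoNLL-U documents parse with root and id invariants enforced", {
  docs <- read_conllu(fig1_conllu_file())
  expect_length(docs, 1)
  expect_length(docs[[1]]$sentences, 1)
  expect_identical(nrow(docs[[1]]$sentences[[1]]), 8L)

  # empty file
  empty <- tempfile(fileext = ".conllu")
  writeLines(character(0), empty)
  expect_length(read_conllu(empty), 0)

  # two roots: sentence rejected
  path <- tempfile(fileext = ".conllu")
  writeLines(c("1\ta\t_\tNOUN\t_\t_\t0\t_\t_\t_",
               "2\tb\t_\tVERB\t_\t_\t0\t_\t_\t_", "",
               "1\tc\t_\tNOUN\t_\t_\t0\t_\t_\t_",
               "2\td\t_\tVERB\t_\t_\t1\t_\t_\t_", ""), path)
  expect_warning(docs <- read_conllu(path), "invalid")
  expect_length(docs[[1]]$sentences, 1)

  # multiword ranges and empty nodes are skipped
  path2 <- tempfile(fileext = ".conllu")
  writeLines(c("1-2\tab\t_\t_\t_\t_\t_\t_\t_\t_",
               "1\ta\t_\tNOUN\t_\t_\t0\t_\t_\t_",
               "1.1\tghost\t_\t_\t_\t_\t_\t_\t_\t_",
               "2\tb\t_\tVERB\t_\t_\t1\t_\t_\t_", ""), path2)
  docs2 <- read_conllu(path2)
  expect_identical(nrow(docs2[[1]]$sentences[[1]]), 2L)
})

test_that("lexical richness features match their closed forms", {
  # all words distinct: diversity exactly 1
  d <- doc_from_counts(rep(1, 12))
  expect_equal(unname(lexical_features(d)["dvrst"]), 1)

  # W = 100, V = 50, hap = 25: 25 hapaxes + 25 forms of multiplicity 3
  d2 <- doc_from_counts(c(rep(1, 25), rep(3, 25)))
  f <- lexical_features(d2)
  expect_equal(unname(f["dvrst"]), 0.5)
  expect_equal(unname(f["BI"]), 11.1896769334, tolerance = 1e-9)
  expect_equal(unname(f["HS"]), 921.0340371976, tolerance = 1e-9)

  # every word a hapax: Honore statistic undefined
  expect_true(is.na(lexical_features(d)["HS"]))

  # vocabulary is case-folded
  s <- fig1_sentence(); s$form[1] <- "GRANDSON"
  f2 <- lexical_features(parsed_document("x", "u", list(s)))
  expect_equal(unname(f2["dvrst"]), 7 / 8)
})

test_that("Brunet index falls and Honore statistic rises with richer language", {
  # BI strictly decreasing in V at fixed W = 60
  bis <- vapply(c(2, 5, 10, 20, 30, 60), function(v) {
    counts <- rep(60 %/% v, v); counts[1] <- counts[1] + 60 - sum(counts)
    unname(lexical_features(doc_from_counts(counts))["BI"])
  }, numeric(1))
  expect_true(all(diff(bis) < 0))

  # HS strictly increasing in hap at fixed W = 60, V = 20
  hss <- vapply(c(1, 5, 10, 15, 19), function(hap) {
    counts <- c(rep(1, hap), rep(2, 20 - hap))
    counts[hap + 1] <- 60 - sum(counts) + counts[hap + 1]
    unname(lexical_features(doc_from_counts(counts))["HS"])
  }, numeric(1))
  expect_true(all(diff(hss) > 0))
})

test_that("sentence structure and word-class ratios follow their definitions", {
  sents <- list(
    data.frame(id = 1:5, form = sprintf("a%d", 1:5),
               upos = c("NOUN", "VERB", "NOUN", "NOUN", "PRON"),
               head = c(0L, 1L, 2L, 1L, 4L), stringsAsFactors = FALSE),
    data.frame(id = 1:7, form = c("the", sprintf("b%d", 1:6)),
               upos = c("DET", "NOUN", "VERB", "NOUN", "NOUN", "PRON", "ADJ"),
               head = c(2L, 0L, 2L, 3L, 4L, 5L, 6L), stringsAsFactors = FALSE))
  doc <- parsed_document("d", "u", sents)

  sf <- structure_features(doc, stopwords = character(0))
  expect_equal(unname(sf["wrd_sent"]), 6)
  expect_equal(unname(sf["nonstop"]), 1)
  expect_equal(unname(structure_features(doc, stopwords = "the")["nonstop"]),
               11 / 12)
  all_forms <- tolower(unique(unlist(lapply(sents, `[[`, "form"))))
  expect_equal(unname(structure_features(doc, all_forms)["nonstop"]), 0)

  wc <- word_class_features(doc)
  expect_equal(unname(wc["NnVrb"]), 6 / 2)
  expect_equal(unname(wc["Nn"]), 6 / 8)
  expect_equal(unname(wc["Prn"]), 2 / 8)

  # degenerate denominators flag, not fail
  no_verbs <- parsed_document("d", "u", list(
    data.frame(id = 1:2, form = c("x", "y"), upos = c("NOUN", "ADJ"),
               head = c(0L, 1L), stringsAsFactors = FALSE)))
  expect_true(is.na(word_class_features(no_verbs)["NnVrb"]))
  no_nominals <- parsed_document("d", "u", list(
    data.frame(id = 1:2, form = c("x", "y"), upos = c("ADV", "ADJ"),
               head = c(0L, 1L), stringsAsFactors = FALSE)))
  expect_true(is.na(word_class_features(no_nominals)["Prn"]))
})

test_that("the example sentence yields MDD 16/7 and simple trees check out", {
  expect_equal(compute_mdd(fig1_document()), 16 / 7, tolerance = 1e-12)

  two <- parsed_document("d", "u", list(
    data.frame(id = 1:2, form = c("a", "b"), upos = c("NOUN", "VERB"),
               head = c(2L, 0L), stringsAsFactors = FALSE)))
  expect_equal(compute_mdd(two), 1)

  chain <- parsed_document("d", "u", list(
    data.frame(id = 1:4, form = letters[1:4], upos = rep("NOUN", 4),
               head = c(0L, 1L, 2L, 3L), stringsAsFactors = FALSE)))
  expect_equal(compute_mdd(chain), 1)

  # punctuation is excluded from both positions and counts
  s <- fig1_sentence()
  s_punct <- rbind(s, data.frame(id = 9L, form = ".", upos = "PUNCT", head = 4L))
  expect_equal(compute_mdd(parsed_document("d", "u", list(s_punct))), 16 / 7)
})

test_that("MDD equals the brute-force per-token distance sum on random trees", {
  set.seed(202)
  for (rep in 1:200) {
    doc <- random_plain_document()
    oracle <- mean(vapply(doc$sentences, function(s)
      sum(abs(s$head[s$head != 0L] - s$id[s$head != 0L])) / (nrow(s) - 1),
      numeric(1)))
    expect_equal(compute_mdd(doc), oracle, tolerance = 1e-12)
  }
})

test_that("the nine-feature vector is complete, deterministic and in range", {
  doc <- fig1_document()
  sw <- c("i", "am", "the", "of", "a")
  v <- extract_features(doc, sw)
  expect_named(v, c("dvrst", "BI", "HS", "wrd_sent", "nonstop", "NnVrb",
                    "Nn", "Prn", "MDD"))
  expect_equal(unname(v["MDD"]), 16 / 7, tolerance = 1e-12)
  expect_identical(unclass(v), unclass(extract_features(doc, sw)))

  set.seed(303)
  for (rep in 1:50) {
    v <- extract_features(random_plain_document())
    expect_true(v["dvrst"] > 0 && v["dvrst"] <= 1)
    expect_true(v["nonstop"] >= 0 && v["nonstop"] <= 1)
    expect_true(is.na(v["Nn"]) || (v["Nn"] >= 0 && v["Nn"] <= 1))
    expect_true(is.na(v["Prn"]) || (v["Prn"] >= 0 && v["Prn"] <= 1))
    expect_true(v["MDD"] >= 0)
    expect_true(v["wrd_sent"] > 0)
  }
})

test_that("user aggregation averages per field and masks flagged entries", {
  v1 <- extract_features(fig1_document())
  expect_equal(unclass(aggregate_user_features(list(v1))), unclass(v1))

  mk <- function(dvrst, hs) {
    v <- v1; v["dvrst"] <- dvrst; v["HS"] <- hs; v
  }
  agg <- aggregate_user_features(list(mk(0.4, 100), mk(0.6, NA), mk(0.5, 200)))
  expect_equal(unname(agg["dvrst"]), 0.5)
  expect_equal(unname(agg["HS"]), 150)  # mean over the two defined entries

  all_na <- aggregate_user_features(list(mk(0.4, NA), mk(0.6, NA)))
  expect_true(is.na(all_na["HS"]))
  expect_error(aggregate_user_features(list()), "no feature vectors")
})
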