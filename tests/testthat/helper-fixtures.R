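# Shared fixtures, all built in code.

# The eight-word example sentence: "I am the grandmother of a wonderful
# grandson". Root is "grandmother" (position 4) heading "I", "am", "the"
# and "grandson"; "grandson" (position 8) heads "of", "a", "wonderful".
# Link distances are 3,2,1,4 and 3,2,1, so the sentence MDD is 16/7.
fig1_sentence <- function() {
  data.frame(
    id = 1:8,
    form = c("I", "am", "the", "grandmother", "of", "a", "wonderful",
             "grandson"),
    upos = c("PRON", "AUX", "DET", "NOUN", "ADP", "DET", "ADJ", "NOUN"),
    head = c(4L, 4L, 4L, 0L, 8L, 8L, 8L, 4L),
    stringsAsFactors = FALSE)
}

fig1_document <- function() parsed_document("fig1", "u1", list(fig1_sentence()))

fig1_conllu_file <- function() {
  path <- tempfile(fileext = ".conllu")
  write_conllu(list(fig1_document()), path)
  path
}

# a random valid typing session with known raw timestamps
random_session <- function(n = NULL, id = "s1", subject = "u1") {
  if (is.null(n)) n <- sample(2:120, 1)
  ht <- sample(10:900, n, replace = TRUE)
  gap <- sample(-50:4000, n - 1, replace = TRUE)
  press <- numeric(n); release <- numeric(n)
  press[1] <- 0; release[1] <- ht[1]
  for (i in seq_len(n - 1)) {
    # negative gaps (rollover) allowed but bounded so presses stay sorted
    press[i + 1] <- release[i] + max(gap[i], -ht[i] + 1)
    release[i + 1] <- press[i + 1] + ht[i + 1]
  }
  typing_session(id, subject, press, release)
}

# a random dependency-parsed document without punctuation, so the raw
# CoNLL-U columns double as the MDD oracle inputs
random_plain_document <- function(n_sent = NULL, id = "d1", subject = "u1") {
  if (is.null(n_sent)) n_sent <- sample(1:5, 1)
  sentences <- lapply(seq_len(n_sent), function(k) {
    n <- sample(2:12, 1)
    heads <- cogtype:::random_tree(n, scale = runif(1, 0.2, 3))
    data.frame(id = seq_len(n),
               form = sample(sprintf("w%02d", 1:30), n, replace = TRUE),
               upos = sample(c("NOUN", "VERB", "PRON", "ADJ", "ADV"), n,
                             replace = TRUE),
               head = heads, stringsAsFactors = FALSE)
  })
  parsed_document(id, subject, sentences)
}

# build a document with prescribed token-frequency structure: `counts[i]`
# tokens of distinct form i (one sentence per 10 tokens, chain trees)
doc_from_counts <- function(counts) {
  forms <- unlist(mapply(function(i, k) rep(sprintf("tok%03d", i), k),
                         seq_along(counts), counts, SIMPLIFY = FALSE))
  sentences <- lapply(split(forms, ceiling(seq_along(forms) / 10)), function(f) {
    n <- length(f)
    data.frame(id = seq_len(n), form = f,
               upos = rep("NOUN", n),
               head = c(0L, seq_len(n - 1L)), stringsAsFactors = FALSE)
  })
  # a 1-token sentence would be skipped by MDD but is fine elsewhere
  parsed_document("counts", "u1", unname(sentences))
}

# padded dynamics series with given channel values
padded_series <- function(ht, ft, id = "s1", subject = "u1", L = 100L) {
  s <- structure(list(session_id = id, subject_id = subject,
                      ht = ht, ft = ft, n_raw = length(ht),
                      filtered = TRUE, unusable = FALSE,
                      padded_ht = NULL, padded_ft = NULL),
                 class = "dynamics_series")
  pad_series(s, L)
}

# a minimally-trained fmi_models object, shared across cheap tests
tiny_fmi_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    samp <- simulate_severity_dataset(
      severity_generator_spec(n_subjects = 5, sessions_per_subject = 3,
                              seed = 11))
    cfg <- training_config(pretrain_epochs = 3, finetune_epochs = 3, seed = 11)
    enc <- pretrain_autoencoder(lapply(samp, `[[`, "dynamics"), cfg = cfg)
    cache <<- finetune_regressors(enc, samp, cfg)
    cache
  }
})
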