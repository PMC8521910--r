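# Nine written-speech biomarkers from dependency-parsed documents.
# Word tokens are all non-PUNCT tokens; the vocabulary is the set of
# case-folded surface forms. Degenerate denominators yield NA sentinels
# (never errors) so one pathological text cannot abort a subject's
# aggregation.

nlp_feature_names <- c("dvrst", "BI", "HS", "wrd_sent", "nonstop",
                       "NnVrb", "Nn", "Prn", "MDD")

word_tokens <- function(sentence) sentence[sentence$upos != "PUNCT", , drop = FALSE]

doc_forms <- function(doc) {
  unlist(lapply(doc$sentences, function(s) tolower(word_tokens(s)$form)),
         use.names = FALSE)
}

#' Lexical richness features
#'
#' From the case-folded word forms of a document: lexical diversity
#' `dvrst = V/W`, the Brunet index `BI = W^(V^-0.165)` (richer language has
#' lower values), and Honore's statistic `HS = 100 log(W) / (1 - hap/V)`
#' (richer language has higher values), where `W` is the word-token count,
#' `V` the vocabulary size and `hap` the number of hapax legomena. When
#' every vocabulary item is a hapax (`hap == V`) HS is undefined and
#' returned as `NA`.
#'
#' @param doc A `parsed_document`.
#' @return Named numeric vector `c(dvrst, BI, HS)`.
#' @export
lexical_features <- function(doc) {
  forms <- doc_forms(doc)
  W <- length(forms)
  if (W == 0L) stop("document has no word tokens")
  tab <- table(forms)
  V <- length(tab)
  hap <- sum(tab == 1L)
  HS <- if (hap == V) NA_real_ else 100 * log(W) / (1 - hap / V)
  c(dvrst = V / W, BI = W^(V^-0.165), HS = HS)
}

#' Sentence-structure features
#'
#' Mean number of word tokens per sentence (`wrd_sent`) and the meaningful
#' fraction of the vocabulary (`nonstop`): the share of distinct word forms
#' that are not stopwords.
#'
#' @param doc A `parsed_document`.
#' @param stopwords Character vector of (case-folded) stopwords; may be
#'   empty, in which case `nonstop = 1`.
#' @return Named numeric vector `c(wrd_sent, nonstop)`.
#' @export
structure_features <- function(doc, stopwords = character(0)) {
  counts <- vapply(doc$sentences, function(s) nrow(word_tokens(s)), numeric(1))
  if (sum(counts) == 0) stop("document has no word tokens")
  vocab <- unique(doc_forms(doc))
  c(wrd_sent = mean(counts),
    nonstop = sum(!vocab %in% tolower(stopwords)) / length(vocab))
}

#' Word-class (POS ratio) features
#'
#' Counts tokens tagged NOUN, VERB and PRON and returns the noun-over-verb
#' ratio `NnVrb = nn/vrb`, the noun ratio `Nn = nn/(vrb + nn)` and the
#' pronoun ratio `Prn = prn/(nn + prn)`. A zero denominator yields `NA` for
#' that ratio.
#'
#' @param doc A `parsed_document`.
#' @param noun_tags POS tags counted as nouns (default `"NOUN"`; add
#'   `"PROPN"` for tagsets that fold proper nouns in).
#' @return Named numeric vector `c(NnVrb, Nn, Prn)`.
#' @export
word_class_features <- function(doc, noun_tags = "NOUN") {
  upos <- unlist(lapply(doc$sentences, function(s) word_tokens(s)$upos),
                 use.names = FALSE)
  nn <- sum(upos %in% noun_tags)
  vrb <- sum(upos == "VERB")
  prn <- sum(upos == "PRON")
  c(NnVrb = if (vrb == 0L) NA_real_ else nn / vrb,
    Nn    = if (vrb + nn == 0L) NA_real_ else nn / (vrb + nn),
    Prn   = if (nn + prn == 0L) NA_real_ else prn / (nn + prn))
}

# Pre-order traversal of a dependency tree over word-token positions:
# visit the root, then each child subtree in sentence order. Returns the
# visited positions; used to enumerate tokens when summing dependency
# distances, and must enumerate every token exactly once.
preorder_positions <- function(heads) {
  children <- split(seq_along(heads), heads)
  out <- integer(0)
  visit <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (ch in sort(children[[as.character(node)]])) visit(ch)
  }
  for (root in which(heads == 0L)) visit(root)
  out
}

#' Mean dependency distance of a document
#'
#' For each sentence, the dependency distance of a non-root word token is
#' the absolute difference between its position and its head's position
#' (1-based, counted over word tokens only); the sentence MDD is the sum of
#' those distances divided by `N - 1` for `N` word tokens; the document MDD
#' is the mean over sentences. Tokens are enumerated by pre-order tree
#' traversal (root, then child subtrees left to right), which visits each
#' token once, so the result equals the direct per-token sum. Sentences with
#' fewer than two word tokens are skipped.
#'
#' @param doc A `parsed_document`.
#' @return The document MDD (numeric scalar).
#' @export
compute_mdd <- function(doc) {
  sent_mdd <- vapply(doc$sentences, function(s) {
    w <- word_tokens(s)
    n <- nrow(w)
    if (n < 2L) return(NA_real_)
    # re-index heads over word tokens; links to excluded (PUNCT) heads
    # contribute nothing, like the root's own link
    pos <- stats::setNames(seq_len(n), w$id)
    heads <- ifelse(w$head == 0L, 0L,
                    ifelse(as.character(w$head) %in% names(pos),
                           pos[as.character(w$head)], 0L))
    total <- 0
    for (i in preorder_positions(as.integer(heads))) {
      h <- heads[[i]]
      if (h != 0L) total <- total + abs(h - i)
    }
    total / (n - 1)
  }, numeric(1))
  sent_mdd <- sent_mdd[!is.na(sent_mdd)]
  if (length(sent_mdd) == 0L) stop("no sentence with >= 2 word tokens")
  mean(sent_mdd)
}

#' Extract the full nine-feature vector for one document
#'
#' Composes [lexical_features()], [structure_features()],
#' [word_class_features()] and [compute_mdd()] into a named vector with
#' fields `dvrst, BI, HS, wrd_sent, nonstop, NnVrb, Nn, Prn, MDD`.
#' Undefined components are `NA` sentinels.
#'
#' @inheritParams structure_features
#' @inheritParams word_class_features
#' @return Named numeric vector of length 9 (class `nlp_features`).
#' @export
extract_features <- function(doc, stopwords = character(0), noun_tags = "NOUN") {
  mdd <- tryCatch(compute_mdd(doc), error = function(e) NA_real_)
  v <- c(lexical_features(doc), structure_features(doc, stopwords),
         word_class_features(doc, noun_tags), MDD = mdd)
  structure(v[nlp_feature_names], class = "nlp_features",
            names = nlp_feature_names)
}

#' Aggregate per-document feature vectors to one subject row
#'
#' Field-wise arithmetic mean across a subject's documents, ignoring `NA`
#' sentinels per field; a field undefined in every document stays `NA`.
#'
#' @param vectors List of `nlp_features` vectors.
#' @return Named numeric vector of length 9 (class `nlp_features`).
#' @export
aggregate_user_features <- function(vectors) {
  if (length(vectors) < 1L) stop("no feature vectors to aggregate")
  m <- do.call(rbind, lapply(vectors, unclass))
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  structure(out[nlp_feature_names], class = "nlp_features",
            names = nlp_feature_names)
}

#' Per-subject linguistic feature table
#'
#' Extracts the nine features for every document and averages them within
#' subject.
#'
#' @param docs List of `parsed_document` objects.
#' @inheritParams extract_features
#' @return data.frame with `subject_id`, `n_texts` and one column per
#'   feature.
#' @export
nlp_feature_table <- function(docs, stopwords = character(0), noun_tags = "NOUN") {
  subj <- vapply(docs, function(d) d$subject_id, character(1))
  rows <- lapply(split(docs, subj), function(dd) {
    agg <- aggregate_user_features(lapply(dd, extract_features,
                                          stopwords = stopwords,
                                          noun_tags = noun_tags))
    cbind(data.frame(subject_id = dd[[1]]$subject_id, n_texts = length(dd),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(agg))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
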