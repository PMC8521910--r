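# Synthetic cohort generation. Keystroke timings are log-normal (the
# standard model for keystroke latencies), vocabularies are Zipf-distributed,
# POS tags come from a subject-level multinomial, and dependency trees are
# random attachment trees with an exponential distance decay whose scale
# controls the mean dependency distance. Group effects are standardized
# shifts (Cohen's d on the subject-level parameter scale) applied to the
# MCI group in the pathology directions: longer and more variable hold
# times, longer flight times, steeper Zipf exponent (poorer lexical
# richness), fewer stopwords, lower noun rate, higher pronoun rate, shorter
# dependency distances.

# subject-level generator SDs (the scale on which effect sizes d act)
.sd_ht_loc <- 0.08
.sd_ht_scale <- 0.04
.sd_ft_loc <- 0.10
.sd_zipf <- 0.08
.sd_stop <- 0.05
.sd_mdd <- 0.20

#' Cohort generator specification
#'
#' Effect sizes are standardized differences (d) applied to the MCI group
#' on the subject-level parameter scale, each in the direction reported for
#' cognitive impairment (see package vignette). Setting every effect to 0
#' yields an exchangeable null cohort.
#'
#' @param n_mci,n_hc Subject counts (defaults 11 and 12, the study cohort).
#' @param sessions_per_subject,texts_per_subject Per-subject data volumes.
#' @param d_ht_loc,d_ht_scale,d_ft_loc Keystroke effects: hold-time
#'   location, hold-time variability, flight-time location.
#' @param d_zipf,d_stop,d_noun,d_pron,d_mdd Linguistic effects: Zipf
#'   exponent, stopword rate, noun rate, pronoun rate, dependency-distance
#'   scale.
#' @param seed Mandatory integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mci = 11L, n_hc = 12L, sessions_per_subject = 20L,
                        texts_per_subject = 4L,
                        d_ht_loc = 1, d_ht_scale = 1, d_ft_loc = 0.5,
                        d_zipf = 1, d_stop = 1, d_noun = 1, d_pron = 1,
                        d_mdd = 1, seed = 1L) {
  stopifnot(n_mci > 0, n_hc > 0, sessions_per_subject > 0,
            texts_per_subject > 0, is.finite(seed))
  eff <- c(d_ht_loc = d_ht_loc, d_ht_scale = d_ht_scale, d_ft_loc = d_ft_loc,
           d_zipf = d_zipf, d_stop = d_stop, d_noun = d_noun,
           d_pron = d_pron, d_mdd = d_mdd)
  stopifnot(all(is.finite(eff)))
  structure(c(list(n_mci = as.integer(n_mci), n_hc = as.integer(n_hc),
                   sessions_per_subject = as.integer(sessions_per_subject),
                   texts_per_subject = as.integer(texts_per_subject),
                   seed = as.integer(seed)), as.list(eff)),
            class = "cohort_spec")
}

#' Null and powered cohort presets
#'
#' `null_cohort_spec()`: 25 + 25 subjects, every effect size 0 — the two
#' groups are exchangeable. `powered_cohort_spec()`: large effects (d = 3
#' on hold-time location, d = 2 on the other dials) so the group difference
#' dominates sampling noise.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(n_mci = 25L, n_hc = 25L, d_ht_loc = 0, d_ht_scale = 0,
              d_ft_loc = 0, d_zipf = 0, d_stop = 0, d_noun = 0, d_pron = 0,
              d_mdd = 0, seed = seed, ...)
}

#' @rdname null_cohort_spec
#' @export
powered_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(d_ht_loc = 3, d_ht_scale = 2, d_ft_loc = 2, d_zipf = 2,
              d_stop = 2, d_noun = 2, d_pron = 2, d_mdd = 2, seed = seed, ...)
}

# subject-level typing parameters; d_* already include direction
typing_params <- function(d_ht_loc = 0, d_ht_scale = 0, d_ft_loc = 0) {
  list(ht_meanlog = stats::rnorm(1, log(0.10) + d_ht_loc * .sd_ht_loc, .sd_ht_loc),
       ht_sdlog = max(0.05, stats::rnorm(1, 0.25 + d_ht_scale * .sd_ht_scale,
                                         .sd_ht_scale)),
       ft_meanlog = stats::rnorm(1, log(0.35) + d_ft_loc * .sd_ft_loc, .sd_ft_loc),
       ft_sdlog = 0.45, pause_rate = 0.04, n_mean = 80)
}

#' Simulate one typing session
#'
#' Key-event count is log-normal around `n_mean` (support reaches below and
#' above the 40-press QC bar); hold times and inter-key gaps are log-normal
#' in the subject's parameters, with occasional long pauses (> 3 s) injected
#' at `pause_rate` to exercise the flight-time filter. All times are
#' quantized to whole milliseconds and timestamps assembled so that the
#' hold/flight-time equations recover the drawn values exactly; the drawn
#' series are attached as attributes `true_ht` / `true_ft` (seconds).
#'
#' Uses the current R RNG state; seed upstream for reproducibility.
#'
#' @param params Subject typing parameters (`ht_meanlog`, `ht_sdlog`,
#'   `ft_meanlog`, `ft_sdlog`, `pause_rate`, `n_mean`).
#' @param session_id,subject_id Identifiers.
#' @return A [typing_session()].
#' @export
simulate_typing_session <- function(params, session_id = "s1",
                                    subject_id = "u1") {
  n <- max(2L, round(stats::rlnorm(1, log(params$n_mean), 0.35)))
  ht_ms <- pmax(1, round(1000 * stats::rlnorm(n, params$ht_meanlog,
                                              params$ht_sdlog)))
  gap <- stats::rlnorm(n - 1, params$ft_meanlog, params$ft_sdlog)
  pause <- stats::runif(n - 1) < params$pause_rate
  gap[pause] <- gap[pause] + stats::runif(sum(pause), 3.5, 12)
  ft_ms <- pmax(1, round(1000 * gap))
  press <- numeric(n); release <- numeric(n)
  press[1] <- 0
  release[1] <- ht_ms[1]
  for (i in seq_len(n - 1)) {
    press[i + 1] <- release[i] + ft_ms[i]
    release[i + 1] <- press[i + 1] + ht_ms[i + 1]
  }
  s <- typing_session(session_id, subject_id, press, release)
  attr(s, "true_ht") <- ht_ms / 1000
  attr(s, "true_ft") <- ft_ms / 1000
  s
}

zipf_sample <- function(n, n_ranks, a) {
  sample.int(n_ranks, n, replace = TRUE, prob = seq_len(n_ranks)^(-a))
}

# attach tokens to a random tree: process tokens outward from the root and
# head each one at an already-attached token, weighted exp(-(dist-1)/scale);
# at tiny scale this degenerates to adjacent attachment (every distance 1)
random_tree <- function(n, scale) {
  if (n == 1L) return(0L)
  root <- sample.int(n, 1)
  heads <- integer(n); heads[root] <- 0L
  ord <- setdiff(order(abs(seq_len(n) - root), seq_len(n)), root)
  attached <- root
  for (i in ord) {
    d <- abs(i - attached)
    if (scale < 1e-3) {
      h <- attached[which.min(d)]
    } else {
      w <- exp(-(d - 1) / scale)
      if (!any(w > 0)) w <- as.numeric(d == min(d))
      h <- if (length(attached) == 1L) attached
           else sample(attached, 1, prob = w)
    }
    heads[i] <- h
    attached <- c(attached, i)
  }
  heads
}

#' Default stopword lexicon of the generator
#'
#' Forty synthetic function-word forms; written to `stopwords.txt` by
#' [simulate_cohort()] so the round trip through [read_stopwords()] is
#' exercised. Any real-language list (e.g. an NLTK stopword file) can be
#' used instead.
#'
#' @return Character vector.
#' @export
default_stopwords <- function() sprintf("sw%02d", 1:40)

# subject-level linguistic parameters
linguistic_params <- function(d_zipf = 0, d_stop = 0, d_noun = 0,
                              d_pron = 0, d_mdd = 0) {
  p_noun <- min(0.6, max(0.05, stats::rnorm(1, 0.32 - d_noun * 0.03, 0.02)))
  p_verb <- min(0.6, max(0.05, stats::rnorm(1, 0.24, 0.02)))
  p_pron <- min(0.4, max(0.02, stats::rnorm(1, 0.10 + d_pron * 0.02, 0.015)))
  rest <- max(1e-6, 1 - p_noun - p_verb - p_pron)
  list(zipf_a = max(0.7, stats::rnorm(1, 1.05 + d_zipf * .sd_zipf, .sd_zipf)),
       stop_rate = min(0.7, max(0.05, stats::rnorm(1, 0.35 - d_stop * .sd_stop,
                                                   .sd_stop))),
       pos_probs = c(NOUN = p_noun, VERB = p_verb, PRON = p_pron,
                     ADJ = rest * 0.4, ADV = rest * 0.3, X = rest * 0.3),
       mdd_scale = max(1e-6, stats::rnorm(1, 1.5 - d_mdd * .sd_mdd, .sd_mdd)),
       vocab_size = 500L)
}

#' Simulate one dependency-parsed document
#'
#' Sentences of 2+ words; each token is a stopword (function word, tags
#' DET/ADP/CCONJ, forms from the stopword lexicon) with probability
#' `stop_rate`, otherwise a content word with a Zipf-distributed form and a
#' POS tag from the subject's NOUN/VERB/PRON/... multinomial. Each sentence
#' gets a random single-root dependency tree whose distance scale controls
#' the MDD, plus a trailing full stop (PUNCT, attached to the root).
#'
#' Uses the current R RNG state; seed upstream for reproducibility.
#'
#' @param params Subject linguistic parameters (see the cohort generator).
#' @param doc_id,subject_id Identifiers.
#' @param n_sentences Number of sentences (default drawn in 3..8).
#' @param stopwords Stopword lexicon to draw function words from.
#' @return A `parsed_document`.
#' @export
simulate_document <- function(params, doc_id = "d1", subject_id = "u1",
                              n_sentences = NULL,
                              stopwords = default_stopwords()) {
  if (is.null(n_sentences)) n_sentences <- sample(3:8, 1)
  func_tags <- c("DET", "ADP", "CCONJ")
  sentences <- vector("list", n_sentences)
  for (k in seq_len(n_sentences)) {
    nw <- 2L + stats::rpois(1, 5)
    is_stop <- stats::runif(nw) < params$stop_rate
    form <- character(nw); upos <- character(nw)
    n_stop <- sum(is_stop)
    if (n_stop > 0) {
      form[is_stop] <- stopwords[zipf_sample(n_stop, length(stopwords), 1)]
      upos[is_stop] <- sample(func_tags, n_stop, replace = TRUE)
    }
    n_cont <- nw - n_stop
    if (n_cont > 0) {
      form[!is_stop] <- sprintf("w%04d",
                                zipf_sample(n_cont, params$vocab_size,
                                            params$zipf_a))
      upos[!is_stop] <- sample(names(params$pos_probs), n_cont,
                               replace = TRUE, prob = params$pos_probs)
    }
    heads <- random_tree(nw, params$mdd_scale)
    root <- which(heads == 0L)
    sentences[[k]] <- data.frame(
      id = seq_len(nw + 1L), form = c(form, "."),
      upos = c(upos, "PUNCT"), head = c(heads, root),
      stringsAsFactors = FALSE)
  }
  parsed_document(doc_id, subject_id, sentences)
}

#' Severity generator specification
#'
#' Stand-in for a clinician-scored fine-motor cohort: subjects span the 0-4
#' severity range; severity acts monotonically on the typing parameters
#' (hold-time log-location +0.12 per point, hold-time log-SD +0.06,
#' flight-time log-location +0.10) and the three item scores (rigidity,
#' alternate finger tapping, bradykinesia) are noisy integer readings of
#' the same latent severity, which induces their inter-item correlation.
#'
#' @param n_subjects,sessions_per_subject Cohort shape (defaults 30 and 20).
#' @param seed Mandatory integer seed.
#' @return A `severity_spec` list.
#' @export
severity_generator_spec <- function(n_subjects = 30L,
                                    sessions_per_subject = 20L, seed = 1L) {
  stopifnot(n_subjects >= 3, sessions_per_subject > 0, is.finite(seed))
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 ht_loc_slope = 0.12, ht_scale_slope = 0.06,
                 ft_loc_slope = 0.10, item_noise = 0.35,
                 seed = as.integer(seed)),
            class = "severity_spec")
}

#' Simulate a severity-labelled keystroke training set
#'
#' Generates typing sessions whose hold/flight-time distributions shift
#' monotonically with each subject's latent severity, preprocesses them
#' (QC, filtering, padding) and pairs each padded series with the subject's
#' item scores. Latent severities cycle through 0..4 across subjects;
#' ground truth is retained per sample.
#'
#' @param spec A [severity_generator_spec()].
#' @return List of `severity_sample` objects (`dynamics`, `subject_id`,
#'   `scores`, `latent`), with attribute `truth` (subject table).
#' @export
simulate_severity_dataset <- function(spec = severity_generator_spec()) {
  set.seed(spec$seed)
  samples <- list()
  truth <- data.frame()
  for (i in seq_len(spec$n_subjects)) {
    sev <- (i - 1L) %% 5L
    lat <- sev + stats::rnorm(1, 0, 0.25)
    items <- pmin(4L, pmax(0L, round(lat + stats::rnorm(3, 0, spec$item_noise))))
    names(items) <- c("item22", "item23", "item31")
    params <- list(
      ht_meanlog = log(0.10) + spec$ht_loc_slope * lat + stats::rnorm(1, 0, 0.03),
      ht_sdlog = max(0.05, 0.22 + spec$ht_scale_slope * lat),
      ft_meanlog = log(0.35) + spec$ft_loc_slope * lat + stats::rnorm(1, 0, 0.04),
      ft_sdlog = 0.45, pause_rate = 0.03, n_mean = 80)
    sid <- sprintf("subj%02d", i)
    truth <- rbind(truth, data.frame(subject_id = sid, severity = sev,
                                     latent = lat, item22 = items[[1]],
                                     item23 = items[[2]], item31 = items[[3]]))
    for (j in seq_len(spec$sessions_per_subject)) {
      sess <- simulate_typing_session(params, sprintf("%s_s%03d", sid, j), sid)
      dyn <- pad_series(filter_dynamics(compute_dynamics(sess)))
      if (dyn$unusable) next
      samples[[length(samples) + 1L]] <- structure(
        list(dynamics = dyn, subject_id = sid, scores = items, latent = lat),
        class = "severity_sample")
    }
  }
  attr(samples, "truth") <- truth
  samples
}

#' Simulate a full two-group cohort
#'
#' Draws subject-level typing and linguistic parameters per group (MCI
#' shifted by the spec's effect sizes), generates sessions and documents,
#' and produces labels plus MMSE/FUCAS/FRSSD-like clinical scores that
#' correlate negatively (MMSE) and positively (FUCAS, FRSSD) with the
#' subject's latent impairment. With `dir` set, writes `sessions.jsonl`,
#' `conllu/<subject>.conllu`, `labels.csv`, `clinical.csv`,
#' `stopwords.txt` and `manifest.json` in exactly the formats the reading
#' functions consume.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return A `synthetic_cohort` list: `sessions`, `documents`, `labels`,
#'   `clinical`, `subject_params`, `stopwords`, `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            overwrite = FALSE) {
  set.seed(spec$seed)
  ids <- c(sprintf("mci%02d", seq_len(spec$n_mci)),
           sprintf("hc%02d", seq_len(spec$n_hc)))
  labels <- c(rep(1L, spec$n_mci), rep(0L, spec$n_hc))
  stopwords <- default_stopwords()

  sessions <- list(); documents <- list()
  subject_params <- list()
  clinical <- data.frame()
  for (i in seq_along(ids)) {
    g <- labels[[i]]
    tp <- typing_params(g * spec$d_ht_loc, g * spec$d_ht_scale,
                        g * spec$d_ft_loc)
    lp <- linguistic_params(g * spec$d_zipf, g * spec$d_stop,
                            g * spec$d_noun, g * spec$d_pron, g * spec$d_mdd)
    subject_params[[ids[[i]]]] <- c(tp, lp)
    for (j in seq_len(spec$sessions_per_subject))
      sessions[[length(sessions) + 1L]] <- simulate_typing_session(
        tp, sprintf("%s_s%03d", ids[[i]], j), ids[[i]])
    for (j in seq_len(spec$texts_per_subject))
      documents[[length(documents) + 1L]] <- simulate_document(
        lp, sprintf("%s_t%02d", ids[[i]], j), ids[[i]], stopwords = stopwords)
    z <- ((tp$ht_meanlog - log(0.10)) / .sd_ht_loc +
            (lp$zipf_a - 1.05) / .sd_zipf) / 2
    clinical <- rbind(clinical, data.frame(
      subject_id = ids[[i]],
      MMSE = min(30, max(10, 29 - 1.2 * z + stats::rnorm(1, 0, 0.8))),
      FUCAS = max(42, 43 + 2.5 * z + stats::rnorm(1, 0, 2)),
      FRSSD = max(0, 3 + 1.5 * z + stats::rnorm(1, 0, 1.2))))
  }
  cohort <- structure(
    list(sessions = sessions, documents = documents,
         labels = data.frame(subject_id = ids, label = labels,
                             stringsAsFactors = FALSE),
         clinical = clinical, subject_params = subject_params,
         stopwords = stopwords, spec = spec),
    class = "synthetic_cohort")

  if (!is.null(dir)) {
    if (dir.exists(dir) && !overwrite &&
        length(list.files(dir, all.files = TRUE, no.. = TRUE)) > 0)
      stop("output directory exists and is not empty: ", dir,
           " (use overwrite = TRUE)")
    dir.create(file.path(dir, "conllu"), recursive = TRUE, showWarnings = FALSE)
    write_sessions(sessions, file.path(dir, "sessions.jsonl"))
    for (id in ids) {
      dd <- Filter(function(d) d$subject_id == id, documents)
      write_conllu(dd, file.path(dir, "conllu", paste0(id, ".conllu")))
    }
    utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    writeLines(stopwords, file.path(dir, "stopwords.txt"))
    jsonlite::write_json(
      list(generator = "cogtype::simulate_cohort", seed = spec$seed,
           spec = unclass(spec),
           distributions = list(
             hold_time = "log-normal, subject log-location SD 0.08, base median 0.10 s",
             flight_time = "log-normal, base median 0.35 s, pauses > 3 s at rate 0.04",
             vocabulary = "Zipf over 500 forms, base exponent 1.05",
             trees = "random attachment with exponential distance decay")),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort %d MCI + %d HC, %d sessions, %d documents>\n",
              x$spec$n_mci, x$spec$n_hc, length(x$sessions),
              length(x$documents)))
  invisible(x)
}

#' Build the subject-level feature table of a synthetic cohort
#'
#' Linguistic features always; R/B/AFT index features when `models` is
#' given.
#'
#' @param cohort A `synthetic_cohort`.
#' @param models Optional `fmi_models` for the keystroke indices.
#' @return A [feature_table()].
#' @export
cohort_feature_table <- function(cohort, models = NULL) {
  nlp <- nlp_feature_table(cohort$documents, cohort$stopwords)
  tab <- merge(cohort$labels, nlp, by = "subject_id")
  if (!is.null(models)) {
    fmi <- fmi_feature_table(cohort$sessions, models)
    tab <- merge(tab, fmi[, c("subject_id", "R", "B", "AFT")],
                 by = "subject_id")
  }
  tab <- tab[match(cohort$labels$subject_id, tab$subject_id), , drop = FALSE]
  tab <- tab[!is.na(tab$subject_id), , drop = FALSE]
  feature_table(tab$subject_id, tab$label,
                tab[, setdiff(names(tab), c("subject_id", "label", "n_texts")),
                    drop = FALSE])
}
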