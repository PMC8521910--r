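#' Read dependency-parsed documents from a CoNLL-U file
#'
#' Parses the standard 10-column CoNLL-U format. Multiword-token ranges
#' (`1-2`) and empty nodes (`1.1`) are ignored. Documents are split on
#' `# newdoc id = ...` comments when present, otherwise the whole file is a
#' single document named after the file. A `# subject = ...` (or
#' `# subject_id = ...`) comment sets the subject; otherwise the part of the
#' file name before the first underscore is used.
#'
#' Each sentence must have exactly one root token (`HEAD == 0`) and
#' consistent 1-based ids; offending sentences are dropped with a warning.
#'
#' @param path Path to a `.conllu` file.
#' @return List of `parsed_document` objects, each a list with `doc_id`,
#'   `subject_id` and `sentences`; a sentence is a data.frame with columns
#'   `id`, `form`, `upos`, `head`.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("cannot read CoNLL-U file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  fallback_doc <- sub("\\.[^.]*$", "", basename(path))
  fallback_subj <- sub("_.*$", "", fallback_doc)

  docs <- list()
  cur_doc_id <- fallback_doc; cur_subj <- fallback_subj
  sentences <- list(); tok_buf <- list(); n_bad <- 0L

  flush_sentence <- function() {
    if (length(tok_buf) == 0L) return(invisible())
    toks <- do.call(rbind, tok_buf)
    tok_buf <<- list()
    n <- nrow(toks)
    ok <- identical(toks$id, seq_len(n)) &&
      all(toks$head >= 0L & toks$head <= n) &&
      all(toks$head != toks$id) &&
      sum(toks$head == 0L) == 1L
    if (!ok) { n_bad <<- n_bad + 1L; return(invisible()) }
    sentences[[length(sentences) + 1L]] <<- toks
  }
  flush_doc <- function() {
    flush_sentence()
    if (length(sentences) > 0L)
      docs[[length(docs) + 1L]] <<- parsed_document(cur_doc_id, cur_subj, sentences)
    sentences <<- list()
  }

  for (line in lines) {
    if (!nzchar(trimws(line))) { flush_sentence(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*newdoc id\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2L) { flush_doc(); cur_doc_id <- trimws(m[2]); cur_subj <- fallback_subj }
      m <- regmatches(line, regexec("^#\\s*subject(?:_id)?\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2L) cur_subj <- trimws(m[2])
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) { n_bad <- n_bad + 1L; tok_buf <- list(); next }
    if (grepl("[-.]", f[1])) next  # multiword range or empty node
    tok_buf[[length(tok_buf) + 1L]] <- data.frame(
      id = as.integer(f[1]), form = f[2], upos = f[4],
      head = suppressWarnings(as.integer(f[7])),
      stringsAsFactors = FALSE)
  }
  flush_doc()
  if (n_bad > 0L)
    warning(sprintf("dropped %d invalid sentence(s) in %s", n_bad, path))
  attr(docs, "n_rejected") <- n_bad
  docs
}

#' Construct a parsed document
#'
#' @param doc_id,subject_id Identifier strings.
#' @param sentences List of token data.frames (`id`, `form`, `upos`, `head`).
#' @return A `parsed_document`.
#' @export
parsed_document <- function(doc_id, subject_id, sentences) {
  if (length(sentences) < 1L) stop("a document needs at least one sentence")
  for (s in sentences) {
    stopifnot(all(c("id", "form", "upos", "head") %in% names(s)))
    if (sum(s$head == 0L) != 1L) stop("sentence must have exactly one root")
  }
  structure(list(doc_id = as.character(doc_id),
                 subject_id = as.character(subject_id),
                 sentences = sentences),
            class = "parsed_document")
}

#' @export
print.parsed_document <- function(x, ...) {
  cat(sprintf("<parsed_document %s subject=%s sentences=%d>\n",
              x$doc_id, x$subject_id, length(x$sentences)))
  invisible(x)
}

#' Write parsed documents to a CoNLL-U file
#'
#' Emits `# newdoc id` / `# subject` comments so [read_conllu()] round-trips
#' document and subject identity. Unknown columns are written as `_`.
#'
#' @param docs List of `parsed_document` objects.
#' @param path Output path.
#' @export
write_conllu <- function(docs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in docs) {
    writeLines(c(sprintf("# newdoc id = %s", d$doc_id),
                 sprintf("# subject = %s", d$subject_id)), con)
    for (s in d$sentences) {
      for (i in seq_len(nrow(s))) {
        writeLines(paste(s$id[i], s$form[i], "_", s$upos[i], "_", "_",
                         s$head[i], "_", "_", "_", sep = "\t"), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a stopword list
#'
#' Plain UTF-8 text, one word per line; case-folded on read. Empty lines and
#' lines starting with `#` are ignored.
#'
#' @param path Path to the stopword file.
#' @return Character vector of stopwords.
#' @export
read_stopwords <- function(path) {
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}
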