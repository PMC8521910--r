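#' Construct a typing session
#'
#' A typing session is the raw record of one keyboard interaction: paired
#' press/release timestamps (integer milliseconds since epoch) for every key
#' event, without any character content.
#'
#' @param session_id,subject_id Opaque identifier strings.
#' @param press,release Integer millisecond timestamps, paired index-wise.
#' @return An object of class `typing_session`.
#' @export
typing_session <- function(session_id, subject_id, press, release) {
  press <- as.numeric(press)
  release <- as.numeric(release)
  if (length(press) != length(release) || length(press) < 1L)
    stop("press/release must be non-empty and of equal length")
  if (is.unsorted(press))
    stop("press times must be ascending")
  if (any(release < press))
    stop("release time before press time")
  structure(
    list(session_id = as.character(session_id),
         subject_id = as.character(subject_id),
         press_times = press, release_times = release,
         n_keys = length(press)),
    class = "typing_session")
}

#' @export
print.typing_session <- function(x, ...) {
  cat(sprintf("<typing_session %s subject=%s keys=%d>\n",
              x$session_id, x$subject_id, x$n_keys))
  invisible(x)
}

#' Read typing sessions from a JSON Lines file
#'
#' One JSON object per line: `{"session_id": str, "subject_id": str,
#' "press": [ms...], "release": [ms...]}`. Malformed records (bad JSON,
#' missing fields, mismatched press/release lengths, unsorted presses,
#' release before press) are skipped with a warning; the number of rejected
#' records is attached as attribute `n_rejected`.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of [typing_session()] objects with attribute `n_rejected`.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("cannot read session file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  n_bad <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    s <- NULL
    if (!is.null(rec) && all(c("session_id", "subject_id", "press", "release") %in% names(rec)))
      s <- tryCatch(typing_session(rec$session_id, rec$subject_id, rec$press, rec$release),
                    error = function(e) NULL)
    if (is.null(s)) n_bad <- n_bad + 1L else out[[i]] <- s
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (n_bad > 0L)
    warning(sprintf("skipped %d malformed session record(s) in %s", n_bad, path))
  attr(out, "n_rejected") <- n_bad
  out
}

#' Write typing sessions to a JSON Lines file
#'
#' @param sessions List of [typing_session()] objects.
#' @param path Output path.
#' @export
write_sessions <- function(sessions, path) {
  lines <- vapply(sessions, function(s) {
    jsonlite::toJSON(list(session_id = s$session_id, subject_id = s$subject_id,
                          press = s$press_times, release = s$release_times),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hold- and flight-time series of one session
#'
#' Hold time of key n is the press-to-release interval of that key; flight
#' time of key n is the interval from its release to the next press (may be
#' negative under rollover typing, when the next key is pressed before the
#' previous is released). Both are returned in seconds.
#'
#' @param session A [typing_session()].
#' @return A `dynamics_series`: list with `ht` (length N), `ft` (length
#'   N - 1), `n_raw`, identifiers, and bookkeeping flags.
#' @export
compute_dynamics <- function(session) {
  stopifnot(inherits(session, "typing_session"))
  p <- session$press_times; r <- session$release_times
  n <- length(p)
  ht <- (r - p) / 1000
  ft <- if (n > 1) (p[-1] - r[-n]) / 1000 else numeric(0)
  structure(
    list(session_id = session$session_id, subject_id = session$subject_id,
         ht = ht, ft = ft, n_raw = n,
         filtered = FALSE, unusable = FALSE,
         padded_ht = NULL, padded_ft = NULL),
    class = "dynamics_series")
}

#' @export
print.dynamics_series <- function(x, ...) {
  cat(sprintf("<dynamics_series %s ht=%d ft=%d%s%s>\n", x$session_id,
              length(x$ht), length(x$ft),
              if (x$filtered) " filtered" else "",
              if (x$unusable) " UNUSABLE" else ""))
  invisible(x)
}

#' Filter implausible hold and flight times
#'
#' Retains hold times strictly below `ht_max` and flight times strictly
#' below `ft_max`, removing long pauses and spurious events. Negative flight
#' times (rollover) pass the upper-bound filter. A series whose hold times
#' are all removed is flagged unusable for downstream QC.
#'
#' @param series A `dynamics_series`.
#' @param ht_max Hold-time cut-off in seconds (default 0.700).
#' @param ft_max Flight-time cut-off in seconds (default 3.0).
#' @return The filtered series; attributes `n_removed_ht`, `n_removed_ft`
#'   record the removal counts.
#' @export
filter_dynamics <- function(series, ht_max = 0.700, ft_max = 3.0) {
  stopifnot(inherits(series, "dynamics_series"))
  keep_ht <- series$ht < ht_max
  keep_ft <- series$ft < ft_max
  n_rm_ht <- sum(!keep_ht); n_rm_ft <- sum(!keep_ft)
  series$ht <- series$ht[keep_ht]
  series$ft <- series$ft[keep_ft]
  series$filtered <- TRUE
  series$unusable <- length(series$ht) == 0L
  attr(series, "n_removed_ht") <- n_rm_ht
  attr(series, "n_removed_ft") <- n_rm_ft
  series
}

#' Zero-pad (or truncate) a dynamics series to fixed length
#'
#' Produces `padded_ht`/`padded_ft` of exactly `length` values: shorter
#' sequences are padded with trailing zeros, longer ones truncated to their
#' first `length` values (the earliest, least-fatigued typing).
#'
#' @param series A filtered `dynamics_series`.
#' @param length Target length (default 100).
#' @return The series with `padded_ht`/`padded_ft` set.
#' @export
pad_series <- function(series, length = 100L) {
  stopifnot(inherits(series, "dynamics_series"))
  if (length <= 0L) stop("padding length must be positive")
  pad1 <- function(x) {
    if (base::length(x) >= length) x[seq_len(length)]
    else c(x, numeric(length - base::length(x)))
  }
  series$padded_ht <- pad1(series$ht)
  series$padded_ft <- pad1(series$ft)
  series
}

#' Session-level quality control
#'
#' Keeps sessions with strictly more than `min_presses` key presses, the
#' usability bar used before any feature extraction.
#'
#' @param sessions List of [typing_session()] objects.
#' @param min_presses Minimum key-press count (exclusive; default 40).
#' @return Filtered list, order preserved.
#' @export
qc_sessions <- function(sessions, min_presses = 40L) {
  keep <- vapply(sessions, function(s) s$n_keys > min_presses, logical(1))
  sessions[keep]
}

#' Full keystroke preprocessing for a list of sessions
#'
#' QC, dynamics extraction, filtering and padding in one call; unusable
#' series (all hold times filtered away) are dropped.
#'
#' @inheritParams qc_sessions
#' @inheritParams filter_dynamics
#' @inheritParams pad_series
#' @return List of padded `dynamics_series`.
#' @export
preprocess_sessions <- function(sessions, min_presses = 40L,
                                ht_max = 0.700, ft_max = 3.0, length = 100L) {
  kept <- qc_sessions(sessions, min_presses)
  out <- lapply(kept, function(s)
    pad_series(filter_dynamics(compute_dynamics(s), ht_max, ft_max), length))
  out[!vapply(out, function(d) d$unusable, logical(1))]
}
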