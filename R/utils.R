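# Shared helpers: word-boundary matching, calendar quarters, rounding, I/O.

#' Round half away from zero
#'
#' Presentation rounding used throughout the package for percentages and
#' relative changes: ties are rounded away from zero (so 0.5 -> 1, -0.5 -> -1),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Escape a literal string for use inside a regular expression.
regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Word-boundary regex for a literal phrase: the match may not be preceded or
# followed by an alphanumeric character. Boundaries are transitions between
# alphanumeric and non-alphanumeric, so hyphens and spaces inside the phrase
# are matched literally.
boundary_pattern <- function(phrase) {
  paste0("(?<![[:alnum:]])", regex_escape(phrase), "(?![[:alnum:]])")
}

# Does `text` contain `phrase` on word boundaries, case-insensitively?
contains_phrase <- function(text, phrase) {
  grepl(boundary_pattern(phrase), text, perl = TRUE, ignore.case = TRUE)
}

#' Calendar quarter label of a timestamp
#'
#' Quarters are calendar quarters (January-March is Q1) and labels have the
#' form `"YYYYQk"`, e.g. `"2011Q3"`.
#'
#' @param time a `POSIXct` vector (UTC) or anything coercible via
#'   [as.POSIXct()].
#' @return character vector of quarter labels.
#' @export
quarter_label <- function(time) {
  time <- as.POSIXct(time, tz = "UTC")
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  mo <- as.integer(format(time, "%m", tz = "UTC"))
  sprintf("%dQ%d", yr, (mo - 1L) %/% 3L + 1L)
}

#' Sequence of quarter labels between two quarters
#'
#' @param from,to quarter labels `"YYYYQk"`, inclusive.
#' @return character vector of consecutive quarter labels.
#' @export
quarter_seq <- function(from, to) {
  parse_q <- function(q) {
    m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))[[1]]
    if (length(m) != 3) stop("malformed quarter label: ", q, call. = FALSE)
    as.integer(m[2]) * 4L + as.integer(m[3]) - 1L
  }
  a <- parse_q(from); b <- parse_q(to)
  if (b < a) stop("empty quarter range: ", from, " .. ", to, call. = FALSE)
  idx <- a:b
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

# Uniform random POSIXct within quarter labels (vectorized; length(quarter)
# must be 1 or n).
random_time_in_quarter <- function(quarter, n = length(quarter)) {
  quarter <- rep_len(quarter, n)
  yr <- as.integer(substr(quarter, 1, 4))
  qk <- as.integer(substr(quarter, 6, 6))
  start <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", yr, (qk - 1L) * 3L + 1L),
                      tz = "UTC")
  end <- quarter_end(quarter)
  start + stats::runif(n, 0, as.numeric(difftime(end, start, units = "secs")))
}

# End-of-quarter instant (exclusive upper bound) for cumulative slicing.
quarter_end <- function(quarter) {
  yr <- as.integer(substr(quarter, 1, 4))
  qk <- as.integer(substr(quarter, 6, 6))
  end_yr <- ifelse(qk == 4L, yr + 1L, yr)
  end_mo <- ifelse(qk == 4L, 1L, qk * 3L + 1L)
  as.POSIXct(sprintf("%d-%02d-01 00:00:00", end_yr, end_mo), tz = "UTC")
}

#' Read a plain-text lexicon
#'
#' One entry per line; blank lines and lines starting with `#` are ignored;
#' entries are trimmed and lowercased.
#'
#' @param path file path.
#' @return character vector of phrases.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tolower(lines)
}

#' Read posts from a JSONL file
#'
#' One JSON object per line with keys `forum`, `post_id`, `thread_id`,
#' `author_id`, `timestamp` (ISO-8601, UTC) and `text`.
#'
#' @param path file path.
#' @return a tibble of posts with a `POSIXct` timestamp column.
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    forum     = vapply(recs, `[[`, "", "forum"),
    post_id   = vapply(recs, `[[`, "", "post_id"),
    thread_id = vapply(recs, `[[`, "", "thread_id"),
    author_id = vapply(recs, `[[`, "", "author_id"),
    timestamp = as.POSIXct(vapply(recs, `[[`, "", "timestamp"),
                           format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    text      = vapply(recs, `[[`, "", "text")
  )
}

#' Write posts to a JSONL file
#'
#' @param posts a tibble of posts as returned by [read_posts_jsonl()] or
#'   [generate_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  stamp <- format(posts$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    writeLines(jsonlite::toJSON(list(
      forum = posts$forum[i], post_id = posts$post_id[i],
      thread_id = posts$thread_id[i], author_id = posts$author_id[i],
      timestamp = stamp[i], text = posts$text[i]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}
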