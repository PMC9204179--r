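# Dictionary matching of adverse-event verbatims in post text. Matching is
# case-insensitive, on word boundaries, longest-match-first; shorter synonyms
# wholly inside an accepted longer match are suppressed, and each PT is
# counted at most once per post. No negation or hypothetical filtering is
# applied (a documented limitation: "no more fractures" still matches).

# Resolve one post's candidate matches: candidates arrive in priority order
# (synonym length desc, synonym lex, position asc); a candidate is accepted
# iff it overlaps no previously accepted span. Then one event per PT (the
# earliest accepted span wins).
resolve_candidates <- function(cand, text) {
  acc_s <- integer(0); acc_e <- integer(0)  # accepted spans, end exclusive
  keep <- logical(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    s <- cand$start[j]; e <- cand$end[j]
    if (any(s < acc_e & e > acc_s)) next
    keep[j] <- TRUE
    acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
  }
  cand <- cand[keep, ]
  ord <- order(cand$start)
  cand <- cand[ord[!duplicated(cand$pt_code[ord])], ]
  cand[order(cand$start), ]
}

#' Match terminology synonyms in post text
#'
#' Scans each post's text (the `masked_text` column when present, otherwise
#' `text`) for synonym surface strings and maps hits to PT codes. Matching is
#' case-insensitive on word boundaries; longer synonyms win over shorter ones
#' at the same location, ties broken lexicographically, so the result does
#' not depend on synonym file order. A PT mentioned several times in one post
#' yields a single event for that post.
#'
#' @param posts a tibble of posts with at least `post_id` and `text`
#'   (or `masked_text`) columns.
#' @param term a `pv_terminology`.
#' @return a tibble of matched events: `post_id`, `pt_code`, `verbatim`,
#'   `start`, `end` (1-based start, exclusive end, offsets into the scanned
#'   text).
#' @export
match_events <- function(posts, term) {
  stopifnot(inherits(term, "pv_terminology"))
  txt_col <- if ("masked_text" %in% names(posts)) "masked_text" else "text"
  txts <- posts[[txt_col]]
  syn <- term$synonyms
  ord <- order(-nchar(syn$synonym), syn$synonym)
  syn_order <- syn[ord, ]
  empty <- tibble::tibble(post_id = character(0), pt_code = character(0),
                          verbatim = character(0), start = integer(0),
                          end = integer(0))
  if (nrow(posts) == 0) return(empty)

  # one vectorized scan per synonym, in priority order
  cands <- vector("list", nrow(syn_order))
  for (k in seq_len(nrow(syn_order))) {
    ml <- gregexpr(boundary_pattern(syn_order$synonym[k]), txts,
                   perl = TRUE, ignore.case = TRUE)
    hits <- which(vapply(ml, function(m) m[1] != -1L, TRUE))
    if (length(hits) == 0) next
    cands[[k]] <- do.call(rbind, lapply(hits, function(i) {
      m <- ml[[i]]
      data.frame(row = i, prio = k, start = as.integer(m),
                 end = as.integer(m) + attr(m, "match.length"),
                 pt_code = syn_order$pt_code[k], stringsAsFactors = FALSE)
    }))
  }
  cands <- do.call(rbind, cands)
  if (is.null(cands) || nrow(cands) == 0) return(empty)

  res <- lapply(split(cands, cands$row), function(cand) {
    cand <- cand[order(cand$prio, cand$start), ]
    resolve_candidates(cand, txts[cand$row[1]])
  })
  res <- do.call(rbind, res)
  tibble::tibble(post_id = posts$post_id[res$row],
                 pt_code = res$pt_code,
                 verbatim = substr(txts[res$row], res$start, res$end - 1L),
                 start = res$start, end = res$end)
}
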