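# Preprocessing chain for raw forum posts: deduplicate -> de-spam ->
# relevance-filter -> mask person names. Stages are pure functions on post
# tibbles; each records the ids it removed so the pipeline can assert
# conservation (|input| = |kept| + sum of removals).

#' Ids removed by an ingest stage
#'
#' Each filtering stage attaches the `post_id`s it dropped to its result;
#' this accessor retrieves them (empty character vector if none).
#'
#' @param x the tibble returned by an ingest stage.
#' @return character vector of removed post ids.
#' @export
removed_ids <- function(x) {
  ids <- attr(x, "removed_ids")
  if (is.null(ids)) character(0) else ids
}

with_removed <- function(kept, removed) {
  attr(kept, "removed_ids") <- removed
  kept
}

#' Remove exact duplicate posts
#'
#' Posts sharing identical content, poster and timestamp are collapsed to a
#' single survivor. Text is compared after Unicode NFC normalization so that
#' encoding variants of the same string compare equal; among duplicates the
#' post with the lexicographically smallest `post_id` survives, and the
#' relative input order of survivors is preserved.
#'
#' @param posts a tibble of posts (`post_id`, `author_id`, `timestamp`,
#'   `text`, ...).
#' @return the surviving posts; removed ids are available via
#'   [removed_ids()].
#' @export
remove_duplicates <- function(posts) {
  if (nrow(posts) == 0) return(with_removed(posts, character(0)))
  key <- paste(stringi::stri_trans_nfc(posts$text), posts$author_id,
               format(posts$timestamp, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC"),
               sep = "\r")
  survivor_id <- ave(posts$post_id, key, FUN = min)
  keep <- posts$post_id == survivor_id
  with_removed(posts[keep, ], posts$post_id[!keep])
}

#' Remove spam posts by keyword lexicon
#'
#' A post is dropped iff its lowercased text contains at least one lexicon
#' phrase as a substring on word boundaries. An empty lexicon is a
#' configuration error: a silent no-op would let spam through unnoticed.
#'
#' @param posts a tibble of posts.
#' @param spam_lexicon character vector of phrases (see [read_lexicon()]).
#' @return the retained posts; removed ids via [removed_ids()].
#' @export
remove_spam <- function(posts, spam_lexicon) {
  if (length(spam_lexicon) == 0) {
    stop("spam lexicon is empty; refusing to run a no-op spam filter",
         call. = FALSE)
  }
  if (nrow(posts) == 0) return(with_removed(posts, character(0)))
  pat <- paste0("(?<![[:alnum:]])(?:",
                paste(regex_escape(spam_lexicon), collapse = "|"),
                ")(?![[:alnum:]])")
  is_spam <- grepl(pat, posts$text, perl = TRUE, ignore.case = TRUE)
  with_removed(posts[!is_spam, ], posts$post_id[is_spam])
}

#' Keep medically relevant posts and record drug mentions
#'
#' A post is retained iff at least one generic-name, brand-name or drug-class
#' keyword of some drug matches its text case-insensitively on word
#' boundaries. Every matched drug is recorded in a `drug_mentions`
#' list-column, so a post mentioning two products counts for both.
#'
#' @param posts a tibble of posts.
#' @param drug_lexicons named list: drug id -> either a character vector of
#'   keywords or a list with elements `generic`, `brand`, `class`.
#' @return retained posts with a `drug_mentions` list-column; removed ids via
#'   [removed_ids()].
#' @export
filter_relevant <- function(posts, drug_lexicons) {
  kw <- lapply(drug_lexicons, function(lex) {
    v <- tolower(unique(unlist(lex, use.names = FALSE)))
    if (length(v) == 0) stop("drug lexicon with no keywords", call. = FALSE)
    v
  })
  if (nrow(posts) == 0) {
    posts$drug_mentions <- list()
    return(with_removed(posts, character(0)))
  }
  hit <- vapply(kw, function(v) {
    pat <- paste0("(?<![[:alnum:]])(?:",
                  paste(regex_escape(v), collapse = "|"),
                  ")(?![[:alnum:]])")
    grepl(pat, posts$text, perl = TRUE, ignore.case = TRUE)
  }, logical(nrow(posts)))
  hit <- matrix(hit, nrow = nrow(posts),
                dimnames = list(NULL, names(drug_lexicons)))
  any_hit <- rowSums(hit) > 0
  kept <- posts[any_hit, ]
  kept$drug_mentions <- lapply(which(any_hit), function(i) {
    names(drug_lexicons)[hit[i, ]]
  })
  with_removed(kept, posts$post_id[!any_hit])
}

#' Mask person names in post text
#'
#' Replaces every case-insensitive word-boundary occurrence of a dictionary
#' name with the fixed token `"[NAME]"`, writing the result to a
#' `masked_text` column; the original `text` is kept unchanged. The token
#' preserves token boundaries, and the operation is idempotent as long as the
#' dictionary does not contain the word "name".
#'
#' @param posts a tibble of posts.
#' @param name_dictionary character vector of names (see [read_lexicon()]).
#' @return `posts` with a `masked_text` column.
#' @export
mask_pii <- function(posts, name_dictionary) {
  src <- if ("masked_text" %in% names(posts)) posts$masked_text else posts$text
  if (length(name_dictionary) == 0) {
    posts$masked_text <- src
    return(posts)
  }
  nd <- name_dictionary[order(-nchar(name_dictionary), name_dictionary)]
  pat <- paste0("(?<![[:alnum:]])(?:",
                paste(regex_escape(nd), collapse = "|"),
                ")(?![[:alnum:]])")
  posts$masked_text <- gsub(pat, "[NAME]", src, perl = TRUE, ignore.case = TRUE)
  posts
}

#' Run the full ingest pipeline
#'
#' Applies the four preprocessing stages in order (deduplicate, de-spam,
#' relevance-filter, mask names) and returns the clean posts together with a
#' per-stage removal log.
#'
#' @param posts raw posts tibble.
#' @param spam_lexicon,drug_lexicons,name_dictionary stage configuration;
#'   see [remove_spam()], [filter_relevant()], [mask_pii()].
#' @return a list with `posts` (clean posts, with `drug_mentions` and
#'   `masked_text`) and `log` (tibble: `stage`, `removed`, `remaining`).
#' @export
run_ingest <- function(posts, spam_lexicon, drug_lexicons, name_dictionary) {
  s1 <- remove_duplicates(posts)
  s2 <- remove_spam(s1, spam_lexicon)
  s3 <- filter_relevant(s2, drug_lexicons)
  clean <- mask_pii(s3, name_dictionary)
  log <- tibble::tibble(
    stage = c("duplicates", "spam", "irrelevant"),
    removed = c(length(removed_ids(s1)), length(removed_ids(s2)),
                length(removed_ids(s3))),
    remaining = c(nrow(s1), nrow(s2), nrow(s3))
  )
  stopifnot(nrow(posts) == nrow(clean) + sum(log$removed))
  list(posts = clean, log = log)
}

#' Default drug keyword lexicons
#'
#' Generic, brand and class keywords for the two products the package's
#' worked examples follow: denosumab (Prolia, Xgeva; a RANKL inhibitor used
#' in osteoporosis and bone metastases) and pembrolizumab (Keytruda; a PD-1
#' checkpoint inhibitor).
#'
#' @return named list suitable for [filter_relevant()].
#' @export
default_drug_lexicons <- function() {
  list(
    denosumab = list(generic = "denosumab",
                     brand   = c("prolia", "xgeva"),
                     class   = "rankl inhibitor"),
    pembrolizumab = list(generic = "pembrolizumab",
                         brand   = "keytruda",
                         class   = c("checkpoint inhibitor", "pd-1 inhibitor"))
  )
}
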