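# Shared fixtures built in code: small corpora, lexicons, a post constructor.

fixture_term <- function() example_terminology()

fixture_spam_lexicon <- function() {
  read_lexicon(system.file("extdata", "spam_lexicon.txt", package = "pvforum"))
}

fixture_names <- function() {
  read_lexicon(system.file("extdata", "names_dictionary.txt",
                           package = "pvforum"))
}

# Minimal post tibble builder with sensible defaults.
make_posts <- function(text,
                       post_id = sprintf("P%03d", seq_along(text)),
                       author_id = sprintf("A%03d", seq_along(text)),
                       thread_id = "T001",
                       forum = "inspire",
                       timestamp = as.POSIXct("2015-06-01 12:00:00",
                                              tz = "UTC") +
                         3600 * seq_along(text)) {
  tibble::tibble(forum = forum, post_id = post_id,
                 thread_id = rep_len(thread_id, length(text)),
                 author_id = author_id,
                 timestamp = rep_len(timestamp, length(text)),
                 text = text)
}

# A small corpus with every artifact planted, reused across ingest tests.
fixture_corpus <- function(n_posts = 1000, seed = 7,
                           ae_injection = list(
                             list(drug = "denosumab", pt_code = "PT0001",
                                  prob = 0.2))) {
  cfg <- corpus_config(n_posts = n_posts, n_authors = 60, seed = seed,
                       period = c("2012Q1", "2015Q4"),
                       ae_injection = ae_injection)
  generate_corpus(cfg)
}

fixture_ingest <- function(corp) {
  run_ingest(corp$posts, fixture_spam_lexicon(), default_drug_lexicons(),
             fixture_names())
}

# Write a terminology CSV fixture with given rows (for loader error tests).
write_term_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  header <- "synonym,pt_code,pt_name,hlt_code,hlgt_code,soc_code"
  writeLines(c(header, rows), path)
  path
}
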