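# Synthetic forum corpus with known ground truth. Text is template-based:
# slot-filled drug keywords, AE synonyms and neutral filler sentences --
# downstream stages test dictionary matching, not language fidelity, so the
# filler vocabulary is kept disjoint from every lexicon the pipeline matches
# against (drug keywords, terminology synonyms, spam phrases, person names).

FILLER_OPENERS <- c(
  "Quick update from me.",
  "Checking in after a long while.",
  "Hope everyone is doing well this week.",
  "It has been a busy month over here.",
  "Just wanted to share how things are going.",
  "Long time reader, first time writing.",
  "Back again with another update.",
  "Greetings to the whole community."
)

FILLER_CLOSERS <- c(
  "Sending good thoughts to all of you.",
  "Will write more when I know more.",
  "Thanks for reading my long ramble.",
  "Stay strong everyone.",
  "Grateful for this community.",
  "More updates soon, promise.",
  "Take care of yourselves.",
  "Wishing everyone a calm week."
)

DRUG_SENTENCES <- c(
  "I have been taking %s since last spring.",
  "My treatment plan includes %s every few months.",
  "Started %s recently after talking it over with my care team.",
  "Has anyone else here been given %s lately?",
  "The clinic put me on %s at my last visit."
)

AE_SENTENCES <- c(
  "Since then I have been dealing with %s.",
  "The hardest part has been the %s.",
  "My care team thinks it might be %s.",
  "I was not expecting the %s at all.",
  "Now I am coping with %s as well."
)

SPAM_SENTENCES <- c(
  "Visit the number one %s for unbeatable savings today.",
  "Huge savings at our %s this weekend only.",
  "Use this %s before midnight for twenty percent off.",
  "Our %s has everything you could possibly want."
)

NAME_SENTENCES <- c(
  "Thanks %s for the kind words last time.",
  "A big hello to %s from our group.",
  "%s suggested I post here.",
  "My friend %s has been a huge support."
)

#' Constant, ramp and step injection-rate functions
#'
#' Helpers building per-quarter mention-probability functions for
#' [corpus_config()]'s `ae_injection`. Each returns a function of the
#' quarter's position `t` in `[0, 1]` (0 = first quarter of the period,
#' 1 = last).
#'
#' @param p,from,to,before,after probabilities in `[0, 1]`.
#' @param at breakpoint position in `[0, 1]` for [step_rate()].
#' @return a function `t -> probability`.
#' @name injection_rates
NULL

#' @rdname injection_rates
#' @export
constant_rate <- function(p) {
  force(p)
  function(t) rep(p, length(t))
}

#' @rdname injection_rates
#' @export
ramp_rate <- function(from, to) {
  force(from); force(to)
  function(t) from + (to - from) * t
}

#' @rdname injection_rates
#' @export
step_rate <- function(before, after, at = 0.5) {
  force(before); force(after); force(at)
  function(t) ifelse(t < at, before, after)
}

#' Configuration for the synthetic corpus generator
#'
#' @param fora character vector of forum names.
#' @param n_posts total number of posts to emit, duplicates included.
#' @param n_authors number of distinct authors.
#' @param period length-2 character vector of quarter labels
#'   (`c("2010Q3", "2021Q1")`), inclusive.
#' @param drug_lexicons named list as in [filter_relevant()].
#' @param ae_injection list of injection plans, each a list with elements
#'   `drug`, `pt_code` and `prob` (a probability or a function from the
#'   helpers in [injection_rates]). Every `pt_code` must exist in `term`.
#' @param dup_rate,spam_rate,pii_rate,irrelevant_rate fractions in `[0, 1]`:
#'   probability that an emitted post is an exact duplicate of an earlier
#'   one, that a fresh post is spam, that a fresh post carries an inserted
#'   person name, and that a fresh non-spam post mentions no drug.
#' @param author_skew Zipf exponent for the posts-per-author distribution
#'   (0 = uniform; larger = more skewed towards a few prolific authors).
#' @param seed integer seed; the single source of randomness for the run.
#' @return a validated `pv_corpus_config` list.
#' @export
corpus_config <- function(fora = c("inspire", "breastcancer.org",
                                   "healthunlocked.com", "melanoma.org"),
                          n_posts = 1000L,
                          n_authors = 100L,
                          period = c("2010Q3", "2021Q1"),
                          drug_lexicons = default_drug_lexicons(),
                          ae_injection = list(),
                          dup_rate = 0.05,
                          spam_rate = 0.05,
                          pii_rate = 0.1,
                          irrelevant_rate = 0.2,
                          author_skew = 1,
                          seed = 1L) {
  rates <- c(dup_rate = dup_rate, spam_rate = spam_rate, pii_rate = pii_rate,
             irrelevant_rate = irrelevant_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  if (length(period) != 2) stop("period must be c(start, end)", call. = FALSE)
  quarters <- quarter_seq(period[1], period[2])  # errors on empty period
  stopifnot(n_posts >= 1, n_authors >= 1, length(fora) >= 1,
            length(drug_lexicons) >= 1)
  ae_injection <- lapply(ae_injection, function(plan) {
    stopifnot(all(c("drug", "pt_code", "prob") %in% names(plan)))
    if (!plan$drug %in% names(drug_lexicons)) {
      stop("ae_injection names unknown drug: ", plan$drug, call. = FALSE)
    }
    if (is.numeric(plan$prob)) plan$prob <- constant_rate(plan$prob)
    plan
  })
  structure(list(fora = fora, n_posts = as.integer(n_posts),
                 n_authors = as.integer(n_authors), period = period,
                 quarters = quarters, drug_lexicons = drug_lexicons,
                 ae_injection = ae_injection, dup_rate = dup_rate,
                 spam_rate = spam_rate, pii_rate = pii_rate,
                 irrelevant_rate = irrelevant_rate,
                 author_skew = author_skew, seed = as.integer(seed)),
            class = "pv_corpus_config")
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Emits `config$n_posts` posts across the configured fora and period.
#' Duplicate posts are byte-identical copies of an earlier post with the same
#' author and timestamp (only the post id differs); spam posts carry at least
#' one spam-lexicon phrase and never a drug keyword; relevant posts carry at
#' least one drug keyword; planted AE mentions are surface synonyms of the
#' planted PT inserted into the text. The returned ground truth indexes every
#' planted artifact, so filtering and extraction stages can be scored
#' exactly.
#'
#' @param config a [corpus_config()].
#' @param term a `pv_terminology`; every injected PT must exist in it.
#' @param spam_lexicon phrases planted into spam posts (default: the bundled
#'   lexicon).
#' @param name_dictionary names planted into posts (default: the bundled
#'   dictionary).
#' @return a list with `posts` (tibble in corpus schema) and `truth`, itself
#'   a list: `posts` (per-post tibble: `post_id`, `is_duplicate_of`,
#'   `is_spam`, `is_relevant`, `drug`, `quarter`, `inserted_names`,
#'   `true_pt_mentions`) and `planted_rates` (tibble: `drug`, `pt_code`,
#'   `quarter`, `prob`).
#' @export
generate_corpus <- function(config,
                            term = example_terminology(),
                            spam_lexicon = read_lexicon(
                              system.file("extdata", "spam_lexicon.txt",
                                          package = "pvforum")),
                            name_dictionary = read_lexicon(
                              system.file("extdata", "names_dictionary.txt",
                                          package = "pvforum"))) {
  stopifnot(inherits(config, "pv_corpus_config"))
  for (plan in config$ae_injection) {
    if (!plan$pt_code %in% term$hierarchy$pt_code) {
      stop("ae_injection references PT absent from terminology: ",
           plan$pt_code, call. = FALSE)
    }
  }
  n <- config$n_posts
  quarters <- config$quarters
  nq <- length(quarters)
  qfrac <- if (nq == 1) 0 else (seq_len(nq) - 1) / (nq - 1)

  syn_by_pt <- split(term$synonyms$synonym, term$synonyms$pt_code)

  # Sub-streams keyed by fixed offsets from the single config seed, so adding
  # a generator stage never perturbs another.
  set.seed(config$seed + 101L)
  author_w <- (seq_len(config$n_authors))^(-config$author_skew)
  authors <- sprintf("A%05d", sample.int(config$n_authors, n, replace = TRUE,
                                         prob = author_w / sum(author_w)))
  n_threads <- max(1L, n %/% 5L)
  threads <- sprintf("T%05d", sample.int(n_threads, n, replace = TRUE))
  fora <- sample(config$fora, n, replace = TRUE)
  qidx <- sample.int(nq, n, replace = TRUE)
  stamps <- random_time_in_quarter(quarters[qidx], n)

  set.seed(config$seed + 202L)
  is_dup <- stats::runif(n) < config$dup_rate
  is_dup[1] <- FALSE
  u_spam <- stats::runif(n)
  u_irrel <- stats::runif(n)
  u_pii <- stats::runif(n)

  set.seed(config$seed + 303L)
  post_id <- sprintf("P%06d", seq_len(n))
  text <- character(n)
  drug_of <- rep(NA_character_, n)
  is_spam <- logical(n)
  is_relevant <- logical(n)
  dup_of <- rep(NA_character_, n)
  names_ins <- rep(list(character(0)), n)
  pts_ins <- rep(list(character(0)), n)

  drugs <- names(config$drug_lexicons)
  for (i in seq_len(n)) {
    if (is_dup[i]) {
      src <- sample.int(i - 1L, 1L)
      dup_of[i] <- post_id[src]
      text[i] <- text[src]
      authors[i] <- authors[src]
      threads[i] <- threads[src]
      fora[i] <- fora[src]
      stamps[i] <- stamps[src]
      qidx[i] <- qidx[src]
      drug_of[i] <- drug_of[src]
      is_spam[i] <- is_spam[src]
      is_relevant[i] <- is_relevant[src]
      names_ins[i] <- names_ins[src]
      pts_ins[i] <- pts_ins[src]
      next
    }
    parts <- sample(FILLER_OPENERS, 1L)
    if (u_spam[i] < config$spam_rate) {
      is_spam[i] <- TRUE
      parts <- c(parts, sprintf(sample(SPAM_SENTENCES, 1L),
                                sample(spam_lexicon, 1L)))
    } else if (u_irrel[i] >= config$irrelevant_rate) {
      is_relevant[i] <- TRUE
      drug_of[i] <- sample(drugs, 1L)
      kw <- sample(unlist(config$drug_lexicons[[drug_of[i]]],
                          use.names = FALSE), 1L)
      parts <- c(parts, sprintf(sample(DRUG_SENTENCES, 1L), kw))
      mentioned <- character(0)
      for (plan in config$ae_injection) {
        if (plan$drug != drug_of[i]) next
        if (stats::runif(1) < plan$prob(qfrac[qidx[i]])) {
          synv <- sample(syn_by_pt[[plan$pt_code]], 1L)
          parts <- c(parts, sprintf(sample(AE_SENTENCES, 1L), synv))
          mentioned <- c(mentioned, plan$pt_code)
        }
      }
      pts_ins[[i]] <- unique(mentioned)
    }
    if (u_pii[i] < config$pii_rate) {
      nm <- sample(name_dictionary, 1L)
      nm_cap <- paste0(toupper(substr(nm, 1, 1)), substring(nm, 2))
      parts <- c(parts, sprintf(sample(NAME_SENTENCES, 1L), nm_cap))
      names_ins[[i]] <- nm
    }
    parts <- c(parts, sample(FILLER_CLOSERS, 1L))
    text[i] <- paste(parts, collapse = " ")
  }

  planted <- do.call(rbind, lapply(config$ae_injection, function(plan) {
    data.frame(drug = plan$drug, pt_code = plan$pt_code, quarter = quarters,
               prob = plan$prob(qfrac), stringsAsFactors = FALSE)
  }))
  planted <- if (is.null(planted)) {
    tibble::tibble(drug = character(0), pt_code = character(0),
                   quarter = character(0), prob = numeric(0))
  } else tibble::as_tibble(planted)

  list(
    posts = tibble::tibble(forum = fora, post_id = post_id,
                           thread_id = threads, author_id = authors,
                           timestamp = stamps, text = text),
    truth = list(
      posts = tibble::tibble(post_id = post_id, is_duplicate_of = dup_of,
                             is_spam = is_spam, is_relevant = is_relevant,
                             drug = drug_of, quarter = quarters[qidx],
                             inserted_names = names_ins,
                             true_pt_mentions = pts_ins),
      planted_rates = planted
    )
  )
}

#' Generate labeled posts for adverse-event text classification
#'
#' Builds a balanced-vocabulary training set: positive ("AE") documents draw
#' a fraction `signal_rate` of their tokens from `vocab$positive` and the
#' rest from `vocab$shared`; negative documents likewise from
#' `vocab$negative` and `vocab$shared`. With disjoint class vocabularies the
#' classes are perfectly separable; with identical vocabularies and rates the
#' problem degenerates to chance.
#'
#' @param n_pos,n_neg number of positive / negative documents (> 0).
#' @param seed integer seed.
#' @param vocab list with character vectors `positive`, `negative`, `shared`.
#' @param signal_rate fraction of tokens drawn from the class vocabulary.
#' @param doc_length tokens per document.
#' @return tibble with `text` and `label` (`"AE"` / `"not-AE"`).
#' @export
generate_labeled_posts <- function(n_pos, n_neg, seed = 1L,
                                   vocab = default_nb_vocab(),
                                   signal_rate = 0.4,
                                   doc_length = 12L) {
  if (n_pos <= 0 || n_neg <= 0) {
    stop("both classes need at least one document", call. = FALSE)
  }
  stopifnot(all(c("positive", "negative", "shared") %in% names(vocab)))
  set.seed(seed)
  make_doc <- function(class_vocab) {
    # every document carries at least one class-vocabulary token
    k <- max(1L, stats::rbinom(1L, doc_length, signal_rate))
    toks <- c(sample(class_vocab, k, replace = TRUE),
              sample(vocab$shared, doc_length - k, replace = TRUE))
    paste(sample(toks), collapse = " ")
  }
  tibble::tibble(
    text = c(vapply(seq_len(n_pos), function(i) make_doc(vocab$positive), ""),
             vapply(seq_len(n_neg), function(i) make_doc(vocab$negative), "")),
    label = rep(c("AE", "not-AE"), c(n_pos, n_neg))
  )
}

#' Default vocabulary for [generate_labeled_posts()]
#'
#' @return list with `positive` (AE-flavoured tokens), `negative`
#'   (non-medical tokens) and `shared` (neutral filler) vocabularies.
#' @export
default_nb_vocab <- function() {
  list(
    positive = c("fracture", "nausea", "rash", "dizzy", "vomiting", "swelling",
                 "cramps", "fever", "itching", "soreness", "reaction",
                 "worsened", "hospital", "sideeffect"),
    negative = c("recipe", "garden", "holiday", "weather", "movie", "football",
                 "knitting", "travel", "birthday", "concert", "painting",
                 "puzzle", "picnic", "museum"),
    shared = c("today", "week", "month", "feeling", "update", "sharing",
               "morning", "evening", "community", "thread", "reading",
               "writing", "question", "answer", "thanks", "everyone")
  )
}
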