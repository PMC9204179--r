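# Follow-up workflow: rank posts by naive Bayes AE probability, assess which
# data elements required for causality assessment are missing, select
# follow-up candidates under the study's caps, and compute engagement
# metrics on the resulting case timelines.

#' Data elements required for proper assessment of a report
#'
#' The ten elements a reviewer may require, in the priority order used when
#' clamping a question list: confirmation of the diagnosis first, the
#' generic catch-alls (outcome, dose, action taken) last.
#'
#' @return character vector of element names, highest priority first.
#' @export
assessment_elements <- function() {
  c("diagnosis_confirmation", "time_to_onset", "duration", "risk_factors",
    "history_of_similar_events", "concomitant_medication",
    "relevant_medical_history", "outcome", "dose", "action_taken")
}

QUESTION_TEMPLATES <- c(
  diagnosis_confirmation = "Was the event confirmed by a healthcare professional, and how?",
  time_to_onset = "How long after starting the medicine did the event begin?",
  duration = "How long did the event last, or is it still ongoing?",
  risk_factors = "Do you have any conditions or risk factors relevant to this event?",
  history_of_similar_events = "Had you experienced a similar event before starting the medicine?",
  concomitant_medication = "What other medicines were you taking at the time?",
  relevant_medical_history = "What relevant medical history should we know about?",
  outcome = "What was the outcome of the event?",
  dose = "What dose of the medicine were you taking?",
  action_taken = "Was the medicine stopped, reduced, or continued after the event?"
)

#' Default required-element map by AE class
#'
#' Which of the ten [assessment_elements()] a reviewer requires before a
#' report of the given class can be assessed. The map is configuration, not
#' clinical guidance; the `"default"` entry applies to unlisted classes.
#'
#' @return named list: AE class -> character vector of required elements.
#' @export
default_requirements <- function() {
  list(
    fracture = c("diagnosis_confirmation", "time_to_onset", "duration",
                 "risk_factors", "history_of_similar_events",
                 "concomitant_medication", "outcome"),
    skin_reaction = c("diagnosis_confirmation", "time_to_onset",
                      "relevant_medical_history", "concomitant_medication",
                      "outcome", "dose"),
    default = c("diagnosis_confirmation", "time_to_onset", "outcome",
                "concomitant_medication", "relevant_medical_history",
                "action_taken")
  )
}

#' Train a multinomial naive Bayes adverse-event classifier
#'
#' Multinomial model over lowercased word tokens with Laplace smoothing
#' `a = 1`; per-class token likelihoods normalize over the vocabulary plus
#' one out-of-vocabulary bucket, and class priors are the training
#' frequencies. Training is deterministic.
#'
#' @param texts character vector of training documents.
#' @param labels class labels; both classes must be present.
#' @param positive_class label treated as "AE" at scoring time.
#' @return a `pv_nb_model`.
#' @export
train_nb <- function(texts, labels, positive_class = "AE") {
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("training data contains a single class: ", classes, call. = FALSE)
  }
  if (!positive_class %in% classes) {
    stop("positive_class not among labels", call. = FALSE)
  }
  toks <- nb_tokenize(texts)
  vocab <- sort(unique(unlist(toks)))
  counts <- sapply(classes, function(cl) {
    tab <- table(factor(unlist(toks[labels == cl]), levels = vocab))
    as.numeric(tab)
  })
  counts <- matrix(counts, nrow = length(vocab),
                   dimnames = list(vocab, classes))
  totals <- colSums(counts)
  denom <- totals + length(vocab) + 1  # +1: out-of-vocabulary bucket
  loglik <- log(sweep(counts + 1, 2, denom, "/"))
  log_oov <- log(1 / denom)
  structure(list(vocab = vocab, loglik = loglik, log_oov = log_oov,
                 log_prior = log(table(labels)[classes] / length(labels)),
                 classes = classes, positive_class = positive_class),
            class = "pv_nb_model")
}

nb_tokenize <- function(texts) {
  lapply(strsplit(tolower(texts), "[^[:alnum:]]+"), function(t) t[nzchar(t)])
}

#' Posterior AE probability under a naive Bayes model
#'
#' @param model a [train_nb()] model.
#' @param texts character vector of documents to score.
#' @return numeric vector of `P(positive class | text)`; an empty document
#'   scores at the class prior.
#' @export
predict_nb <- function(model, texts) {
  stopifnot(inherits(model, "pv_nb_model"))
  toks <- nb_tokenize(texts)
  vapply(toks, function(t) {
    idx <- match(t, model$vocab)
    logp <- vapply(seq_along(model$classes), function(j) {
      tok_ll <- ifelse(is.na(idx), model$log_oov[j], model$loglik[idx, j])
      model$log_prior[j] + sum(tok_ll)
    }, numeric(1))
    m <- max(logp)
    post <- exp(logp - m) / sum(exp(logp - m))
    post[match(model$positive_class, model$classes)]
  }, numeric(1))
}

#' Rank posts by AE probability with a date floor
#'
#' Keeps posts dated on or after `date_floor`, scores them with the model
#' and sorts by descending AE probability, ties broken by post id.
#'
#' @param model a [train_nb()] model.
#' @param posts posts tibble (`post_id`, `timestamp`, text column).
#' @param date_floor earliest admissible timestamp (default
#'   `"2020-01-01"`).
#' @return `posts` filtered and ordered, with an `ae_probability` column.
#' @export
rank_by_ae_probability <- function(model, posts,
                                   date_floor = as.POSIXct("2020-01-01",
                                                           tz = "UTC")) {
  date_floor <- as.POSIXct(date_floor, tz = "UTC")
  keep <- posts[posts$timestamp >= date_floor, ]
  if (nrow(keep) == 0) {
    keep$ae_probability <- numeric(0)
    return(keep)
  }
  txt <- if ("masked_text" %in% names(keep)) keep$masked_text else keep$text
  keep$ae_probability <- predict_nb(model, txt)
  keep[order(-keep$ae_probability, keep$post_id), ]
}

#' Assess completeness of an initial report
#'
#' Computes the data elements still missing (`required \ provided`) for the
#' report's AE class and drafts one follow-up question per missing element.
#' When questions are to be sent, the list is clamped to 4–11: padded with
#' the generic elements (outcome, dose, action taken, then remaining
#' elements by priority) when shorter, truncated at the lowest-priority end
#' when longer.
#'
#' @param ae_class the report's AE class; must appear in `requirements` (or
#'   a `"default"` entry must exist).
#' @param provided character vector of elements already present in the
#'   post.
#' @param requirements named list AE class -> required elements (default
#'   [default_requirements()]).
#' @return list with `required`, `missing`, `needs_followup` (FALSE when
#'   nothing is missing: such a case is excluded from follow-up) and
#'   `questions` (named character vector, empty when no follow-up is
#'   needed).
#' @export
assess_completeness <- function(ae_class, provided,
                                requirements = default_requirements()) {
  req <- requirements[[ae_class]]
  if (is.null(req)) req <- requirements[["default"]]
  if (is.null(req)) {
    stop("no requirements defined for AE class: ", ae_class, call. = FALSE)
  }
  req <- unname(req)
  unknown <- setdiff(c(req, provided), assessment_elements())
  if (length(unknown)) {
    stop("unknown assessment element: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(req, provided)
  if (length(missing) == 0) {
    return(list(required = req, missing = character(0),
                needs_followup = FALSE, questions = character(0)))
  }
  ask <- missing
  if (length(ask) < 4) {
    pad_pool <- c("outcome", "dose", "action_taken", assessment_elements())
    pad <- setdiff(pad_pool, ask)
    ask <- c(ask, pad[seq_len(4 - length(ask))])
  }
  if (length(ask) > 11) {
    prio <- match(ask, assessment_elements())
    ask <- ask[order(prio)][seq_len(11)]
  }
  ask <- ask[order(match(ask, assessment_elements()))]
  list(required = req, missing = missing, needs_followup = TRUE,
       questions = QUESTION_TEMPLATES[ask])
}

#' Select follow-up candidates under the study's caps
#'
#' From a ranked candidate table, removes non-serious cases and cases with
#' nothing missing, then draws a random sample of up to `pool_size` cases
#' with at most `max_per_class` cases per similarity class and at most
#' `max_per_author` per author. Sampling is deterministic given `seed`. If
#' fewer than `batch_size` candidates survive the filters, all are returned
#' with a warning (the criteria-widening hook).
#'
#' @param candidates tibble with columns `post_id`, `author_id`, `serious`
#'   (logical), `similarity_class`, `needs_followup` (logical).
#' @param pool_size sample size target (default 30).
#' @param max_per_class cap per similarity class (default 2).
#' @param max_per_author cap per author (default 1).
#' @param batch_size size of a follow-up batch (default 15), used only for
#'   the too-few warning.
#' @param seed integer seed for the random sample.
#' @return the selected rows, in selection order.
#' @export
select_candidates <- function(candidates, pool_size = 30L,
                              max_per_class = 2L, max_per_author = 1L,
                              batch_size = 15L, seed = 1L) {
  needed <- c("post_id", "author_id", "serious", "similarity_class",
              "needs_followup")
  stopifnot(all(needed %in% names(candidates)))
  pool <- candidates[candidates$serious & candidates$needs_followup, ]
  set.seed(seed)
  ord <- sample.int(nrow(pool))
  picked <- integer(0)
  class_n <- integer(0)
  author_n <- integer(0)
  for (i in ord) {
    cl <- pool$similarity_class[i]
    au <- pool$author_id[i]
    if ((class_n[cl] %||% 0L) >= max_per_class) next
    if ((author_n[au] %||% 0L) >= max_per_author) next
    picked <- c(picked, i)
    class_n[cl] <- (class_n[cl] %||% 0L) + 1L
    author_n[au] <- (author_n[au] %||% 0L) + 1L
    if (length(picked) >= pool_size) break
  }
  if (length(picked) < batch_size) {
    warning("only ", length(picked), " candidates available after filters ",
            "(batch size ", batch_size, "); consider widening criteria",
            call. = FALSE)
  }
  pool[picked, ]
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Simulate patient engagement on selected cases
#'
#' Emulates the follow-up lifecycle: cases are contacted in batches of
#' `batch_size`; each contact consents with probability `consent_p` after a
#' short delay, consenting patients are sent their questions, and each
#' returns answers with probability `receipt_p` (otherwise a 30-day timeout);
#' declines and timeouts are replaced from the remainder until
#' `target_completed` follow-ups are received or the pool is exhausted.
#' Default probabilities reflect engagement rates typical of spontaneous-
#' report follow-up campaigns; both are configurable.
#'
#' @param cases tibble with one row per selected case; a `n_questions`
#'   column is used if present (otherwise 4-11 drawn uniformly).
#' @param batch_size contacts per wave (default 15).
#' @param target_completed stop once this many follow-ups are received
#'   (default `Inf`: contact the whole pool).
#' @param consent_p,receipt_p consent and receipt probabilities (defaults
#'   0.205 and 0.75).
#' @param start_date date of the first contact wave.
#' @param seed integer seed.
#' @return tibble of case timelines: `post_id`, `n_questions`,
#'   `contacted_at`, `consented_at`, `questions_sent_at`, `received_at`,
#'   `n_answered`, `assessable`.
#' @export
simulate_engagement <- function(cases, batch_size = 15L,
                                target_completed = Inf,
                                consent_p = 0.205, receipt_p = 0.75,
                                start_date = as.POSIXct("2021-05-01",
                                                        tz = "UTC"),
                                seed = 1L) {
  set.seed(seed)
  n <- nrow(cases)
  nq <- if ("n_questions" %in% names(cases)) cases$n_questions
        else sample(4:11, n, replace = TRUE)
  day <- 86400
  out <- tibble::tibble(
    post_id = cases$post_id, n_questions = as.integer(nq),
    contacted_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    consented_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    questions_sent_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    received_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    n_answered = 0L, assessable = NA
  )
  completed <- 0L
  next_case <- 1L
  wave_start <- as.POSIXct(start_date, tz = "UTC")
  while (completed < target_completed && next_case <= n) {
    wave <- next_case:min(n, next_case + batch_size - 1L)
    next_case <- max(wave) + 1L
    for (i in wave) {
      out$contacted_at[i] <- wave_start
      if (stats::runif(1) >= consent_p) next  # declined or never answered
      out$consented_at[i] <- out$contacted_at[i] +
        stats::runif(1, 0, 5) * day
      out$questions_sent_at[i] <- out$consented_at[i] +
        stats::runif(1, 0, 1) * day
      if (stats::runif(1) < receipt_p) {
        out$received_at[i] <- out$questions_sent_at[i] +
          stats::runif(1, 0, 4) * day
        out$n_answered[i] <- out$n_questions[i]
        out$assessable[i] <- stats::runif(1) < 2 / 3
        completed <- completed + 1L
        if (completed >= target_completed) break
      }
    }
    wave_start <- wave_start + 30 * day  # replacements after the timeout
  }
  out[!is.na(out$contacted_at), ]
}

#' Engagement metrics over follow-up cases
#'
#' Consent and receipt rates (percent, rounded half away from zero),
#' time-to-receipt distributions from both clocks (initial contact and
#' question dispatch; median with the midpoint convention, plus range),
#' question completeness, and assessability counts.
#'
#' @param cases case-timeline tibble as produced by
#'   [simulate_engagement()].
#' @return list of class `pv_engagement_metrics`.
#' @export
engagement_metrics <- function(cases) {
  ok <- is.na(cases$received_at) | is.na(cases$questions_sent_at) |
    cases$received_at >= cases$questions_sent_at
  ok <- ok & (is.na(cases$questions_sent_at) | is.na(cases$consented_at) |
                cases$questions_sent_at >= cases$consented_at)
  ok <- ok & (is.na(cases$consented_at) |
                cases$consented_at >= cases$contacted_at)
  if (any(!ok)) {
    stop("inconsistent case timeline for post(s): ",
         paste(cases$post_id[!ok], collapse = ", "), call. = FALSE)
  }
  n_sent <- nrow(cases)
  n_consented <- sum(!is.na(cases$consented_at))
  n_received <- sum(!is.na(cases$received_at))
  rec <- !is.na(cases$received_at)
  d_contact <- as.numeric(difftime(cases$received_at[rec],
                                   cases$contacted_at[rec], units = "days"))
  d_quest <- as.numeric(difftime(cases$received_at[rec],
                                 cases$questions_sent_at[rec],
                                 units = "days"))
  asked <- sum(cases$n_questions[rec])
  answered <- sum(cases$n_answered[rec])
  dist_summary <- function(d) {
    if (length(d) == 0) return(list(median = NA_real_, min = NA_real_,
                                    max = NA_real_))
    list(median = stats::median(d), min = min(d), max = max(d))
  }
  structure(list(
    n_sent = n_sent, n_consented = n_consented,
    consent_rate = round_half_away(100 * n_consented / n_sent),
    n_received = n_received,
    receipt_rate = if (n_consented > 0)
      round_half_away(100 * n_received / n_consented) else NA_real_,
    days_from_contact = dist_summary(d_contact),
    days_from_questions = dist_summary(d_quest),
    question_completeness = if (asked > 0)
      round_half_away(100 * answered / asked) else NA_real_,
    n_assessable = sum(cases$assessable %in% TRUE),
    n_not_assessable = sum(cases$assessable %in% FALSE)
  ), class = "pv_engagement_metrics")
}

#' Percent agreement between two reviewers' annotations
#'
#' The dual independent safety-review step is modeled as two annotation
#' tables over the same cases; this reports percent agreement per element
#' column.
#'
#' @param a,b annotation tibbles with identical `post_id` sets and the same
#'   logical element columns.
#' @param elements columns to compare (default: all shared logical columns).
#' @return tibble `element`, `agreement_pct`.
#' @export
review_agreement <- function(a, b, elements = NULL) {
  a <- a[order(a$post_id), ]
  b <- b[order(b$post_id), ]
  if (!identical(a$post_id, b$post_id)) {
    stop("annotation tables cover different cases", call. = FALSE)
  }
  if (is.null(elements)) {
    elements <- intersect(names(a), names(b))
    elements <- elements[vapply(elements, function(cl) is.logical(a[[cl]]) &&
                                  is.logical(b[[cl]]), TRUE)]
  }
  tibble::tibble(
    element = elements,
    agreement_pct = unname(vapply(elements, function(cl) {
      round_half_away(100 * mean(a[[cl]] == b[[cl]]))
    }, numeric(1)))
  )
}
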