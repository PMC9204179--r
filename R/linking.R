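# Longitudinal author linking. Posts sharing an author id are assembled into
# a time-ordered dossier, each dossier is scored with a registry of
# complexity indicators (the default profile has 28 presence/threshold
# indicators with unit weights), and the best-scoring dossiers are ranked
# for clinical inspection. Medical-insight coverage over expert annotations
# is summarized separately.
#
# The indicator lexicons below are heuristics for synthetic and exploratory
# use; they are not clinically validated extractors.

INSIGHT_CATEGORIES <- c("medical_history", "disease_burden",
                        "non_medical_treatments", "laboratory_results",
                        "treatment_history", "concomitant_medications",
                        "ae_mention")

AE_SUBELEMENTS <- c("time_to_onset", "outcome", "treatment_of_ae",
                    "causality_statement", "dose", "rechallenge_dechallenge")

INSIGHT_LEXICONS <- list(
  medical_history = c("diagnosed", "diagnosis", "history of", "years ago",
                      "since my surgery"),
  disease_burden = c("quality of life", "daily life", "struggling",
                     "hard to cope", "exhausting"),
  non_medical_treatments = c("yoga", "acupuncture", "supplement", "vitamin",
                             "herbal", "meditation"),
  laboratory_results = c("blood test", "lab results", "t-score", "bone scan",
                         "blood work", "scan showed"),
  treatment_history = c("used to take", "switched from", "previous treatment",
                        "stopped taking", "before this drug"),
  concomitant_medications = c("also taking", "along with", "together with",
                              "other medication", "also on"),
  ae_mention = NULL  # driven by terminology matching, not a lexicon
)

SUBELEMENT_LEXICONS <- list(
  time_to_onset = c("after starting", "weeks after", "days after",
                    "months after", "soon after"),
  outcome = c("recovered", "resolved", "getting better", "no improvement",
              "still ongoing", "back to normal"),
  treatment_of_ae = c("prescribed", "treated with", "was given", "to manage"),
  causality_statement = c("caused by", "because of the", "due to the",
                          "blame the"),
  dose = c("mg", "dose", "dosage", "milligrams"),
  rechallenge_dechallenge = c("restarted", "stopped and started",
                              "went back on", "off and on again")
)

#' Build longitudinal dossiers by author
#'
#' Partitions clean posts into one dossier per distinct author, each a
#' tibble of that author's posts sorted by timestamp (ties broken by post
#' id).
#'
#' @param posts clean posts tibble; `author_id` must be present and
#'   non-missing on every row.
#' @return named list (author id -> post tibble) of class `pv_dossiers`.
#' @export
build_dossiers <- function(posts) {
  bad <- posts$post_id[is.na(posts$author_id) | !nzchar(posts$author_id)]
  if (length(bad)) {
    stop("posts without author_id: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ord <- order(posts$author_id, posts$timestamp, posts$post_id)
  posts <- posts[ord, ]
  out <- split(posts, posts$author_id)
  structure(out[order(names(out))], class = "pv_dossiers")
}

#' Default complexity-indicator registry (28 indicators)
#'
#' Each indicator is a pure function of a dossier context (`posts`: the
#' author's post tibble; `pts`: distinct PT codes matched in the dossier;
#' `all_text`: concatenated post text) returning a value in `[0, 1]`. The
#' default profile is 28 binary presence/threshold indicators with unit
#' weights: volume and span thresholds, clinical-text patterns, the seven
#' insight-category lexicons, the six AE sub-element lexicons, and
#' voice/context markers. All are monotone under appending a post.
#'
#' @return named list of indicator functions with attribute
#'   `declared_size = 28`.
#' @export
default_indicator_registry <- function() {
  any_phrase <- function(phrases) {
    force(phrases)
    function(ctx) as.numeric(any(vapply(
      phrases, function(p) contains_phrase(ctx$all_text, p), TRUE)))
  }
  any_regex <- function(pattern) {
    force(pattern)
    function(ctx) as.numeric(grepl(pattern, ctx$all_text,
                                   perl = TRUE, ignore.case = TRUE))
  }
  reg <- list(
    # volume / structure
    posts_ge_10       = function(ctx) as.numeric(nrow(ctx$posts) >= 10),
    span_ge_90_days   = function(ctx) {
      as.numeric(as.numeric(difftime(max(ctx$posts$timestamp),
                                     min(ctx$posts$timestamp),
                                     units = "days")) >= 90)
    },
    threads_ge_3      = function(ctx) as.numeric(length(unique(ctx$posts$thread_id)) >= 3),
    distinct_pts_ge_2 = function(ctx) as.numeric(length(ctx$pts) >= 2),
    distinct_pts_ge_5 = function(ctx) as.numeric(length(ctx$pts) >= 5),
    # clinical text patterns
    drug_mention      = function(ctx) {
      if (!"drug_mentions" %in% names(ctx$posts)) return(0)
      as.numeric(any(lengths(ctx$posts$drug_mentions) > 0))
    },
    temporal_expression = any_regex(
      "\\b(yesterday|last (week|month|year)|[0-9]+ (day|week|month|year)s?( ago| after| later)?)\\b"),
    dosage_pattern    = any_regex("\\b[0-9]+ ?(mg|mcg|milligrams?)\\b"),
    lab_value_pattern = any_regex(
      "\\b(t-score|[0-9]+(\\.[0-9]+)? ?(mg/dl|mmol|ng/ml))\\b"),
    negation_marker   = any_regex("\\b(no|not|never|without)\\b"),
    question_form     = function(ctx) as.numeric(grepl("\\?", ctx$all_text, fixed = FALSE)),
    # seven insight-category lexicons (ae_mention via terminology matching)
    medical_history        = any_phrase(INSIGHT_LEXICONS$medical_history),
    disease_burden         = any_phrase(INSIGHT_LEXICONS$disease_burden),
    non_medical_treatments = any_phrase(INSIGHT_LEXICONS$non_medical_treatments),
    laboratory_results     = any_phrase(INSIGHT_LEXICONS$laboratory_results),
    treatment_history      = any_phrase(INSIGHT_LEXICONS$treatment_history),
    concomitant_medications = any_phrase(INSIGHT_LEXICONS$concomitant_medications),
    ae_mention             = function(ctx) as.numeric(length(ctx$pts) >= 1),
    # six AE sub-element lexicons
    time_to_onset          = any_phrase(SUBELEMENT_LEXICONS$time_to_onset),
    outcome                = any_phrase(SUBELEMENT_LEXICONS$outcome),
    treatment_of_ae        = any_phrase(SUBELEMENT_LEXICONS$treatment_of_ae),
    causality_statement    = any_phrase(SUBELEMENT_LEXICONS$causality_statement),
    dose                   = any_phrase(SUBELEMENT_LEXICONS$dose),
    rechallenge_dechallenge = any_phrase(SUBELEMENT_LEXICONS$rechallenge_dechallenge),
    # voice / context
    first_person      = any_regex("\\b(i|my|me)\\b"),
    hcp_visit         = any_phrase(c("doctor", "oncologist", "specialist",
                                     "appointment", "care team", "clinic")),
    co_suspect_drug   = function(ctx) {
      if (!"drug_mentions" %in% names(ctx$posts)) return(0)
      as.numeric(length(unique(unlist(ctx$posts$drug_mentions))) >= 2)
    },
    family_voice      = any_phrase(c("my mother", "my father", "my husband",
                                     "my wife", "my son", "my daughter"))
  )
  stopifnot(length(reg) == 28)
  structure(reg, declared_size = 28L)
}

#' Complexity score of a dossier
#'
#' Evaluates every indicator in the registry on the dossier and returns the
#' weighted sum `S = sum_k u_k I_k`. The score is invariant to the input
#' order of posts (the dossier is re-sorted) and, with the default registry,
#' monotone non-decreasing as posts are appended.
#'
#' @param dossier one author's post tibble (a [build_dossiers()] element).
#' @param registry indicator registry (default
#'   [default_indicator_registry()]); if it carries a `declared_size`
#'   attribute its length is enforced against it.
#' @param term terminology used to find PT mentions for the PT-based
#'   indicators.
#' @param weights numeric vector of indicator weights (default all 1).
#' @return list with `score`, `indicators` (named numeric vector) and
#'   `n_posts`.
#' @export
complexity_score <- function(dossier, registry = default_indicator_registry(),
                             term = example_terminology(),
                             weights = rep(1, length(registry))) {
  declared <- attr(registry, "declared_size")
  if (!is.null(declared) && length(registry) != declared) {
    stop("registry declares ", declared, " indicators but has ",
         length(registry), call. = FALSE)
  }
  if (length(weights) != length(registry)) {
    stop("weights length must match registry size", call. = FALSE)
  }
  dossier <- dossier[order(dossier$timestamp, dossier$post_id), ]
  ev <- match_events(dossier, term)
  ctx <- list(posts = dossier, pts = unique(ev$pt_code),
              all_text = paste(
                if ("masked_text" %in% names(dossier)) dossier$masked_text
                else dossier$text, collapse = "\n"))
  vals <- vapply(registry, function(f) {
    v <- f(ctx)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("indicator returned a value outside [0, 1]", call. = FALSE)
    }
    v
  }, numeric(1))
  list(score = sum(weights * vals), indicators = vals, n_posts = nrow(dossier))
}

#' Score all dossiers
#'
#' @param dossiers a [build_dossiers()] result.
#' @inheritParams complexity_score
#' @return tibble `author_id`, `n_posts`, `first_post`, `score`, plus an
#'   `indicators` list-column.
#' @export
score_dossiers <- function(dossiers, registry = default_indicator_registry(),
                           term = example_terminology(),
                           weights = rep(1, length(registry))) {
  rows <- lapply(names(dossiers), function(a) {
    cs <- complexity_score(dossiers[[a]], registry, term, weights)
    tibble::tibble(author_id = a, n_posts = cs$n_posts,
                   first_post = min(dossiers[[a]]$timestamp),
                   score = cs$score, indicators = list(cs$indicators))
  })
  do.call(rbind, rows)
}

#' Top-k dossiers by complexity score
#'
#' Descending by score; ties broken by earlier first post, then author id.
#' The ordering is total, so the result is stable and reproducible.
#'
#' @param scored the tibble from [score_dossiers()].
#' @param k number of dossiers to return (`k <= nrow(scored)`).
#' @return the top `k` rows, ordered.
#' @export
rank_dossiers <- function(scored, k) {
  if (k > nrow(scored)) {
    stop("k (", k, ") exceeds the number of dossiers (", nrow(scored), ")",
         call. = FALSE)
  }
  ord <- order(-scored$score, scored$first_post, scored$author_id)
  scored[ord, ][seq_len(k), ]
}

#' Validate an insight annotation table
#'
#' @param annotations tibble with `group_id`, the seven insight-category
#'   logical columns and the six AE sub-element logical columns.
#' @return the validated tibble, invisibly.
#' @export
validate_annotations <- function(annotations) {
  needed <- c("group_id", INSIGHT_CATEGORIES, AE_SUBELEMENTS)
  missing <- setdiff(needed, names(annotations))
  if (length(missing)) {
    stop("annotation table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- as.matrix(annotations[, AE_SUBELEMENTS])
  bad <- rowSums(sub) > 0 & !annotations$ae_mention
  if (any(bad)) {
    stop("AE sub-element true without ae_mention for group(s): ",
         paste(annotations$group_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(annotations)
}

#' Medical-insight coverage report
#'
#' Summarizes expert annotations of linked-post groups: per-category counts
#' and percentages, the number and percentage of groups covering all seven
#' insight categories, AE sub-element coverage (denominator: all groups, the
#' printed convention, even though only AE-mentioning groups can carry
#' sub-elements), and — when per-post annotations are supplied — the count
#' of single posts containing all seven categories. Percentages are rounded
#' half away from zero to integers.
#'
#' @param annotations group-level annotation tibble (see
#'   [validate_annotations()]).
#' @param per_post_annotations optional post-level tibble with the seven
#'   category columns.
#' @return list with `n_groups`, `per_category`, `sub_elements`,
#'   `all_seven` (list `n`, `pct`) and `single_posts_all_seven`.
#' @export
insight_coverage <- function(annotations, per_post_annotations = NULL) {
  validate_annotations(annotations)
  ng <- nrow(annotations)
  cat_m <- as.matrix(annotations[, INSIGHT_CATEGORIES])
  sub_m <- as.matrix(annotations[, AE_SUBELEMENTS])
  per_category <- tibble::tibble(
    category = INSIGHT_CATEGORIES,
    n = as.integer(colSums(cat_m)),
    pct = unname(round_half_away(100 * colSums(cat_m) / ng))
  )
  sub_elements <- tibble::tibble(
    element = AE_SUBELEMENTS,
    n = as.integer(colSums(sub_m)),
    pct = unname(round_half_away(100 * colSums(sub_m) / ng))
  )
  n_all7 <- sum(rowSums(cat_m) == length(INSIGHT_CATEGORIES))
  single_all7 <- if (is.null(per_post_annotations)) {
    NA_integer_
  } else {
    pm <- as.matrix(per_post_annotations[, INSIGHT_CATEGORIES])
    sum(rowSums(pm) == length(INSIGHT_CATEGORIES))
  }
  list(n_groups = ng, per_category = per_category,
       sub_elements = sub_elements,
       all_seven = list(n = n_all7, pct = round_half_away(100 * n_all7 / ng)),
       single_posts_all_seven = single_all7)
}
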