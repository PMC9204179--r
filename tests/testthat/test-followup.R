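test_that("naive Bayes matches a hand-computed posterior on two documents", {
  # training: one document per class, disjoint vocabularies
  m <- train_nb(c("rash fever rash", "garden picnic"), c("AE", "not-AE"))
  # by hand: vocab = {fever, garden, picnic, rash}, |V| = 4, a = 1
  # AE:    totals 3, denom 3 + 4 + 1 = 8;  P(rash|AE) = 3/8, P(fever|AE) = 2/8
  # not:   totals 2, denom 2 + 4 + 1 = 7;  P(rash|not) = 1/7, P(fever|not) = 1/7
  # priors 1/2 each; doc "rash fever":
  num <- 0.5 * (3 / 8) * (2 / 8)
  den <- num + 0.5 * (1 / 7) * (1 / 7)
  expect_equal(predict_nb(m, "rash fever"), num / den, tolerance = 1e-12)
  # the two class scores sum to one and lie in (0, 1)
  p <- predict_nb(m, c("rash", "garden", "picnic fever"))
  expect_true(all(p > 0 & p < 1))
  # empty document returns the class prior
  expect_equal(predict_nb(m, ""), 0.5)
  # balanced classes with identical texts score exactly 1/2
  sym <- train_nb(c("same words here", "same words here"), c("AE", "not-AE"))
  expect_equal(predict_nb(sym, "same words"), 0.5)
  expect_error(train_nb(c("a", "b"), c("AE", "AE")), "single class")
})

test_that("disjoint vocabularies give near-certain held-out scores", {
  train <- generate_labeled_posts(150, 150, seed = 21)
  m <- train_nb(train$text, train$label)
  test <- generate_labeled_posts(80, 80, seed = 22)
  p <- predict_nb(m, test$text)
  # perfect separation, with mean scores beyond 0.99 (documents carrying a
  # single class token sit near 0.98, the rest at ~1)
  expect_true(all(p[test$label == "AE"] > 0.5))
  expect_true(all(p[test$label == "not-AE"] < 0.5))
  expect_gt(mean(p[test$label == "AE"]), 0.99)
  expect_lt(mean(p[test$label == "not-AE"]), 0.01)
})

test_that("ranking filters by date floor and sorts by probability then id", {
  train <- generate_labeled_posts(100, 100, seed = 23)
  m <- train_nb(train$text, train$label)
  test <- generate_labeled_posts(20, 20, seed = 24)
  posts <- make_posts(test$text,
                      timestamp = as.POSIXct("2019-06-01", tz = "UTC") +
                        seq_along(test$text) * 86400 * 30)
  floor_dt <- as.POSIXct("2020-01-01", tz = "UTC")
  ranked <- rank_by_ae_probability(m, posts, floor_dt)
  expect_true(all(ranked$timestamp >= floor_dt))
  # brute-force oracle ordering
  keep <- posts[posts$timestamp >= floor_dt, ]
  pr <- predict_nb(m, keep$text)
  oracle <- keep$post_id[order(-pr, keep$post_id)]
  expect_equal(ranked$post_id, oracle)
  # floor beyond all posts -> empty; floor at minimum -> everything
  expect_equal(nrow(rank_by_ae_probability(m, posts,
                                           max(posts$timestamp) + 1)), 0)
  expect_equal(nrow(rank_by_ae_probability(m, posts, min(posts$timestamp))),
               nrow(posts))
})

test_that("completeness assessment is the set difference with 4-11 questions", {
  req <- default_requirements()
  # nothing missing: excluded from follow-up, no questions drafted
  full <- assess_completeness("fracture", req$fracture)
  expect_false(full$needs_followup)
  expect_length(full$questions, 0)
  # nothing provided: one question per missing element
  none <- assess_completeness("fracture", character(0))
  expect_setequal(none$missing, req$fracture)
  expect_length(none$questions, 7)
  # brute-force element-by-element difference
  provided <- c("time_to_onset", "outcome")
  got <- assess_completeness("fracture", provided)
  oracle <- req$fracture[!vapply(req$fracture, `%in%`, TRUE, provided)]
  expect_setequal(got$missing, oracle)
  # single missing element: padded up to 4 questions with generic elements
  one <- assess_completeness("fracture", setdiff(req$fracture, "duration"))
  expect_equal(one$missing, "duration")
  expect_length(one$questions, 4)
  expect_setequal(names(one$questions),
                  c("duration", "outcome", "dose", "action_taken"))
  # unknown class without a default entry errors
  expect_error(assess_completeness("unknown", character(0),
                                   list(fracture = req$fracture)),
               "no requirements")
  expect_error(assess_completeness("fracture", "not_an_element"), "unknown")
})

test_that("candidate selection honours seriousness, caps, and determinism", {
  set.seed(101)
  cand <- tibble::tibble(
    post_id = sprintf("P%03d", 1:80),
    author_id = sprintf("A%03d", rep(1:60, length.out = 80)),
    serious = rep(c(TRUE, TRUE, TRUE, FALSE), 20),
    similarity_class = sample(letters[1:12], 80, replace = TRUE),
    needs_followup = rep(c(TRUE, TRUE, FALSE, TRUE), 20))
  sel <- select_candidates(cand, pool_size = 30, seed = 6)
  expect_true(all(sel$serious))
  expect_true(all(sel$needs_followup))
  expect_lte(max(table(sel$similarity_class)), 2)
  expect_lte(max(table(sel$author_id)), 1)
  expect_identical(sel, select_candidates(cand, pool_size = 30, seed = 6))
  # brute-force equivalence: replay the same shuffled order greedily
  pool <- cand[cand$serious & cand$needs_followup, ]
  set.seed(6)
  ord <- sample.int(nrow(pool))
  taken <- integer(0); cl <- c(); au <- c()
  for (i in ord) {
    key_c <- pool$similarity_class[i]; key_a <- pool$author_id[i]
    if (sum(cl == key_c) >= 2 || sum(au == key_a) >= 1) next
    taken <- c(taken, i); cl <- c(cl, key_c); au <- c(au, key_a)
    if (length(taken) == 30) break
  }
  expect_equal(sel$post_id, pool$post_id[taken])
  # three candidates in one similarity class -> at most two selected
  trio <- tibble::tibble(post_id = c("P1", "P2", "P3"),
                         author_id = c("A1", "A2", "A3"),
                         serious = TRUE, similarity_class = "x",
                         needs_followup = TRUE)
  expect_warning(s3 <- select_candidates(trio, pool_size = 30, seed = 1),
                 "widening")
  expect_equal(nrow(s3), 2)
  # two candidates, same author -> one selected
  duo <- tibble::tibble(post_id = c("P1", "P2"), author_id = "A1",
                        serious = TRUE, similarity_class = c("x", "y"),
                        needs_followup = TRUE)
  expect_warning(s2 <- select_candidates(duo, pool_size = 30, seed = 1))
  expect_equal(nrow(s2), 1)
})

test_that("engagement metrics reproduce the printed rate arithmetic", {
  t0 <- as.POSIXct("2021-05-01", tz = "UTC")
  day <- 86400
  n <- 39
  cases <- tibble::tibble(
    post_id = sprintf("P%03d", 1:n), n_questions = 5L,
    contacted_at = rep(t0, n),
    consented_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    questions_sent_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    received_at = as.POSIXct(rep(NA, n), tz = "UTC"),
    n_answered = 0L, assessable = NA)
  # 8 consent; 6 of those return everything they are asked
  cases$consented_at[1:8] <- t0 + day
  cases$questions_sent_at[1:8] <- t0 + 1.5 * day
  cases$received_at[1:6] <- t0 + 1.5 * day + c(0.5, 0.5, 1, 2, 4, 25.5) * day
  cases$n_answered[1:6] <- 5L
  cases$assessable[1:6] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  met <- engagement_metrics(cases)
  expect_equal(met$consent_rate, 21)        # 8/39
  expect_equal(met$receipt_rate, 75)        # 6/8
  expect_equal(met$question_completeness, 100)  # 30/30 asked of receivers
  expect_equal(met$n_assessable, 4)
  expect_equal(met$n_not_assessable, 2)
  # midpoint median convention on the question clock
  expect_equal(met$days_from_questions$median, 1.5)
  expect_equal(met$days_from_questions$min, 0.5)
  expect_equal(met$days_from_questions$max, 25.5)
  # metrics are invariant to row order
  perm <- sample(n)
  met2 <- engagement_metrics(cases[perm, ])
  expect_equal(met2$consent_rate, met$consent_rate)
  expect_equal(met2$days_from_contact, met$days_from_contact)
  # received before questions sent is rejected
  bad <- cases
  bad$received_at[1] <- bad$questions_sent_at[1] - day
  expect_error(engagement_metrics(bad), "inconsistent")
})

test_that("simulated engagement recovers its configured probabilities", {
  cases <- tibble::tibble(post_id = sprintf("P%04d", 1:1000),
                          n_questions = rep(5L, 1000))
  sim <- simulate_engagement(cases, consent_p = 0.205, receipt_p = 0.75,
                             seed = 33)
  met <- engagement_metrics(sim)
  expect_equal(met$n_sent, 1000)
  se_c <- sqrt(0.205 * 0.795 / 1000)
  expect_lt(abs(met$n_consented / 1000 - 0.205), 3 * se_c)
  se_r <- sqrt(0.75 * 0.25 / met$n_consented)
  expect_lt(abs(met$n_received / met$n_consented - 0.75), 3 * se_r)
  # timelines are internally consistent by construction
  rec <- sim[!is.na(sim$received_at), ]
  expect_true(all(rec$received_at >= rec$questions_sent_at))
  expect_true(all(rec$questions_sent_at >= rec$consented_at))
})

test_that("reviewer agreement is percent concordance per element", {
  a <- tibble::tibble(post_id = c("P1", "P2", "P3", "P4"),
                      outcome = c(TRUE, TRUE, FALSE, FALSE),
                      dose = c(TRUE, FALSE, TRUE, FALSE))
  b <- tibble::tibble(post_id = c("P1", "P2", "P3", "P4"),
                      outcome = c(TRUE, FALSE, FALSE, FALSE),
                      dose = c(TRUE, FALSE, TRUE, FALSE))
  agr <- review_agreement(a, b)
  expect_equal(agr$agreement_pct[agr$element == "outcome"], 75)
  expect_equal(agr$agreement_pct[agr$element == "dose"], 100)
  expect_error(review_agreement(a, b[1:3, ]), "different cases")
})
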