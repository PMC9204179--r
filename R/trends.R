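# Quarterly adverse-event frequency series among drug-mentioning posts: the
# social-media counterpart of a disproportionality time series. For a drug
# and quarter, N_q is the number of clean posts mentioning the drug, n_q the
# number of those also carrying the event of interest (or any mapped event),
# and f_q = 100 * n_q / N_q the frequency in percent.

#' Quarterly summary of matched events for one drug
#'
#' Counts, per calendar quarter, the posts mentioning `drug` (N_q), the
#' drug posts with at least one mapped event, and the drug posts carrying
#' each PT. A post contributes at most 1 to each PT in its quarter, however
#' many times the PT is mentioned; a post with several distinct PTs counts
#' once towards each. Quarters inside the covered period with no drug posts
#' are present with N_q = 0.
#'
#' @param posts clean posts tibble (with `drug_mentions`, `timestamp`).
#' @param events matched events tibble from [match_events()]; every
#'   `post_id` must reference a row of `posts`.
#' @param drug drug id to summarize.
#' @param quarters optional quarter labels delimiting the series (default:
#'   first to last quarter seen in `posts`).
#' @return a `pv_quarterly_summary`: list with `drug`, `totals` (tibble
#'   `quarter`, `N`, `n_any`) and `pt_counts` (tibble `quarter`, `pt_code`,
#'   `n`).
#' @export
quarterly_summary <- function(posts, events, drug, quarters = NULL) {
  stopifnot("drug_mentions" %in% names(posts))
  unknown <- setdiff(unique(events$post_id), posts$post_id)
  if (length(unknown)) {
    stop("events reference unknown posts: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(quarters)) {
    qs <- quarter_label(posts$timestamp)
    quarters <- quarter_seq(min(qs), max(qs))
  }
  sel <- vapply(posts$drug_mentions, function(d) drug %in% d, TRUE)
  dp <- posts[sel, ]
  dq <- quarter_label(dp$timestamp)
  N <- table(factor(dq, levels = quarters))

  ev <- events[events$post_id %in% dp$post_id, ]
  ev_q <- dq[match(ev$post_id, dp$post_id)]
  n_any <- table(factor(unique(data.frame(q = ev_q, id = ev$post_id))$q,
                        levels = quarters))
  pt_pairs <- unique(data.frame(q = ev_q, pt = ev$pt_code, id = ev$post_id,
                                stringsAsFactors = FALSE))
  pt_counts <- if (nrow(pt_pairs)) {
    agg <- stats::aggregate(id ~ q + pt, data = pt_pairs, FUN = length)
    tibble::tibble(quarter = agg$q, pt_code = agg$pt, n = agg$id)
  } else {
    tibble::tibble(quarter = character(0), pt_code = character(0),
                   n = integer(0))
  }
  structure(list(
    drug = drug,
    totals = tibble::tibble(quarter = quarters, N = as.integer(N),
                            n_any = as.integer(n_any)),
    pt_counts = pt_counts
  ), class = "pv_quarterly_summary")
}

#' Frequency series for one PT (or any mapped event)
#'
#' Builds the per-quarter and overall frequency of an event of interest
#' among drug-mentioning posts: `f_q = 100 * n_q / N_q` percent. Quarters
#' with no drug posts have an undefined frequency, reported as `NA`; full
#' precision is stored and rounding is left to presentation.
#'
#' @param summary a [quarterly_summary()].
#' @param pt_code a PT code, or `"ANY_AE"` for posts with at least one
#'   mapped event.
#' @return a `pv_frequency_series`: list with `drug`, `pt_code`, `quarters`
#'   (tibble `quarter`, `N`, `n`, `f`) and `overall` (list `N`, `n`, `f`).
#' @export
frequency_series <- function(summary, pt_code = "ANY_AE") {
  stopifnot(inherits(summary, "pv_quarterly_summary"))
  tot <- summary$totals
  n <- if (identical(pt_code, "ANY_AE")) {
    tot$n_any
  } else {
    pc <- summary$pt_counts[summary$pt_counts$pt_code == pt_code, ]
    out <- integer(nrow(tot))
    out[match(pc$quarter, tot$quarter)] <- pc$n
    out
  }
  f <- ifelse(tot$N > 0, 100 * n / tot$N, NA_real_)
  structure(list(
    drug = summary$drug, pt_code = pt_code,
    quarters = tibble::tibble(quarter = tot$quarter, N = tot$N, n = n, f = f),
    overall = list(N = sum(tot$N), n = sum(n),
                   f = if (sum(tot$N) > 0) 100 * sum(n) / sum(tot$N) else NA_real_)
  ), class = "pv_frequency_series")
}

#' @export
print.pv_frequency_series <- function(x, ...) {
  cat(sprintf("<pv_frequency_series> %s / %s\n", x$drug, x$pt_code))
  cat(sprintf("  overall: N = %d, n = %d, f = %s%%\n", x$overall$N,
              x$overall$n, formatC(x$overall$f, digits = 3, format = "fg")))
  cat(sprintf("  %d quarters, %s .. %s\n", nrow(x$quarters),
              x$quarters$quarter[1], x$quarters$quarter[nrow(x$quarters)]))
  invisible(x)
}

#' Relative change between two frequencies
#'
#' `100 * (f_end - f_start) / f_start` percent — the statistic used to
#' compare the growth of a social-media frequency series with the growth of
#' an EBGM series over the same window. By default the result is rounded
#' half away from zero to an integer, the package's presentation convention.
#'
#' @param f_start,f_end series values at the window endpoints
#'   (`f_start > 0`).
#' @param round round to integer for presentation (default `TRUE`).
#' @return percent change, scalar.
#' @export
relative_change <- function(f_start, f_end, round = TRUE) {
  if (!is.finite(f_start) || f_start <= 0) {
    stop("relative change undefined for f_start <= 0", call. = FALSE)
  }
  pc <- 100 * (f_end - f_start) / f_start
  if (round) round_half_away(pc) else pc
}

#' Export a frequency series as a plain table
#'
#' @param series a [frequency_series()].
#' @return tibble `drug`, `pt_code`, `quarter`, `N`, `n`, `f`.
#' @export
series_table <- function(series) {
  stopifnot(inherits(series, "pv_frequency_series"))
  tibble::tibble(drug = series$drug, pt_code = series$pt_code,
                 quarter = series$quarters$quarter, N = series$quarters$N,
                 n = series$quarters$n, f = series$quarters$f)
}
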