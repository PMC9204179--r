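# Empirical-Bayes gamma-Poisson shrinker for spontaneous-report tables.
#
# Model: cell count N_ij ~ Poisson(lambda_ij * E_ij) with E_ij the expected
# count under independence of the drug and event margins, and the relative
# reporting rate lambda drawn from a two-component gamma mixture prior
#   lambda ~ pi * Gamma(alpha1, beta1) + (1 - pi) * Gamma(alpha2, beta2)
# (shape + rate parameterization throughout). The marginal of N is then a
# mixture of two negative binomials with size alpha and success probability
# beta / (beta + E). The posterior is the conjugate gamma mixture; EBGM is
# the geometric mean 2^(E[log2 lambda | N]) and EB05/EB95 are the posterior
# 5th and 95th percentiles of lambda.

#' Two-component gamma mixture prior
#'
#' @param alpha1,beta1 shape and rate of the first gamma component.
#' @param alpha2,beta2 shape and rate of the second gamma component.
#' @param pi mixture fraction of the first component, in `[0, 1]`.
#' @return a validated `pv_mixture_prior`.
#' @export
mixture_prior <- function(alpha1, beta1, alpha2, beta2, pi) {
  p <- list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
            pi = pi)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  TRUE))) {
    stop("prior parameters must be finite scalars", call. = FALSE)
  }
  if (alpha1 <= 0 || beta1 <= 0 || alpha2 <= 0 || beta2 <= 0) {
    stop("gamma shapes and rates must be positive", call. = FALSE)
  }
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]", call. = FALSE)
  structure(p, class = "pv_mixture_prior")
}

#' @export
print.pv_mixture_prior <- function(x, ...) {
  cat(sprintf(
    "<pv_mixture_prior> pi = %.4f | G1(shape %.4g, rate %.4g) | G2(shape %.4g, rate %.4g)\n",
    x$pi, x$alpha1, x$beta1, x$alpha2, x$beta2))
  ll <- attr(x, "loglik")
  if (!is.null(ll)) cat(sprintf("  fitted log-likelihood: %.4f\n", ll))
  invisible(x)
}

# Aggregate raw report rows (drug, event_pt[, quarter], count) to one row per
# drug x event cell.
aggregate_reports <- function(reports) {
  stopifnot(all(c("drug", "event_pt", "count") %in% names(reports)))
  if (nrow(reports) == 0) {
    return(tibble::tibble(drug = character(0), event_pt = character(0),
                          count = integer(0)))
  }
  agg <- stats::aggregate(count ~ drug + event_pt, data = reports, FUN = sum)
  tibble::as_tibble(agg)
}

#' Expected cell counts under the independence model
#'
#' For a drug x event contingency table, E_ij = N_i. * N_.j / N_.. — the
#' count expected if drug and event were reported independently. The table is
#' completed to the full drug x event grid (absent cells have N = 0) so the
#' expected counts sum exactly to the grand total.
#'
#' @param reports tibble of report rows `drug`, `event_pt`, `count`
#'   (a `quarter` column, if present, is summed over).
#' @return tibble with one row per cell of the full grid: `drug`,
#'   `event_pt`, `N`, `E`.
#' @export
expected_counts <- function(reports) {
  agg <- aggregate_reports(reports)
  if (nrow(agg) == 0 || sum(agg$count) == 0) {
    stop("empty report table: no counts to baseline", call. = FALSE)
  }
  drugs <- sort(unique(agg$drug))
  events <- sort(unique(agg$event_pt))
  grid <- expand.grid(drug = drugs, event_pt = events,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$drug, grid$event_pt, sep = "\r"),
               paste(agg$drug, agg$event_pt, sep = "\r"))
  grid$N <- ifelse(is.na(idx), 0L, agg$count[idx])
  row_tot <- tapply(grid$N, grid$drug, sum)
  col_tot <- tapply(grid$N, grid$event_pt, sum)
  total <- sum(grid$N)
  grid$E <- as.numeric(row_tot[grid$drug]) * as.numeric(col_tot[grid$event_pt]) / total
  tibble::as_tibble(grid)
}

# Per-cell log marginal: log[ pi NB(N; a1, b1/(b1+E)) + (1-pi) NB(N; a2, b2/(b2+E)) ]
cell_log_marginal <- function(N, E, prior) {
  l1 <- stats::dnbinom(N, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(N, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  w1 <- if (prior$pi > 0) log(prior$pi) + l1 else rep(-Inf, length(N))
  w2 <- if (prior$pi < 1) log1p(-prior$pi) + l2 else rep(-Inf, length(N))
  m <- pmax(w1, w2)
  m + log(exp(w1 - m) + exp(w2 - m))
}

#' Marginal log-likelihood of a report table under a mixture prior
#'
#' Sums, over cells, the log of the negative-binomial mixture marginal of
#' the gamma-Poisson model. Computed in log space throughout.
#'
#' @param N integer vector of observed cell counts.
#' @param E numeric vector of expected counts (all > 0).
#' @param prior a [mixture_prior()].
#' @return the scalar log-likelihood.
#' @export
marginal_loglik <- function(N, E, prior) {
  stopifnot(inherits(prior, "pv_mixture_prior"), length(N) == length(E))
  if (any(E <= 0)) stop("expected counts must be positive", call. = FALSE)
  ll <- cell_log_marginal(N, E, prior)
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    stop("non-finite marginal likelihood at cell ", bad[1],
         " (N=", N[bad[1]], ", E=", signif(E[bad[1]], 4), ")", call. = FALSE)
  }
  sum(ll)
}

# Transform between the optimizer space (log shapes/rates, logit pi) and the
# natural parameter space.
theta_to_prior <- function(theta) {
  mixture_prior(exp(theta[1]), exp(theta[2]), exp(theta[3]), exp(theta[4]),
                stats::plogis(theta[5]))
}

#' Fit the mixture prior by maximum marginal likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of [marginal_loglik()] in
#' log/logit-transformed parameter space, with box bounds `[1e-4, 1e4]` on
#' shapes and rates. Starts from the canonical point
#' `(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, pi = 1/3)` plus
#' `restarts` jittered restarts drawn with a fixed seed, so the fit is
#' deterministic; the best restart is returned.
#'
#' @param N,E cell counts and expected counts (at least 5 cells).
#' @param restarts number of jittered restarts beyond the canonical start.
#' @param restart_seed fixed seed for the jitter.
#' @return the fitted [mixture_prior()] with attributes `loglik` (achieved
#'   log-likelihood) and `convergence`.
#' @export
fit_prior <- function(N, E, restarts = 4L, restart_seed = 42L) {
  stopifnot(length(N) == length(E))
  if (length(N) < 5) stop("need at least 5 cells to fit the prior", call. = FALSE)
  if (any(E <= 0)) stop("expected counts must be positive", call. = FALSE)
  nll <- function(theta) {
    pr <- theta_to_prior(theta)
    -sum(cell_log_marginal(N, E, pr))
  }
  canonical <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1/3))
  lower <- c(rep(log(1e-4), 4), -12)
  upper <- c(rep(log(1e4), 4), 12)
  starts <- list(canonical)
  set.seed(restart_seed)
  for (r in seq_len(restarts)) {
    starts[[r + 1L]] <- pmin(pmax(canonical + stats::rnorm(5, 0, 0.75), lower),
                             upper)
  }
  best <- NULL
  traces <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      traces <- c(traces, conditionMessage(fit))
      next
    }
    if (!is.finite(fit$value)) {
      traces <- c(traces, "non-finite objective at optimum")
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("prior fitting failed on all restarts: ",
         paste(unique(traces), collapse = "; "), call. = FALSE)
  }
  prior <- theta_to_prior(best$par)
  attr(prior, "loglik") <- -best$value
  attr(prior, "convergence") <- best$convergence
  prior
}

#' Posterior summary of the relative reporting rate
#'
#' Given counts, expected counts and a mixture prior, computes for each cell
#' the posterior-component weight `Q_n`, the posterior mean of log2 lambda,
#' `EBGM = 2^E[log2 lambda | N]`, and the posterior 5th/95th percentiles
#' `EB05`/`EB95` found by bisection on the posterior mixture CDF to an
#' interval width of 1e-8.
#'
#' The posterior is `Q_n Gamma(alpha1 + N, beta1 + E) +
#' (1 - Q_n) Gamma(alpha2 + N, beta2 + E)` with `Q_n` proportional to the
#' first component's share of the marginal; the log2 mean uses the digamma
#' identity `E[ln lambda] = psi(alpha + N) - ln(beta + E)` per component.
#'
#' @param N,E numeric vectors of cell counts and expected counts (`E > 0`).
#' @param prior a [mixture_prior()].
#' @return tibble with columns `N`, `E`, `Qn`, `EBlog2`, `EBGM`, `EB05`,
#'   `EB95`.
#' @export
posterior_summary <- function(N, E, prior) {
  stopifnot(inherits(prior, "pv_mixture_prior"), length(N) == length(E))
  if (any(E <= 0)) stop("expected counts must be positive", call. = FALSE)
  l1 <- stats::dnbinom(N, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(N, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  if (prior$pi == 1) {
    Qn <- rep(1, length(N))
  } else if (prior$pi == 0) {
    Qn <- rep(0, length(N))
  } else {
    w1 <- log(prior$pi) + l1
    w2 <- log1p(-prior$pi) + l2
    Qn <- 1 / (1 + exp(w2 - w1))
  }
  a1 <- prior$alpha1 + N; b1 <- prior$beta1 + E
  a2 <- prior$alpha2 + N; b2 <- prior$beta2 + E
  eblog2 <- (Qn * (digamma(a1) - log(b1)) +
             (1 - Qn) * (digamma(a2) - log(b2))) / log(2)
  mix_cdf <- function(x) Qn * stats::pgamma(x, a1, rate = b1) +
    (1 - Qn) * stats::pgamma(x, a2, rate = b2)
  quantile_bisect <- function(p) {
    lo <- rep(0, length(N))
    hi <- pmax(stats::qgamma(0.999999, a1, rate = b1),
               stats::qgamma(0.999999, a2, rate = b2)) + 1
    # expand the bracket until the CDF at hi exceeds p everywhere
    while (any(mix_cdf(hi) < p)) hi <- hi * 2
    repeat {
      mid <- (lo + hi) / 2
      below <- mix_cdf(mid) < p
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
      if (all(hi - lo < 1e-8)) break
    }
    (lo + hi) / 2
  }
  tibble::tibble(N = N, E = E, Qn = Qn, EBlog2 = eblog2, EBGM = 2^eblog2,
                 EB05 = quantile_bisect(0.05), EB95 = quantile_bisect(0.95))
}

#' Score a report table: expected counts, fitted prior, posterior summaries
#'
#' Convenience wrapper chaining [expected_counts()], [fit_prior()] (unless a
#' prior is supplied) and [posterior_summary()] over the full drug x event
#' grid.
#'
#' @param reports tibble of report rows `drug`, `event_pt`, `count`.
#' @param prior optional [mixture_prior()]; fitted from the table if `NULL`.
#' @return tibble `drug`, `event_pt`, `N`, `E`, `Qn`, `EBGM`, `EB05`,
#'   `EB95`, with the prior used attached as attribute `prior`.
#' @export
ebgm_scores <- function(reports, prior = NULL) {
  cells <- expected_counts(reports)
  keep <- cells$E > 0
  cells <- cells[keep, ]
  if (is.null(prior)) prior <- fit_prior(cells$N, cells$E)
  post <- posterior_summary(cells$N, cells$E, prior)
  out <- tibble::tibble(drug = cells$drug, event_pt = cells$event_pt,
                        N = post$N, E = post$E, Qn = post$Qn,
                        EBGM = post$EBGM, EB05 = post$EB05, EB95 = post$EB95)
  attr(out, "prior") <- prior
  out
}

#' Cumulative-by-quarter EBGM series for one drug-event pair
#'
#' For each quarter, builds the cumulative report table from all rows dated
#' in or before that quarter, refits the prior from scratch (no warm start,
#' so any single quarter is reproducible in isolation) and reports the EBGM
#' of the requested cell. Quarters where the cell has no reports yet are
#' returned with missing EBGM.
#'
#' @param reports tibble `drug`, `event_pt`, `quarter`, `count`.
#' @param drug,pt the cell to follow.
#' @param quarters quarter labels to evaluate (default: every quarter from
#'   the first to the last seen in `reports`).
#' @return tibble `quarter`, `N`, `E`, `EBGM`, `EB05`, `EB95`.
#' @export
cumulative_quarterly_ebgm <- function(reports, drug, pt, quarters = NULL) {
  stopifnot(all(c("drug", "event_pt", "quarter", "count") %in% names(reports)))
  qs <- sort(unique(reports$quarter))
  if (is.null(quarters)) quarters <- quarter_seq(qs[1], qs[length(qs)])
  out <- lapply(quarters, function(q) {
    sub <- reports[reports$quarter <= q, ]
    if (nrow(sub) == 0 || sum(sub$count) == 0) {
      return(tibble::tibble(quarter = q, N = NA_integer_, E = NA_real_,
                            EBGM = NA_real_, EB05 = NA_real_, EB95 = NA_real_))
    }
    cells <- expected_counts(sub)
    cells <- cells[cells$E > 0, ]
    i <- which(cells$drug == drug & cells$event_pt == pt)
    if (length(i) == 0 || cells$N[i] == 0) {
      return(tibble::tibble(quarter = q, N = 0L, E = NA_real_,
                            EBGM = NA_real_, EB05 = NA_real_, EB95 = NA_real_))
    }
    prior <- fit_prior(cells$N, cells$E)
    post <- posterior_summary(cells$N[i], cells$E[i], prior)
    tibble::tibble(quarter = q, N = as.integer(post$N), E = post$E,
                   EBGM = post$EBGM, EB05 = post$EB05, EB95 = post$EB95)
  })
  do.call(rbind, out)
}

#' Mann-Kendall trend statistic
#'
#' Nonparametric monotone-trend check used to verify that cumulative EBGM
#' series are trend-free under a null simulation. Returns the S statistic,
#' its null variance `n(n-1)(2n+5)/18` (ties ignored) and the normal
#' z-score with continuity correction.
#'
#' @param x numeric series (NAs dropped).
#' @return list with `S`, `var_S`, `z`.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  S <- 0
  for (i in seq_len(n - 1)) {
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  }
  var_S <- n * (n - 1) * (2 * n + 5) / 18
  z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  list(S = S, var_S = var_S, z = z)
}
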