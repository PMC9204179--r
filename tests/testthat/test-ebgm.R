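# The two-gamma mixture used across these tests as the simulation truth:
# a null component concentrated near lambda = 1 and a minority elevated
# component, the structure typical of spontaneous-report databases.
harness_prior <- function() mixture_prior(1, 1, 2, 0.5, 0.8)

test_that("expected counts follow the independence model and conserve totals", {
  tab <- tibble::tibble(drug = c("d1", "d1", "d2", "d2"),
                        event_pt = c("e1", "e2", "e1", "e2"),
                        count = c(5L, 5L, 5L, 5L))
  E <- expected_counts(tab)
  expect_equal(E$E, rep(5, 4))  # all margins 10, total 20
  # conservation on a random table (including grid completion)
  set.seed(1)
  rnd <- tibble::tibble(drug = sample(paste0("d", 1:6), 40, TRUE),
                        event_pt = sample(paste0("e", 1:8), 40, TRUE),
                        count = rpois(40, 3))
  Er <- expected_counts(rnd)
  expect_equal(sum(Er$E), sum(Er$N))
  expect_equal(sum(Er$N), sum(rnd$count))
  # degenerate single-cell table: E = N
  single <- tibble::tibble(drug = "d", event_pt = "e", count = 7L)
  expect_equal(expected_counts(single)$E, 7)
  expect_error(expected_counts(single[0, ]), "empty")
})

test_that("marginal likelihood matches closed form and quadrature", {
  # pi = 1, alpha = beta = 1, E = 1, N = 0: geometric marginal, P = 1/2
  p <- mixture_prior(1, 1, 2, 4, 1)
  expect_equal(marginal_loglik(0L, 1, p), -log(2))
  # quadrature oracle on a 10-cell random instance
  set.seed(2)
  pr <- mixture_prior(0.7, 0.4, 2.5, 1.5, 0.35)
  N <- rpois(10, 4)
  E <- runif(10, 0.5, 8)
  quad <- vapply(1:10, function(i) {
    f <- function(lam) {
      dpois(N[i], lam * E[i]) *
        (pr$pi * dgamma(lam, pr$alpha1, rate = pr$beta1) +
           (1 - pr$pi) * dgamma(lam, pr$alpha2, rate = pr$beta2))
    }
    log(integrate(f, 0, Inf, rel.tol = 1e-10)$value)
  }, numeric(1))
  expect_equal(marginal_loglik(N, E, pr), sum(quad), tolerance = 1e-6)
  # an N = 0 cell with E -> 0+ contributes vanishing log-likelihood
  eps <- marginal_loglik(c(N, 0L), c(E, 1e-12), pr) - marginal_loglik(N, E, pr)
  expect_lt(abs(eps), 1e-10)
  expect_error(marginal_loglik(0L, 0, pr), "positive")
})

test_that("posterior summary matches the single-gamma closed form", {
  p <- mixture_prior(1.3, 0.8, 2, 4, 1)
  N <- c(0L, 3L, 25L); E <- c(0.5, 2, 12)
  ps <- posterior_summary(N, E, p)
  closed <- exp(digamma(p$alpha1 + N) - log(p$beta1 + E))
  expect_equal(ps$EBGM, closed, tolerance = 1e-10)
  expect_equal(ps$Qn, rep(1, 3))
  # closed-form gamma quantiles
  expect_equal(ps$EB05, qgamma(0.05, p$alpha1 + N, rate = p$beta1 + E),
               tolerance = 1e-6)
  expect_equal(ps$EB95, qgamma(0.95, p$alpha1 + N, rate = p$beta1 + E),
               tolerance = 1e-6)
})

test_that("posterior CDF at the bisected quantiles is exact to 1e-6", {
  pr <- mixture_prior(0.5, 0.3, 3, 2, 0.4)
  N <- c(0L, 3L, 20L, 100L); E <- c(1, 2, 8, 40)
  ps <- posterior_summary(N, E, pr)
  mix_cdf <- function(x, i) {
    ps$Qn[i] * pgamma(x, pr$alpha1 + N[i], rate = pr$beta1 + E[i]) +
      (1 - ps$Qn[i]) * pgamma(x, pr$alpha2 + N[i], rate = pr$beta2 + E[i])
  }
  for (i in seq_along(N)) {
    expect_equal(mix_cdf(ps$EB05[i], i), 0.05, tolerance = 1e-6)
    expect_equal(mix_cdf(ps$EB95[i], i), 0.95, tolerance = 1e-6)
    expect_lte(ps$EB05[i], ps$EB95[i])
    expect_gt(ps$EBGM[i], 0)
  }
})

test_that("EBGM is monotone in N and bounded for empty cells", {
  pr <- mixture_prior(0.8, 0.5, 2, 1, 0.3)
  for (E in c(0.5, 5, 50)) {
    eb <- posterior_summary(0:100, rep(E, 101), pr)$EBGM
    expect_true(all(diff(eb) > 0))
  }
  # N = 0: below 1 + the larger prior component mean, for several priors
  for (pr0 in list(pr, mixture_prior(1, 1, 4, 2, 0.5),
                   mixture_prior(2, 2, 1, 0.2, 0.9))) {
    max_mean <- max(pr0$alpha1 / pr0$beta1, pr0$alpha2 / pr0$beta2)
    eb0 <- posterior_summary(0L, 1, pr0)$EBGM
    expect_lt(eb0, 1 + max_mean)
    expect_gt(eb0, 0)
  }
})

test_that("shrinkage vanishes for large counts: EBGM -> N / E", {
  diffuse <- mixture_prior(0.01, 0.01, 0.01, 0.01, 0.5)
  eb <- posterior_summary(500L, 100, diffuse)$EBGM
  expect_lt(abs(eb / 5 - 1), 0.02)
})

test_that("prior fitting beats its start, is deterministic, and validates", {
  sim <- simulate_report_table(harness_prior(), 20, 25, 50, seed = 19)
  N <- sim$reports$count; E <- sim$cells$E
  fit <- fit_prior(N, E)
  canonical <- mixture_prior(0.2, 0.1, 2, 4, 1/3)
  expect_gte(attr(fit, "loglik"), marginal_loglik(N, E, canonical))
  fit2 <- fit_prior(N, E)
  expect_equal(unclass(fit)[1:5], unclass(fit2)[1:5])
  expect_error(fit_prior(c(1L, 2L), c(1, 2)), "at least 5")
  expect_error(mixture_prior(-1, 1, 1, 1, 0.5), "positive")
  expect_error(mixture_prior(1, 1, 1, 1, 1.5), "\\[0, 1\\]")
})

test_that("fitting recovers true-prior EBGM on 5000 simulated cells", {
  truep <- harness_prior()
  sim <- simulate_report_table(truep, 50, 100, 100, seed = 3)
  N <- sim$reports$count; E <- sim$cells$E
  fit <- fit_prior(N, E)
  eb_fit <- posterior_summary(N, E, fit)$EBGM
  eb_true <- posterior_summary(N, E, truep)$EBGM
  expect_gte(mean(abs(eb_fit / eb_true - 1) < 0.10), 0.95)
})

test_that("cumulative series rises under a planted ramp, not under the null", {
  truep <- harness_prior()
  qs <- paste0(rep(2015:2017, each = 4), "Q", 1:4)
  n_seeds <- 20
  null_z <- numeric(n_seeds); ramp_diff <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    simn <- simulate_report_table(truep, 10, 12, c(100, 400), seed = 500 + s,
                                  quarters = qs,
                                  lambda_override = list("D001|PT0001" = 1))
    sern <- cumulative_quarterly_ebgm(simn$reports, "D001", "PT0001")
    g <- sern[!is.na(sern$N) & sern$N >= 50, ]  # sufficient-observations gate
    null_z[s] <- mann_kendall(g$EBGM)$z
    simr <- simulate_report_table(truep, 10, 12, c(100, 400), seed = 700 + s,
                                  quarters = qs,
                                  lambda_override = list(
                                    "D001|PT0001" = ramp_rate(1, 6)))
    serr <- cumulative_quarterly_ebgm(simr$reports, "D001", "PT0001")
    ramp_diff[s] <- serr$EBGM[nrow(serr)] - serr$EBGM[1]
  }
  # null: no systematic trend direction across seeds (cumulative series are
  # autocorrelated, so the ensemble mean is the calibrated check)
  expect_gt(t.test(null_z)$p.value, 0.05)
  # signal: last > first at 95% confidence over the seeds
  expect_lt(t.test(ramp_diff, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(ramp_diff > 0), 0.9)
})

test_that("single-quarter data yield a one-point series", {
  truep <- harness_prior()
  sim <- simulate_report_table(truep, 8, 10, c(100, 300), seed = 77,
                               quarters = "2016Q2")
  ser <- cumulative_quarterly_ebgm(sim$reports, "D001", "PT0001")
  expect_equal(nrow(ser), 1)
  expect_equal(ser$quarter, "2016Q2")
})
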