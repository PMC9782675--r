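test_that("Kaplan-Meier estimates match hand product-limit computations", {
  # no censoring: S drops 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # censoring at 2 removes the middle drop: S(1)=2/3, S(3)=0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))

  # all censored: flat at 1
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(km$event_times), 0)
  expect_equal(as.numeric(survival_at(km, c(0, 5))), c(1, 1))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")

  # random instances against the oracle (with event/censoring ties)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    times <- sample(1:8, n, TRUE)
    events <- rbinom(n, 1, 0.6)
    km <- km_estimate(times, events)
    oracle <- km_oracle(times, events)
    expect_equal(km$event_times, oracle$time)
    expect_equal(km$survival, oracle$surv, tolerance = 1e-12)
  }
})

test_that("KM without censoring equals the empirical survivor function", {
  set.seed(6)
  times <- rexp(300, 0.3)
  km <- km_estimate(times, rep(1, 300))
  grid <- quantile(times, c(0.1, 0.4, 0.7, 0.9))
  expect_equal(as.numeric(survival_at(km, grid)),
               vapply(grid, function(t) mean(times > t), 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("survival_at is a right-continuous step function with extrapolation flag", {
  km <- km_estimate(c(1, 2, 4), c(1, 0, 1))
  expect_equal(as.numeric(survival_at(km, 0)), 1)
  expect_equal(as.numeric(survival_at(km, 1)), 2 / 3)       # value jumps at the event
  expect_equal(as.numeric(survival_at(km, 0.999)), 1)
  expect_equal(as.numeric(survival_at(km, 3)), 2 / 3)
  s <- survival_at(km, c(2, 10))
  expect_equal(attr(s, "extrapolated"), c(FALSE, TRUE))
  expect_equal(as.numeric(s)[2], 0)
})

test_that("survival_at recovers the exponential survivor function", {
  set.seed(17)
  n <- 20000
  lambda <- 0.07
  t_true <- rexp(n, lambda)
  events <- as.integer(t_true <= 10)
  km <- km_estimate(pmin(t_true, 10), events)
  s5 <- as.numeric(survival_at(km, 5))
  target <- exp(-5 * lambda)
  se <- sqrt(target * (1 - target) / n) # binomial bound, no censoring before 10
  expect_lt(abs(s5 - target), 3 * se)
})

test_that("log-rank matches the textbook oracle and handles degenerate groups", {
  # identical groups: statistic 0, p = 1
  g <- list(times = c(1, 2, 3, 4), events = c(1, 0, 1, 1))
  tr <- logrank_test(list(g, g))
  expect_equal(tr$statistic, 0, tolerance = 1e-12)
  expect_equal(tr$p_value, 1)

  # no events anywhere: undefined comparison, p = 1
  none <- list(times = c(1, 2), events = c(0, 0))
  tr <- logrank_test(list(none, none))
  expect_true(is.na(tr$statistic))
  expect_equal(tr$p_value, 1)
  expect_match(tr$note, "no events")

  # small two-group instances against the independent implementation
  cases <- list(
    list(t1 = c(1, 3, 5, 7), e1 = c(1, 1, 0, 1), t2 = c(2, 4, 6, 8), e2 = c(1, 0, 1, 1)),
    list(t1 = c(2, 2, 4), e1 = c(1, 1, 1), t2 = c(1, 5, 6, 7, 9), e2 = c(0, 1, 1, 0, 1)),
    list(t1 = c(1, 1, 2, 2), e1 = c(1, 0, 1, 0), t2 = c(1, 2, 3, 3), e2 = c(1, 1, 1, 0))
  )
  for (cs in cases) {
    ours <- logrank_test(list(list(times = cs$t1, events = cs$e1),
                              list(times = cs$t2, events = cs$e2)))
    expect_equal(ours$statistic,
                 logrank_oracle_2g(cs$t1, cs$e1, cs$t2, cs$e2), tolerance = 1e-10)
    expect_equal(ours$df, 1)
  }
})

test_that("two-group log-rank permutation null matches its chi-squared reference", {
  set.seed(23)
  n <- 60
  times <- rexp(n, 0.2)
  events <- rbinom(n, 1, 0.8)
  grp <- rep(1:2, each = n / 2)
  stat_for <- function(g) {
    logrank_test(list(list(times = times[g == 1], events = events[g == 1]),
                      list(times = times[g == 2], events = events[g == 2])))$statistic
  }
  perm <- replicate(1000, stat_for(sample(grp)))
  q95 <- quantile(perm, 0.95)
  ref <- qchisq(0.95, 1)
  # Monte-Carlo tolerance on the 95th percentile of 1000 permutations
  expect_lt(abs(q95 - ref) / ref, 0.25)
})

test_that("chi-squared test matches the direct Pearson computation", {
  # identical row distributions: statistic 0
  even <- rbind(c(10, 20), c(10, 20))
  tr <- chi_squared_test(even)
  expect_equal(tr$statistic, 0, tolerance = 1e-12)
  expect_equal(tr$p_value, 1)

  # brute-force O/E sum on a 2x2
  tab <- rbind(c(10, 20), c(20, 10))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_squared_test(tab)$statistic,
               sum((tab - expected)^2 / expected), tolerance = 1e-12)
  expect_equal(chi_squared_test(tab)$df, 1)

  # invariance to row/column permutation
  set.seed(29)
  m <- matrix(rpois(12, 30) + 1, 3, 4)
  expect_equal(chi_squared_test(m)$statistic,
               chi_squared_test(m[sample(3), sample(4)])$statistic, tolerance = 1e-10)

  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("one-way ANOVA equals the squared pooled t statistic for two groups", {
  expect_equal(anova_oneway(list(c(2, 2), c(2, 2, 2)))$statistic, 0)

  set.seed(31)
  a <- rnorm(12, 1); b <- rnorm(15, 2)
  f <- anova_oneway(list(a, b))
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f$statistic, unname(t2), tolerance = 1e-10)
  expect_equal(f$df, c(1, 25))

  inf <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(inf$statistic))
  expect_equal(inf$p_value, 0)
})

test_that("outcome summary reproduces registry-style percentages and tests", {
  # printed-count fixture: one cluster of 1984 subjects with 759 DGF events
  n1 <- 1984; n2 <- 335
  outcomes <- data.frame(
    death_time = rep(1, n1 + n2), death_event = 0,
    dc_graft_time = 1, dc_graft_event = 0,
    graft_time = 1, graft_event = 0,
    primary_non_function = c(rep(1, 36), rep(0, n1 - 36), rep(0, n2)),
    delayed_graft_function = c(rep(1, 759), rep(0, n1 - 759), rep(1, 101), rep(0, n2 - 101)),
    rejection_1yr = c(rep(1, 157), rep(0, n1 - 157), rep(1, 8), rep(0, n2 - 8))
  )
  labels <- rep(1:2, c(n1, n2))
  summ <- outcome_summary(outcomes, labels)

  dgf <- summ$binary[summ$binary$outcome == "delayed_graft_function", ]
  expect_equal(dgf$pct, c(38.3, 30.1))
  pnf <- summ$binary[summ$binary$outcome == "primary_non_function", ]
  expect_equal(pnf$pct[1], 1.8)
  rej <- summ$binary[summ$binary$outcome == "rejection_1yr", ]
  expect_equal(rej$pct, c(7.9, 2.4))
  # percentages always equal count / denominator to rounding
  expect_equal(summ$binary$pct, pct(summ$binary$events, summ$binary$n))
  expect_equal(unique(summ$binary$n), c(n1, n2))

  expect_error(outcome_summary(outcomes[, -3], labels), "dc_graft_time")
})

test_that("ordered cluster hazards produce ordered survival and significant tests", {
  labels <- rep(1:3, each = 1700)
  specs <- list(death_rate = c(0.03, 0.08, 0.20), graft_failure_rate = c(0.02, 0.05, 0.12),
                pnf_prob = c(0.01, 0.01, 0.01), dgf_prob = c(0.1, 0.3, 0.5),
                rejection_prob = c(0.03, 0.06, 0.12))
  out <- generate_outcomes(labels, specs, admin_censor_time = 10, seed = 37)
  summ <- outcome_summary(out, labels)

  s5 <- summ$survival[summ$survival$outcome == "death" & summ$survival$horizon == 5, ]
  expect_equal(s5$cluster[order(-s5$survival_pct)], 1:3)
  # survival percentages sit near the exponential truth
  expect_equal(s5$survival_pct, 100 * exp(-5 * specs$death_rate), tolerance = 0.05)

  tests <- summ$tests
  expect_true(all(tests$p_value[tests$outcome %in%
    c("delayed_graft_function", "death_survival", "graft_survival")] < 0.001))
  expect_true(all(tests$p_bonferroni >= tests$p_value))
  expect_equal(nrow(tests), 6)

  dir <- withr::local_tempdir()
  write_outcome_results(summ, dir)
  expect_true(file.exists(file.path(dir, "binary_outcomes.csv")))
  expect_true(file.exists(file.path(dir, "km_death.csv")))
})
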