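test_that("product-limit curve matches the hand-computed example", {
  km <- km_fit(c(2, 4, 5), c(1, 0, 1))
  expect_equal(km$event_times, c(2, 5))
  expect_equal(km$n_at_risk, c(3, 1))
  expect_equal(km$n_events, c(1, 1))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(median_survival(km), 5)
})

test_that("KM equals the empirical survival function without censoring", {
  km <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(3, 2, 1, 0) / 4)
  set.seed(31)
  for (i in 1:20) {
    times <- sample(1:15, sample(5:25, 1), replace = TRUE)
    km <- km_fit(times, rep(1, length(times)))
    expect_equal(km$survival,
                 vapply(km$event_times, function(t) mean(times > t), numeric(1)))
  }
})

test_that("KM with all observations censored is identically one", {
  km <- km_fit(c(3, 7, 9), c(0, 0, 0))
  expect_length(km$event_times, 0)
  expect_true(is.na(median_survival(km)))
})

test_that("KM is invariant to patient ordering", {
  set.seed(17)
  times <- stats::rexp(40, 0.1) + 0.1
  events <- stats::rbinom(40, 1, 0.6)
  a <- km_fit(times, events)
  ord <- sample(40)
  b <- km_fit(times[ord], events[ord])
  expect_equal(a, b)
})

test_that("median survival uses the first-time-at-or-below-one-half convention", {
  # survival hits exactly 0.5 at the first event time of a 2-patient group
  km <- km_fit(c(4, 9), c(1, 0))
  expect_equal(km$survival[1], 0.5)
  expect_equal(median_survival(km), 4)
  # curve never reaching 0.5 -> undefined
  km2 <- km_fit(c(2, 3, 4, 5, 6), c(1, 0, 0, 0, 0))
  expect_true(min(km2$survival) > 0.5)
  expect_true(is.na(median_survival(km2)))
})

test_that("log-rank is symmetric, null on identical groups, and safe with no events", {
  t1 <- c(2, 5, 7, 9, 12); e1 <- c(1, 0, 1, 1, 0)
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  t2 <- c(1, 3, 4, 8, 15); e2 <- c(1, 1, 0, 1, 1)
  ab <- logrank_test(t1, e1, t2, e2)
  ba <- logrank_test(t2, e2, t1, e1)
  expect_equal(ab$chi2, ba$chi2)
  expect_equal(ab$p, ba$p)
  expect_gte(ab$chi2, 0)
  expect_true(ab$p > 0 && ab$p <= 1)
  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(none$chi2, 0)
  expect_equal(none$p, 1)
})

test_that("ratio marker applies the zero conventions", {
  d <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                  os_months = c(10, 20, 30, 40), event = c(1, 1, 0, 1),
                  GCK = c(12, 0, 5, 8), HK2 = c(4, 0, 0, 2))
  coh <- cohort(d)
  expect_message(mv <- ratio_values(coh, "GCK", "HK2"), "s2")
  expect_equal(unname(mv$values[c("s1", "s4")]), c(3, 4))
  expect_equal(unname(mv$values["s3"]), Inf)   # positive numerator over zero
  expect_equal(mv$excluded$sample_id, "s2")    # both zero: ratio undefined
  expect_match(mv$excluded$reason, "undefined")
  expect_error(ratio_values(coh, "GCK", "NOPE"), "missing from cohort")
  expect_error(marker_values(coh, "NOPE"), "missing from cohort")
})

test_that("best-cutoff stratification recovers a planted survival split", {
  set.seed(23)
  n <- 40
  marker <- stats::runif(n, 0, 10)
  d <- data.frame(sample_id = sprintf("s%02d", 1:n),
                  os_months = ifelse(marker > 5, 100, 10),
                  event = rep(1, n), MK = marker)
  coh <- cohort(d)
  res <- best_cutoff_stratify(coh, marker_values(coh, "MK"))
  expect_gte(res$cutoff, 4)
  expect_lte(res$cutoff, 6)
  expect_lt(res$p, 1e-4)
  expect_equal(res$median_high, 100)
  expect_equal(res$median_low, 10)
  expect_equal(res$delta_median, 90)
  expect_setequal(c(res$high_group, res$low_group), coh$sample_id)
  # optimal p is never worse than a fixed median split
  med <- stats::median(marker)
  high <- marker > med
  lr_med <- logrank_test(d$os_months[high], d$event[high],
                         d$os_months[!high], d$event[!high])
  expect_lte(res$p, lr_med$p)
})

test_that("stratification rejects constant markers and tiny cohorts", {
  d <- data.frame(sample_id = sprintf("s%02d", 1:12), os_months = 1:12,
                  event = rep(1, 12), MK = rep(5, 12))
  coh <- cohort(d)
  expect_error(best_cutoff_stratify(coh, marker_values(coh, "MK")),
               "no admissible cutoff")
  d2 <- d[1:5, ]
  coh2 <- cohort(d2)
  expect_error(best_cutoff_stratify(coh2, marker_values(coh2, "MK")),
               "at least 10")
})

test_that("min_group_frac = 0.5 forces the median split on even n", {
  set.seed(7)
  n <- 20
  d <- data.frame(sample_id = sprintf("s%02d", 1:n),
                  os_months = stats::rexp(n, 0.05) + 1, event = rep(1, n),
                  MK = sample(seq_len(n)))
  coh <- cohort(d)
  res <- best_cutoff_stratify(coh, marker_values(coh, "MK"), min_group_frac = 0.5)
  expect_equal(res$n_cutoffs_scanned, 1L)
  expect_equal(length(res$high_group), n / 2)
})

test_that("infinite ratio values rank above every finite cutoff", {
  n <- 20
  d <- data.frame(sample_id = sprintf("s%02d", 1:n),
                  os_months = c(rep(60, 10), rep(5, 10)), event = rep(1, n),
                  NUM = c(rep(4, 8), 9, 9, rep(1, 10)),
                  DEN = c(rep(1, 8), 0, 0, rep(4, 10)))
  coh <- cohort(d)
  mv <- ratio_values(coh, "NUM", "DEN")
  expect_equal(sum(is.infinite(mv$values)), 2)
  res <- best_cutoff_stratify(coh, mv, min_group_frac = 0.2)
  # the two infinite-ratio patients always fall in the high group
  expect_true(all(c("s09", "s10") %in% res$high_group))
  expect_lt(res$p, 0.01)
})

test_that("uncensored keeps only observed deaths and is idempotent", {
  d <- data.frame(sample_id = c("a", "b", "c", "d"), os_months = c(5, 6, 7, 8),
                  event = c(1, 0, 1, 0), GCK = 1:4)
  coh <- cohort(d)
  u <- uncensored(coh)
  expect_equal(u$sample_id, c("a", "c"))
  expect_equal(uncensored(u), u)
  all_cens <- cohort(data.frame(sample_id = "x", os_months = 5, event = 0, GCK = 1))
  expect_equal(nrow(uncensored(all_cens)), 0)
})

test_that("Spearman correlation matches hand ranking and cor.test", {
  res <- spearman_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)   # sum d^2 = 4: 1 - 6*4/(5*24)
  ref <- suppressWarnings(stats::cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))
  # monotone transforms give +/-1
  x <- c(0.3, 1.1, 2.2, 5.5, 9)
  expect_equal(spearman_test(x, exp(x))$rho, 1)
  expect_equal(spearman_test(x, -x^3)$rho, -1)
  expect_equal(spearman_test(x, exp(x))$p, 0)
  # t-approximation agrees with cor.test's asymptotic p for moderate n
  set.seed(41)
  xx <- stats::rnorm(60); yy <- xx + stats::rnorm(60)
  mine <- spearman_test(xx, yy)
  ref2 <- stats::cor.test(xx, yy, method = "spearman")
  expect_equal(mine$rho, unname(ref2$estimate), tolerance = 1e-12)
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
})
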