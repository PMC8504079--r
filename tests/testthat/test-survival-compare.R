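test_that("product-limit estimate matches hand-computed tables", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_equal(nrow(km0), 0)
  expect_equal(km_survival_at(km0, c(0, 20)), c(1, 1))

  # n = 4, one event at t = 10: S(10) = 3/4
  km1 <- km_estimate(c(10, 12, 15, 20), c(1, 0, 0, 0))
  expect_equal(km1$surv, 0.75)
  expect_equal(km_survival_at(km1, 10), 0.75)
  expect_equal(km_survival_at(km1, 9.9), 1)

  # mixed 6-record table, hand-computed product-limit sequence:
  # t=2 (d=1, n=6): 5/6; t=4 (d=1, n=4): 5/6*3/4; t=7 (d=2, n=2): 0
  km2 <- km_estimate(c(2, 3, 4, 7, 7, 5), c(1, 0, 1, 1, 1, 0))
  expect_equal(km2$time, c(2, 4, 7))
  expect_equal(km2$n_risk, c(6, 4, 2))
  expect_equal(km2$n_event, c(1, 1, 2))
  expect_equal(km2$surv, c(5/6, 5/6 * 3/4, 0))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("km curves are monotone within [0, 1] under heavy censoring", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    time <- rexp(n, 0.01)
    event <- rbinom(n, 1, 0.3)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("km estimate agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(14)
  time <- round(rexp(40, 0.02)) + 1
  event <- rbinom(40, 1, 0.6)
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  at_events <- summary(sf, times = km$time)
  expect_equal(km$surv, at_events$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand-computed O/E/V table", {
  # 8 records, 2 groups; computing O, E and hypergeometric V stepwise:
  # group A times: 1(event) 3(event) 5(cens) 7(event)
  # group B times: 2(event) 4(cens) 6(event) 8(cens)
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0)
  grp <- rep(c("A", "B"), each = 4)
  # per-event-time risk sets (event times 1, 2, 3, 6, 7):
  tab <- data.frame(nA = c(4, 3, 3, 1, 1), nB = c(4, 4, 3, 2, 1),
                    dA = c(1, 0, 1, 0, 1), dB = c(0, 1, 0, 1, 0))
  n <- tab$nA + tab$nB; d <- tab$dA + tab$dB
  EA <- sum(d * tab$nA / n)
  V <- sum(d * (n - d) / (n - 1) * (tab$nA / n) * (1 - tab$nA / n))
  stat_hand <- (sum(tab$dA) - EA)^2 / V
  res <- logrank_test(time, event, grp)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(unname(res$observed), c(sum(tab$dA), sum(tab$dB)))
})

test_that("log-rank agrees with survival::survdiff on random data", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (k in c(2, 3)) {
    for (i in 1:10) {
      n <- 60
      grp <- sample(letters[1:k], n, replace = TRUE)
      time <- round(rexp(n, ifelse(grp == "a", 0.02, 0.01))) + 1
      event <- rbinom(n, 1, 0.7)
      if (length(unique(grp)) < k || sum(event) == 0) next
      mine <- logrank_test(time, event, grp)
      ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
      expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
      expect_equal(mine$p_value,
                   pchisq(ref$chisq, k - 1, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  }
})

test_that("log-rank degenerate and symmetry properties hold", {
  time <- c(1, 2, 3, 1, 2, 3)
  event <- c(1, 0, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 3)
  # identical record multisets in the two groups -> statistic 0, p = 1
  res <- logrank_test(time, event, grp)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # invariance to swapping group labels
  set.seed(19)
  t2 <- rexp(30, 0.1); e2 <- rbinom(30, 1, 0.8)
  g2 <- rep(c("A", "B"), 15)
  a <- logrank_test(t2, e2, g2)
  b <- logrank_test(t2, e2, ifelse(g2 == "A", "B", "A"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(logrank_test(t2, e2, rep("A", 30)), "2 groups")
  expect_error(logrank_test(t2, rep(0, 30), g2), "no events")
})

test_that("call-source comparison enforces disjoint subject sets", {
  set.seed(23)
  n <- 120
  ids <- sprintf("P%03d", 1:n)
  labels <- rep(0:1, each = n / 2)
  surv <- simulate_survival(labels, lambda = 0.001, hazard_ratio = 4,
                            censor_rate = 0.2, seed = 31)
  records <- data.frame(sample_id = ids, time = surv$survival_days,
                        event = surv$event)
  a_ids <- ids[1:60 * 2 - 1]   # odd positions
  b_ids <- setdiff(ids, a_ids)
  cmp <- compare_call_sources(records,
                              setNames(labels[match(a_ids, ids)], a_ids),
                              setNames(labels[match(b_ids, ids)], b_ids))
  expect_s3_class(cmp, "call_source_comparison")
  expect_equal(cmp$reference$n, 60)
  expect_equal(cmp$model$n, 60)
  # identical calls on identical (copied) cohorts give identical statistics
  rec2 <- records
  rec2$sample_id <- paste0("X", rec2$sample_id)
  cmp2 <- compare_call_sources(rbind(records, rec2),
                               setNames(labels, ids),
                               setNames(labels, rec2$sample_id))
  expect_equal(cmp2$reference$test$statistic, cmp2$model$test$statistic)
  expect_error(compare_call_sources(records,
                                    setNames(labels[1:4], ids[1:4]),
                                    setNames(labels[3:6], ids[3:6])),
               "disjoint")
})

test_that("noisy model calls lose prognostic separation vs clean calls", {
  set.seed(41)
  worse <- 0L
  reps <- 30
  for (i in 1:reps) {
    n <- 160
    ids <- sprintf("P%03d", 1:n)
    labels <- rep(0:1, each = n / 2)
    surv <- simulate_survival(labels, lambda = 0.002, hazard_ratio = 4,
                              censor_rate = 0.2)
    records <- data.frame(sample_id = ids, time = surv$survival_days,
                          event = surv$event)
    half <- sample(n, n / 2)
    a_ids <- ids[half]; b_ids <- setdiff(ids, a_ids)
    clean <- setNames(labels[match(a_ids, ids)], a_ids)
    noisy <- labels[match(b_ids, ids)]
    flip <- sample(length(noisy), round(0.2 * length(noisy)))
    noisy[flip] <- 1L - noisy[flip]
    cmp <- compare_call_sources(records, clean, setNames(noisy, b_ids))
    worse <- worse + (cmp$model$test$p_value > cmp$reference$test$p_value)
  }
  expect_gt(worse / reps, 0.5)
})
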