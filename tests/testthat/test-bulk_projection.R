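test_that("median split sends ties to low and survives monotone transforms", {
  s <- median_split(c(1, 2, 3, 4))
  expect_identical(as.character(s), c("low", "low", "high", "high"))
  s3 <- median_split(c(1, 2, 3))
  expect_identical(as.character(s3), c("low", "low", "high"))  # 2 -> low
  v <- c(5, 1, 9, 4, 7)
  expect_identical(median_split(v), median_split(log(v)))
  expect_identical(median_split(v), median_split(v^3))
  expect_error(median_split(rep(2, 5)), "identical")
  expect_error(median_split(3), "at least 2")
})

test_that("Kaplan-Meier estimates match closed forms", {
  none <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(none$curve$survival == 1))

  two <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(two$curve$survival, c(0.5, 0))

  # hand-computed mixed censored/event table:
  # t=1 event (5 at risk) -> 4/5; t=2 censored; t=3 event (3 at risk) ->
  # 4/5 * 2/3 = 8/15; t=4 censored; t=5 event (1 at risk) -> 0
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- km$curve[km$curve$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 8 / 15, 0), tolerance = 1e-12)
  # survival is non-increasing and starts below 1
  expect_true(all(diff(km$curve$survival) <= 0))

  # with no censoring the KM curve equals the empirical survival function
  set.seed(3)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- vapply(km2$curve$time, function(s) mean(t > s), numeric(1))
  expect_equal(km2$curve$survival, emp, tolerance = 1e-12)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")

  rt <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1),
                    risk_times = c(0, 2.5))
  expect_equal(rt$risk_table$n_risk, c(5, 3))
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # identical groups: statistic 0, p 1
  t <- c(1, 2, 3, 1, 2, 3); e <- rep(1, 6); g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(t, e, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # 6-subject toy with censoring vs the explicit O-E/V computation
  t2 <- c(1, 3, 4, 2, 5, 7); e2 <- c(1, 1, 0, 1, 1, 1)
  g2 <- rep(c("a", "b"), each = 3)
  res2 <- logrank_test(t2, e2, g2)
  oracle <- logrank_reference(t2, e2, g2)
  expect_equal(res2$statistic, oracle$chisq, tolerance = 1e-10)
  expect_equal(res2$p, oracle$p, tolerance = 1e-10)

  # invariance to swapping group labels
  swapped <- logrank_test(t2, e2, ifelse(g2 == "a", "b", "a"))
  expect_equal(res2$p, swapped$p, tolerance = 1e-12)

  expect_warning(r0 <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(r0$p, 1)
  expect_error(logrank_test(t2, e2, rep("a", 6)), "2 non-empty levels")
})

test_that("strong separation yields a decisive log-rank result", {
  res <- simulate_bulk_cohort(400, beta = log(5), censor_rate = 0.2,
                              seed = 12L)
  clin <- res$cohort$clinical
  g <- median_split(res$cohort$expr$SLC2A1)
  expect_lt(logrank_test(clin$time, clin$event, g)$p, 0.001)
})

test_that("Cox fit recovers null covariates and fails loudly on separation", {
  set.seed(140)
  n <- 2000
  d <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8),
                  marker_high = rbinom(n, 1, 0.5))
  tab <- cox_ph(d, terms = "marker_high")
  expect_gt(tab$upper95, 1)
  expect_lt(tab$lower95, 1)
  expect_true(tab$lower95 <= tab$hr & tab$hr <= tab$upper95)

  # complete separation: the marker-high arm has no events
  sep <- data.frame(time = c(rexp(30) + 10, rexp(30)),
                    event = rep(c(0L, 1L), each = 30),
                    marker_high = rep(c(1L, 0L), each = 30))
  expect_error(cox_ph(sep, terms = "marker_high"), "converge")
  expect_error(cox_ph(d[1:3, ], terms = c("marker_high", "time", "event",
                                          "marker_high")), "fewer events")
})

test_that("Cox score test agrees with the log-rank statistic without ties", {
  set.seed(15)
  n <- 120
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = exp(0.6 * g))
  e <- rbinom(n, 1, 0.85)
  fit <- survival::coxph(survival::Surv(t, e) ~ g, ties = "efron")
  sc <- summary(fit)$sctest[["test"]]
  lr <- logrank_test(t, e, g)$statistic
  expect_equal(sc, lr, tolerance = 1e-6)
})

test_that("BH adjustment and Fisher enrichment behave canonically", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(16)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q <= 1))
  ordq <- q[order(p)]
  expect_true(all(diff(ordq) >= 0))
  expect_true(all(q >= p))

  high <- cbind(mutated = c(5, 10), wildtype = c(5, 0))
  low <- cbind(mutated = c(5, 0), wildtype = c(5, 10))
  rownames(high) <- rownames(low) <- c("BAL", "SEP")
  fe <- fisher_enrichment(high, low)
  expect_equal(fe$p[fe$gene == "BAL"], 1)
  expect_equal(fe$odds_ratio[fe$gene == "BAL"], 1, tolerance = 1e-6)
  expect_lt(fe$p[fe$gene == "SEP"], 0.001)
  expect_true(all(fe$q >= fe$p))
  expect_error(fisher_enrichment(-high, low), "negative")

  # random tables against the enumeration oracle
  set.seed(17)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    fe2 <- fisher_enrichment(
      cbind(mutated = tab[1, 1], wildtype = tab[1, 2]),
      cbind(mutated = tab[2, 1], wildtype = tab[2, 2]))
    expect_equal(fe2$p, fisher_enumeration(tab), tolerance = 1e-12)
  }
})

test_that("the full bulk survival flow stratifies a planted cohort", {
  res <- simulate_bulk_cohort(800, beta = log(2.64), censor_rate = 0.3,
                              seed = 18L)
  sv <- bulk_survival(res$cohort, "SLC2A1",
                      subgroups = list(
                        stage_III_IV = function(d) d$stage == "III/IV",
                        empty = function(d) d$age > 1000)) |>
    suppressWarnings()
  hr <- sv$cox$hr[sv$cox$term == "marker_high"]
  expect_gt(hr, 1)
  expect_lt(sv$overall$logrank$p, 0.01)
  expect_true(sv$cox$lower95[sv$cox$term == "marker_high"] <= hr)
  expect_null(sv$subgroups$empty)
  expect_false(is.null(sv$subgroups$stage_III_IV))
  # KM curves are valid survival functions
  expect_true(all(diff(sv$overall$km_high$curve$survival) <= 0))
  expect_true(all(sv$overall$km_low$curve$survival >= 0 &
                    sv$overall$km_low$curve$survival <= 1))
  expect_error(bulk_survival(res$cohort, "NOPE"), "absent")
})
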