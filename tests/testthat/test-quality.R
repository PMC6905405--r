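frame <- default_frame()

test_that("Clopper-Pearson intervals match the exact binomial test", {
  ci <- binomial_ci(0, 10)
  expect_equal(ci$ci_low, 0)
  expect_equal(ci$ci_high, 0.3085, tolerance = 1e-4)

  ci <- binomial_ci(39, 138)
  expect_equal(ci$proportion, 0.2826, tolerance = 1e-4)

  ci <- binomial_ci(7, 7)
  expect_equal(ci$proportion, 1)
  expect_equal(ci$ci_high, 1)

  # oracle: stats::binom.test over a grid of (s, n)
  for (n in c(5, 20, 138)) {
    for (s in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- binomial_ci(s, n)
      ref <- binom.test(s, n)$conf.int
      expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref),
                   tolerance = 1e-10)
    }
  }
  expect_error(binomial_ci(0, 0), "trials")
  expect_error(binomial_ci(5, 3), "successes")
})

test_that("Wilson intervals bracket the point estimate inside [0, 1]", {
  grid <- expand.grid(s = c(0, 3, 10), n = c(10, 50))
  w <- binomial_ci(grid$s, grid$n, method = "wilson")
  expect_true(all(w$ci_low >= 0 & w$ci_high <= 1))
  expect_true(all(w$ci_low <= w$proportion & w$proportion <= w$ci_high))
  # midpoint recovers the standard score interval at p = 1/2
  m <- binomial_ci(25, 50, method = "wilson")
  z <- qnorm(0.975)
  expect_equal(m$ci_high - 0.5, z * sqrt(0.25 / 50 + z^2 / 1e4) /
                 (1 + z^2 / 50), tolerance = 1e-12)
})

test_that("viability pools flotation outcomes per period", {
  flags <- c(rep("sink", 63), rep("float", 37))
  samples <- make_samples(rep("Er", 100), viable = flags)
  v <- viability_by_period(samples, frame)
  early <- v[v$period == "early", ]
  expect_equal(early$proportion, 0.63)
  expect_equal(early$trials, 100L)
  expect_true(all(v$trials[v$period != "early"] == 0))
  expect_true(all(is.na(v$proportion[v$period != "early"])))

  allfloat <- viability_by_period(
    make_samples(rep("Er", 5), viable = rep("float", 5)), frame
  )
  expect_equal(allfloat$proportion[allfloat$period == "early"], 0)

  # untested seeds are excluded, not imputed
  mix <- viability_by_period(
    make_samples("Er", n_seeds = 3, viable = "sink;untested;float"), frame
  )
  expect_equal(mix$trials[mix$period == "early"], 2L)
})

test_that("escape probability pools seeds across depots per cell", {
  depots <- tibble::tibble(
    depot_id = sprintf("D%02d", 1:75),
    period = rep(frame$periods$period, each = 25),
    microhabitat = rep(frame$microhabitats, length.out = 75),
    n_seeds = 10L, n_surviving = 0L
  )
  depots$n_surviving[c(1, 30, 31, 55, 60)] <- 1L
  p <- escape_probability(depots, frame)
  expect_equal(sum(p$successes), 5L)
  expect_equal(sum(p$trials), 750L)
  pooled <- binomial_ci(5, 750)
  expect_equal(pooled$proportion, 5 / 750)
  expect_equal(round(pooled$proportion, 4), 0.0067)

  depots$n_surviving[1] <- 11L
  expect_error(escape_probability(depots, frame), "D01")
})

test_that("germination excludes lost stations from both counts", {
  sowing <- rbind(
    make_station("W1", "early", "trees",
                 germ_weeks = c(6, 8, 9, rep(NA, 6))),
    make_station("W2", "early", "trees", germ_weeks = rep(NA, 9),
                 lost_germ = 1, lost_surv = 1)
  )
  g <- germination_probability(sowing, frame)
  cell <- g[g$period == "early" & g$microhabitat == "trees", ]
  expect_equal(cell$successes, 3L)
  expect_equal(cell$trials, 9L)
  expect_equal(cell$proportion, 1 / 3)

  # a cell whose stations were all lost is undefined
  lost <- make_station("W3", "mid", "trees", lost_germ = 1, lost_surv = 1)
  g2 <- germination_probability(rbind(sowing, lost), frame)
  cellm <- g2[g2$period == "mid" & g2$microhabitat == "trees", ]
  expect_equal(cellm$trials, 0L)
  expect_true(is.na(cellm$proportion))
})

test_that("germination speed averages weeks among germinated seeds", {
  sowing <- rbind(
    make_station("W1", "early", "trees", germ_weeks = c(8, 8, rep(NA, 7))),
    make_station("W2", "mid", "trees", germ_weeks = c(6, 8, 10, rep(NA, 6)))
  )
  sp <- germination_speed(sowing, frame)
  expect_equal(sp$mean_weeks[sp$period == "early"], 8)
  expect_equal(sp$mean_weeks[sp$period == "mid"], 8)
  expect_true(is.na(sp$mean_weeks[sp$period == "late"]))
  expect_equal(sp$n_germinated[sp$period == "late"], 0L)
})

test_that("survival conditions on emergence in survival-retained stations", {
  sowing <- rbind(
    make_station("W1", "early", "trees",
                 germ_weeks = c(5, 6, 7, 8, rep(NA, 5)),
                 survived = c(1, 0, 0, 1, rep(NA, 5))),
    # lost for survival but not germination: counts for g, not s
    make_station("W2", "early", "trees",
                 germ_weeks = c(5, 5, rep(NA, 7)),
                 survived = rep(NA, 9), lost_surv = 1)
  )
  g <- germination_probability(sowing, frame)
  s <- seedling_survival(sowing, frame)
  gcell <- g[g$period == "early" & g$microhabitat == "trees", ]
  scell <- s[s$period == "early" & s$microhabitat == "trees", ]
  expect_equal(gcell$successes, 6L)
  expect_equal(gcell$trials, 18L)
  expect_equal(scell$successes, 2L)
  expect_equal(scell$trials, 4L)
  expect_equal(scell$proportion, 0.5)
})

test_that("sowing invariants are enforced", {
  bad <- make_station("W1", "early", "trees", lost_germ = 1, lost_surv = 0)
  expect_error(germination_probability(bad, frame), "W1")
  bad2 <- make_station("W2", "early", "trees",
                       survived = c(1, rep(NA, 8)))
  expect_error(seedling_survival(bad2, frame), "ungerminated")
})

test_that("the zero policy replaces as documented and is idempotent", {
  p <- tibble::tibble(period = "x", proportion = c(0, 0, 0.0067, 0.002))
  s <- tibble::tibble(period = "x", proportion = c(0.2, 0, 0.09))
  adj <- apply_zero_policy(p, s)
  expect_equal(adj$p$proportion, rep(0.01, 4))
  expect_equal(adj$s$proportion, c(0.2, 0.09, 0.09))
  expect_equal(adj$s$replaced, c(FALSE, TRUE, FALSE))
  expect_true(all(adj$p$replaced))

  # idempotence: applying the policy twice equals applying it once
  twice <- apply_zero_policy(adj$p, adj$s)
  expect_equal(twice$p, adj$p)
  expect_equal(twice$s, adj$s)

  # raw policy is the identity on the estimates
  raw <- apply_zero_policy(p, s, policy = "raw")
  expect_equal(raw$p$proportion, p$proportion)
  expect_equal(raw$s$proportion, s$proportion)

  expect_error(
    apply_zero_policy(p, tibble::tibble(proportion = c(0, 0))),
    "s_replacement"
  )
})

test_that("the period-effect G2 test matches a contingency-table oracle", {
  # equal proportions across periods carry no evidence
  eq <- tibble::tibble(period = c("a", "b"), successes = c(10, 10),
                       trials = c(20, 20))
  res <- period_effect_test(eq)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  g2_oracle <- function(s, n) {
    # 2 * sum O log(O/E) over the k x 2 table of successes and failures
    obs <- cbind(s, n - s)
    expd <- outer(n, colSums(obs) / sum(n))
    2 * sum(ifelse(obs == 0, 0, obs * log(obs / expd)))
  }
  set.seed(99)
  for (i in 1:25) {
    n <- sample(20:200, 3)
    s <- rbinom(3, n, runif(3, 0.05, 0.95))
    got <- period_effect_test(tibble::tibble(
      period = c("early", "mid", "late"), successes = s, trials = n
    ))
    expect_equal(got$statistic, g2_oracle(s, n), tolerance = 1e-10)
    expect_equal(got$df, 2)
    expect_equal(got$p_value, pchisq(g2_oracle(s, n), 2, lower.tail = FALSE))
  }
  expect_error(period_effect_test(eq[1, ]), "at least two periods")
})

test_that("G2 and Pearson chi-squared agree on large tables", {
  set.seed(5)
  for (i in 1:20) {
    n <- rep(500, 3)
    p <- c(0.3, 0.5, 0.7) + runif(3, -0.05, 0.05)
    s <- rbinom(3, n, p)
    tab <- tibble::tibble(period = c("a", "b", "c"), successes = s,
                          trials = n)
    g2 <- period_effect_test(tab)$statistic
    x2 <- suppressWarnings(chisq.test(cbind(s, n - s),
                                      correct = FALSE)$statistic)
    expect_lt(abs(g2 - x2) / x2, 0.05)
  }
})

test_that("quality cells multiply the four subcomponents exactly", {
  cfg <- small_config()
  b <- generate_study(cfg, 17)
  v <- viability_by_period(b$samples, frame)
  p <- escape_probability(b$depots, frame)
  g <- germination_probability(b$sowing, frame)
  s <- seedling_survival(b$sowing, frame)
  q <- quality_table(v, p, g, s, frame)
  expect_equal(q$ql, q$v * q$p * q$g * q$s)
  ok <- !is.na(q$ql)
  expect_true(all(q$ql[ok] >= 0 & q$ql[ok] <= 1))
  expect_true(all(q$p[!is.na(q$p)] == 0.01))
  # product is invariant to factor ordering
  expect_equal(q$ql, q$s * q$g * q$p * q$v)
})
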