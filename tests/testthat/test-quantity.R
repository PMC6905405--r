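frame <- default_frame()

test_that("per-trap densities total counts over a period and divide by area", {
  traps <- tibble::tibble(trap_id = "T01", microhabitat = "fb_shrubs")
  surveys <- make_surveys("T01", c("2014-08-20", "2014-09-03"), c(4L, 7L))
  d <- seed_rain_density(surveys, traps, frame)
  early <- d[d$period == "early" & d$microhabitat == "fb_shrubs", ]
  expect_equal(early$mean_density, 11 / 0.22)
  expect_equal(early$mean_density, 50)

  # a second trap with no seeds halves the mean
  traps2 <- tibble::tibble(trap_id = c("T01", "T02"),
                           microhabitat = "fb_shrubs")
  d2 <- seed_rain_density(surveys, traps2, frame)
  early2 <- d2[d2$period == "early" & d2$microhabitat == "fb_shrubs", ]
  expect_equal(early2$mean_density, 25)
  expect_equal(sort(early2$per_trap[[1]]), c(0, 50))

  # all-zero cells get a degenerate [0, 0] interval
  expect_equal(early2$n_traps, 2L)
  mid2 <- d2[d2$period == "mid" & d2$microhabitat == "fb_shrubs", ]
  expect_equal(c(mid2$mean_density, mid2$ci_low, mid2$ci_high), c(0, 0, 0))

  # microhabitats with no traps are explicit missing cells, not zeros
  trees <- d[d$microhabitat == "trees", ]
  expect_true(all(trees$n_traps == 0))
  expect_true(all(is.na(trees$mean_density)))
})

test_that("densities scale inversely with trap area", {
  traps <- make_traps(frame)
  set.seed(3)
  surveys <- tidyr::expand_grid(
    trap_id = traps$trap_id,
    survey_date = as.Date(c("2014-09-01", "2014-12-01", "2015-03-01"))
  )
  surveys$seed_count <- rpois(nrow(surveys), 5)
  d1 <- seed_rain_density(surveys, traps, frame)
  traps2 <- traps
  traps2$area_m2 <- 2 * frame$trap_area
  d2 <- seed_rain_density(surveys, traps2, frame)
  expect_equal(d2$mean_density, d1$mean_density / 2)
  for (i in seq_len(nrow(d2))) {
    expect_equal(d2$per_trap[[i]], d1$per_trap[[i]] / 2)
  }
})

test_that("group frequencies count per seed and renormalise over identified", {
  samples <- make_samples(c(rep("Er", 5), rep("Sm", 3), "Fh",
                            SPECIES_UNIDENTIFIED))
  f <- group_frequencies(samples, frame)
  cell <- f[f$period == "early" & f$microhabitat == "fb_shrubs", ]
  freq <- setNames(cell$frequency, cell$group)
  expect_equal(unname(freq[c("European", "resident", "sub-Saharan")]),
               c(5, 3, 1) / 9)
  expect_equal(sum(cell$frequency), 1)

  # single-species cell pins its group's frequency at one
  one <- group_frequencies(make_samples(rep("Tp", 4)), frame)
  cell1 <- one[one$period == "early" & one$microhabitat == "fb_shrubs", ]
  expect_equal(sort(cell1$frequency), c(0, 0, 1))

  # cells with no identified seed are undefined, not zero
  expect_true(all(is.na(f$frequency[f$period == "late"])))
})

test_that("frequencies are invariant to splitting multi-seed droppings", {
  multi <- make_samples(c("Er", "Sm", "Fh"), n_seeds = c(3, 2, 1))
  split <- make_samples(c(rep("Er", 3), rep("Sm", 2), "Fh"), n_seeds = 1)
  f1 <- group_frequencies(multi, frame)
  f2 <- group_frequencies(split, frame)
  expect_equal(f1$frequency, f2$frequency)
})

test_that("unknown species codes are rejected with the frame's codes listed", {
  expect_error(group_frequencies(make_samples("Zz"), frame),
               "unknown species code.*Sm")
})

test_that("the quantity component conserves density across groups", {
  cfg <- small_config()
  b <- generate_study(cfg, 5)
  d <- seed_rain_density(b$surveys, b$traps, frame)
  f <- group_frequencies(b$samples, frame)
  qt <- quantity_component(d, f)
  expect_equal(qt$qt, qt$density * qt$frequency)
  recon <- qt |>
    dplyr::group_by(period, microhabitat) |>
    dplyr::summarise(total = sum(qt), d = density[1], .groups = "drop")
  expect_equal(recon$total, recon$d, tolerance = 1e-12)
})

test_that("undefined frequencies with positive density are an error", {
  d <- tibble::tibble(period = "early", microhabitat = "trees",
                      n_traps = 2L, mean_density = 10)
  f <- tibble::tibble(group = frame$groups, period = "early",
                      microhabitat = "trees", frequency = NA_real_)
  expect_error(quantity_component(d, f), "early x trees")
  # zero density propagates zero quantity even with undefined frequencies
  d$mean_density <- 0
  qt <- quantity_component(d, f)
  expect_equal(qt$qt, c(0, 0, 0))
})

test_that("the factorial ANOVA matches a least-squares projection oracle", {
  traps <- make_traps(frame, n_per_mh = 4)
  set.seed(21)
  surveys <- tidyr::expand_grid(
    trap_id = traps$trap_id,
    survey_date = as.Date(c("2014-09-01", "2014-12-01", "2015-03-01"))
  )
  mh <- traps$microhabitat[match(surveys$trap_id, traps$trap_id)]
  lambda <- c(trees = 3, fb_shrubs = 9, nfb_shrubs = 6)[mh] *
    c(early = 1, mid = 3, late = 1)[assign_period(surveys$survey_date, frame)]
  surveys$seed_count <- rpois(nrow(surveys), lambda)
  got <- density_anova(surveys, traps, frame)

  # oracle: type-II sums of squares from explicit nested least squares
  df <- sdeland:::per_trap_densities(surveys, traps, frame)
  df$y <- log1p(df$density)
  rss <- function(form) sum(resid(lm(form, data = df))^2)
  ss_period <- rss(y ~ microhabitat) - rss(y ~ period + microhabitat)
  ss_mh <- rss(y ~ period) - rss(y ~ period + microhabitat)
  ss_int <- rss(y ~ period + microhabitat) - rss(y ~ period * microhabitat)
  expect_equal(got$sumsq[got$term == "period"], ss_period)
  expect_equal(got$sumsq[got$term == "microhabitat"], ss_mh)
  expect_equal(got$sumsq[got$term == "period:microhabitat"], ss_int)
  expect_equal(got$df[got$term == "period"], 2)
  expect_equal(got$df[got$term == "period:microhabitat"], 4)
})

test_that("identical densities give zero F statistics", {
  traps <- make_traps(frame)
  surveys <- tidyr::expand_grid(
    trap_id = traps$trap_id,
    survey_date = as.Date(c("2014-09-01", "2014-12-01", "2015-03-01"))
  )
  surveys$seed_count <- 4L
  a <- density_anova(surveys, traps, frame)
  terms <- a[a$term != "Residuals", ]
  expect_equal(terms$statistic, rep(0, nrow(terms)))
  expect_equal(terms$p_value, rep(1, nrow(terms)))
})

test_that("the ANOVA holds its nominal type-I error under the null", {
  traps <- make_traps(frame, n_per_mh = 4)
  dates <- as.Date(c("2014-09-15", "2014-12-15", "2015-03-15"))
  set.seed(7)
  rej <- replicate(1000, {
    surveys <- tidyr::expand_grid(trap_id = traps$trap_id,
                                  survey_date = dates)
    surveys$seed_count <- rpois(nrow(surveys), 20)
    a <- density_anova(surveys, traps, frame)
    a$p_value[a$term == "period"] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
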