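frame <- default_frame()

cell_tbl <- function(qt, ql, group = "European", period = "early",
                     microhabitat = "fb_shrubs") {
  q <- tibble::tibble(group = group, period = period,
                      microhabitat = microhabitat, qt = qt)
  l <- tibble::tibble(period = period, microhabitat = microhabitat,
                      ql = ql)
  sde_cells(q, unique(l))
}

test_that("effectiveness is the cell-wise quantity-quality product", {
  x <- cell_tbl(25, 0.002)
  expect_equal(x$sde, 0.05)
  expect_equal(cell_tbl(0, 0.9)$sde, 0)

  # missing quality with positive quantity is an error, never a zero
  q <- tibble::tibble(group = "g", period = "early",
                      microhabitat = "trees", qt = 3)
  l <- tibble::tibble(period = "early", microhabitat = "trees",
                      ql = NA_real_)
  expect_error(sde_cells(q, l), "early x trees")
})

test_that("group-wise effectiveness sums to density times quality per cell", {
  b <- generate_study(small_config(), 23)
  res <- run_sde_pipeline(b, frame, zero_policy = "raw")
  joined <- res$cells |>
    dplyr::group_by(period, microhabitat) |>
    dplyr::summarise(total = sum(sde), .groups = "drop") |>
    dplyr::inner_join(res$density[c("period", "microhabitat",
                                    "mean_density")],
                      by = c("period", "microhabitat")) |>
    dplyr::inner_join(res$quality[c("period", "microhabitat", "ql")],
                      by = c("period", "microhabitat"))
  expect_equal(joined$total, joined$mean_density * joined$ql,
               tolerance = 1e-12)
})

test_that("quantity-weighted aggregation reproduces the worked example", {
  cells <- tibble::tibble(
    group = "g", microhabitat = "m",
    period = c("early", "mid", "late"),
    qt = c(2, 1, 1), ql = c(0.1, 0.02, 0.01)
  )
  cells$sde <- cells$qt * cells$ql
  ov <- aggregate_overall(cells)
  expect_equal(ov$qt_total, 4)
  expect_equal(ov$ql_weighted, 0.0575)
  expect_equal(ov$sde_overall, 0.23)
  # additivity: overall equals the sum of per-period effectiveness
  expect_equal(ov$sde_overall, sum(cells$sde), tolerance = 1e-12)

  # equal quantities reduce the weighted mean to the simple mean
  eq <- cells
  eq$qt <- 1
  eq$sde <- eq$qt * eq$ql
  expect_equal(aggregate_overall(eq)$ql_weighted, mean(cells$ql))

  # a group that dispersed nothing has undefined quality, zero sde
  zero <- cells
  zero$qt <- 0
  zero$sde <- 0
  ovz <- aggregate_overall(zero)
  expect_true(is.na(ovz$ql_weighted))
  expect_equal(ovz$sde_overall, 0)
})

test_that("overall additivity holds exactly on synthetic tensors", {
  b <- generate_study(small_config(), 31)
  res <- run_sde_pipeline(b, frame)
  per_group <- res$cells |>
    dplyr::group_by(group, microhabitat) |>
    dplyr::summarise(sum_sde = sum(sde), .groups = "drop")
  ov <- dplyr::inner_join(res$overall, per_group,
                          by = c("group", "microhabitat"))
  expect_equal(ov$sde_overall, ov$sum_sde, tolerance = 1e-12)
  tot <- res$cells |>
    dplyr::group_by(period) |>
    dplyr::summarise(s = sum(sde), .groups = "drop")
  pt <- dplyr::inner_join(res$period_totals, tot, by = "period")
  expect_equal(pt$sde_total, pt$s, tolerance = 1e-12)
})

test_that("scaling quantity scales effectiveness, not weighted quality", {
  cells <- tibble::tibble(
    group = rep(c("a", "b"), each = 3), microhabitat = "m",
    period = rep(c("early", "mid", "late"), 2),
    qt = c(2, 1, 1, 4, 0, 1), ql = rep(c(0.1, 0.02, 0.01), 2)
  )
  cells$sde <- cells$qt * cells$ql
  scaled <- cells
  scaled$qt <- 3 * scaled$qt
  scaled$sde <- scaled$qt * scaled$ql
  ov1 <- aggregate_overall(cells)
  ov3 <- aggregate_overall(scaled)
  expect_equal(ov3$sde_overall, 3 * ov1$sde_overall)
  expect_equal(ov3$ql_weighted, ov1$ql_weighted)
  expect_equal(period_totals(scaled)$sde_total,
               3 * period_totals(cells)$sde_total)
})

test_that("period totals sum cells and ignore ordering", {
  cells <- tibble::tibble(
    group = "g", microhabitat = "m",
    period = c("early", "mid", "late"), qt = c(1, 0, 0),
    ql = c(0.05, 0.1, 0.1), sde = c(0.05, 0, 0)
  )
  tot <- period_totals(cells)
  expect_equal(tot$sde_total[tot$period == "early"], 0.05)
  expect_equal(sum(tot$sde_total), 0.05)
  shuffled <- period_totals(cells[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(shuffled, period),
               dplyr::arrange(tot, period))
})

test_that("contribution shares are percentages summing to one hundred", {
  ov <- tibble::tibble(
    group = c("European", "resident", "sub-Saharan"),
    microhabitat = "fb_shrubs",
    qt_total = c(100, 20, 7),
    sde_overall = c(0.049, 0.017, 0.009)
  )
  sh <- contribution_shares(ov)
  expect_equal(sh$share_sde, 100 * c(0.049, 0.017, 0.009) / 0.075,
               tolerance = 1e-12)
  expect_equal(round(sh$share_sde, 1), c(65.3, 22.7, 12.0))
  expect_equal(sum(sh$share_sde), 100)
  expect_equal(sum(sh$share_qt), 100)

  solo <- contribution_shares(ov[1, ])
  expect_equal(solo$share_sde, 100)
})

test_that("landscapes place points on their own isoclines", {
  pts <- tibble::tibble(qt = c(2, 4), ql = c(0.5, 0.25))
  ls <- sde_landscape(pts, n_isoclines = 1)
  expect_equal(unique(ls$isoclines$level), 1)
  # both points share sde = 1, hence the same isocline
  expect_equal(unique(ls$points$sde), 1)
  on_curve <- ls$isoclines$qt * ls$isoclines$ql
  expect_true(all(abs(on_curve[ls$isoclines$ql < 1] - 1) < 1e-9))

  # log spacing over [0.001, 0.1] with five levels
  pts2 <- tibble::tibble(qt = c(1, 1), ql = c(0.001, 0.1))
  ls2 <- sde_landscape(pts2, n_isoclines = 5)
  expect_equal(unique(ls2$isoclines$level), 10^seq(-3, -1, by = 0.5),
               tolerance = 1e-10)

  # all-zero input yields an empty landscape
  ls0 <- sde_landscape(tibble::tibble(qt = c(0, 0), ql = c(0.2, 0)))
  expect_equal(nrow(ls0$isoclines), 0)
  expect_error(sde_landscape(tibble::tibble(qt = -1, ql = 0.5)), "qt")

  p <- plot_landscape(ls)
  expect_s3_class(p, "ggplot")
})

test_that("effectiveness composes the six factors in any order", {
  b <- generate_study(small_config(), 41)
  res <- run_sde_pipeline(b, frame, zero_policy = "raw")
  x <- res$cells |>
    dplyr::inner_join(res$quantity, by = c("group", "period",
                                           "microhabitat", "qt")) |>
    dplyr::inner_join(res$quality, by = c("period", "microhabitat", "ql"))
  ok <- !is.na(x$sde)
  alt1 <- x$density * x$frequency * x$v * x$p * x$g * x$s
  alt2 <- (x$v * (x$density * x$frequency)) * (x$s * x$g * x$p)
  expect_equal(x$sde[ok], alt1[ok], tolerance = 1e-12)
  expect_equal(x$sde[ok], alt2[ok], tolerance = 1e-12)
})
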