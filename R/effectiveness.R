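#' Seed dispersal effectiveness per cell
#'
#' Multiplies the quantity component (group-specific seed rain density) by
#' the quality component (cumulative recruitment probability, shared by all
#' groups within a period x microhabitat cell): `sde = qt * ql`, in units of
#' recruiting seeds per square metre.
#'
#' @param quantity Output of [quantity_component()].
#' @param quality Output of [quality_table()].
#' @return A tibble with one row per group x period x microhabitat: `qt`,
#'   `ql`, `sde`.
#' @export
sde_cells <- function(quantity, quality) {
  check_columns(quantity, c("group", "period", "microhabitat", "qt"),
                "quantity")
  check_columns(quality, c("period", "microhabitat", "ql"), "quality")
  out <- dplyr::left_join(
    quantity[c("group", "period", "microhabitat", "qt")],
    quality[c("period", "microhabitat", "ql")],
    by = c("period", "microhabitat")
  )
  bad <- is.na(out$ql) & out$qt > 0
  if (any(bad)) {
    cells <- unique(out[bad, c("period", "microhabitat")])
    stop("quality undefined for cell(s) with positive quantity: ",
         paste(paste(cells$period, cells$microhabitat, sep = " x "),
               collapse = "; "),
         call. = FALSE)
  }
  out$sde <- dplyr::if_else(out$qt == 0, 0, out$qt * out$ql)
  out
}

#' Season-overall effectiveness per group and microhabitat
#'
#' Aggregates the cell tensor across periods: `qt_total` is the sum of the
#' group's quantity over periods, and the overall quality `ql_weighted` is
#' the mean of the per-period qualities weighted by that group's own
#' quantities — different fractions of a group's seed rain arrive in each
#' period, so its overall quality must weight periods accordingly. The
#' quantity-weighted mean makes the overall effectiveness exactly additive:
#' `sde_overall = qt_total * ql_weighted = sum over periods of sde`.
#' Groups that dispersed nothing in a microhabitat have undefined
#' `ql_weighted` and zero `sde_overall`.
#'
#' @param cells Output of [sde_cells()].
#' @return A tibble with one row per group x microhabitat: `qt_total`,
#'   `ql_weighted`, `sde_overall`.
#' @export
aggregate_overall <- function(cells) {
  check_columns(cells, c("group", "period", "microhabitat", "qt", "ql",
                         "sde"), "cells")
  cells |>
    dplyr::group_by(.data$group, .data$microhabitat) |>
    dplyr::summarise(
      qt_total = sum(.data$qt),
      ql_weighted = dplyr::if_else(
        sum(.data$qt) > 0,
        sum(.data$qt * .data$ql) / sum(.data$qt),
        NA_real_
      ),
      sde_overall = dplyr::if_else(sum(.data$qt) > 0,
                                   sum(.data$sde), 0),
      .groups = "drop"
    )
}

#' Total effectiveness per period
#'
#' Sums effectiveness over disperser groups and microhabitats within each
#' period — the season-wide comparison of when dispersal pays off. Undefined
#' cells are excluded with a warning, never silently zeroed.
#'
#' @param cells Output of [sde_cells()].
#' @return A tibble: `period`, `sde_total`.
#' @export
period_totals <- function(cells) {
  check_columns(cells, c("period", "sde"), "cells")
  if (anyNA(cells$sde)) {
    warning(sum(is.na(cells$sde)),
            " undefined cell(s) excluded from period totals", call. = FALSE)
  }
  cells |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(sde_total = sum(.data$sde, na.rm = TRUE),
                     .groups = "drop")
}

#' Group contribution shares within a margin
#'
#' Expresses each group's season-overall effectiveness and quantity as a
#' percentage of the margin total (by default within each microhabitat).
#' Shares within a margin sum to 100 wherever the denominator is positive.
#'
#' @param overall Output of [aggregate_overall()].
#' @param within Margin over which shares are formed: `"microhabitat"`
#'   (default, shares across groups beneath each microhabitat) or `"group"`
#'   (shares across microhabitats within each group).
#' @return A tibble with the margin columns plus `share_sde` and `share_qt`
#'   (percentages; `NA` where the margin total is zero).
#' @export
contribution_shares <- function(overall,
                                within = c("microhabitat", "group")) {
  within <- match.arg(within)
  check_columns(overall, c("group", "microhabitat", "qt_total",
                           "sde_overall"), "overall")
  pct <- function(x) {
    tot <- sum(x)
    if (tot > 0) 100 * x / tot else rep(NA_real_, length(x))
  }
  overall |>
    dplyr::group_by(.data[[within]]) |>
    dplyr::mutate(share_sde = pct(.data$sde_overall),
                  share_qt = pct(.data$qt_total)) |>
    dplyr::ungroup() |>
    dplyr::select("group", "microhabitat", "qt_total", "sde_overall",
                  "share_qt", "share_sde")
}

#' Effectiveness landscape: points and isoclines
#'
#' Lays out effectiveness as a quantity x quality scatter. Isoclines are
#' curves of constant effectiveness `qt * ql = c`; their levels are spaced
#' (geometrically by default) between the smallest and largest positive
#' effectiveness among the points, so every point lies exactly on the
#' isocline of its own value when that level is drawn.
#'
#' @param points Tibble with columns `qt` (>= 0) and `ql` (in `[0, 1]`);
#'   any further columns (group, period, microhabitat) are kept as labels.
#' @param n_isoclines Number of isocline levels (default 8).
#' @param scale `"log"` (geometric spacing, default) or `"linear"`.
#' @return An object of class `sde_landscape`: `points` (with their `sde`),
#'   `isoclines` (tibble `level`, `qt`, `ql` tracing each curve), and the
#'   axis ranges. All-zero input yields an empty landscape with no
#'   isoclines. Render with [plot_landscape()] or inspect the tables
#'   directly.
#' @export
sde_landscape <- function(points, n_isoclines = 8,
                          scale = c("log", "linear")) {
  scale <- match.arg(scale)
  check_columns(points, c("qt", "ql"), "points")
  points <- tibble::as_tibble(points)
  if (any(points$qt < 0) || any(points$ql < 0 | points$ql > 1,
                                na.rm = TRUE)) {
    stop("landscape points need qt >= 0 and ql in [0, 1]", call. = FALSE)
  }
  points$sde <- points$qt * points$ql
  pos <- points$sde[!is.na(points$sde) & points$sde > 0]
  if (!length(pos)) {
    levels <- numeric(0)
  } else if (length(unique(pos)) == 1 || n_isoclines == 1) {
    levels <- unique(range(pos))
  } else if (scale == "log") {
    levels <- exp(seq(log(min(pos)), log(max(pos)),
                      length.out = n_isoclines))
  } else {
    levels <- seq(min(pos), max(pos), length.out = n_isoclines)
  }
  qt_max <- max(points$qt, 1e-12)
  iso <- if (length(levels)) {
    dplyr::bind_rows(lapply(levels, function(lv) {
      # qt grid from where the curve enters ql = 1 out to the axis limit
      qt_grid <- exp(seq(log(max(lv, qt_max * 1e-4)), log(qt_max * 1.05),
                         length.out = 200))
      tibble::tibble(level = lv, qt = qt_grid,
                     ql = pmin(1, lv / qt_grid))
    }))
  } else {
    tibble::tibble(level = numeric(0), qt = numeric(0), ql = numeric(0))
  }
  structure(
    list(points = points, isoclines = iso,
         qt_range = c(0, qt_max * 1.05), ql_range = c(0, 1),
         scale = scale),
    class = "sde_landscape"
  )
}

#' @export
print.sde_landscape <- function(x, ...) {
  cat("<sde_landscape> ", nrow(x$points), " points, ",
      length(unique(x$isoclines$level)), " isoclines (", x$scale,
      " spacing)\n", sep = "")
  invisible(x)
}

#' Render an effectiveness landscape with ggplot2
#'
#' @param landscape An [sde_landscape()].
#' @param colour,shape Optional names of label columns in the landscape's
#'   points mapped to point colour and shape.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, colour = NULL, shape = NULL) {
  stopifnot(inherits(landscape, "sde_landscape"))
  pts <- landscape$points
  gg <- ggplot2::ggplot() +
    ggplot2::geom_line(
      data = landscape$isoclines,
      ggplot2::aes(x = .data$qt, y = .data$ql, group = .data$level),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(
        x = .data$qt, y = .data$ql,
        colour = if (!is.null(colour)) .data[[colour]] else NULL,
        shape = if (!is.null(shape)) .data[[shape]] else NULL
      ),
      size = 2.5
    ) +
    ggplot2::coord_cartesian(xlim = landscape$qt_range,
                             ylim = landscape$ql_range) +
    ggplot2::labs(
      x = expression(paste("Quantity: seed rain density (seeds/", m^2, ")")),
      y = "Quality: probability of recruitment",
      colour = colour, shape = shape
    ) +
    ggplot2::theme_minimal()
  gg
}
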