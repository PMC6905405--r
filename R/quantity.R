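#' Per-trap and cell-level seed rain densities
#'
#' Totals each trap's seed counts over the fortnightly surveys of a period,
#' divides by the trap's sampling area, and summarises traps within each
#' period x microhabitat cell. The replication unit is the trap x period
#' total (one density per trap per period), not the individual survey.
#'
#' The 95% interval is a t-interval computed on ln(x + 1)-transformed
#' per-trap densities and back-transformed, matching the transformation used
#' for the factorial test ([density_anova()]); the lower bound is clamped at
#' zero. For strongly skewed per-trap densities the back-transformed interval
#' tracks the transformed-scale mean and can sit below the arithmetic mean
#' it accompanies; at field scales the two agree closely. With a single trap,
#' or when all traps in a cell tie (e.g. all zero), the interval degenerates
#' to the mean.
#'
#' @param surveys Survey table: `trap_id`, `survey_date`, `seed_count`.
#' @param traps Trap roster: `trap_id`, `microhabitat`, optional `area_m2`
#'   overriding the frame-level trap area. Traps with no recorded seeds in a
#'   period contribute zero densities, so the roster — not the survey table —
#'   defines the replication.
#' @param frame A [study_frame()].
#' @param level Confidence level for the interval (default 0.95).
#' @return A tibble with one row per period x microhabitat:
#'   `n_traps`, `mean_density` (seeds/m^2), `ci_low`, `ci_high`, and a
#'   `per_trap` list-column of per-trap densities. Microhabitats with no
#'   traps are kept as explicit missing cells (`n_traps = 0`, `NA`
#'   densities), never silently zeroed.
#' @export
seed_rain_density <- function(surveys, traps, frame, level = 0.95) {
  d <- per_trap_densities(surveys, traps, frame)
  cells <- d |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::summarise(
      n_traps = dplyr::n(),
      mean_density = mean(.data$density),
      ci_low = density_ci(.data$density, level)[1],
      ci_high = density_ci(.data$density, level)[2],
      per_trap = list(.data$density),
      .groups = "drop"
    )
  all_cells <- frame_cells(frame, c("period", "microhabitat"))
  cells <- dplyr::left_join(all_cells, cells,
                            by = c("period", "microhabitat"))
  cells$n_traps[is.na(cells$n_traps)] <- 0L
  order_cells(cells, frame)
}

# Trap x period seed rain densities (seeds/m^2); zero-filled over the roster.
per_trap_densities <- function(surveys, traps, frame) {
  check_columns(traps, c("trap_id", "microhabitat"), "traps")
  check_columns(surveys, c("trap_id", "survey_date", "seed_count"), "surveys")
  bad_mh <- setdiff(unique(traps$microhabitat), frame$microhabitats)
  if (length(bad_mh)) {
    stop("unknown microhabitat(s) in trap roster: ",
         paste(bad_mh, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(surveys$trap_id), traps$trap_id)
  if (length(unknown)) {
    stop("survey records reference unrosterd trap(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (any(surveys$seed_count < 0)) {
    stop("seed_count must be non-negative", call. = FALSE)
  }
  traps <- tibble::as_tibble(traps)
  if (!"area_m2" %in% names(traps)) traps$area_m2 <- frame$trap_area
  traps$area_m2[is.na(traps$area_m2)] <- frame$trap_area
  if (any(traps$area_m2 <= 0)) stop("trap areas must be positive", call. = FALSE)

  surveys <- tibble::as_tibble(surveys)
  surveys$period <- assign_period(surveys$survey_date, frame)
  totals <- surveys |>
    dplyr::group_by(.data$trap_id, .data$period) |>
    dplyr::summarise(total_seeds = sum(.data$seed_count), .groups = "drop")

  grid <- tidyr::expand_grid(
    trap_id = traps$trap_id,
    period = frame$periods$period
  )
  grid |>
    dplyr::left_join(totals, by = c("trap_id", "period")) |>
    dplyr::mutate(total_seeds = dplyr::coalesce(.data$total_seeds, 0L)) |>
    dplyr::left_join(traps[c("trap_id", "microhabitat", "area_m2")],
                     by = "trap_id") |>
    dplyr::mutate(density = .data$total_seeds / .data$area_m2)
}

# Back-transformed t-interval on ln(x+1) densities; degenerate when there is
# no between-trap variance to estimate.
density_ci <- function(x, level) {
  n <- length(x)
  lx <- log1p(x)
  if (n < 2 || stats::sd(lx) == 0) return(c(mean(x), mean(x)))
  se <- stats::sd(lx) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  ci <- expm1(mean(lx) + c(-1, 1) * tq * se)
  c(max(0, ci[1]), ci[2])
}

#' Disperser-group frequencies from barcoded seed samples
#'
#' Counts identified seeds per disperser group within each period x
#' microhabitat cell and converts them to relative frequencies. Counting is
#' per seed: a dropping holding three seeds contributes three. Seeds whose
#' disperser could not be identified ([SPECIES_UNIDENTIFIED]) are excluded
#' and the remaining frequencies renormalised to one, i.e. frequencies are
#' relative contributions among identified seeds.
#'
#' @param samples Sample table: `sample_id`, `microhabitat`, `sample_date`,
#'   `n_seeds`, `species_code`.
#' @param frame A [study_frame()].
#' @return A tibble with one row per group x period x microhabitat:
#'   `n_seeds_identified` (that group's seeds) and `frequency`. Cells with no
#'   identified seed have `NA` frequencies (undefined, not zero).
#' @export
group_frequencies <- function(samples, frame) {
  check_columns(samples,
                c("sample_id", "microhabitat", "sample_date", "n_seeds"),
                "samples")
  if (!"species_code" %in% names(samples)) {
    stop("samples table is missing column(s): species_code", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  if (any(samples$n_seeds < 1)) {
    stop("every sample must hold at least one seed", call. = FALSE)
  }
  bad_mh <- setdiff(unique(samples$microhabitat), frame$microhabitats)
  if (length(bad_mh)) {
    stop("unknown microhabitat(s) in samples: ",
         paste(bad_mh, collapse = ", "), call. = FALSE)
  }
  known <- names(frame$species_to_group)
  bad_sp <- setdiff(unique(samples$species_code),
                    c(known, SPECIES_UNIDENTIFIED))
  if (length(bad_sp)) {
    stop("unknown species code(s): ", paste(bad_sp, collapse = ", "),
         "; frame codes are: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  samples$period <- assign_period(samples$sample_date, frame)
  identified <- samples[samples$species_code != SPECIES_UNIDENTIFIED, ]
  identified$group <- unname(frame$species_to_group[identified$species_code])

  counts <- identified |>
    dplyr::group_by(.data$group, .data$period, .data$microhabitat) |>
    dplyr::summarise(n_seeds_identified = sum(.data$n_seeds),
                     .groups = "drop")
  out <- frame_cells(frame) |>
    dplyr::left_join(counts, by = c("group", "period", "microhabitat")) |>
    dplyr::mutate(
      n_seeds_identified = dplyr::coalesce(.data$n_seeds_identified, 0L)
    ) |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::mutate(
      cell_total = sum(.data$n_seeds_identified),
      frequency = dplyr::if_else(
        .data$cell_total > 0,
        .data$n_seeds_identified / .data$cell_total,
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"cell_total")
  order_cells(out, frame)
}

#' Quantity component of seed dispersal effectiveness
#'
#' Combines cell-level seed rain densities with disperser-group frequencies:
#' `qt = mean_density * frequency`, the seed rain density (seeds/m^2)
#' attributable to each group in each period x microhabitat cell. Group
#' frequencies estimated on the barcoded subset of trapped seeds are applied
#' to the full density, which assumes the subset is representative within
#' each cell. By construction the group-wise `qt` values in a cell sum back
#' to its total density.
#'
#' @param density Output of [seed_rain_density()].
#' @param frequencies Output of [group_frequencies()].
#' @return A tibble with one row per group x period x microhabitat: `qt`
#'   plus the `density` and `frequency` factors it multiplies.
#' @export
quantity_component <- function(density, frequencies) {
  check_columns(density, c("period", "microhabitat", "mean_density"),
                "density")
  check_columns(frequencies,
                c("group", "period", "microhabitat", "frequency"),
                "frequencies")
  n_traps <- if ("n_traps" %in% names(density)) density$n_traps else 1
  missing_cells <- density[n_traps == 0 | is.na(density$mean_density), ]
  if (nrow(missing_cells)) {
    warning("dropping ", nrow(missing_cells),
            " cell(s) with no traps from the quantity component",
            call. = FALSE)
    density <- dplyr::anti_join(
      density, missing_cells[c("period", "microhabitat")],
      by = c("period", "microhabitat")
    )
  }
  out <- dplyr::inner_join(
    frequencies,
    density[c("period", "microhabitat", "mean_density")],
    by = c("period", "microhabitat")
  )
  undefined <- is.na(out$frequency) & out$mean_density > 0
  if (any(undefined)) {
    bad <- unique(out[undefined, c("period", "microhabitat")])
    stop("positive seed rain density but no identified seeds in cell(s): ",
         paste(paste(bad$period, bad$microhabitat, sep = " x "),
               collapse = "; "),
         call. = FALSE)
  }
  out$qt <- dplyr::if_else(out$mean_density == 0, 0,
                           out$mean_density * out$frequency)
  dplyr::select(out, "group", "period", "microhabitat",
                density = "mean_density", "frequency", "qt")
}

#' Factorial test on seed rain densities
#'
#' Two-way fixed-effects analysis of variance on ln(x + 1)-transformed
#' trap x period densities, with period, microhabitat and their interaction
#' as factors, type-II sums of squares, and p-values from the F
#' distribution. The interaction term asks whether period differences are
#' consistent across microhabitats; it is dropped (with a warning) when some
#' design cell has no trap.
#'
#' @inheritParams seed_rain_density
#' @return A tibble with one row per term: `term`, `sumsq`, `df`,
#'   `statistic` (F), `p_value` (`NA` for the residual row).
#' @export
density_anova <- function(surveys, traps, frame) {
  d <- per_trap_densities(surveys, traps, frame)
  d$log_density <- log1p(d$density)
  d$period <- factor(d$period, levels = frame$periods$period)
  d$microhabitat <- factor(d$microhabitat, levels = frame$microhabitats)
  filled <- table(d$period, d$microhabitat)
  form <- log_density ~ period * microhabitat
  if (any(filled == 0)) {
    warning("empty period x microhabitat cell(s): interaction term dropped",
            call. = FALSE)
    form <- log_density ~ period + microhabitat
  }
  if (stats::sd(d$log_density) == 0) {
    # no variation at all: every term explains nothing
    p_df <- nlevels(droplevels(d$period)) - 1
    m_df <- nlevels(droplevels(d$microhabitat)) - 1
    with_int <- length(form) == 3 && identical(form[[3]][[1]], as.name("*"))
    terms <- c("period", "microhabitat",
               if (with_int) "period:microhabitat")
    dfs <- c(p_df, m_df, if (with_int) p_df * m_df)
    return(tibble::tibble(
      term = c(terms, "Residuals"), sumsq = 0,
      df = c(dfs, nrow(d) - 1 - sum(dfs)),
      statistic = c(rep(0, length(terms)), NA_real_),
      p_value = c(rep(1, length(terms)), NA_real_)
    ))
  }
  fit <- stats::lm(form, data = d)
  aov_tab <- car::Anova(fit, type = 2)
  out <- tibble::tibble(
    term = rownames(aov_tab),
    sumsq = aov_tab[["Sum Sq"]],
    df = aov_tab[["Df"]],
    statistic = aov_tab[["F value"]],
    p_value = aov_tab[["Pr(>F)"]]
  )
  # a term explaining exactly nothing has F = 0 even when the residual
  # variance is also zero (all densities identical)
  degenerate <- !is.na(out$sumsq) & out$sumsq == 0 &
    !is.finite(out$statistic) & out$term != "Residuals"
  out$statistic[degenerate] <- 0
  out$p_value[degenerate] <- 1
  out
}
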