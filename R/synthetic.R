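#' Configuration of the synthetic study generator
#'
#' Describes the data-generating process the analysis assumes: Poisson seed
#' deposition per trap and survey, a period-structured disperser assemblage,
#' seed-level subsampling for barcoding with an identification-failure rate,
#' Bernoulli viability declining across periods, near-total post-dispersal
#' predation, and period/microhabitat-dependent germination and seedling
#' survival with station-level losses. Defaults reproduce the scale and
#' orderings of the lentisc field study (about 1,030 trapped seeds over 37
#' traps and 18 fortnightly surveys; deposition peaking threefold in the
#' mid-period; trees receiving 2--3 times fewer seeds than shrubs; viability
#' 63/35/5% across periods; escape 0.67%; germination averaging ~0.30 and
#' lowest mid-period; survival averaging ~0.28 and highest beneath
#' fruit-bearing shrubs; station losses 13% and 25%). Per-cell deposition
#' rates and mixtures are illustrative calibrations, not reproduction
#' targets.
#'
#' @param frame A [study_frame()].
#' @param deposition Matrix of expected seeds per trap per survey,
#'   periods x microhabitats (dimnames required).
#' @param species_abundance Tibble `species`, `period`, `abundance`:
#'   within-period relative abundances of the species present (a species
#'   absent from a period simply has no row). Abundances are normalised
#'   within period.
#' @param n_traps Named integer vector: traps per microhabitat.
#' @param surveys_per_period Fortnightly surveys per 3-month period
#'   (default 6).
#' @param multiplicity Probabilities that a dropping holds 1, 2 or 3 seeds.
#' @param id_failure_rate Probability a barcoded sample fails to amplify.
#' @param subsample_rate Probability a dropping is collected for barcoding.
#' @param viability Named per-period viability probabilities.
#' @param escape,germination,survival Periods x microhabitats probability
#'   matrices for the three post-dispersal transitions.
#' @param germ_week_mean Named per-period mean weeks to germination;
#'   `germ_week_sd` its spread.
#' @param germ_week_sd Standard deviation of germination week.
#' @param station_loss Probabilities `c(germination, survival)` that a
#'   sowing station is lost before germination scoring and before the end of
#'   the survival census. Loss before germination implies loss for survival,
#'   so the survival entry is the total survival-stage loss.
#' @param depots_per_cell,seeds_per_depot Seed-predation design.
#' @param stations_per_cell,seeds_per_station Sowing design.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    frame = default_frame(),
    deposition = default_deposition(frame),
    species_abundance = default_species_abundance(),
    n_traps = c(trees = 12L, fb_shrubs = 13L, nfb_shrubs = 12L),
    surveys_per_period = 6L,
    multiplicity = c(0.97, 0.02, 0.01),
    id_failure_rate = 0.047,
    subsample_rate = 0.44,
    viability = c(early = 0.63, mid = 0.35, late = 0.05),
    escape = default_cell_matrix(frame, 0.0067),
    germination = default_germination(frame),
    survival = default_survival(frame),
    germ_week_mean = c(early = 8.1, mid = 11.3, late = 6.9),
    germ_week_sd = 2,
    station_loss = c(germination = 0.13, survival = 0.25),
    depots_per_cell = 8L, seeds_per_depot = 10L,
    stations_per_cell = 8L, seeds_per_station = 9L) {
  stopifnot(inherits(frame, "study_frame"))
  periods <- frame$periods$period
  check_cell_matrix <- function(m, what, upper = Inf) {
    if (!all(periods %in% rownames(m)) ||
        !all(frame$microhabitats %in% colnames(m))) {
      stop(what, " matrix needs periods as rows and microhabitats as ",
           "columns", call. = FALSE)
    }
    if (any(m < 0) || any(m > upper)) {
      stop(what, " values out of range", call. = FALSE)
    }
    m[periods, frame$microhabitats, drop = FALSE]
  }
  deposition <- check_cell_matrix(deposition, "deposition")
  escape <- check_cell_matrix(escape, "escape", 1)
  germination <- check_cell_matrix(germination, "germination", 1)
  survival <- check_cell_matrix(survival, "survival", 1)
  stopifnot(
    all(names(n_traps) %in% frame$microhabitats),
    all(n_traps >= 1),
    surveys_per_period >= 1,
    length(multiplicity) == 3, all(multiplicity >= 0),
    abs(sum(multiplicity) - 1) < 1e-8,
    id_failure_rate >= 0, id_failure_rate <= 1,
    subsample_rate >= 0, subsample_rate <= 1,
    all(periods %in% names(viability)),
    all(viability >= 0 & viability <= 1),
    all(periods %in% names(germ_week_mean)), germ_week_sd >= 0,
    station_loss[["germination"]] >= 0,
    station_loss[["survival"]] >= station_loss[["germination"]],
    station_loss[["survival"]] <= 1,
    depots_per_cell >= 1, seeds_per_depot >= 1,
    stations_per_cell >= 1, seeds_per_station >= 1
  )
  species_abundance <- tibble::as_tibble(species_abundance)
  check_columns(species_abundance, c("species", "period", "abundance"),
                "species_abundance")
  bad <- setdiff(species_abundance$species, names(frame$species_to_group))
  if (length(bad)) {
    stop("species_abundance lists species missing from the frame: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(periods[rowSums(deposition) > 0],
                   unique(species_abundance$period))
  if (length(empty)) {
    stop("no species present in period(s) with positive deposition: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      frame = frame, deposition = deposition,
      species_abundance = species_abundance,
      n_traps = n_traps[frame$microhabitats],
      surveys_per_period = as.integer(surveys_per_period),
      multiplicity = multiplicity,
      id_failure_rate = id_failure_rate, subsample_rate = subsample_rate,
      viability = viability[periods], escape = escape,
      germination = germination, survival = survival,
      germ_week_mean = germ_week_mean[periods],
      germ_week_sd = germ_week_sd,
      station_loss = station_loss,
      depots_per_cell = as.integer(depots_per_cell),
      seeds_per_depot = as.integer(seeds_per_depot),
      stations_per_cell = as.integer(stations_per_cell),
      seeds_per_station = as.integer(seeds_per_station)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  exp_seeds <- sum(t(x$deposition) * as.numeric(x$n_traps)) *
    x$surveys_per_period
  cat("<generator_config>\n")
  cat("  traps:", sum(x$n_traps), "| surveys/period:",
      x$surveys_per_period, "| expected seeds:", round(exp_seeds), "\n")
  cat("  subsample:", x$subsample_rate, "| id failure:",
      x$id_failure_rate, "\n")
  cat("  depots:", x$depots_per_cell, "x", x$seeds_per_depot,
      "seeds/cell | stations:", x$stations_per_cell, "x",
      x$seeds_per_station, "seeds/cell\n")
  invisible(x)
}

# Period x microhabitat matrix filled with a constant.
default_cell_matrix <- function(frame, value) {
  matrix(value, nrow = nrow(frame$periods),
         ncol = length(frame$microhabitats),
         dimnames = list(frame$periods$period, frame$microhabitats))
}

# Deposition calibrated to the study scale: ~1,030 seeds in total, a
# threefold mid-period peak, trees 2.5x below shrubs.
default_deposition <- function(frame = default_frame()) {
  m <- default_cell_matrix(frame, 0)
  m["early", ] <- c(0.46, 1.15, 1.15)
  m["mid", ] <- c(1.38, 3.46, 3.46)
  m["late", ] <- c(0.46, 1.15, 1.15)
  m
}

# Period-structured assemblage: one resident present year-round, seven
# sub-Saharan migrants transient in the early period, three European
# migrants dominating the mid and late periods.
default_species_abundance <- function() {
  tibble::tribble(
    ~species, ~period, ~abundance,
    "Sm", "early", 0.30,
    "Fh", "early", 0.15, "Lm", "early", 0.06, "Ms", "early", 0.04,
    "Pp", "early", 0.03, "Sb", "early", 0.02, "Sc", "early", 0.02,
    "Sh", "early", 0.01,
    "Er", "early", 0.15, "Sa", "early", 0.15, "Tp", "early", 0.07,
    "Sm", "mid", 0.10,
    "Er", "mid", 0.38, "Sa", "mid", 0.40, "Tp", "mid", 0.12,
    "Sm", "late", 0.08,
    "Er", "late", 0.38, "Sa", "late", 0.42, "Tp", "late", 0.12
  )
}

default_germination <- function(frame = default_frame()) {
  m <- default_cell_matrix(frame, 0)
  m["early", ] <- c(0.40, 0.48, 0.40)
  m["mid", ] <- c(0.14, 0.18, 0.14)
  m["late", ] <- c(0.36, 0.42, 0.36)
  m
}

default_survival <- function(frame = default_frame()) {
  m <- default_cell_matrix(frame, 0)
  m["early", ] <- c(0.15, 0.45, 0.20)
  m["mid", ] <- c(0.20, 0.50, 0.30)
  m["late", ] <- c(0.10, 0.40, 0.15)
  m
}

#' The study-scale generator configuration
#'
#' [generator_config()] with all defaults: the configuration that emulates
#' the field study's design and reported rates.
#'
#' @return A `generator_config`.
#' @export
paper_like_config <- function() generator_config()

# Partition m seeds of one species in one trap x survey into droppings whose
# sizes follow the multiplicity distribution (last dropping truncated).
partition_droppings <- function(m, multiplicity) {
  sizes <- integer(0)
  while (sum(sizes) < m) {
    draw <- sample.int(3L, size = max(1L, ceiling((m - sum(sizes)) / 2)),
                       replace = TRUE, prob = multiplicity)
    sizes <- c(sizes, draw)
  }
  excess <- sum(sizes) - m
  if (excess > 0) {
    k <- length(sizes)
    sizes[k] <- sizes[k] - excess
    if (sizes[k] == 0L) sizes <- sizes[-k]
  }
  sizes
}

#' Generate a complete synthetic study dataset
#'
#' Draws a full dataset bundle — trap roster, fortnightly survey counts,
#' barcoded seed samples with viability flags, seed depots and sowing
#' stations — from a [generator_config()], together with its ground truth.
#' One RNG stream is used with a fixed draw order (survey counts, species
#' assignments, dropping multiplicities, barcoding and identification,
#' viability, depots, stations), so a given `config` and `seed` yield
#' byte-identical bundles.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `study_bundle`: tibbles `traps`, `surveys`,
#'   `samples`, `depots`, `sowing`, and `truth` — the configured parameter
#'   values per cell ([truth_tensor()]) plus `f_realised`, the realised
#'   disperser-group frequencies among all trapped seeds.
#' @export
generate_study <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  frame <- config$frame
  periods <- frame$periods$period

  # trap roster
  traps <- tibble::tibble(
    trap_id = sprintf("T%02d", seq_len(sum(config$n_traps))),
    microhabitat = rep(frame$microhabitats, config$n_traps),
    area_m2 = frame$trap_area
  )

  # fortnightly survey dates within each period
  dates <- lapply(seq_along(periods), function(i) {
    frame$periods$start[i] + 10 + 14 * (seq_len(config$surveys_per_period) - 1)
  })
  survey_dates <- tibble::tibble(
    period = rep(periods, each = config$surveys_per_period),
    survey_date = as.Date(unlist(dates), origin = "1970-01-01")
  )

  # 1) survey counts: Poisson deposition per trap x survey
  surveys <- tidyr::expand_grid(traps[c("trap_id", "microhabitat")],
                                survey_dates)
  lambda <- config$deposition[cbind(surveys$period, surveys$microhabitat)]
  surveys$seed_count <- stats::rpois(nrow(surveys), lambda)

  # 2) species assignment per trapped seed, by period-specific abundances
  seeds <- surveys[rep(seq_len(nrow(surveys)), surveys$seed_count),
                   c("trap_id", "microhabitat", "period", "survey_date")]
  seeds$species <- NA_character_
  for (p in periods) {
    idx <- which(seeds$period == p)
    if (!length(idx)) next
    pool <- config$species_abundance[config$species_abundance$period == p, ]
    seeds$species[idx] <- sample(pool$species, length(idx), replace = TRUE,
                                 prob = pool$abundance)
  }

  # 3) seeds of one species in one trap x survey aggregate into droppings
  if (nrow(seeds)) {
    key <- paste(seeds$trap_id, seeds$survey_date, seeds$species, sep = "\r")
    grp <- split(seq_len(nrow(seeds)), factor(key, levels = unique(key)))
    dropping_id <- integer(nrow(seeds))
    next_id <- 1L
    for (ix in grp) {
      sizes <- partition_droppings(length(ix), config$multiplicity)
      dropping_id[ix] <- next_id + rep(seq_along(sizes), sizes) - 1L
      next_id <- next_id + length(sizes)
    }
    seeds$dropping <- dropping_id
  } else {
    seeds$dropping <- integer(0)
  }

  droppings <- seeds |>
    dplyr::group_by(.data$dropping) |>
    dplyr::summarise(
      trap_id = .data$trap_id[1], microhabitat = .data$microhabitat[1],
      period = .data$period[1], sample_date = .data$survey_date[1],
      species = .data$species[1], n_seeds = dplyr::n(), .groups = "drop"
    )

  # 4) barcoding: droppings are collected whole, then identified or not
  if (nrow(droppings)) {
    collected <- stats::runif(nrow(droppings)) < config$subsample_rate
    samples <- droppings[collected, ]
    identified <- stats::runif(nrow(samples)) >= config$id_failure_rate
    samples$species_code <- ifelse(identified, samples$species,
                                   SPECIES_UNIDENTIFIED)
    # 5) flotation outcome of every sampled seed
    v <- config$viability[samples$period]
    samples$viable_flags <- vapply(seq_len(nrow(samples)), function(i) {
      sink <- stats::runif(samples$n_seeds[i]) < v[i]
      paste(ifelse(sink, "sink", "float"), collapse = ";")
    }, character(1))
    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(nrow(samples))),
      trap_id = samples$trap_id, microhabitat = samples$microhabitat,
      sample_date = samples$sample_date, n_seeds = samples$n_seeds,
      species_code = samples$species_code,
      viable_flags = samples$viable_flags
    )
  } else {
    samples <- tibble::tibble(
      sample_id = character(0), trap_id = character(0),
      microhabitat = character(0), sample_date = as.Date(character(0)),
      n_seeds = integer(0), species_code = character(0),
      viable_flags = character(0)
    )
  }

  # 6) seed depots: binomial escape fates per depot
  depot_cells <- tidyr::expand_grid(
    period = periods, microhabitat = frame$microhabitats,
    rep = seq_len(config$depots_per_cell)
  )
  depots <- tibble::tibble(
    depot_id = sprintf("D%03d", seq_len(nrow(depot_cells))),
    period = depot_cells$period, microhabitat = depot_cells$microhabitat,
    n_seeds = config$seeds_per_depot,
    n_surviving = stats::rbinom(
      nrow(depot_cells), config$seeds_per_depot,
      config$escape[cbind(depot_cells$period, depot_cells$microhabitat)]
    )
  )

  # 7) sowing stations: germination, week at emergence, survival, losses
  station_cells <- tidyr::expand_grid(
    period = periods, microhabitat = frame$microhabitats,
    rep = seq_len(config$stations_per_cell)
  )
  station_cells$station_id <- sprintf("W%03d", seq_len(nrow(station_cells)))
  sowing <- station_cells[rep(seq_len(nrow(station_cells)),
                              each = config$seeds_per_station), ]
  sowing$seed_index <- rep(seq_len(config$seeds_per_station),
                           nrow(station_cells))
  g <- config$germination[cbind(sowing$period, sowing$microhabitat)]
  s <- config$survival[cbind(sowing$period, sowing$microhabitat)]
  germinated <- stats::runif(nrow(sowing)) < g
  week <- pmax(1, round(stats::rnorm(
    nrow(sowing), config$germ_week_mean[sowing$period], config$germ_week_sd
  )))
  survived <- as.integer(stats::runif(nrow(sowing)) < s)
  sowing$germination_week <- ifelse(germinated, week, NA_integer_)
  sowing$survived <- ifelse(germinated, survived, NA_integer_)

  loss_g <- config$station_loss[["germination"]]
  loss_s <- config$station_loss[["survival"]]
  extra <- if (loss_g < 1) (loss_s - loss_g) / (1 - loss_g) else 0
  lost_germ <- stats::runif(nrow(station_cells)) < loss_g
  lost_surv <- lost_germ | (stats::runif(nrow(station_cells)) < extra)
  station_cells$lost_germ <- as.integer(lost_germ)
  station_cells$lost_surv <- as.integer(lost_surv)
  sowing <- dplyr::left_join(
    sowing, station_cells[c("station_id", "lost_germ", "lost_surv")],
    by = "station_id"
  )
  # a station destroyed before germination scoring yields no observations
  blank <- sowing$lost_germ == 1
  sowing$germination_week[blank] <- NA_integer_
  sowing$survived[blank] <- NA_integer_
  sowing$survived[sowing$lost_surv == 1] <- NA_integer_
  sowing <- dplyr::select(sowing, "station_id", "period", "microhabitat",
                          "seed_index", "germination_week", "survived",
                          "lost_germ", "lost_surv")

  truth <- truth_tensor(config)
  truth$f_realised <- realised_frequencies(seeds, frame)

  structure(
    list(traps = traps, surveys = surveys[
      c("trap_id", "survey_date", "seed_count")
    ], samples = samples, depots = depots, sowing = sowing, truth = truth),
    class = "study_bundle"
  )
}

# Group frequencies among all trapped seeds (pre-subsampling), per cell.
realised_frequencies <- function(seeds, frame) {
  if (!nrow(seeds)) {
    out <- frame_cells(frame)
    out$frequency <- NA_real_
    return(out)
  }
  seeds$group <- unname(frame$species_to_group[seeds$species])
  counts <- seeds |>
    dplyr::group_by(.data$group, .data$period, .data$microhabitat) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  frame_cells(frame) |>
    dplyr::left_join(counts, by = c("group", "period", "microhabitat")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(frequency = ifelse(is.nan(.data$frequency), NA_real_,
                                     .data$frequency)) |>
    dplyr::select(-"n")
}

#' Ground-truth effectiveness tensor of a generator configuration
#'
#' Computes analytically, from the configured parameters, the quantities the
#' pipeline estimates: expected seed rain density per cell
#' (`d = deposition * surveys / trap_area`), the configured disperser-group
#' mixture per period, the four quality subcomponents and their raw product,
#' and the implied quantity, quality and effectiveness tensor.
#'
#' @param config A [generator_config()].
#' @return A list of tibbles: `density` (per period x microhabitat),
#'   `frequencies` (per group x period; shared across microhabitats),
#'   `quality` (per cell, raw probabilities), and `sde` (per group x period
#'   x microhabitat with `qt`, `ql`, `sde`).
#' @export
truth_tensor <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  frame <- config$frame
  cells <- frame_cells(frame, c("period", "microhabitat"))
  cells$d <- config$deposition[cbind(cells$period, cells$microhabitat)] *
    config$surveys_per_period / frame$trap_area

  ab <- config$species_abundance
  ab$group <- unname(frame$species_to_group[ab$species])
  freq <- ab |>
    dplyr::group_by(.data$period, .data$group) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$period) |>
    dplyr::mutate(frequency = .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup()
  freq <- tidyr::expand_grid(group = frame$groups,
                             period = frame$periods$period) |>
    dplyr::left_join(freq[c("period", "group", "frequency")],
                     by = c("period", "group")) |>
    dplyr::mutate(frequency = dplyr::coalesce(.data$frequency, 0))

  quality <- cells
  quality$v <- unname(config$viability[quality$period])
  quality$p <- config$escape[cbind(quality$period, quality$microhabitat)]
  quality$g <- config$germination[cbind(quality$period,
                                        quality$microhabitat)]
  quality$s <- config$survival[cbind(quality$period, quality$microhabitat)]
  quality$ql <- quality$v * quality$p * quality$g * quality$s
  quality$d <- NULL

  sde <- frame_cells(frame) |>
    dplyr::left_join(cells, by = c("period", "microhabitat")) |>
    dplyr::left_join(freq, by = c("group", "period")) |>
    dplyr::left_join(quality[c("period", "microhabitat", "ql")],
                     by = c("period", "microhabitat")) |>
    dplyr::mutate(qt = .data$d * .data$frequency,
                  sde = .data$qt * .data$ql) |>
    dplyr::select("group", "period", "microhabitat", "qt", "ql", "sde")

  list(density = cells, frequencies = freq, quality = quality, sde = sde)
}
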