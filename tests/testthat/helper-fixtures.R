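# Small in-code fixtures shared across test files.

# A reduced generator configuration for fast property tests: same frame and
# rate structure as the study-scale defaults, fewer experimental units, and
# exhaustive barcoding so every non-empty cell has defined frequencies.
small_config <- function(...) {
  defaults <- list(
    n_traps = c(trees = 3L, fb_shrubs = 3L, nfb_shrubs = 3L),
    depots_per_cell = 3L, stations_per_cell = 6L,
    subsample_rate = 1, id_failure_rate = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# Minimal trap roster: n traps per microhabitat of the frame.
make_traps <- function(frame, n_per_mh = 2) {
  tibble::tibble(
    trap_id = sprintf("T%02d", seq_len(n_per_mh * length(frame$microhabitats))),
    microhabitat = rep(frame$microhabitats, each = n_per_mh)
  )
}

# Survey rows for one trap: one record per given date.
make_surveys <- function(trap_id, dates, counts) {
  tibble::tibble(trap_id = trap_id, survey_date = as.Date(dates),
                 seed_count = counts)
}

# Barcode sample rows with sensible defaults.
make_samples <- function(species, n_seeds = 1, date = "2014-09-15",
                         microhabitat = "fb_shrubs",
                         viable = NULL) {
  k <- length(species)
  n_seeds <- rep_len(n_seeds, k)
  if (is.null(viable)) {
    viable <- vapply(n_seeds, function(n) {
      paste(rep("untested", n), collapse = ";")
    }, character(1))
  }
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(k)),
    trap_id = "T01",
    microhabitat = rep_len(microhabitat, k),
    sample_date = as.Date(rep_len(date, k)),
    n_seeds = n_seeds,
    species_code = species,
    viable_flags = viable
  )
}

# One sowing station expanded to per-seed rows.
make_station <- function(station_id, period, microhabitat,
                         germ_weeks = rep(NA, 9), survived = rep(NA, 9),
                         lost_germ = 0, lost_surv = 0) {
  tibble::tibble(
    station_id = station_id, period = period, microhabitat = microhabitat,
    seed_index = seq_along(germ_weeks),
    germination_week = as.numeric(germ_weeks),
    survived = as.numeric(survived),
    lost_germ = lost_germ, lost_surv = lost_surv
  )
}
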