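#' Read and validate the study tables
#'
#' Reads the five delimited tables (comma-separated, UTF-8, ISO-8601 dates)
#' the pipeline consumes and enforces the record invariants, reporting every
#' offending row with its line number before stopping. A column-mapping
#' layer adapts externally deposited tables whose headers differ from the
#' canonical schemas without editing the files.
#'
#' Canonical schemas: `traps(trap_id, microhabitat[, area_m2])`,
#' `surveys(trap_id, survey_date, seed_count)`,
#' `samples(sample_id, trap_id, microhabitat, sample_date, n_seeds,
#' species_code, viable_flags)`,
#' `depots(depot_id, period, microhabitat, n_seeds, n_surviving)`,
#' `sowing(station_id, period, microhabitat, seed_index, germination_week,
#' survived, lost_germ, lost_surv)`.
#'
#' @param paths Named list of file paths: `traps`, `surveys`, `samples`,
#'   `depots`, `sowing` (any subset).
#' @param frame A [study_frame()] used to validate labels and dates.
#' @param mapping Optional column mapping: a named list per table of
#'   `canonical_name = "name_in_file"` pairs, or the path of a YAML file
#'   holding the same structure.
#' @return A list of validated tibbles (class `study_bundle`), keyed like
#'   `paths`.
#' @export
read_study_tables <- function(paths, frame, mapping = NULL) {
  stopifnot(inherits(frame, "study_frame"))
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- yaml::read_yaml(mapping)
  }
  known <- c("traps", "surveys", "samples", "depots", "sowing")
  bad <- setdiff(names(paths), known)
  if (length(bad)) {
    stop("unknown table(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bundle <- list()
  for (tb in intersect(known, names(paths))) {
    if (!file.exists(paths[[tb]])) {
      stop(tb, " table not found: ", paths[[tb]], call. = FALSE)
    }
    df <- readr::read_csv(paths[[tb]], show_col_types = FALSE,
                          progress = FALSE)
    map <- mapping[[tb]]
    if (!is.null(map)) {
      map <- unlist(map)
      found <- map[map %in% names(df)]
      names(df)[match(found, names(df))] <- names(found)
    }
    bundle[[tb]] <- df
  }
  validate_study_tables(bundle, frame)
  structure(bundle, class = "study_bundle")
}

# Row-numbered validation of every table present in the bundle; collects
# all problems before stopping so a bad file is reported once, completely.
validate_study_tables <- function(bundle, frame) {
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))
  rows <- function(i) paste(utils::head(i, 5), collapse = ", ")
  season <- range(frame$periods$start, frame$periods$end)
  check_dates <- function(x, what) {
    d <- as.Date(as.character(x), format = "%Y-%m-%d")
    bad <- which(is.na(d))
    if (length(bad)) {
      note(what, ": unparseable date(s) at row(s) ", rows(bad))
    }
    out <- which(!is.na(d) & (d < season[1] | d > season[2]))
    if (length(out)) {
      note(what, ": date(s) outside the study season at row(s) ", rows(out))
    }
    d
  }

  if (!is.null(bundle$traps)) {
    check_columns(bundle$traps, c("trap_id", "microhabitat"), "traps")
    bad <- which(!bundle$traps$microhabitat %in% frame$microhabitats)
    if (length(bad)) {
      note("traps: unknown microhabitat at row(s) ", rows(bad))
    }
  }
  if (!is.null(bundle$surveys)) {
    check_columns(bundle$surveys, c("trap_id", "survey_date", "seed_count"),
                  "surveys")
    check_dates(bundle$surveys$survey_date, "surveys")
    bad <- which(bundle$surveys$seed_count < 0)
    if (length(bad)) {
      note("surveys: negative seed_count at row(s) ", rows(bad))
    }
  }
  if (!is.null(bundle$samples)) {
    check_columns(bundle$samples,
                  c("sample_id", "microhabitat", "sample_date", "n_seeds",
                    "species_code"), "samples")
    check_dates(bundle$samples$sample_date, "samples")
    bad <- which(bundle$samples$n_seeds < 1)
    if (length(bad)) note("samples: n_seeds < 1 at row(s) ", rows(bad))
    codes <- c(names(frame$species_to_group), SPECIES_UNIDENTIFIED)
    bad <- which(!bundle$samples$species_code %in% codes)
    if (length(bad)) {
      note("samples: unknown species code at row(s) ", rows(bad),
           " (frame codes: ", paste(names(frame$species_to_group),
                                    collapse = ", "), ")")
    }
  }
  if (!is.null(bundle$depots)) {
    check_columns(bundle$depots,
                  c("depot_id", "period", "microhabitat", "n_seeds",
                    "n_surviving"), "depots")
    bad <- which(bundle$depots$n_surviving > bundle$depots$n_seeds |
                   bundle$depots$n_surviving < 0)
    if (length(bad)) {
      note("depots: n_surviving outside [0, n_seeds] for depot(s) ",
           paste(utils::head(bundle$depots$depot_id[bad], 5),
                 collapse = ", "))
    }
  }
  if (!is.null(bundle$sowing)) {
    res <- tryCatch(validate_sowing(bundle$sowing), error = function(e) e)
    if (inherits(res, "error")) note(conditionMessage(res))
  }
  if (length(errs)) {
    stop("invalid study tables:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(bundle)
}

#' Write a study bundle as delimited tables
#'
#' Writes each table of the bundle as a UTF-8 comma-separated file with
#' ISO-8601 dates, in the canonical schemas [read_study_tables()] reads, so
#' write and read round-trip losslessly.
#'
#' @param bundle A `study_bundle` (e.g. from [generate_study()]) or a named
#'   list of tables.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- intersect(c("traps", "surveys", "samples", "depots", "sowing"),
                      names(bundle))
  paths <- stats::setNames(file.path(dir, paste0(tables, ".csv")), tables)
  for (tb in tables) readr::write_csv(bundle[[tb]], paths[[tb]])
  invisible(paths)
}
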