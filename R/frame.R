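#' Sentinel species code for samples whose disperser could not be identified
#'
#' Barcoded samples whose PCR amplification failed carry this code in the
#' `species_code` column; they are excluded (with renormalisation) when
#' disperser-group frequencies are computed.
#'
#' @export
SPECIES_UNIDENTIFIED <- "unidentified"

#' Define the factorial study frame
#'
#' A study frame fixes the three axes of the design — fruiting periods,
#' deposition microhabitats and disperser groups — together with the mapping
#' from species codes to groups and the sampling area of one seed trap.
#' Every downstream estimate is indexed by cells of this frame.
#'
#' @param periods Data frame with columns `period` (label), `start`, `end`
#'   (Dates, inclusive). Periods must be non-overlapping, contiguous and in
#'   temporal order.
#' @param microhabitats Character vector of microhabitat labels.
#' @param groups Character vector of disperser-group labels.
#' @param species_to_group Named character vector mapping each species code
#'   to exactly one group label.
#' @param trap_area Area in square metres of one seed trap; must be positive.
#'
#' @return An object of class `study_frame`.
#' @seealso [default_frame()] for the lentisc study design.
#' @export
study_frame <- function(periods, microhabitats, groups, species_to_group,
                        trap_area) {
  periods <- tibble::as_tibble(periods)
  stopifnot(all(c("period", "start", "end") %in% names(periods)))
  periods$start <- as.Date(periods$start)
  periods$end <- as.Date(periods$end)
  if (any(periods$end < periods$start)) {
    stop("each period must end on or after its start date", call. = FALSE)
  }
  if (nrow(periods) > 1) {
    ord <- order(periods$start)
    if (!identical(ord, seq_len(nrow(periods)))) {
      stop("periods must be listed in temporal order", call. = FALSE)
    }
    gaps <- as.integer(periods$start[-1] - periods$end[-nrow(periods)])
    if (any(gaps != 1)) {
      stop("periods must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  if (anyDuplicated(periods$period)) {
    stop("period labels must be unique", call. = FALSE)
  }
  microhabitats <- as.character(microhabitats)
  groups <- as.character(groups)
  species_to_group <- unlist(species_to_group)
  if (is.null(names(species_to_group)) || any(!nzchar(names(species_to_group)))) {
    stop("species_to_group must be a named vector (species code -> group)",
         call. = FALSE)
  }
  if (anyDuplicated(names(species_to_group))) {
    stop("every species code must map to exactly one group", call. = FALSE)
  }
  bad <- setdiff(unique(species_to_group), groups)
  if (length(bad)) {
    stop("species_to_group targets unknown groups: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(trap_area) || length(trap_area) != 1 || trap_area <= 0) {
    stop("trap_area must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      periods = periods,
      microhabitats = microhabitats,
      groups = groups,
      species_to_group = species_to_group,
      trap_area = as.numeric(trap_area)
    ),
    class = "study_frame"
  )
}

#' @export
print.study_frame <- function(x, ...) {
  cat("<study_frame>\n")
  cat("  periods:      ", paste(x$periods$period, collapse = ", "), "\n")
  cat("  season:       ", format(min(x$periods$start)), "to",
      format(max(x$periods$end)), "\n")
  cat("  microhabitats:", paste(x$microhabitats, collapse = ", "), "\n")
  cat("  groups:       ", paste(x$groups, collapse = ", "), "\n")
  cat("  species:      ", length(x$species_to_group), "codes\n")
  cat("  trap_area:    ", x$trap_area, "m^2\n")
  invisible(x)
}

#' The lentisc study frame
#'
#' The design of the field study: a nine-month fruiting season (August 2014 to
#' April 2015) split into three three-month periods (`early` =
#' August--October, `mid` = November--January, `late` = February--April);
#' three deposition microhabitats (beneath oak trees, fruit-bearing shrubs
#' and shrubs without fleshy fruits); and eleven frugivorous bird species
#' grouped by migratory strategy into residents, sub-Saharan migrants and
#' European wintering migrants. Seed traps are 40 cm x 55 cm trays, so
#' `trap_area` is 0.22 m^2. The three frame axes cross into 27 effectiveness
#' cells.
#'
#' Period boundaries are inclusive of their first and last calendar month;
#' fortnightly surveys are assigned to periods by survey date.
#'
#' @return A `study_frame`.
#' @examples
#' frame <- default_frame()
#' frame$species_to_group[["Er"]]
#' assign_period(as.Date("2014-09-15"), frame)
#' @export
default_frame <- function() {
  study_frame(
    periods = tibble::tibble(
      period = c("early", "mid", "late"),
      start = as.Date(c("2014-08-01", "2014-11-01", "2015-02-01")),
      end = as.Date(c("2014-10-31", "2015-01-31", "2015-04-30"))
    ),
    microhabitats = c("trees", "fb_shrubs", "nfb_shrubs"),
    groups = c("resident", "sub-Saharan", "European"),
    species_to_group = c(
      Sm = "resident",
      Lm = "sub-Saharan", Fh = "sub-Saharan", Ms = "sub-Saharan",
      Pp = "sub-Saharan", Sb = "sub-Saharan", Sc = "sub-Saharan",
      Sh = "sub-Saharan",
      Er = "European", Sa = "European", Tp = "European"
    ),
    trap_area = 0.40 * 0.55
  )
}

#' Assign calendar dates to fruiting periods
#'
#' Maps each date to the unique period of the frame whose (inclusive) range
#' contains it. Dates outside the season are an error: out-of-season records
#' indicate a data problem and are never silently dropped.
#'
#' @param dates A `Date` vector (or something coercible via `as.Date`).
#' @param frame A [study_frame()].
#' @return A character vector of period labels, same length as `dates`.
#' @export
assign_period <- function(dates, frame) {
  stopifnot(inherits(frame, "study_frame"))
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable or missing dates", call. = FALSE)
  p <- frame$periods
  idx <- rep(NA_integer_, length(dates))
  for (i in seq_len(nrow(p))) {
    idx[dates >= p$start[i] & dates <= p$end[i]] <- i
  }
  if (anyNA(idx)) {
    bad <- unique(dates[is.na(idx)])
    stop("date(s) outside the study season (",
         format(min(p$start)), " to ", format(max(p$end)), "): ",
         paste(format(utils::head(bad, 5)), collapse = ", "),
         call. = FALSE)
  }
  p$period[idx]
}

#' Enumerate the cells of a study frame
#'
#' @param frame A [study_frame()].
#' @param axes Which axes to cross: any subset of `"group"`, `"period"`,
#'   `"microhabitat"`.
#' @return A tibble with one row per cell, ordered period-major.
#' @export
frame_cells <- function(frame,
                        axes = c("group", "period", "microhabitat")) {
  stopifnot(inherits(frame, "study_frame"))
  axes <- match.arg(axes, several.ok = TRUE)
  parts <- list(
    group = frame$groups,
    period = frame$periods$period,
    microhabitat = frame$microhabitats
  )[axes]
  out <- do.call(tidyr::expand_grid, parts)
  tibble::as_tibble(out)
}

#' Read and write a study frame as a YAML configuration
#'
#' The on-disk form holds the period table, axis labels, the species-to-group
#' mapping and the trap area, so alternative designs can be supplied without
#' touching code. `write_frame()` round-trips with `read_frame()`.
#'
#' @param path File path of the YAML configuration.
#' @return `read_frame()` returns a `study_frame`; `write_frame()` returns
#'   `path` invisibly.
#' @export
read_frame <- function(path) {
  cfg <- yaml::read_yaml(path)
  study_frame(
    periods = tibble::tibble(
      period = vapply(cfg$periods, `[[`, character(1), "period"),
      start = as.Date(vapply(cfg$periods, `[[`, character(1), "start")),
      end = as.Date(vapply(cfg$periods, `[[`, character(1), "end"))
    ),
    microhabitats = unlist(cfg$microhabitats),
    groups = unlist(cfg$groups),
    species_to_group = unlist(cfg$species_to_group),
    trap_area = cfg$trap_area
  )
}

#' @rdname read_frame
#' @param frame A [study_frame()] to serialise.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "study_frame"))
  cfg <- list(
    periods = lapply(seq_len(nrow(frame$periods)), function(i) {
      list(
        period = frame$periods$period[i],
        start = format(frame$periods$start[i]),
        end = format(frame$periods$end[i])
      )
    }),
    microhabitats = as.list(frame$microhabitats),
    groups = as.list(frame$groups),
    species_to_group = as.list(frame$species_to_group),
    trap_area = frame$trap_area
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
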