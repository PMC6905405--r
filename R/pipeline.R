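#' Run the full effectiveness pipeline on a study bundle
#'
#' Executes the three estimation stages — quantity (densities, group
#' frequencies, their product), quality (the four demographic
#' subcomponents, zero policy, cumulative product) and effectiveness (cell
#' tensor, quantity-weighted overall aggregates, period totals, shares,
#' landscapes) — and optionally writes every result as a tidy delimited
#' table plus a machine-readable run manifest. Any stage failure aborts
#' with a message naming the stage; nothing is written unless all stages
#' succeed.
#'
#' @param bundle A `study_bundle`: named list with tibbles `traps`,
#'   `surveys`, `samples`, `depots`, `sowing` (from [generate_study()] or
#'   [read_study_tables()]).
#' @param frame A [study_frame()].
#' @param level Confidence level for all intervals (default 0.95).
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @param zero_policy `"paper"` or `"raw"`; see [apply_zero_policy()].
#' @param p_constant,s_replacement Passed to [apply_zero_policy()].
#' @param n_isoclines Isocline count for the landscapes.
#' @param out_dir Optional output directory; when given, all tables, the
#'   landscape coordinate tables and `manifest.json` are written there.
#' @param seed Seed recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @return A list of results: `density`, `frequencies`, `quantity`,
#'   `viability`, `escape`, `germination`, `survival`, `germination_speed`,
#'   `quality`, `cells`, `overall`, `period_totals`, `shares`,
#'   `landscape_periods`, `landscape_overall`, `manifest`.
#' @export
run_sde_pipeline <- function(bundle, frame = default_frame(), level = 0.95,
                             ci_method = c("clopper-pearson", "wilson"),
                             zero_policy = c("paper", "raw"),
                             p_constant = 0.01, s_replacement = NULL,
                             n_isoclines = 8, out_dir = NULL, seed = NULL) {
  ci_method <- match.arg(ci_method)
  zero_policy <- match.arg(zero_policy)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  need <- c("traps", "surveys", "samples", "depots", "sowing")
  missing <- setdiff(need, names(bundle))
  if (length(missing)) {
    st <- if (any(missing %in% c("depots", "sowing"))) "quality" else
      "quantity"
    stop("[stage ", st, "] bundle is missing table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  density <- stage("quantity", seed_rain_density(bundle$surveys,
                                                 bundle$traps, frame, level))
  frequencies <- stage("quantity", group_frequencies(bundle$samples, frame))
  quantity <- stage("quantity", quantity_component(density, frequencies))

  viability <- stage("quality", viability_by_period(bundle$samples, frame,
                                                    level, ci_method))
  escape <- stage("quality", escape_probability(bundle$depots, frame,
                                                level, ci_method))
  germination <- stage("quality", germination_probability(bundle$sowing,
                                                          frame, level,
                                                          ci_method))
  survival <- stage("quality", seedling_survival(bundle$sowing, frame,
                                                 level, ci_method))
  speed <- stage("quality", germination_speed(bundle$sowing, frame))
  quality <- stage("quality", quality_table(viability, escape, germination,
                                            survival, frame, zero_policy,
                                            p_constant, s_replacement))

  cells <- stage("effectiveness", sde_cells(quantity, quality))
  overall <- stage("effectiveness", aggregate_overall(cells))
  totals <- stage("effectiveness", period_totals(cells))
  shares <- stage("effectiveness", contribution_shares(overall))
  land_periods <- stage("effectiveness", sde_landscape(
    cells[!is.na(cells$sde), ], n_isoclines
  ))
  ov <- overall[overall$qt_total > 0, ]
  land_overall <- stage("effectiveness", sde_landscape(
    tibble::tibble(group = ov$group, microhabitat = ov$microhabitat,
                   qt = ov$qt_total, ql = ov$ql_weighted), n_isoclines
  ))

  manifest <- list(
    package = "sdeland",
    version = as.character(utils::packageVersion("sdeland")),
    seed = seed,
    options = list(level = level, ci_method = ci_method,
                   zero_policy = zero_policy, p_constant = p_constant,
                   n_isoclines = n_isoclines),
    config_hash = rlang::hash(list(bundle[need], frame, level, ci_method,
                                   zero_policy, p_constant, s_replacement,
                                   n_isoclines))
  )

  res <- list(
    density = density, frequencies = frequencies, quantity = quantity,
    viability = viability, escape = escape, germination = germination,
    survival = survival, germination_speed = speed, quality = quality,
    cells = cells, overall = overall, period_totals = totals,
    shares = shares, landscape_periods = land_periods,
    landscape_overall = land_overall, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Serialise pipeline results: tidy CSVs, landscape coordinates, manifest.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(df) {
    df[vapply(df, is.list, logical(1))] <- NULL
    df
  }
  tables <- c("density", "frequencies", "quantity", "viability", "escape",
              "germination", "survival", "germination_speed", "quality",
              "cells", "overall", "period_totals", "shares")
  for (tb in tables) {
    readr::write_csv(flat(res[[tb]]), file.path(out_dir,
                                                paste0(tb, ".csv")))
  }
  readr::write_csv(res$landscape_periods$points,
                   file.path(out_dir, "landscape_period_points.csv"))
  readr::write_csv(res$landscape_periods$isoclines,
                   file.path(out_dir, "landscape_period_isoclines.csv"))
  readr::write_csv(res$landscape_overall$points,
                   file.path(out_dir, "landscape_overall_points.csv"))
  readr::write_csv(res$landscape_overall$isoclines,
                   file.path(out_dir, "landscape_overall_isoclines.csv"))
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
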