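#' Compare one replicate's estimates with the generator's ground truth
#'
#' Lines up pipeline estimates computed from a synthetic bundle against the
#' parameter values that generated it: seed rain density `d`, group
#' frequencies `f` (against the configured period-level mixture), viability
#' `v`, raw escape `p`, germination `g` and seedling survival `s`. For the
#' binomial subcomponents the 95% interval's coverage of the true value is
#' recorded.
#'
#' @param truth Ground truth, `bundle$truth` from [generate_study()] (or
#'   [truth_tensor()] output).
#' @param estimates Named list of estimate tables: `density`
#'   ([seed_rain_density()]), `frequencies` ([group_frequencies()]),
#'   `viability`, `escape`, `germination`, `survival` (any subset).
#' @return A tidy tibble: `parameter`, cell labels (`group`, `period`,
#'   `microhabitat`, `NA` where an axis does not apply), `truth`,
#'   `estimate`, `error` and `covered` (`NA` where no interval applies).
#' @export
recovery_report <- function(truth, estimates) {
  out <- list()
  if (!is.null(estimates$density)) {
    x <- dplyr::inner_join(truth$density,
                           estimates$density[
                             c("period", "microhabitat", "mean_density")
                           ], by = c("period", "microhabitat"))
    out$d <- tibble::tibble(
      parameter = "d", group = NA_character_, period = x$period,
      microhabitat = x$microhabitat, truth = x$d,
      estimate = x$mean_density, covered = NA
    )
  }
  if (!is.null(estimates$frequencies)) {
    x <- dplyr::inner_join(estimates$frequencies, truth$frequencies,
                           by = c("group", "period"),
                           suffix = c("", "_true"))
    out$f <- tibble::tibble(
      parameter = "f", group = x$group, period = x$period,
      microhabitat = x$microhabitat, truth = x$frequency_true,
      estimate = x$frequency, covered = NA
    )
  }
  binom_part <- function(est, true_col, parameter, by) {
    x <- dplyr::inner_join(est, truth$quality[c(by, true_col)], by = by)
    x <- x[!duplicated(x[by]), ]
    tibble::tibble(
      parameter = parameter, group = NA_character_, period = x$period,
      microhabitat = if ("microhabitat" %in% by) x$microhabitat else
        NA_character_,
      truth = x[[true_col]], estimate = x$proportion,
      covered = !is.na(x$proportion) &
        x$ci_low <= x[[true_col]] & x[[true_col]] <= x$ci_high
    )
  }
  if (!is.null(estimates$viability)) {
    out$v <- binom_part(estimates$viability, "v", "v", "period")
  }
  if (!is.null(estimates$escape)) {
    out$p <- binom_part(estimates$escape, "p", "p",
                        c("period", "microhabitat"))
  }
  if (!is.null(estimates$germination)) {
    out$g <- binom_part(estimates$germination, "g", "g",
                        c("period", "microhabitat"))
  }
  if (!is.null(estimates$survival)) {
    out$s <- binom_part(estimates$survival, "s", "s",
                        c("period", "microhabitat"))
  }
  if (!length(out)) stop("no recognised estimate tables", call. = FALSE)
  res <- dplyr::bind_rows(out)
  res$error <- res$estimate - res$truth
  res
}

# Estimators the recovery study runs on each replicate.
estimate_all <- function(bundle, frame, level = 0.95,
                         method = "clopper-pearson") {
  list(
    density = seed_rain_density(bundle$surveys, bundle$traps, frame, level),
    frequencies = group_frequencies(bundle$samples, frame),
    viability = viability_by_period(bundle$samples, frame, level, method),
    escape = escape_probability(bundle$depots, frame, level, method),
    germination = germination_probability(bundle$sowing, frame, level,
                                          method),
    survival = seedling_survival(bundle$sowing, frame, level, method)
  )
}

#' Parameter-recovery study over replicated synthetic datasets
#'
#' Generates `n_reps` independent synthetic studies from one configuration,
#' runs the estimation stages on each, and summarises, per parameter cell,
#' the bias and root-mean-square error of the estimates and the empirical
#' coverage of the binomial confidence intervals. Also tracks the realised
#' fraction of barcoded samples whose disperser was identified.
#'
#' @param config A [generator_config()].
#' @param n_reps Number of replicates.
#' @param seed Master RNG seed; per-replicate seeds are drawn from it.
#' @param level Confidence level of the intervals whose coverage is scored.
#' @param method Binomial CI method.
#' @return A list: `by_cell` (tibble: `parameter`, cell labels, `truth`,
#'   `bias`, `rmse`, `coverage`, `n_reps`), `by_parameter` (the same pooled
#'   over cells of each parameter family), and `identified_fraction` (mean
#'   over replicates of the identified sample share).
#' @export
recovery_study <- function(config, n_reps, seed, level = 0.95,
                           method = "clopper-pearson") {
  stopifnot(inherits(config, "generator_config"), n_reps >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  reports <- vector("list", n_reps)
  identified <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    bundle <- generate_study(config, rep_seeds[r])
    est <- estimate_all(bundle, config$frame, level, method)
    reports[[r]] <- recovery_report(bundle$truth, est)
    identified[r] <- mean(bundle$samples$species_code !=
                            SPECIES_UNIDENTIFIED)
  }
  all <- dplyr::bind_rows(reports, .id = "rep")
  by_cell <- all |>
    dplyr::group_by(.data$parameter, .data$group, .data$period,
                    .data$microhabitat) |>
    dplyr::summarise(
      truth = .data$truth[1],
      bias = mean(.data$error, na.rm = TRUE),
      rmse = sqrt(mean(.data$error^2, na.rm = TRUE)),
      coverage = mean(.data$covered),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  by_parameter <- all |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      bias = mean(.data$error, na.rm = TRUE),
      rmse = sqrt(mean(.data$error^2, na.rm = TRUE)),
      coverage = mean(.data$covered),
      n_cells = dplyr::n_distinct(paste(.data$group, .data$period,
                                        .data$microhabitat)),
      .groups = "drop"
    )
  list(by_cell = by_cell, by_parameter = by_parameter,
       identified_fraction = mean(identified, na.rm = TRUE))
}
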