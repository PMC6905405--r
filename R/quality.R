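#' Binomial proportion with exact or Wilson confidence interval
#'
#' Clopper--Pearson (default) intervals are computed from beta quantiles:
#' lower = B(alpha/2; s, n - s + 1), upper = B(1 - alpha/2; s + 1, n - s),
#' with the conventional closures at s = 0 and s = n. The Wilson score
#' interval is available as a shorter, slightly anti-conservative
#' alternative. Vectorised over `successes` and `trials`.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials >= 1` (a zero-trial cell has no defined proportion and is an
#'   error, never a silent zero).
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return A tibble: `successes`, `trials`, `proportion`, `ci_low`,
#'   `ci_high`, `method`.
#' @export
binomial_ci <- function(successes, trials, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(trials < 1)) {
    stop("undefined estimate: trials must be >= 1", call. = FALSE)
  }
  if (any(successes < 0) || any(successes > trials)) {
    stop("successes must lie in [0, trials]", call. = FALSE)
  }
  n <- as.numeric(trials)
  s <- as.numeric(successes)
  p <- s / n
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- ifelse(s == 0, 0, stats::qbeta(a / 2, s, n - s + 1))
    hi <- ifelse(s == n, 1, stats::qbeta(1 - a / 2, s + 1, n - s))
  } else {
    z <- stats::qnorm(1 - a / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- ifelse(s == 0, 0, pmax(0, centre - half))
    hi <- ifelse(s == n, 1, pmin(1, centre + half))
  }
  tibble::tibble(
    successes = successes, trials = trials, proportion = p,
    ci_low = lo, ci_high = hi, method = method
  )
}

# Split "sink;float;untested" flag strings into one row per seed.
unnest_viability <- function(samples) {
  check_columns(samples, c("sample_date", "viable_flags"), "samples")
  flags <- strsplit(as.character(samples$viable_flags), ";", fixed = TRUE)
  flags <- lapply(flags, trimws)
  out <- tibble::tibble(
    sample_date = rep(samples$sample_date, lengths(flags)),
    flag = unlist(flags)
  )
  bad <- setdiff(unique(out$flag), c("sink", "float", "untested"))
  if (length(bad)) {
    stop("viable_flags tokens must be sink/float/untested; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Seed viability per fruiting period
#'
#' The flotation assay: seeds that sink hold a developed embryo and count as
#' viable; floaters are empty or parasitised. Viability is estimated per
#' period, pooled over microhabitats (the design assesses this subcomponent
#' between periods only). Untested seeds are excluded, not imputed.
#'
#' @param samples Sample table with `sample_date` and `viable_flags`
#'   (per-seed `sink`/`float`/`untested` tokens separated by `;`).
#' @param frame A [study_frame()].
#' @inheritParams binomial_ci
#' @return A tibble with one row per period: the [binomial_ci()] columns.
#'   Periods with no tested seed appear with zero trials and `NA` estimates.
#' @export
viability_by_period <- function(samples, frame, level = 0.95,
                                method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  seeds <- unnest_viability(samples)
  seeds <- seeds[seeds$flag != "untested", ]
  seeds$period <- assign_period(seeds$sample_date, frame)
  counts <- seeds |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(successes = sum(.data$flag == "sink"),
                     trials = dplyr::n(), .groups = "drop")
  finish_binomial_cells(counts, frame, c("period"), level, method)
}

#' Escape from post-dispersal seed predation
#'
#' Pools seeds across the depots of each period x microhabitat cell and
#' estimates the probability that an exposed seed is neither removed nor
#' gnawed over the exposure window. Point estimates pool seeds over depots;
#' depot-level clustering is not modelled here.
#'
#' @param depots Depot table: `depot_id`, `period`, `microhabitat`,
#'   `n_seeds`, `n_surviving`.
#' @param frame A [study_frame()].
#' @inheritParams binomial_ci
#' @return A tibble with one row per period x microhabitat.
#' @export
escape_probability <- function(depots, frame, level = 0.95,
                               method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  check_columns(depots,
                c("depot_id", "period", "microhabitat", "n_seeds",
                  "n_surviving"), "depots")
  bad <- depots$n_surviving > depots$n_seeds | depots$n_surviving < 0
  if (any(bad)) {
    stop("n_surviving outside [0, n_seeds] for depot(s): ",
         paste(depots$depot_id[bad], collapse = ", "), call. = FALSE)
  }
  counts <- depots |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::summarise(successes = sum(.data$n_surviving),
                     trials = sum(.data$n_seeds), .groups = "drop")
  finish_binomial_cells(counts, frame, c("period", "microhabitat"),
                        level, method)
}

validate_sowing <- function(sowing) {
  check_columns(sowing,
                c("station_id", "period", "microhabitat", "seed_index",
                  "germination_week", "survived", "lost_germ", "lost_surv"),
                "sowing")
  bad <- sowing$lost_germ == 1 & sowing$lost_surv != 1
  if (any(bad)) {
    stop("station(s) lost before germination scoring must also be lost for ",
         "survival: ", paste(unique(sowing$station_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(sowing$survived) & is.na(sowing$germination_week)
  if (any(bad)) {
    stop("survival recorded for ungerminated seed(s) in station(s): ",
         paste(unique(sowing$station_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(sowing)
}

#' Germination probability per cell
#'
#' Stations destroyed before germination scoring (wild-boar damage) are
#' excluded from numerator and denominator; among retained stations,
#' `g = germinated seeds / sown seeds`. Sown seeds are pre-screened viable
#' by flotation, so `g` is conditional on viability and multiplies correctly
#' with the viability subcomponent.
#'
#' @param sowing Long sowing table, one row per sown seed: `station_id`,
#'   `period`, `microhabitat`, `seed_index`, `germination_week` (week index
#'   or `NA`), `survived` (0/1 or `NA`), `lost_germ`, `lost_surv` (0/1,
#'   station-level flags).
#' @param frame A [study_frame()].
#' @inheritParams binomial_ci
#' @return A tibble with one row per period x microhabitat; cells whose
#'   stations were all lost have zero trials and `NA` estimates.
#' @export
germination_probability <- function(sowing, frame, level = 0.95,
                                    method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  sowing <- validate_sowing(sowing)
  kept <- sowing[sowing$lost_germ == 0, ]
  counts <- kept |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::summarise(successes = sum(!is.na(.data$germination_week)),
                     trials = dplyr::n(), .groups = "drop")
  finish_binomial_cells(counts, frame, c("period", "microhabitat"),
                        level, method)
}

#' Mean germination speed per period
#'
#' Arithmetic mean of the week index at emergence, over germinated seeds in
#' stations retained for germination scoring.
#'
#' @inheritParams germination_probability
#' @return A tibble: `period`, `n_germinated`, `mean_weeks` (`NA` where no
#'   seed germinated).
#' @export
germination_speed <- function(sowing, frame) {
  sowing <- validate_sowing(sowing)
  kept <- sowing[sowing$lost_germ == 0 & !is.na(sowing$germination_week), ]
  out <- kept |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(n_germinated = dplyr::n(),
                     mean_weeks = mean(.data$germination_week),
                     .groups = "drop")
  all_p <- tibble::tibble(period = frame$periods$period)
  out <- dplyr::left_join(all_p, out, by = "period")
  out$n_germinated[is.na(out$n_germinated)] <- 0L
  out
}

#' First-summer seedling survival per cell
#'
#' Stations lost before the end of the survival census are excluded; among
#' retained stations the denominator is the number of emerged seedlings and
#' the numerator those still alive in early autumn after their first summer.
#' A station lost for survival but not for germination still contributes to
#' [germination_probability()].
#'
#' @inheritParams germination_probability
#' @return A tibble with one row per period x microhabitat; cells with no
#'   emerged seedling among retained stations have zero trials and `NA`
#'   estimates.
#' @export
seedling_survival <- function(sowing, frame, level = 0.95,
                              method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  sowing <- validate_sowing(sowing)
  kept <- sowing[sowing$lost_surv == 0 & !is.na(sowing$germination_week), ]
  counts <- kept |>
    dplyr::group_by(.data$period, .data$microhabitat) |>
    dplyr::summarise(successes = sum(.data$survived == 1, na.rm = TRUE),
                     trials = sum(!is.na(.data$survived)), .groups = "drop")
  finish_binomial_cells(counts, frame, c("period", "microhabitat"),
                        level, method)
}

# Complete counts over the frame's cells and attach binomial CIs; zero-trial
# cells are kept with NA estimates (undefined, not zero).
finish_binomial_cells <- function(counts, frame, axes, level, method) {
  cells <- frame_cells(frame, intersect(c("period", "microhabitat"), axes))
  out <- dplyr::left_join(cells, counts, by = axes)
  out$successes[is.na(out$successes)] <- 0L
  out$trials[is.na(out$trials)] <- 0L
  est <- binomial_ci(out$successes[out$trials > 0],
                     out$trials[out$trials > 0], level, method)
  out$proportion <- out$ci_low <- out$ci_high <- NA_real_
  out$proportion[out$trials > 0] <- est$proportion
  out$ci_low[out$trials > 0] <- est$ci_low
  out$ci_high[out$trials > 0] <- est$ci_high
  out$method <- method
  order_cells(out, frame)
}

#' Zero-replacement policy for predation escape and seedling survival
#'
#' Cumulative recruitment probabilities degenerate when an estimated
#' subcomponent is exactly zero, which at field sample sizes reflects
#' limited power rather than a fully collapsed process. The default
#' (`"paper"`) policy therefore (1) sets the predation-escape probability to
#' a small constant (1%) in every cell — observed predation was near-total
#' and showed no variability — and (2) replaces zero seedling-survival
#' values with the minimum non-zero survival observed across cells. The
#' `"raw"` policy is the identity. The policy is idempotent: applying it
#' twice equals applying it once.
#'
#' @param p,s Tibbles holding the raw (or already-adjusted) estimates with a
#'   `proportion` column, e.g. from [escape_probability()] and
#'   [seedling_survival()].
#' @param policy `"paper"` (constant p, min-non-zero s) or `"raw"`.
#' @param p_constant Constant escape probability used by the `"paper"`
#'   policy (default 0.01).
#' @param s_replacement Replacement for zero survival values; `NULL`
#'   (default) uses the minimum non-zero estimated survival. If every
#'   survival value is zero no minimum exists and an explicit constant must
#'   be supplied.
#' @return A list with elements `p` and `s`: the input tibbles with
#'   `proportion` adjusted and a logical `replaced` flag column.
#' @export
apply_zero_policy <- function(p, s, policy = c("paper", "raw"),
                              p_constant = 0.01, s_replacement = NULL) {
  policy <- match.arg(policy)
  check_columns(p, "proportion", "p")
  check_columns(s, "proportion", "s")
  p <- tibble::as_tibble(p)
  s <- tibble::as_tibble(s)
  has_flag <- function(df) if ("replaced" %in% names(df)) df$replaced else
    rep(FALSE, nrow(df))
  if (policy == "raw") {
    p$replaced <- has_flag(p)
    s$replaced <- has_flag(s)
    return(list(p = p, s = s))
  }
  already_p <- has_flag(p)
  p$replaced <- already_p | p$proportion != p_constant
  p$proportion <- ifelse(is.na(p$proportion), NA_real_, p_constant)

  zero_s <- !is.na(s$proportion) & s$proportion == 0
  if (is.null(s_replacement)) {
    nonzero <- s$proportion[!is.na(s$proportion) & s$proportion > 0]
    if (any(zero_s) && !length(nonzero)) {
      stop("all survival values are zero: no minimum non-zero value ",
           "exists; supply an explicit s_replacement", call. = FALSE)
    }
    s_replacement <- if (length(nonzero)) min(nonzero) else NA_real_
  }
  already_s <- has_flag(s)
  s$proportion[zero_s] <- s_replacement
  s$replaced <- already_s | zero_s
  list(p = p, s = s)
}

#' Likelihood-ratio test for a period effect on a binomial outcome
#'
#' Compares the saturated model (one proportion per period) with the pooled
#' single-proportion model: G^2 = 2 (l_sat - l_pooled), referred to a
#' chi-squared distribution on (periods - 1) degrees of freedom. This is the
#' likelihood-ratio analogue of a Wald chi-squared test on a binomial
#' logit-link model with period as the only factor.
#'
#' @param outcomes Tibble with columns `period`, `successes`, `trials`
#'   (one row per period, `trials >= 1`).
#' @return A list: `statistic` (G^2), `df`, `p_value`, and the per-period
#'   `proportions`.
#' @export
period_effect_test <- function(outcomes) {
  check_columns(outcomes, c("period", "successes", "trials"), "outcomes")
  outcomes <- outcomes[outcomes$trials > 0, ]
  k <- nrow(outcomes)
  if (k < 2) {
    stop("period_effect_test needs at least two periods with trials >= 1",
         call. = FALSE)
  }
  s <- outcomes$successes
  n <- outcomes$trials
  loglik <- function(s, n, p) {
    p <- rep_len(p, length(s))
    ifelse(p <= 0 | p >= 1,
           ifelse((p <= 0 & s == 0) | (p >= 1 & s == n), 0, -Inf),
           s * log(p) + (n - s) * log(1 - p))
  }
  l_sat <- sum(loglik(s, n, s / n))
  p_pool <- sum(s) / sum(n)
  l_pool <- sum(loglik(s, n, p_pool))
  g2 <- max(0, 2 * (l_sat - l_pool))
  df <- k - 1
  list(
    statistic = g2,
    df = df,
    p_value = stats::pchisq(g2, df, lower.tail = FALSE),
    proportions = stats::setNames(s / n, outcomes$period)
  )
}

#' Assemble the quality component per cell
#'
#' Joins the four subcomponents — viability (period-level, replicated across
#' microhabitats), predation escape, germination and seedling survival — on
#' the frame's period x microhabitat cells, applies the zero-replacement
#' policy to escape and survival, and forms the cumulative recruitment
#' probability `ql = v * p * g * s`.
#'
#' @param viability Output of [viability_by_period()].
#' @param escape Output of [escape_probability()].
#' @param germination Output of [germination_probability()].
#' @param survival Output of [seedling_survival()].
#' @param frame A [study_frame()].
#' @inheritParams apply_zero_policy
#' @return A tibble with one row per period x microhabitat: `v`, `p`, `g`,
#'   `s` (policy-adjusted), `ql`, and `p_replaced`/`s_replaced` flags.
#' @export
quality_table <- function(viability, escape, germination, survival, frame,
                          policy = c("paper", "raw"), p_constant = 0.01,
                          s_replacement = NULL) {
  policy <- match.arg(policy)
  adj <- apply_zero_policy(escape, survival, policy, p_constant,
                           s_replacement)
  cells <- frame_cells(frame, c("period", "microhabitat"))
  out <- cells |>
    dplyr::left_join(
      dplyr::select(viability, "period", v = "proportion"), by = "period"
    ) |>
    dplyr::left_join(
      dplyr::select(adj$p, "period", "microhabitat", p = "proportion",
                    p_replaced = "replaced"),
      by = c("period", "microhabitat")
    ) |>
    dplyr::left_join(
      dplyr::select(germination, "period", "microhabitat",
                    g = "proportion"),
      by = c("period", "microhabitat")
    ) |>
    dplyr::left_join(
      dplyr::select(adj$s, "period", "microhabitat", s = "proportion",
                    s_replaced = "replaced"),
      by = c("period", "microhabitat")
    )
  out$ql <- out$v * out$p * out$g * out$s
  order_cells(out, frame)
}
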