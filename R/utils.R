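#' @importFrom rlang .data %||%
NULL

# Require columns in an input table; names errors by table for usable messages.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Order a cell-indexed tibble by the frame's axis order (period-major).
order_cells <- function(df, frame) {
  lv <- list(
    group = frame$groups,
    period = frame$periods$period,
    microhabitat = frame$microhabitats
  )
  for (ax in intersect(names(lv), names(df))) {
    df[[ax]] <- factor(df[[ax]], levels = lv[[ax]])
  }
  df <- dplyr::arrange(df, dplyr::across(dplyr::any_of(c(
    "period", "microhabitat", "group"
  ))))
  for (ax in intersect(names(lv), names(df))) {
    df[[ax]] <- as.character(df[[ax]])
  }
  df
}
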