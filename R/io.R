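#' Currency conversion settings
#'
#' @param exchange_rate Local currency units per USD (> 0); default 14,308,
#'   the average 2021 IDR/USD rate.
#' @param base_year Calendar year the rate refers to.
#' @return A `currency_config` object.
#' @export
currency_config <- function(exchange_rate = 14308, base_year = 2021) {
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop_config("exchange_rate", "must be > 0")
  }
  structure(list(exchange_rate = exchange_rate, base_year = as.integer(base_year)),
            class = "currency_config")
}

# Standard column names of a burden export and their accepted synonyms.
.burden_cols <- c("measure", "location", "sex", "age", "cause", "metric",
                  "year", "val")

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    if (col_map[[std]] %in% names(df)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  df
}

#' Read a burden-export table
#'
#' Reads a comma-delimited export in the results-tool shape (columns
#' `measure`, `location`, `sex`, `age`, `cause`, `metric`, `year`, `val`;
#' `value` is accepted for `val`), filters to one cause and one metric, and
#' normalizes sex and measure labels onto the controlled vocabularies.
#' Absolute counts are materialized whenever a population is joinable: from
#' a `population` column in the file, from the `population` argument, or —
#' when the file carries both the Rate and Number metrics for the same
#' cells — from their ratio.
#'
#' @param path File to read.
#' @param cause_filter Cause label to retain (exact match); `NULL` keeps all.
#' @param metric `"Rate"` (per 100,000) or `"Number"` (absolute events).
#' @param population Optional data frame with `province`, `sex`,
#'   `age_group`, `population` to join.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's names, e.g. `c(location = "location_name")`.
#' @return Tibble of burden cells: `province`, `sex`, `age_group`,
#'   `measure`, `rate`, `population`, `count`, `cause`, `year`.
#' @export
read_burden_table <- function(path, cause_filter = NULL,
                              metric = c("Rate", "Number"),
                              population = NULL, col_map = NULL) {
  metric <- match.arg(metric)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- apply_col_map(df, col_map)
  if ("value" %in% names(df) && !"val" %in% names(df)) {
    names(df)[names(df) == "value"] <- "val"
  }
  missing <- setdiff(.burden_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Burden table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      class = "vlw_schema_error"
    )
  }
  if (!is.null(cause_filter)) df <- df[df$cause == cause_filter, ]
  if (nrow(df) == 0) {
    return(tibble::tibble(
      province = character(), sex = character(), age_group = character(),
      measure = character(), rate = double(), population = double(),
      count = double(), cause = character(), year = integer()
    ))
  }
  df$sex <- normalize_sex(df$sex)
  df$measure <- normalize_measure(df$measure)
  keys <- c("province", "sex", "age_group", "measure")

  cells <- df[df$metric == metric, ] |>
    dplyr::rename(province = "location", age_group = "age") |>
    dplyr::select(dplyr::all_of(keys), "cause", "year", "val",
                  dplyr::any_of("population"))

  # population fallback chain: file column -> join -> Number/Rate ratio
  if (!"population" %in% names(cells) && !is.null(population)) {
    cells <- dplyr::left_join(cells, population,
                              by = intersect(keys, names(population)))
  }
  if (!"population" %in% names(cells)) {
    other <- setdiff(c("Rate", "Number"), metric)
    twin <- df[df$metric == other, ] |>
      dplyr::rename(province = "location", age_group = "age") |>
      dplyr::select(dplyr::all_of(keys), twin_val = "val")
    cells <- dplyr::left_join(cells, twin, by = keys)
    cells$population <- if (metric == "Rate") {
      cells$twin_val / cells$val * 1e5
    } else {
      cells$val / cells$twin_val * 1e5
    }
    cells$twin_val <- NULL
  }
  if (metric == "Rate") {
    cells$rate <- cells$val
    cells$count <- cells$rate / 1e5 * cells$population
  } else {
    cells$count <- cells$val
    cells$rate <- cells$count / cells$population * 1e5
  }
  if (any(cells$rate < 0, na.rm = TRUE)) {
    rlang::abort("Negative burden rates are not allowed.",
                 class = "vlw_data_error")
  }
  cells |>
    dplyr::select("province", "sex", "age_group", "measure", "rate",
                  "population", "count", "cause", "year") |>
    tibble::as_tibble()
}

#' Write burden cells as a burden-export table
#'
#' Emits the same dialect [read_burden_table()] reads: one row per cell and
#' metric (`Rate` and `Number`), plus a `population` column so the table
#' round-trips exactly.
#'
#' @param cells Burden cells as returned by [generate_burden()] or
#'   [read_burden_table()].
#' @param path Output file.
#' @param include_population Keep the `population` column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(cells, path, include_population = TRUE) {
  if (nrow(cells) == 0) {
    rlang::abort("Refusing to write an empty burden table.",
                 class = "vlw_data_error")
  }
  long <- dplyr::bind_rows(
    dplyr::mutate(cells, metric = "Rate", val = .data$rate),
    dplyr::mutate(cells, metric = "Number", val = .data$count)
  ) |>
    dplyr::select(measure = "measure", location = "province", sex = "sex",
                  age = "age_group", "cause", "metric", "year", "val",
                  dplyr::any_of(if (include_population) "population" else character()))
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a provincial economy table
#'
#' Expects columns `province`, `population`, and GDP either in USD
#' (`gdp_usd`) or in local currency (`gdp_local` or `gdp`), converted at
#' `currency$exchange_rate`. GDP per capita is taken from a
#' `gdp_per_capita_usd` column when present and recomputed otherwise.
#'
#' @param path File to read.
#' @param currency A [currency_config()].
#' @param col_map Optional named character vector mapping standard names to
#'   the file's column names.
#' @return Tibble with `province`, `gdp_local`, `gdp_usd`,
#'   `gdp_per_capita_usd`, `population`.
#' @export
read_economy_table <- function(path, currency = currency_config(),
                               col_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- apply_col_map(df, col_map)
  if ("gdp" %in% names(df) && !"gdp_local" %in% names(df)) {
    names(df)[names(df) == "gdp"] <- "gdp_local"
  }
  if (!"province" %in% names(df) || !"population" %in% names(df) ||
      !any(c("gdp_local", "gdp_usd") %in% names(df))) {
    rlang::abort(
      "Economy table needs columns `province`, `population`, and `gdp_local`/`gdp`/`gdp_usd`.",
      class = "vlw_schema_error"
    )
  }
  if (!"gdp_usd" %in% names(df)) {
    df$gdp_usd <- df$gdp_local / currency$exchange_rate
  }
  if (!"gdp_local" %in% names(df)) {
    df$gdp_local <- df$gdp_usd * currency$exchange_rate
  }
  if (!"gdp_per_capita_usd" %in% names(df)) {
    df$gdp_per_capita_usd <- df$gdp_usd / df$population
  }
  bad <- df$province[df$gdp_usd <= 0 | df$population <= 0]
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Non-positive GDP or population for province(s): %s",
              paste(sQuote(bad), collapse = ", ")),
      class = "vlw_data_error"
    )
  }
  df |>
    dplyr::select("province", "gdp_local", "gdp_usd", "gdp_per_capita_usd",
                  "population") |>
    tibble::as_tibble()
}

#' Write a result table
#'
#' Long/tidy comma-delimited output with a stable column order; values are
#' written at full precision so that a write/read cycle is lossless.
#'
#' @param records A non-empty data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    rlang::abort("Refusing to write an empty result table.",
                 class = "vlw_data_error")
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path File to read.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
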