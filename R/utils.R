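#' Round half away from zero
#'
#' Presentation rounding used for printed tables: ties round away from zero
#' (so 0.0425 -> 0.043), unlike [base::round()]'s round-half-even.
#' Internal computations always run at full precision; this is applied only
#' when emitting presentation tables or reproducing printed figures.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(0.0425, 3)  # 0.043
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * (abs(x) > 0)) / p
}

# controlled vocabularies
.sexes <- c("male", "female", "both")
.measures <- c("DALY", "YLL")

# Map free-text sex labels (GBD exports use "Male"/"Female"/"Both") onto the
# controlled vocabulary; unknown labels abort with the offending values.
normalize_sex <- function(x) {
  key <- tolower(trimws(x))
  out <- dplyr::case_when(
    key %in% c("male", "males", "m") ~ "male",
    key %in% c("female", "females", "f") ~ "female",
    key %in% c("both", "both sexes", "all", "total") ~ "both",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    rlang::abort(
      sprintf("Unknown sex label(s): %s", paste(sQuote(bad), collapse = ", ")),
      class = "vlw_vocabulary_error"
    )
  }
  out
}

# Measure labels: accept the short codes and the verbose GBD export strings
# ("DALYs (Disability-Adjusted Life Years)", "YLLs (Years of Life Lost)").
normalize_measure <- function(x) {
  key <- toupper(trimws(x))
  out <- dplyr::case_when(
    grepl("^DALY", key) ~ "DALY",
    grepl("^YLL", key) ~ "YLL",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    rlang::abort(
      sprintf("Unknown measure label(s): %s", paste(sQuote(bad), collapse = ", ")),
      class = "vlw_vocabulary_error"
    )
  }
  out
}

stop_config <- function(field, msg) {
  rlang::abort(sprintf("Invalid `%s`: %s", field, msg),
               class = "vlw_config_error")
}
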