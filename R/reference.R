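#' Published reference VLW tables
#'
#' Province-level value-of-lost-welfare estimates (billion USD, rounded to 3
#' decimals) for congenital heart disease in Indonesia, as published for the
#' three VSL benchmarks and three sex strata, in long format. One table per
#' measure (DALY-based and YLL-based), each including the national row
#' (`"Indonesia"`). These rounded presentation values serve as inputs to the
#' internal-consistency checks: the combined-sex accounting identity,
#' cross-benchmark linear scaling, gender disparity from rounded inputs, and
#' the DALY-YLL gap.
#'
#' @param measure `"DALY"`, `"YLL"`, or both (default).
#' @return Tibble with columns `province`, `sex`, `benchmark`
#'   (`wage`/`oecd`/`usdot`), `measure`, `vlw_billion_usd`.
#' @export
#' @examples
#' ref <- reference_vlw("DALY")
#' subset(ref, province == "Indonesia" & benchmark == "wage")
reference_vlw <- function(measure = c("DALY", "YLL")) {
  measure <- match.arg(measure, several.ok = TRUE)
  files <- c(DALY = "reference_vlw_daly.csv", YLL = "reference_vlw_yll.csv")
  dplyr::bind_rows(lapply(measure, function(m) {
    path <- system.file("extdata", files[[m]], package = "vlwburden",
                        mustWork = TRUE)
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    out$measure <- m
    out
  }))
}
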