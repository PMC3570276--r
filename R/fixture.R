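#' Parse printed table values
#'
#' Published ICC tables truncate very small entries to `"<0.001"` (and one
#' prevalence to `"<0.1"`). For ordering and summary statistics such an
#' entry is valued at half its bound (`"<0.001"` becomes 0.0005): this
#' preserves the ordering of the rows without inventing precision, and the
#' affected entries lie far below the reported medians.
#'
#' @param x character vector of printed values.
#' @return numeric vector.
#' @export
parse_printed <- function(x) {
  x <- trimws(as.character(x))
  lt <- grepl("^<", x)
  out <- suppressWarnings(as.numeric(sub("^<", "", x)))
  out[lt] <- out[lt] / 2
  out
}

#' Published reference table of the surveillance network
#'
#' The per-variable prevalence, ICC, 95% CI, design effect and mean cluster
#' size published for the 27-center severe-maternal-morbidity surveillance
#' network (9,555 women), transcribed from the four printed blocks: process
#' of care (37 variables), clinical outcome (69, including sub-item rows and
#' the maternal death summary rows), personal/obstetric characteristics (40)
#' and structure of services (8) — 154 rows in all. The raw individual-level
#' charts were never released, so these published estimates are the
#' regression surface the package checks its reporting layer against; they
#' are not recomputable from data.
#'
#' Two row labels printed twice in the outcome block ("Shock", "Stroke")
#' carry a "(near miss criteria)" suffix on their second occurrence to keep
#' variable names unique within the table.
#'
#' @return A data frame with character columns `variable`, `block`, `P`,
#'   `ICC`, `ci_low`, `ci_high` (printed form, `"<0.001"` possible), numeric
#'   `DEFF` and `n_a`, plus numeric columns `P_value`, `ICC_value`,
#'   `ci_low_value`, `ci_high_value` from [parse_printed()]. The attribute
#'   `design` holds the published design row (`a = 27`, `n = 9555`).
#' @examples
#' fx <- network_table_fixture()
#' table(fx$block)
#' @export
network_table_fixture <- function() {
  path <- system.file("extdata", "network_icc_tables.csv",
                      package = "svyicc", mustWork = TRUE)
  fx <- utils::read.csv(path, colClasses = c(
    variable = "character", block = "character", P = "character",
    ICC = "character", ci_low = "character", ci_high = "character",
    DEFF = "numeric", n_a = "integer"), check.names = FALSE)
  fx$P_value <- parse_printed(fx$P)
  fx$ICC_value <- parse_printed(fx$ICC)
  fx$ci_low_value <- parse_printed(fx$ci_low)
  fx$ci_high_value <- parse_printed(fx$ci_high)
  attr(fx, "design") <- list(a = 27L, n = 9555L)
  fx
}
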