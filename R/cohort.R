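#' Cluster sizes of the 27-center surveillance network
#'
#' The per-center counts of severe maternal morbidity cases in the Brazilian
#' surveillance network that motivates this package: 27 hospitals (the primary
#' sampling units of a single-stage cluster sample) contributing 9,555 women
#' in total, for a mean cluster size of 354. Names encode the geographical
#' region of each center (SE southeast, NE northeast, S south, MW midwest,
#' N north).
#'
#' @return Named integer vector of length 27 summing to 9555.
#' @examples
#' sum(network_cluster_sizes())  # 9555
#' @export
network_cluster_sizes <- function() {
  c(SE01 = 48L, SE02 = 59L, SE03 = 66L, SE04 = 74L, SE05 = 96L,
    SE06 = 112L, SE07 = 154L, SE08 = 155L, SE09 = 172L, SE10 = 186L,
    SE11 = 253L, SE12 = 369L, SE13 = 1050L,
    NE01 = 118L, NE02 = 210L, NE03 = 263L, NE04 = 281L, NE05 = 294L,
    NE06 = 465L, NE07 = 566L, NE08 = 920L, NE09 = 945L, NE10 = 1086L,
    S01 = 98L, S02 = 841L, MW01 = 609L, N01 = 65L)
}

#' Single-stage cluster design summary
#'
#' @param cluster_sizes named (or unnamed) vector of per-cluster subject
#'   counts; every size must be at least 1.
#' @return An object of class `cohort_design` with fields `cluster_sizes`,
#'   `a` (number of clusters), `n` (total subjects) and `b_bar` (mean cluster
#'   size `n / a`).
#' @examples
#' d <- cohort_design(network_cluster_sizes())
#' round(d$b_bar)  # 354
#' @export
cohort_design <- function(cluster_sizes) {
  sizes <- as.integer(cluster_sizes)
  if (length(sizes) < 1L || anyNA(sizes) || any(sizes < 1L)) {
    stop("all cluster sizes must be integers >= 1", call. = FALSE)
  }
  nms <- names(cluster_sizes) %||% sprintf("C%02d", seq_along(sizes))
  names(sizes) <- nms
  structure(list(cluster_sizes = sizes,
                 a = length(sizes),
                 n = sum(sizes),
                 b_bar = sum(sizes) / length(sizes)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> a = %d clusters, n = %d subjects, mean size = %.1f\n",
    x$a, x$n, x$b_bar))
  invisible(x)
}

new_cohort <- function(data, cluster_col) {
  ids <- data[[cluster_col]]
  tab <- table(ids)
  structure(list(data = data,
                 cluster_col = cluster_col,
                 design = cohort_design(stats::setNames(as.integer(tab),
                                                        names(tab)))),
            class = "svy_cohort")
}

#' Build a cohort from an in-memory data frame
#'
#' @param data data frame with one row per subject.
#' @param cluster_col name of the column holding the cluster (center) id.
#' @return An object of class `svy_cohort` wrapping the subject table and its
#'   derived [cohort_design()].
#' @export
as_cohort <- function(data, cluster_col = "cluster") {
  stopifnot(is.data.frame(data))
  if (!cluster_col %in% names(data)) {
    stop("cluster column '", cluster_col, "' not found", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("cohort has no rows", call. = FALSE)
  ids <- data[[cluster_col]]
  bad <- which(is.na(ids) | !nzchar(as.character(ids)))
  if (length(bad) > 0L) {
    stop("rows without a cluster id: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  new_cohort(data, cluster_col)
}

#' Read a subject-level cohort from delimited text
#'
#' Reads a CSV/TSV extract with a header row and one row per subject (one
#' woman in the surveillance context). All value columns are kept as
#' character: a missing marker (empty string or `"NA"` by default) becomes
#' `NA` and is never silently coerced to 0 — dichotomization is deferred to
#' [apply_rule()]. Rows lacking a cluster id are rejected with their row
#' numbers.
#'
#' @param path path to the delimited file; `.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated.
#' @param cluster_col name of the cluster id column.
#' @param schema optional list of [var_spec()]; every spec's source column
#'   (and subpopulation column) must exist in the file, otherwise the read
#'   fails naming the offending variable.
#' @param na character values treated as missing.
#' @return An `svy_cohort` (see [as_cohort()]).
#' @export
read_cohort <- function(path, cluster_col = "cluster", schema = NULL,
                        na = c("", "NA")) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", na.strings = na,
                            check.names = FALSE, quote = "\"",
                            comment.char = "")
  if (nrow(data) == 0L) stop("cohort file is empty: ", path, call. = FALSE)
  if (!cluster_col %in% names(data)) {
    stop("cluster column '", cluster_col, "' not found in ", path,
         call. = FALSE)
  }
  if (!is.null(schema)) validate_schema(data, schema)
  as_cohort(data, cluster_col)
}

validate_schema <- function(data, schema) {
  for (spec in schema) {
    stopifnot(inherits(spec, "var_spec"))
    if (!spec$variable %in% names(data)) {
      stop("variable '", spec$variable, "' (for '", spec$name,
           "') not present in the cohort", call. = FALSE)
    }
    if (!is.null(spec$subpopulation) &&
        !spec$subpopulation$variable %in% names(data)) {
      stop("subpopulation variable '", spec$subpopulation$variable,
           "' (for '", spec$name, "') not present in the cohort",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a cohort back to delimited text
#'
#' Missing values are written as the empty string, the convention
#' [read_cohort()] reads back.
#'
#' @param cohort an `svy_cohort`.
#' @param path output file path (written as CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "svy_cohort"))
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.svy_cohort <- function(x, ...) {
  cat(sprintf("<svy_cohort> %d subjects in %d clusters ('%s'), %d columns\n",
              x$design$n, x$design$a, x$cluster_col, ncol(x$data)))
  invisible(x)
}
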