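# Apply a var_spec to a cohort: subpopulation restriction, then the success
# rule. Returns subject-level parallel vectors (cluster id, logical success
# with NA for missing), already restricted to the subpopulation.
dichotomize <- function(cohort, spec) {
  stopifnot(inherits(cohort, "svy_cohort"), inherits(spec, "var_spec"))
  data <- cohort$data
  if (!spec$variable %in% names(data)) {
    stop("variable '", spec$variable, "' not present in the cohort",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(data))
  if (!is.null(spec$subpopulation)) {
    sv <- spec$subpopulation$variable
    if (!sv %in% names(data)) {
      stop("subpopulation variable '", sv, "' not present in the cohort",
           call. = FALSE)
    }
    inpop <- apply_rule(spec$subpopulation$rule, data[[sv]])
    keep <- !is.na(inpop) & inpop
  }
  list(cluster = as.character(data[[cohort$cluster_col]])[keep],
       success = apply_rule(spec$success, data[[spec$variable]][keep]))
}

#' Per-cluster summaries of a dichotomized variable
#'
#' Applies a variable's subpopulation restriction and success rule to the
#' subject table, then tallies for each cluster the valid denominator
#' `x` (non-missing, in-subpopulation records), the success count `y`, and
#' the cluster-level ratio `r = y / x`. Missingness is handled listwise per
#' variable: a missing value drops the record from this variable's
#' denominator only. Clusters ending up with no valid record are excluded
#' (recorded in the `excluded_clusters` attribute) so that downstream ANOVA
#' operates on `a_eff` non-empty groups.
#'
#' @param cohort an `svy_cohort`.
#' @param spec a [var_spec()].
#' @return A data frame of class `cluster_summary` with columns `cluster_id`,
#'   `x`, `y`, `r`, and attributes `variable`, `block`, `valid_n`
#'   (total valid denominator), `a_eff` (contributing clusters) and
#'   `excluded_clusters`.
#' @export
summarize_variable <- function(cohort, spec) {
  d <- dichotomize(cohort, spec)
  ok <- !is.na(d$success)
  if (!any(ok)) {
    stop("no valid observations for variable '", spec$name, "'",
         call. = FALSE)
  }
  cl <- d$cluster[ok]
  s <- d$success[ok]
  # tapply indexes by sorted cluster id, so output is independent of record
  # and cluster order in the file
  x <- tapply(s, cl, length)
  ids <- names(x)
  y <- as.integer(tapply(s, cl, sum)[ids])
  x <- as.integer(x)
  out <- data.frame(cluster_id = ids, x = x, y = y, r = y / x,
                    stringsAsFactors = FALSE, row.names = NULL)
  all_ids <- names(cohort$design$cluster_sizes)
  structure(out,
            class = c("cluster_summary", "data.frame"),
            variable = spec$name,
            block = spec$block,
            valid_n = sum(out$x),
            a_eff = nrow(out),
            excluded_clusters = setdiff(all_ids, ids))
}

new_cluster_summary <- function(df, variable = NA_character_,
                                block = NA_character_) {
  stopifnot(all(c("cluster_id", "x", "y") %in% names(df)),
            all(df$y >= 0), all(df$y <= df$x), all(df$x >= 0))
  df$r <- ifelse(df$x > 0, df$y / df$x, NA_real_)
  structure(df[c("cluster_id", "x", "y", "r")],
            class = c("cluster_summary", "data.frame"),
            variable = variable, block = block,
            valid_n = sum(df$x), a_eff = sum(df$x > 0),
            excluded_clusters = character(0))
}

#' Construct cluster summaries from counts
#'
#' Convenience constructor for working directly with per-cluster counts
#' (`x` valid records, `y` successes) rather than subject-level data.
#'
#' @param x integer vector of valid denominators per cluster.
#' @param y integer vector of success counts per cluster (`0 <= y <= x`).
#' @param cluster_id optional ids; defaults to `C01`, `C02`, ...
#' @return A `cluster_summary` data frame (see [summarize_variable()]).
#' @examples
#' cluster_summary(x = c(2, 1), y = c(2, 0))
#' @export
cluster_summary <- function(x, y, cluster_id = sprintf("C%02d",
                                                       seq_along(x))) {
  stopifnot(length(x) == length(y), length(cluster_id) == length(x))
  new_cluster_summary(data.frame(cluster_id = as.character(cluster_id),
                                 x = as.integer(x), y = as.integer(y),
                                 stringsAsFactors = FALSE))
}

#' @export
print.cluster_summary <- function(x, ...) {
  v <- attr(x, "variable")
  cat(sprintf("<cluster_summary>%s %d clusters, valid n = %d\n",
              if (is.na(v)) "" else paste0(" ", v),
              attr(x, "a_eff"), attr(x, "valid_n")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read cluster summaries as CSV
#'
#' The ratio column is serialized with full double precision so that a
#' write/read round trip reproduces the summaries exactly.
#'
#' @param summaries a `cluster_summary` data frame.
#' @param path CSV path.
#' @return `write_cluster_summaries()` returns `path` invisibly;
#'   `read_cluster_summaries()` returns a `cluster_summary`.
#' @export
write_cluster_summaries <- function(summaries, path) {
  stopifnot(inherits(summaries, "cluster_summary"))
  out <- data.frame(cluster_id = summaries$cluster_id,
                    x = summaries$x, y = summaries$y,
                    r = sprintf("%.17g", summaries$r),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_summaries
#' @export
read_cluster_summaries <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cluster_id = "character"))
  new_cluster_summary(df[c("cluster_id", "x", "y")])
}
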