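# Normalize the various result shapes (list of variable_result, pipeline
# results CSV, or the published fixture) into one table with numeric columns.
as_report_table <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "variable_result"))) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame or list of variable results",
         call. = FALSE)
  }
  icc <- if ("ICC_value" %in% names(results)) results$ICC_value
         else parse_printed(results$ICC)
  deff <- suppressWarnings(as.numeric(results$DEFF))
  data.frame(variable = as.character(results$variable),
             block = as.character(results$block),
             icc = icc, deff = deff,
             stringsAsFactors = FALSE)
}

block_stats <- function(tab, icc_threshold) {
  data.frame(
    n_variables = nrow(tab),
    icc_median = stats::median(tab$icc, na.rm = TRUE),
    icc_min = suppressWarnings(min(tab$icc, na.rm = TRUE)),
    icc_max = suppressWarnings(max(tab$icc, na.rm = TRUE)),
    icc_mean = mean(tab$icc, na.rm = TRUE),
    deff_median = stats::median(tab$deff, na.rm = TRUE),
    deff_min = suppressWarnings(min(tab$deff, na.rm = TRUE)),
    deff_max = suppressWarnings(max(tab$deff, na.rm = TRUE)),
    prop_icc_below = mean(tab$icc < icc_threshold, na.rm = TRUE))
}

#' Summary statistics over a table of per-variable results
#'
#' Reproduces the block-level and overall summaries a surveillance report
#' quotes: median/min/max (and mean) of the ICC and the design effect per
#' reporting block and overall, the proportion of variables with ICC below a
#' threshold, and the ratio of the mean process-block ICC to the mean
#' outcome-block ICC (process variables are expected to be more homogeneous
#' across centers than outcomes). Medians use the standard midpoint rule for
#' even counts; printed `"<0.001"` entries are valued at 0.0005 (see
#' [parse_printed()]); rows whose estimates are flagged `NA` are dropped
#' from the statistics.
#'
#' Optionally recalculates the cluster-corrected sample size from a named
#' main-outcome row via [recalc_sample_size()].
#'
#' @param results per-variable results: a list of `variable_result`, the
#'   data frame written by [run_pipeline()], or the fixture from
#'   [network_table_fixture()].
#' @param icc_threshold threshold for the "proportion of variables below"
#'   statistic (default 0.1).
#' @param main_outcome optional variable name whose ICC and DEFF feed the
#'   sample-size recalculation.
#' @param clusters number of clusters for the recalculation; defaults to the
#'   `design` attribute of `results` if present.
#' @param total_n total study size used to express `n*` as a percentage;
#'   same default.
#' @return Object of class `summary_report`: list with `blocks` (one row per
#'   block), `overall`, `mean_icc_ratio` (process / outcome), `icc_threshold`
#'   and, when requested, `sample_size` (with `n_star` and `pct_of_total`).
#' @examples
#' rep <- summarize_results(network_table_fixture(),
#'                          main_outcome = "Maternal Death + NM")
#' rep$overall$icc_median
#' @export
summarize_results <- function(results, icc_threshold = 0.1,
                              main_outcome = NULL, clusters = NULL,
                              total_n = NULL) {
  design <- attr(results, "design")
  tab <- as_report_table(results)

  blocks_present <- intersect(c("process", "outcome", "personal",
                                "structure"), unique(tab$block))
  blocks <- do.call(rbind, lapply(blocks_present, function(b) {
    cbind(data.frame(block = b), block_stats(tab[tab$block == b, ],
                                             icc_threshold))
  }))
  overall <- block_stats(tab, icc_threshold)

  ratio <- NA_real_
  if (all(c("process", "outcome") %in% blocks_present)) {
    ratio <- blocks$icc_mean[blocks$block == "process"] /
      blocks$icc_mean[blocks$block == "outcome"]
  }

  sample_size <- NULL
  if (!is.null(main_outcome)) {
    i <- match(main_outcome, tab$variable)
    if (is.na(i)) {
      stop("main outcome '", main_outcome, "' not found in results",
           call. = FALSE)
    }
    a <- clusters %||% design$a %||%
      stop("supply 'clusters' for the sample-size recalculation",
           call. = FALSE)
    res <- recalc_sample_size(a = a, icc = tab$icc[i], deff = tab$deff[i])
    ntot <- total_n %||% design$n
    sample_size <- list(main_outcome = main_outcome,
                        n_star = res$n_star, a = res$a,
                        icc_used = res$icc_used, deff_used = res$deff_used,
                        total_n = ntot,
                        pct_of_total = if (is.null(ntot)) NA_real_
                                       else 100 * res$n_star / ntot)
  }

  structure(list(blocks = blocks, overall = overall,
                 mean_icc_ratio = ratio, icc_threshold = icc_threshold,
                 sample_size = sample_size),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  df <- rbind(cbind(data.frame(block = "overall"), x$overall),
              if (!is.null(x$blocks)) x$blocks)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print.data.frame(df, row.names = FALSE)
  if (!is.na(x$mean_icc_ratio)) {
    cat(sprintf("process / outcome mean ICC ratio: %.2f\n",
                x$mean_icc_ratio))
  }
  cat(sprintf("proportion of variables with ICC < %s: %.2f\n",
              format(x$icc_threshold), x$overall$prop_icc_below))
  if (!is.null(x$sample_size)) {
    s <- x$sample_size
    cat(sprintf(
      "recalculated n* for '%s': %d subjects (a = %d, ICC = %.3f, DEFF = %.2f)",
      s$main_outcome, s$n_star, s$a, s$icc_used, s$deff_used))
    if (!is.na(s$pct_of_total)) {
      cat(sprintf(" = %.0f%% of the %d observed", s$pct_of_total, s$total_n))
    }
    cat("\n")
  }
  invisible(x)
}

#' Compare estimated results against the published reference table
#'
#' Cell-by-cell regression check of a results table against the embedded
#' fixture (or any reference table with the same columns): prevalence, ICC,
#' CI bounds, DEFF and mean cluster size are compared at per-field
#' tolerances (default: half a unit in the last printed digit), and the
#' block/overall summary statistics of both tables are compared alongside.
#' This is report-only: discrepancies are returned, never raised.
#'
#' @param results a results table ([run_pipeline()] output or a fixture-like
#'   data frame).
#' @param fixture the reference table; defaults to [network_table_fixture()].
#' @param tolerance named list of absolute tolerances for `P`, `ICC`, `ci`,
#'   `DEFF`, `n_a`.
#' @return Object of class `fixture_check`: list with `mismatches` (data
#'   frame: variable, field, value, reference, diff, tol), `n_cells`
#'   compared, and `summary_comparison` (overall medians of both tables).
#' @export
check_against_fixture <- function(results, fixture = network_table_fixture(),
                                  tolerance = list(P = 0.051, ICC = 6e-4,
                                                   ci = 6e-4, DEFF = 6e-3,
                                                   n_a = 0.5)) {
  res <- normalize_check_table(results)
  ref <- normalize_check_table(fixture)
  idx <- match(res$variable, ref$variable)
  if (anyNA(idx)) {
    stop("variables not present in the reference table: ",
         paste(res$variable[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  fields <- c(P = "P", ICC = "ICC", ci = "ci_low", ci = "ci_high",
              DEFF = "DEFF", n_a = "n_a")
  mism <- list()
  n_cells <- 0L
  for (j in seq_along(fields)) {
    col <- fields[[j]]
    tol <- tolerance[[names(fields)[j]]]
    v <- res[[col]]
    w <- ref[[col]][idx]
    comparable <- !is.na(v) & !is.na(w)
    n_cells <- n_cells + sum(comparable)
    bad <- comparable & abs(v - w) > tol
    if (any(bad)) {
      mism[[length(mism) + 1L]] <- data.frame(
        variable = res$variable[bad], field = col,
        value = v[bad], reference = w[bad],
        diff = v[bad] - w[bad], tol = tol, stringsAsFactors = FALSE)
    }
  }
  mismatches <- if (length(mism)) do.call(rbind, mism) else
    data.frame(variable = character(0), field = character(0),
               value = numeric(0), reference = numeric(0),
               diff = numeric(0), tol = numeric(0))
  sum_res <- summarize_results(results)
  sum_ref <- summarize_results(fixture)
  structure(list(
    mismatches = mismatches,
    n_cells = n_cells,
    summary_comparison = data.frame(
      statistic = c("icc_median", "deff_median", "mean_icc_ratio"),
      results = c(sum_res$overall$icc_median, sum_res$overall$deff_median,
                  sum_res$mean_icc_ratio),
      reference = c(sum_ref$overall$icc_median, sum_ref$overall$deff_median,
                    sum_ref$mean_icc_ratio))),
    class = "fixture_check")
}

normalize_check_table <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) >= 1L)
  out <- data.frame(variable = as.character(x$variable),
                    stringsAsFactors = FALSE)
  out$P <- if ("P_value" %in% names(x)) x$P_value
           else if ("P_percent" %in% names(x)) as.numeric(x$P_percent)
           else parse_printed(x$P)
  out$ICC <- if ("ICC_value" %in% names(x)) x$ICC_value
             else parse_printed(x$ICC)
  out$ci_low <- if ("ci_low_value" %in% names(x)) x$ci_low_value
                else if ("ICC_CI_low" %in% names(x)) as.numeric(x$ICC_CI_low)
                else if ("ci_low" %in% names(x)) parse_printed(x$ci_low)
                else NA_real_
  out$ci_high <- if ("ci_high_value" %in% names(x)) x$ci_high_value
                 else if ("ICC_CI_high" %in% names(x))
                   as.numeric(x$ICC_CI_high)
                 else if ("ci_high" %in% names(x)) parse_printed(x$ci_high)
                 else NA_real_
  out$DEFF <- suppressWarnings(as.numeric(x$DEFF))
  out$n_a <- suppressWarnings(as.numeric(x$n_a))
  out
}

#' @export
print.fixture_check <- function(x, ...) {
  cat(sprintf("<fixture_check> %d cells compared, %d discrepancies\n",
              x$n_cells, nrow(x$mismatches)))
  if (nrow(x$mismatches)) print.data.frame(utils::head(x$mismatches, 20))
  invisible(x)
}

#' Run the full per-variable estimation pipeline
#'
#' Reads a subject-level cohort and a variable configuration, estimates
#' prevalence, ICC (with CI), DEFF and mean cluster size for every
#' configured variable, and writes `results.csv`, `summary.csv` (block
#' summaries) and `log.txt` to the output directory. A variable whose
#' estimation fails (e.g. no valid observations) still appears in the
#' results, flagged, with `NA` estimates; configuration errors — such as a
#' variable missing from the cohort — abort before any estimation, naming
#' the offending item.
#'
#' @param cohort_file delimited subject-level file (see [read_cohort()]).
#' @param config_file YAML variable configuration
#'   (see [read_variable_config()]).
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param cluster_col cluster id column name.
#' @param conf_level,k_method passed to [estimate_variable()].
#' @param icc_threshold,main_outcome passed to [summarize_results()].
#' @param quiet suppress per-variable progress messages.
#' @return Invisibly, a list with `results` (data frame, one row per
#'   configured variable), `summary` (a `summary_report`) and `log`
#'   (character vector).
#' @export
run_pipeline <- function(cohort_file, config_file, out_dir = NULL,
                         cluster_col = "cluster", conf_level = 0.95,
                         k_method = "adjusted", icc_threshold = 0.1,
                         main_outcome = NULL, quiet = TRUE) {
  specs <- read_variable_config(config_file)
  cohort <- read_cohort(cohort_file, cluster_col = cluster_col,
                        schema = specs)
  log <- c(sprintf("cohort: %d subjects in %d clusters from %s",
                   cohort$design$n, cohort$design$a, cohort_file),
           sprintf("config: %d variables from %s", length(specs),
                   config_file))

  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    row <- withCallingHandlers(
      tryCatch(
        as.data.frame(estimate_variable(cohort, spec,
                                        conf_level = conf_level,
                                        k_method = k_method)),
        error = function(e) {
          log <<- c(log, sprintf("ERROR %s: %s", spec$name,
                                 conditionMessage(e)))
          data.frame(variable = spec$name, block = spec$block,
                     P_percent = NA_real_, ICC = NA_real_,
                     ICC_CI_low = NA_real_, ICC_CI_high = NA_real_,
                     DEFF = NA_real_, n_a = NA_integer_,
                     a_eff = NA_integer_,
                     flags = paste0("error: ", conditionMessage(e)),
                     stringsAsFactors = FALSE)
        }),
      warning = function(w) {
        log <<- c(log, sprintf("WARN %s: %s", spec$name,
                               conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (nzchar(row$flags)) {
      log <- c(log, sprintf("FLAG %s: %s", spec$name, row$flags))
    }
    if (!quiet) message("estimated ", spec$name)
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  attr(results, "design") <- list(a = cohort$design$a, n = cohort$design$n)

  summary <- summarize_results(results, icc_threshold = icc_threshold,
                               main_outcome = main_outcome,
                               clusters = cohort$design$a,
                               total_n = cohort$design$n)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(summary$blocks, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(list(results = results, summary = summary, log = log))
}
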