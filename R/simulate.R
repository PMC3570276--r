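#' Simulation scenario for a clustered binary cohort
#'
#' Describes one beta-binomial data-generating process: each cluster `a`
#' draws a latent success probability
#' `p_a ~ Beta(mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)` (with
#' `p_a = mu` when `rho = 0`), and each subject in the cluster is an
#' independent Bernoulli(`p_a`) draw. Under this model the marginal
#' prevalence of the generated values is exactly `mu` and their population
#' intraclass correlation is exactly `rho` — no latent-scale conversion is
#' involved, which is why the beta-binomial is used as the validation
#' model for the ANOVA ICC estimator. Values can additionally be masked
#' missing completely at random.
#'
#' The default cluster sizes are the 27-center surveillance network vector
#' ([network_cluster_sizes()], 9,555 subjects), mirroring the single-stage
#' design in which every admitted woman within a participating center is
#' observed: sizes are fixed, not resampled.
#'
#' @param mu marginal prevalence, in `(0, 1)` when `rho > 0` (the Beta
#'   parameters must be positive), in `[0, 1]` when `rho = 0`.
#' @param rho target intraclass correlation in `[0, 1)`.
#' @param cluster_sizes per-cluster subject counts (all >= 1).
#' @param missing_rate probability in `[0, 1)` that a value is masked
#'   missing, independently per cell.
#' @param seed optional integer; a given seed makes [generate_cohort()]
#'   deterministic.
#' @return An object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario(mu = 0.095, rho = 0.077, seed = 1)
#' cohort <- generate_cohort(sc)
#' @export
sim_scenario <- function(mu, rho, cluster_sizes = network_cluster_sizes(),
                         missing_rate = 0, seed = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(rho), length(rho) == 1L,
            is.numeric(missing_rate), length(missing_rate) == 1L)
  if (rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  if (rho > 0 && (mu <= 0 || mu >= 1)) {
    stop("mu must lie strictly in (0, 1) when rho > 0", call. = FALSE)
  }
  if (rho == 0 && (mu < 0 || mu > 1)) {
    stop("mu must lie in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  design <- cohort_design(cluster_sizes)  # validates sizes >= 1
  structure(list(cluster_sizes = design$cluster_sizes,
                 mu = mu, rho = rho,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %d clusters, n = %d, mu = %.3f, rho = %.3f, missing = %.2f\n",
    length(x$cluster_sizes), sum(x$cluster_sizes), x$mu, x$rho,
    x$missing_rate))
  invisible(x)
}

draw_cluster_probs <- function(mu, rho, a) {
  if (rho == 0) return(rep(mu, a))
  theta <- (1 - rho) / rho
  stats::rbeta(a, mu * theta, (1 - mu) * theta)
}

#' Generate a clustered binary cohort
#'
#' Draws one cohort from a [sim_scenario()]'s beta-binomial process. The
#' output is a full subject-level table in the same shape [read_cohort()]
#' produces, so every estimator can be exercised end to end on data with a
#' known prevalence and ICC.
#'
#' @param scenario a [sim_scenario()].
#' @param variable name of the generated outcome column.
#' @return An `svy_cohort` whose data has columns `cluster` and `variable`
#'   (values `1`/`0`, `NA` where masked missing).
#' @export
generate_cohort <- function(scenario, variable = "outcome") {
  stopifnot(inherits(scenario, "sim_scenario"))
  sizes <- scenario$cluster_sizes
  with_seed(scenario$seed, {
    p <- draw_cluster_probs(scenario$mu, scenario$rho, length(sizes))
    cl <- rep(names(sizes), times = sizes)
    v <- stats::rbinom(sum(sizes), 1L, rep(p, times = sizes))
    if (scenario$missing_rate > 0) {
      v[stats::runif(length(v)) < scenario$missing_rate] <- NA_integer_
    }
    df <- data.frame(cluster = cl, stringsAsFactors = FALSE)
    df[[variable]] <- v
    as_cohort(df, "cluster")
  })
}

#' Generate a multi-variable cohort on a shared cluster frame
#'
#' Draws several independent variables — one per scenario — for the same
#' subjects. All scenarios must share the same cluster-size vector; each
#' variable uses its own scenario's `(mu, rho, missing_rate)` and, if set,
#' its own seed (otherwise the current RNG stream, or `seed + i` for the
#' i-th variable when a top-level `seed` is given).
#'
#' @param scenarios named list of [sim_scenario()] objects; names become
#'   column names.
#' @param seed optional top-level seed used to derive per-variable seeds for
#'   scenarios that do not carry one.
#' @return An `svy_cohort` with one column per scenario.
#' @export
generate_multivariable_cohort <- function(scenarios, seed = NULL) {
  if (length(scenarios) == 0L) stop("no scenarios supplied", call. = FALSE)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    stop("scenarios must be a named list", call. = FALSE)
  }
  ref <- scenarios[[1L]]$cluster_sizes
  for (sc in scenarios) {
    stopifnot(inherits(sc, "sim_scenario"))
    if (!identical(unname(sc$cluster_sizes), unname(ref))) {
      stop("all scenarios must share the same cluster_sizes", call. = FALSE)
    }
  }
  df <- data.frame(cluster = rep(names(ref), times = ref),
                   stringsAsFactors = FALSE)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (is.null(sc$seed) && !is.null(seed)) sc$seed <- seed + i
    one <- generate_cohort(sc, variable = "v")
    df[[names(scenarios)[i]]] <- one$data$v
  }
  as_cohort(df, "cluster")
}

#' Default variable spec for a generated outcome column
#'
#' Generated cohorts code success as `1`; this helper builds the matching
#' [var_spec()].
#'
#' @param name column (and display) name.
#' @param block reporting block, default `"outcome"`.
#' @return A [var_spec()].
#' @export
generated_var_spec <- function(name = "outcome", block = "outcome") {
  var_spec(name, block, rule_equals(1))
}
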