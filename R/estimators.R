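#' Cluster ratio estimator of a prevalence
#'
#' Under single-stage cluster sampling (every subject within each selected
#' cluster observed, no weighting), the prevalence of a dichotomized variable
#' is estimated by the ratio of pooled counts across clusters,
#' `r = sum(y_a) / sum(x_a)`, where `x_a` is the valid denominator and `y_a`
#' the success count in cluster `a`. This equals the pooled sample
#' proportion over all valid records.
#'
#' @param summaries a `cluster_summary` (see [summarize_variable()],
#'   [cluster_summary()]).
#' @return The pooled proportion in `[0, 1]`.
#' @examples
#' ratio_estimator(cluster_summary(x = c(2, 1), y = c(2, 0)))  # 2/3
#' @export
ratio_estimator <- function(summaries) {
  stopifnot(inherits(summaries, "cluster_summary"))
  if (nrow(summaries) == 0L) stop("no cluster summaries", call. = FALSE)
  x <- sum(summaries$x)
  if (x < 1) stop("no valid observations (sum of x is 0)", call. = FALSE)
  sum(summaries$y) / x
}

# Fisher-type variance-stabilizing scale for the intraclass correlation with
# group-size coefficient k: h(p) = log((1 + (k-1) p) / (1 - p)) / k, chosen so
# that h'(p) is the reciprocal of the factor (1 - p)(1 + (k-1) p) that drives
# the asymptotic standard error of the ANOVA estimator.
icc_stab <- function(p, k) log((1 + (k - 1) * p) / (1 - p)) / k
icc_stab_inv <- function(z, k) (exp(k * z) - 1) / (exp(k * z) + k - 1)
icc_stab_deriv <- function(p, k) 1 / ((1 - p) * (1 + (k - 1) * p))

# Smith's large-sample standard error of the one-way ANOVA ICC with unequal
# group sizes, evaluated at rho; n_i are the group sizes. Reduces to the
# classical equal-size asymptotic variance when all n_i are equal.
icc_asymptotic_se <- function(rho, n_i) {
  a <- length(n_i)
  n <- sum(n_i)
  k0 <- (n - sum(n_i^2) / n) / (a - 1)
  S <- sum(n_i^2) - 2 * sum(n_i^3) / n + (sum(n_i^2) / n)^2
  v <- 2 * (1 - rho)^2 / k0^2 *
    ((1 + (k0 - 1) * rho)^2 / (n - a) +
     ((a - 1) * (1 - rho) * (1 + (2 * k0 - 1) * rho) + rho^2 * S) /
       (a - 1)^2)
  sqrt(max(v, 0))
}

#' ANOVA intraclass correlation coefficient for clustered binary data
#'
#' Fits the one-way analysis of variance of subject-level 0/1 values grouped
#' by cluster and returns the ANOVA (moment) estimator of the intraclass
#' correlation coefficient,
#' `rho = (MSB - MSW) / (MSB + (k - 1) * MSW)`,
#' where `MSB` is the between-cluster mean square on `a - 1` degrees of
#' freedom, `MSW` the within-cluster mean square on `n - a`, and `k` a
#' group-size summary. With `k_method = "adjusted"` (default), `k` is the
#' standard unequal-size coefficient `k0 = (n - sum(n_i^2)/n) / (a - 1)`;
#' with `k_method = "mean"`, `k = n / a`, which makes the estimate identical
#' to the F-statistic computing form
#' `((F - 1) * a/n) / (1 + (F - 1) * a/n)`. The two choices coincide for
#' equal cluster sizes.
#'
#' The standard error is Smith's large-sample formula for the ANOVA ICC with
#' unequal group sizes (always using `k0`). Two confidence-interval
#' constructions are offered, both clamped to `[0, 1]`:
#' `ci_method = "stabilized"` (default) applies the normal approximation on
#' the Fisher-type variance-stabilizing scale
#' `h(rho) = log((1 + (k0 - 1) rho) / (1 - rho)) / k0` via the delta method,
#' with a `t` critical value on `a - 1` degrees of freedom — the small-sample
#' convention of cluster-sample inference, where between-cluster information
#' comes from `a` PSUs. `ci_method = "wald"` is the plain symmetric interval
#' `rho +/- z * se`. The stabilized construction has markedly better
#' coverage when clusters are few and of very unequal size (the symmetric
#' interval's half-width shrinks with the point estimate, so small estimates
#' yield intervals that miss above).
#'
#' Degenerate inputs are flagged rather than raised: all values identical
#' gives `rho = 0` with flag `"constant"` and a warning; `MSW = 0` with
#' `MSB > 0` (perfect within-cluster homogeneity) gives `F = Inf`,
#' `rho = 1`, flag `"degenerate"`. A negative moment estimate is kept in
#' `rho` and clamped to 0 in `rho_reported`.
#'
#' @param values numeric (or logical) subject-level outcomes, typically 0/1;
#'   `NA` pairs are dropped.
#' @param clusters cluster id per value.
#' @param conf_level confidence level for the interval (default 0.95).
#' @param k_method `"adjusted"` (unequal-size `k0`) or `"mean"` (`n/a`).
#' @param ci_method `"stabilized"` (delta-method interval on the
#'   variance-stabilizing scale, t critical value) or `"wald"`
#'   (`rho +/- z * se`).
#' @return An object of class `icc_estimate`: list with `rho`,
#'   `rho_reported`, `se`, `ci_low`, `ci_high`, `F`, `a`, `n`, `k`, `msb`,
#'   `msw`, `flags`, `conf_level`, `ci_method`.
#' @examples
#' v <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
#' g <- rep(c("A", "B", "C"), each = 3)
#' anova_icc(v, g)$rho  # 2/3
#' @export
anova_icc <- function(values, clusters, conf_level = 0.95,
                      k_method = c("adjusted", "mean"),
                      ci_method = c("stabilized", "wald")) {
  k_method <- match.arg(k_method)
  ci_method <- match.arg(ci_method)
  values <- as.numeric(values)
  clusters <- as.character(clusters)
  stopifnot(length(values) == length(clusters))
  ok <- !is.na(values) & !is.na(clusters)
  values <- values[ok]; clusters <- clusters[ok]

  n_i <- tapply(values, clusters, length)
  a <- length(n_i)
  n <- sum(n_i)
  if (a < 2L) stop("at least 2 clusters with data are required",
                   call. = FALSE)
  if (n <= a) stop("need more observations than clusters (n > a)",
                   call. = FALSE)
  n_i <- as.numeric(n_i)

  sums <- as.numeric(tapply(values, clusters, sum))
  m_i <- sums / n_i
  m <- sum(sums) / n
  ssb <- sum(n_i * (m_i - m)^2)
  ssw <- sum(values^2) - sum(sums^2 / n_i)
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  k <- if (k_method == "adjusted") (n - sum(n_i^2) / n) / (a - 1) else n / a

  flags <- character(0)
  if (msw > 0) {
    f <- msb / msw
    rho <- (msb - msw) / (msb + (k - 1) * msw)
  } else if (msb > 0) {
    f <- Inf
    rho <- 1
    flags <- c(flags, "degenerate")
  } else {
    # every value identical: no variance to partition
    f <- NaN
    rho <- 0
    flags <- c(flags, "constant")
    warning("all values identical; ICC undefined, reported as 0",
            call. = FALSE)
  }

  if (length(flags) == 0L) {
    se <- icc_asymptotic_se(rho, n_i)
    if (ci_method == "wald") {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      ci <- clamp(rho + c(-1, 1) * z * se, 0, 1)
    } else {
      k0 <- (n - sum(n_i^2) / n) / (a - 1)
      q <- stats::qt(1 - (1 - conf_level) / 2, df = a - 1)
      p <- clamp(rho, 0, 1)  # h() needs 1 + (k0-1) p > 0
      se_z <- se * icc_stab_deriv(p, k0)
      ci <- clamp(icc_stab_inv(icc_stab(p, k0) + c(-1, 1) * q * se_z, k0),
                  0, 1)
    }
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }

  structure(list(rho = rho,
                 rho_reported = clamp(rho, 0, 1),
                 se = se, ci_low = ci[1], ci_high = ci[2],
                 F = f, a = a, n = n, k = k, k_method = k_method,
                 msb = msb, msw = msw,
                 flags = flags, conf_level = conf_level,
                 ci_method = ci_method),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf(
    "<icc_estimate> rho = %.4f (%d%% CI %.4f-%.4f), F = %.3f, a = %d, n = %d\n",
    x$rho_reported, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$F, x$a, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical design effect of the cluster ratio estimator
#'
#' The design effect is the ratio of the variance of the prevalence
#' estimator under the actual single-stage cluster design to its variance
#' under simple random sampling of the same size:
#' `deff = var_actual / var_srs` with
#' `var_actual = sum((r_a - r)^2) / (a * (a - 1))` over the unweighted
#' cluster-level ratios `r_a` (the variance of a mean of `a` cluster
#' ratios), and `var_srs = r * (1 - r) / (n - 1)` with `n` the total valid
#' denominator. Cluster ratios enter unweighted by cluster size, exactly as
#' the survey estimator is defined.
#'
#' @param summaries a `cluster_summary` with at least two clusters.
#' @return Object of class `deff_estimate`: list with `deff`, `var_actual`,
#'   `var_srs`, `r`, `a`, `n`, `flags`. A pooled ratio of exactly 0 or 1
#'   makes `var_srs = 0`; `deff` is then `NA` with flag `"degenerate"`.
#' @examples
#' s <- cluster_summary(x = c(3, 3, 3), y = c(3, 1, 0))
#' design_effect(s)$deff  # 2.8
#' @export
design_effect <- function(summaries) {
  stopifnot(inherits(summaries, "cluster_summary"))
  a <- nrow(summaries)
  if (a < 2L) stop("at least 2 clusters are required", call. = FALSE)
  if (any(summaries$x < 1)) {
    stop("clusters with x = 0 must be excluded upstream", call. = FALSE)
  }
  n <- sum(summaries$x)
  r <- ratio_estimator(summaries)
  var_actual <- sum((summaries$r - r)^2) / (a * (a - 1))
  var_srs <- r * (1 - r) / (n - 1)
  flags <- character(0)
  if (var_srs > 0) {
    deff <- var_actual / var_srs
  } else {
    deff <- NA_real_
    flags <- "degenerate"
  }
  structure(list(deff = deff, var_actual = var_actual, var_srs = var_srs,
                 r = r, a = a, n = n, flags = flags),
            class = "deff_estimate")
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf(
    "<deff_estimate> deff = %.3f (var_actual = %.3g, var_srs = %.3g), a = %d, n = %d\n",
    x$deff, x$var_actual, x$var_srs, x$a, x$n))
  invisible(x)
}

#' Cluster-corrected sample-size recalculation
#'
#' Given the number of clusters `a`, the intraclass correlation coefficient
#' of the main outcome and the design effect, the sample size required to
#' account for the cluster design is
#' `n* = (a / ICC) * (Deff - 1 + ICC)`,
#' rounded up to a whole subject. With `deff = 1` (no clustering penalty)
#' this returns `a`.
#'
#' @param a number of clusters (>= 1).
#' @param icc intraclass correlation coefficient of the main outcome; must
#'   be positive, the formula is undefined otherwise.
#' @param deff design effect (> 0).
#' @return Object of class `sample_size_result`: list with `n_star`, `a`,
#'   `icc_used`, `deff_used`.
#' @examples
#' recalc_sample_size(a = 27, icc = 0.077, deff = 21.09)$n_star  # 7072
#' @export
recalc_sample_size <- function(a, icc, deff) {
  if (!is.finite(icc) || icc <= 0) {
    stop("formula undefined for non-positive ICC", call. = FALSE)
  }
  stopifnot(is.finite(deff), deff > 0, is.finite(a), a >= 1)
  n_star <- as.integer(ceiling_safe((a / icc) * (deff - 1 + icc)))
  structure(list(n_star = n_star, a = as.integer(a),
                 icc_used = icc, deff_used = deff),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(
    "<sample_size_result> n* = %d subjects (a = %d, ICC = %.3f, DEFF = %.2f)\n",
    x$n_star, x$a, x$icc_used, x$deff_used))
  invisible(x)
}

#' Full per-variable estimation
#'
#' Composes the pipeline for one reported variable: dichotomize and
#' summarize by cluster ([summarize_variable()]), then estimate prevalence
#' ([ratio_estimator()]), intraclass correlation ([anova_icc()]) and design
#' effect ([design_effect()]). The ANOVA runs on the subject-level 0/1
#' values of the clusters that contribute at least one valid record
#' (`a_eff` groups).
#'
#' @param cohort an `svy_cohort`.
#' @param spec a [var_spec()].
#' @param conf_level,k_method,ci_method passed to [anova_icc()].
#' @return Object of class `variable_result`: list with `variable`, `block`,
#'   `P` (prevalence in percent, unrounded), `icc` (an `icc_estimate`),
#'   `deff` (a `deff_estimate`), `n_a` (mean cluster size for this variable,
#'   `round(valid_n / a_eff)`), `valid_n`, `a_eff`, `flags`. Use
#'   [as.data.frame()] for a report row rounded to the table convention
#'   (prevalence 1 decimal, ICC and CI 3, DEFF 2).
#' @export
estimate_variable <- function(cohort, spec, conf_level = 0.95,
                              k_method = c("adjusted", "mean"),
                              ci_method = c("stabilized", "wald")) {
  k_method <- match.arg(k_method)
  ci_method <- match.arg(ci_method)
  d <- dichotomize(cohort, spec)
  summaries <- summarize_variable(cohort, spec)
  a_eff <- attr(summaries, "a_eff")
  valid_n <- attr(summaries, "valid_n")
  if (a_eff < 2L) {
    stop("variable '", spec$name,
         "' has valid data in fewer than 2 clusters", call. = FALSE)
  }
  r <- ratio_estimator(summaries)
  icc <- anova_icc(d$success, d$cluster, conf_level = conf_level,
                   k_method = k_method, ci_method = ci_method)
  deff <- design_effect(summaries)
  flags <- unique(c(icc$flags, deff$flags))
  structure(list(variable = spec$name, block = spec$block,
                 P = 100 * r, icc = icc, deff = deff,
                 n_a = as.integer(round(valid_n / a_eff)),
                 valid_n = valid_n, a_eff = a_eff, flags = flags),
            class = "variable_result")
}

#' @export
print.variable_result <- function(x, ...) {
  cat(sprintf(
    "<variable_result> %s [%s]: P = %.1f%%, ICC = %.3f (CI %.3f-%.3f), DEFF = %.2f, n_a = %d\n",
    x$variable, x$block, x$P, x$icc$rho_reported, x$icc$ci_low,
    x$icc$ci_high, x$deff$deff, x$n_a))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.variable_result <- function(x, ...) {
  data.frame(variable = x$variable, block = x$block,
             P_percent = round(x$P, 1),
             ICC = round(x$icc$rho_reported, 3),
             ICC_CI_low = round(x$icc$ci_low, 3),
             ICC_CI_high = round(x$icc$ci_high, 3),
             DEFF = round(x$deff$deff, 2),
             n_a = x$n_a, a_eff = x$a_eff,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
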