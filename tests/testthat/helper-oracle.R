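# Independent from-the-definitions oracles used to cross-check the
# estimators. Deliberately written as explicit loops over groups, separate
# from the package's vectorized implementation path.

oracle_anova <- function(values, groups) {
  gs <- split(values, groups)
  a <- length(gs)
  n <- length(values)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in gs) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  ni <- vapply(gs, length, 1L)
  k0 <- (n - sum(ni^2) / n) / (a - 1)
  f <- msb / msw
  list(msb = msb, msw = msw, F = f,
       rho_k0 = (msb - msw) / (msb + (k0 - 1) * msw),
       rho_f = ((f - 1) * a / n) / (1 + (f - 1) * a / n))
}

oracle_deff <- function(x, y) {
  a <- length(x)
  n <- sum(x)
  r <- sum(y) / sum(x)
  ra <- y / x
  va <- sum((ra - r)^2) / (a * (a - 1))
  vs <- r * (1 - r) / (n - 1)
  list(var_actual = va, var_srs = vs, deff = va / vs)
}

# Random small clustered 0/1 instance with non-degenerate mean squares and a
# pooled proportion strictly inside (0, 1).
random_small_instance <- function(max_a = 5L, max_size = 6L) {
  repeat {
    a <- sample(2:max_a, 1L)
    sizes <- sample(1:max_size, a, replace = TRUE)
    if (sum(sizes) <= a) next
    values <- stats::rbinom(sum(sizes), 1L, stats::runif(1, 0.2, 0.8))
    groups <- rep(sprintf("G%02d", seq_len(a)), times = sizes)
    o <- oracle_anova(values, groups)
    r <- mean(values)
    if (o$msw > 0 && r > 0 && r < 1) {
      return(list(values = values, groups = groups, sizes = sizes))
    }
  }
}

# Per-cluster (x, y) counts from a subject-level instance.
instance_counts <- function(inst) {
  x <- as.integer(tapply(inst$values, inst$groups, length))
  y <- as.integer(tapply(inst$values, inst$groups, sum))
  list(x = x, y = y)
}

make_toy_cohort <- function() {
  # three clusters of three: {1,1,1}, {1,0,0}, {0,0,0}
  as_cohort(data.frame(cluster = rep(c("A", "B", "C"), each = 3),
                       v = c(1, 1, 1, 1, 0, 0, 0, 0, 0)),
            cluster_col = "cluster")
}

toy_spec <- function() var_spec("v", "outcome", rule_equals(1))

write_test_config <- function(path, entries) {
  writeLines(c("variables:", entries), path)
  path
}
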