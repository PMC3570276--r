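test_that("rules map raw values to success/failure and keep missing missing", {
  expect_equal(apply_rule(rule_lt(30), c("21", "35", NA)), c(TRUE, FALSE, NA))
  expect_equal(apply_rule(rule_equals("public"), c("public", "private", NA)),
               c(TRUE, FALSE, NA))
  expect_equal(apply_rule(rule_equals(1), c("1", "0", NA)), c(TRUE, FALSE, NA))
  expect_equal(apply_rule(rule_in(c("a", "b")), c("a", "c", NA)),
               c(TRUE, FALSE, NA))
  expect_equal(apply_rule(rule_ge(37), c(37, 36.9, NA)), c(TRUE, FALSE, NA))
  expect_equal(apply_rule(rule_fn(function(x) nchar(x) > 2), c("abc", "a")),
               c(TRUE, FALSE))
  # a custom rule cannot resurrect missing input
  expect_equal(apply_rule(rule_fn(function(x) rep(TRUE, length(x))),
                          c("a", NA)),
               c(TRUE, NA))
})

test_that("read_cohort builds records and a design from delimited text", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,v", "A,1", "A,0", "B,1", "B,"), f)
  co <- read_cohort(f)
  expect_s3_class(co, "svy_cohort")
  expect_equal(co$design$a, 2L)
  expect_equal(co$design$n, 4L)
  expect_equal(co$design$b_bar, 2)
  expect_true(is.na(co$data$v[4]))  # empty cell is missing, not 0
})

test_that("malformed or misconfigured input fails loudly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,v", "A,1", ",0", "B,1"), f)
  expect_error(read_cohort(f), "rows without a cluster id: 2")

  writeLines(c("center,v", "A,1"), f)
  expect_error(read_cohort(f, cluster_col = "cluster"), "cluster column")

  writeLines("cluster,v", f)
  expect_error(read_cohort(f), "empty")

  writeLines(c("cluster,v", "A,1", "B,0"), f)
  schema <- list(var_spec("w", "outcome", rule_equals(1)))
  expect_error(read_cohort(f, schema = schema), "'w'")
})

test_that("summarize_variable tallies valid and success counts per cluster", {
  co <- as_cohort(data.frame(cluster = c("A", "A", "B", "B"),
                             v = c("1", "1", "0", NA)))
  s <- summarize_variable(co, var_spec("v", "outcome", rule_equals(1)))
  expect_equal(s$cluster_id, c("A", "B"))
  expect_equal(s$x, c(2L, 1L))
  expect_equal(s$y, c(2L, 0L))
  expect_equal(s$r, c(1, 0))
  expect_equal(attr(s, "valid_n"), 3L)
  expect_equal(attr(s, "a_eff"), 2L)
})

test_that("subpopulation rules restrict the denominator", {
  co <- as_cohort(data.frame(
    cluster = c("A", "A", "A", "B", "B"),
    abortion = c("1", "1", "0", "1", NA),
    dc = c("1", "0", "1", "1", "1")))
  spec <- var_spec("dc", "process", rule_equals(1),
                   subpopulation = list(variable = "abortion",
                                        rule = rule_equals(1)))
  s <- summarize_variable(co, spec)
  # only the three abortion cases count; the NA subpopulation row is out
  expect_equal(attr(s, "valid_n"), 3L)
  expect_equal(sum(s$y), 2L)
})

test_that("clusters with no valid observation are dropped and recorded", {
  co <- as_cohort(data.frame(cluster = c("A", "A", "B", "C"),
                             v = c("1", "0", NA, "1")))
  s <- summarize_variable(co, var_spec("v", "outcome", rule_equals(1)))
  expect_equal(attr(s, "a_eff"), 2L)
  expect_equal(attr(s, "excluded_clusters"), "B")

  co2 <- as_cohort(data.frame(cluster = c("A", "B"), v = c(NA, NA)))
  expect_error(
    summarize_variable(co2, var_spec("v", "outcome", rule_equals(1))),
    "no valid observations")
})

test_that("summaries are invariant to record and cluster order", {
  set.seed(101)
  df <- data.frame(cluster = sample(c("C3", "C1", "C2"), 60, replace = TRUE),
                   v = sample(c("1", "0", NA), 60, replace = TRUE))
  co1 <- as_cohort(df)
  co2 <- as_cohort(df[sample(nrow(df)), , drop = FALSE])
  spec <- var_spec("v", "outcome", rule_equals(1))
  s1 <- summarize_variable(co1, spec)
  s2 <- summarize_variable(co2, spec)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  # counting invariant: sum(y) <= sum(x) <= records
  expect_lte(sum(s1$y), sum(s1$x))
  expect_lte(sum(s1$x), nrow(df))
})

test_that("cluster summaries survive a write/read round trip exactly", {
  s <- cluster_summary(x = c(7L, 3L, 13L), y = c(2L, 1L, 5L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cluster_summaries(s, f)
  s2 <- read_cluster_summaries(f)
  expect_identical(s2$x, s$x)
  expect_identical(s2$y, s$y)
  expect_identical(s2$r, s$r)
  expect_identical(s2$cluster_id, s$cluster_id)
})

test_that("the 27-center design has the documented structure", {
  sizes <- network_cluster_sizes()
  expect_length(sizes, 27L)
  expect_equal(sum(sizes), 9555L)
  d <- cohort_design(sizes)
  expect_equal(d$a, 27L)
  expect_equal(round(d$b_bar, 1), 353.9)
})

test_that("a full-size generated file reads back to the network design", {
  f <- withr::local_tempfile(fileext = ".csv")
  co <- generate_cohort(sim_scenario(mu = 0.1, rho = 0.05, seed = 5))
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$design$a, 27L)
  expect_equal(back$design$n, 9555L)
  expect_equal(round(back$design$b_bar), 354)
})

test_that("YAML variable configs parse into specs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_test_config(f, c(
    "  - name: age_lt30",
    "    variable: age",
    "    block: personal",
    "    success: {op: lt, value: 30}",
    "  - name: dc_procedure",
    "    variable: dc",
    "    block: process",
    "    success: {op: equals, value: '1'}",
    "    subpopulation: {variable: abortion, op: equals, value: '1'}"))
  specs <- read_variable_config(f)
  expect_named(specs, c("age_lt30", "dc_procedure"))
  expect_equal(specs$age_lt30$block, "personal")
  expect_equal(specs$age_lt30$variable, "age")
  expect_equal(specs$dc_procedure$subpopulation$variable, "abortion")
  expect_equal(apply_rule(specs$age_lt30$success, c("29", "31")),
               c(TRUE, FALSE))

  write_test_config(f, c("  - name: broken", "    block: process"))
  expect_error(read_variable_config(f), "without 'success'")
  write_test_config(f, c("  - name: broken", "    block: process",
                         "    success: {op: sqrt, value: 1}"))
  expect_error(read_variable_config(f), "unknown rule op")
})
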