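#' Dichotomization rules
#'
#' A rule maps a raw column of subject-level values to success
#' (`TRUE`), failure (`FALSE`) or missing (`NA`). Rules are the declarative
#' building blocks of a [var_spec()]: the surveillance tables contain on the
#' order of 150 variables that differ only in how a raw chart value is
#' dichotomized ("age < 30 years", "insurance == public", ...), so the rule —
#' not the variable — carries the logic. Missing input always maps to missing
#' output; a missing marker is never coerced to failure.
#'
#' @param value,values the reference value(s) the raw column is compared to.
#' @param threshold numeric cut-point; raw values are coerced to numeric.
#' @param fn a vectorized function returning logical (with `NA` allowed).
#' @param label optional human-readable description used in printing.
#'
#' @return An object of class `svy_rule`.
#' @examples
#' apply_rule(rule_lt(30), c(21, 35, NA))   # TRUE FALSE NA
#' apply_rule(rule_equals("public"), c("public", "private"))
#' @name rules
NULL

new_rule <- function(op, label, ...) {
  structure(list(op = op, label = label, ...), class = "svy_rule")
}

#' @rdname rules
#' @export
rule_equals <- function(value) {
  stopifnot(length(value) == 1L)
  new_rule("equals", paste0("== ", value), value = value)
}

#' @rdname rules
#' @export
rule_in <- function(values) {
  stopifnot(length(values) >= 1L)
  new_rule("in", paste0("in {", paste(values, collapse = ", "), "}"),
           values = values)
}

#' @rdname rules
#' @export
rule_lt <- function(threshold) new_rule("lt", paste0("< ", threshold),
                                        threshold = as.numeric(threshold))

#' @rdname rules
#' @export
rule_le <- function(threshold) new_rule("le", paste0("<= ", threshold),
                                        threshold = as.numeric(threshold))

#' @rdname rules
#' @export
rule_gt <- function(threshold) new_rule("gt", paste0("> ", threshold),
                                        threshold = as.numeric(threshold))

#' @rdname rules
#' @export
rule_ge <- function(threshold) new_rule("ge", paste0(">= ", threshold),
                                        threshold = as.numeric(threshold))

#' @rdname rules
#' @export
rule_fn <- function(fn, label = "custom") {
  stopifnot(is.function(fn))
  new_rule("fn", label, fn = fn)
}

#' @export
print.svy_rule <- function(x, ...) {
  cat("<rule:", x$label, ">\n")
  invisible(x)
}

#' Apply a dichotomization rule to a vector of raw values
#'
#' @param rule an `svy_rule` created by one of the [rules] constructors.
#' @param x vector of raw values (character or numeric); `NA` is missing.
#' @return logical vector, `NA` wherever `x` is missing (or not coercible to
#'   numeric for threshold rules).
#' @export
apply_rule <- function(rule, x) {
  stopifnot(inherits(rule, "svy_rule"))
  out <- switch(rule$op,
    equals = {
      if (is.character(rule$value)) as.character(x) == rule$value
      else suppressWarnings(as.numeric(x)) == as.numeric(rule$value)
    },
    "in" = {
      xs <- if (is.character(rule$values)) as.character(x)
            else suppressWarnings(as.numeric(x))
      res <- xs %in% rule$values
      res[is.na(xs)] <- NA
      res
    },
    lt = suppressWarnings(as.numeric(x)) < rule$threshold,
    le = suppressWarnings(as.numeric(x)) <= rule$threshold,
    gt = suppressWarnings(as.numeric(x)) > rule$threshold,
    ge = suppressWarnings(as.numeric(x)) >= rule$threshold,
    fn = {
      res <- rule$fn(x)
      stopifnot(is.logical(res), length(res) == length(x))
      res
    },
    stop("unknown rule op: ", rule$op)
  )
  out[is.na(x)] <- NA  # missing in, missing out — regardless of rule
  out
}

#' Variable specification
#'
#' Describes how one reported variable is derived from the subject table: the
#' source column, the success rule that dichotomizes it, the block it is
#' reported under (process of care, clinical outcome, personal/obstetric
#' characteristics, or structure of the service), and optionally a
#' subpopulation restriction that narrows the denominator (e.g. "among
#' abortion cases"). Records failing the subpopulation predicate — or missing
#' it — are excluded from the variable's denominator entirely.
#'
#' @param name display name of the variable (used in reports).
#' @param block one of `"process"`, `"outcome"`, `"personal"`, `"structure"`.
#' @param success an `svy_rule` defining success on the raw column.
#' @param variable source column name in the subject table; defaults to `name`.
#' @param subpopulation optional list `list(variable =, rule =)` restricting
#'   the denominator to records where `rule` evaluates `TRUE` on that column.
#' @return An object of class `var_spec`.
#' @examples
#' var_spec("age_lt30", "personal", rule_lt(30), variable = "age")
#' @export
var_spec <- function(name, block, success, variable = name,
                     subpopulation = NULL) {
  block <- match.arg(block, c("process", "outcome", "personal", "structure"))
  stopifnot(is.character(name), nzchar(name), inherits(success, "svy_rule"))
  if (!is.null(subpopulation)) {
    stopifnot(is.list(subpopulation),
              is.character(subpopulation$variable),
              inherits(subpopulation$rule, "svy_rule"))
  }
  structure(list(name = name, variable = variable, block = block,
                 success = success, subpopulation = subpopulation),
            class = "var_spec")
}

#' @export
print.var_spec <- function(x, ...) {
  cat("<var_spec>", x$name, sprintf("[%s]", x$block), "\n")
  cat("  column:", x$variable, " success:", x$success$label, "\n")
  if (!is.null(x$subpopulation)) {
    cat("  subpopulation:", x$subpopulation$variable,
        x$subpopulation$rule$label, "\n")
  }
  invisible(x)
}

rule_from_config <- function(cfg, where) {
  known <- c("equals", "in", "lt", "le", "gt", "ge")
  op <- cfg$op %||% stop("rule in ", where, " has no 'op'", call. = FALSE)
  if (!op %in% known) {
    stop("unknown rule op '", op, "' in ", where, call. = FALSE)
  }
  val <- cfg$value %||% cfg$values %||%
    stop("rule in ", where, " has no 'value'", call. = FALSE)
  switch(op,
    equals = rule_equals(val),
    "in"   = rule_in(unlist(val)),
    lt = rule_lt(val), le = rule_le(val),
    gt = rule_gt(val), ge = rule_ge(val))
}

#' Read a variable-dichotomization configuration
#'
#' Parses a YAML file with a top-level `variables:` list; each entry has
#' `name`, `block`, a `success` rule (`op` + `value`), and optionally
#' `variable` (source column) and `subpopulation` (`variable` + `op` +
#' `value`). See `system.file("extdata", "example_config.yaml",
#' package = "svyicc")` for a worked example.
#'
#' @param path path to the YAML config.
#' @return A named list of [var_spec()] objects.
#' @export
read_variable_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables) || length(cfg$variables) == 0L) {
    stop("config has no 'variables' entries: ", path, call. = FALSE)
  }
  specs <- lapply(cfg$variables, function(v) {
    nm <- v$name %||% stop("config entry without 'name'", call. = FALSE)
    sub <- NULL
    if (!is.null(v$subpopulation)) {
      sub <- list(variable = v$subpopulation$variable,
                  rule = rule_from_config(v$subpopulation,
                                          paste0("subpopulation of ", nm)))
    }
    var_spec(
      name = nm,
      block = v$block %||% stop("config entry '", nm, "' without 'block'",
                                call. = FALSE),
      success = rule_from_config(
        v$success %||% stop("config entry '", nm, "' without 'success'",
                            call. = FALSE),
        paste0("variable ", nm)),
      variable = v$variable %||% nm,
      subpopulation = sub
    )
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
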