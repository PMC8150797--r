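#' Construct an indicator rule set
#'
#' A rule set maps each origin to one numeric range per indicator variable.
#' A sample is attributed to an origin only if **all** its indicator values
#' fall inside that origin's ranges; samples matching no origin receive the
#' fallback label (`"neither"` — in the three-origin red pepper problem such
#' samples are Chinese by elimination), and samples matching more than one
#' origin receive the explicit sentinel `"ambiguous"`.
#'
#' @param origins Named list: for each origin, a list of ranges, each a list
#'   with `variable`, `lower`, `upper` (either may be `NULL`/`NA` for a
#'   one-sided range), `lower_inclusive`, `upper_inclusive`.
#' @param application_order Order in which origin rule sets are applied
#'   (retained for reporting; evaluation is exhaustive, so results are
#'   order-independent by construction).
#' @param fallback_label Label for samples matching no origin.
#' @return An object of class `indicator_rules`.
#' @export
indicator_rules <- function(origins, application_order = names(origins),
                            fallback_label = "neither") {
  stopifnot(is.list(origins), length(origins) >= 1L)
  vars <- lapply(origins, function(rl) sort(vapply(rl, `[[`, "", "variable")))
  if (length(unique(vars)) != 1L)
    stop("every origin must cover the same indicator variables")
  for (o in names(origins)) for (r in origins[[o]]) {
    lo <- r$lower; up <- r$upper
    lo_ok <- !is.null(lo) && !is.na(lo); up_ok <- !is.null(up) && !is.na(up)
    if (!lo_ok && !up_ok)
      stop(sprintf("range for %s/%s has no bounds", o, r$variable))
    if (lo_ok && up_ok && lo >= up)
      stop(sprintf("range for %s/%s has lower >= upper", o, r$variable))
  }
  if (!setequal(application_order, names(origins)))
    stop("application_order must be a permutation of the origin names")
  structure(list(origins = origins,
                 variables = vars[[1]],
                 application_order = application_order,
                 fallback_label = fallback_label),
            class = "indicator_rules")
}

#' @export
print.indicator_rules <- function(x, ...) {
  cat("Indicator rule set (order:",
      paste(x$application_order, collapse = " -> "),
      "; fallback:", x$fallback_label, ")\n")
  for (o in x$application_order) {
    cat(" ", o, ":\n")
    for (r in x$origins[[o]]) cat("    ", r$variable, " ",
                                  format_range(r), "\n", sep = "")
  }
  invisible(x)
}

format_range <- function(r) {
  lo <- if (!is.null(r$lower) && !is.na(r$lower)) r$lower else NULL
  up <- if (!is.null(r$upper) && !is.na(r$upper)) r$upper else NULL
  if (is.null(lo)) sprintf("%s%g", if (isTRUE(r$upper_inclusive)) "<=" else "<", up)
  else if (is.null(up)) sprintf("%s%g", if (isTRUE(r$lower_inclusive)) ">=" else ">", lo)
  else sprintf("%g-%g", lo, up)
}

#' The packaged reference rule set
#'
#' The published indicator ranges for Korean and Vietnamese red pepper
#' powders over P8, P12, P14 and P17 (printed `<`/`>` bounds are strict;
#' `a-b` intervals are inclusive at both ends). Chinese samples carry no
#' rule set and are identified by elimination ("neither").
#'
#' @return An [indicator_rules] object.
#' @export
reference_rules <- function() {
  read_rules(system.file("extdata", "indicator_ranges.json",
                         package = "ftirorigin"))
}

#' Read / write rule sets as JSON
#' @param path JSON file path.
#' @return [read_rules]: an [indicator_rules] object.
#' @export
read_rules <- function(path) {
  o <- jsonlite::read_json(path)
  indicator_rules(o$origins,
                  application_order = unlist(o$application_order),
                  fallback_label = o$fallback_label %||% "neither")
}

#' @rdname read_rules
#' @param rules An [indicator_rules] object.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "indicator_rules"))
  jsonlite::write_json(list(application_order = rules$application_order,
                            fallback_label = rules$fallback_label,
                            origins = rules$origins),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select indicator variables
#'
#' Ranks candidate variables by a composite of discriminating strength: the
#' rank of the ANOVA F statistic plus the rank of the largest absolute
#' structure-matrix correlation across functions (smaller composite =
#' stronger; ties broken by F). On the published screening statistics and
#' structure matrix this returns P8, P12, P14 and P17.
#'
#' @param screening A `screening_result` (or any data frame with `variable`
#'   and `F` columns).
#' @param structure Structure matrix: variables x functions, with variable
#'   rownames, or a data frame with a `variable` column.
#' @param n Number of indicators to select (default 4).
#' @return Character vector of `n` variable labels, ordered by rank.
#' @export
select_indicators <- function(screening, structure, n = 4) {
  sc <- as.data.frame(screening)
  sc <- sc[!is.na(sc$F), c("variable", "F")]
  if (is.data.frame(structure) && "variable" %in% names(structure)) {
    rn <- structure$variable
    structure <- as.matrix(structure[setdiff(names(structure), "variable")])
    rownames(structure) <- rn
  }
  common <- intersect(sc$variable, rownames(structure))
  if (n > length(common))
    stop("n exceeds the number of screened variables with structure entries")
  sc <- sc[match(common, sc$variable), ]
  smax <- apply(abs(structure[common, , drop = FALSE]), 1, max)
  composite <- rank(-sc$F) + rank(-smax)
  ord <- order(composite, -sc$F)
  sc$variable[ord][seq_len(n)]
}

#' Derive indicator ranges from a labeled peak table
#'
#' For each indicator variable, origins are ordered by their group means:
#' the lowest-lying origin receives an upper bound (its own maximum), the
#' highest a lower bound (its own minimum), and intermediate origins a
#' two-sided range. The `"quantile"` strategy replaces minima/maxima with
#' the `q`/`1-q` sample quantiles, trading training-set coverage for
#' tighter, more robust ranges. Derived bounds are inclusive.
#'
#' @param table Labeled [peak_table] containing all indicator variables.
#' @param indicators Character vector of indicator variable labels.
#' @param origins Origins to build rules for (default: all origins present).
#'   The published rule set covers Korean and Vietnamese only; Chinese
#'   ranges overlap both and are left to elimination.
#' @param strategy `"extremum"` (default) or `"quantile"`.
#' @param q Tail probability for the quantile strategy (default 0.05).
#' @param fallback_label Passed to [indicator_rules].
#' @return An [indicator_rules] object.
#' @export
derive_ranges <- function(table, indicators,
                          origins = sort(unique(table$origin)),
                          strategy = c("extremum", "quantile"), q = 0.05,
                          fallback_label = "neither") {
  strategy <- match.arg(strategy)
  table <- peak_table(table)
  missing <- setdiff(indicators, names(table))
  if (length(missing))
    stop("table lacks indicator variable(s): ",
         paste(missing, collapse = ", "))
  if (length(bad <- setdiff(origins, unique(table$origin))))
    stop("group absent from table: ", paste(bad, collapse = ", "))
  lo_fun <- function(x) if (strategy == "extremum") min(x)
                        else as.numeric(stats::quantile(x, q))
  hi_fun <- function(x) if (strategy == "extremum") max(x)
                        else as.numeric(stats::quantile(x, 1 - q))
  rules <- lapply(origins, function(o) {
    lapply(indicators, function(v) {
      by_g <- split_by_origin(table, v)
      if (length(by_g[[o]]) < 2L)
        warning(sprintf("degenerate range for %s/%s: only one training sample",
                        o, v))
      pos <- rank(vapply(by_g, mean, numeric(1)))[[o]]
      r <- list(variable = v, lower = NA_real_, upper = NA_real_,
                lower_inclusive = TRUE, upper_inclusive = TRUE)
      if (pos > 1) r$lower <- lo_fun(by_g[[o]])
      if (pos < length(by_g)) r$upper <- hi_fun(by_g[[o]])
      if (is.na(r$lower) && is.na(r$upper)) { # single group: keep both extrema
        r$lower <- lo_fun(by_g[[o]]); r$upper <- hi_fun(by_g[[o]])
      }
      r
    })
  })
  names(rules) <- origins
  indicator_rules(rules, application_order = origins,
                  fallback_label = fallback_label)
}

range_matches <- function(r, value) {
  lo <- r$lower; up <- r$upper
  ok <- TRUE
  if (!is.null(lo) && !is.na(lo))
    ok <- ok && (if (isTRUE(r$lower_inclusive)) value >= lo else value > lo)
  if (!is.null(up) && !is.na(up))
    ok <- ok && (if (isTRUE(r$upper_inclusive)) value <= up else value < up)
  ok
}

#' Classify one sample with an indicator rule set
#'
#' Evaluates every origin's ranges exhaustively: exactly one match returns
#' that origin; none returns the fallback label; more than one returns
#' `"ambiguous"` (so rule-set overlap is explicit, never hidden by the
#' application order).
#'
#' @param rules An [indicator_rules] object.
#' @param row Named numeric vector or one-row data frame containing all rule
#'   variables.
#' @return A single label.
#' @export
apply_rules <- function(rules, row) {
  stopifnot(inherits(rules, "indicator_rules"))
  if (is.data.frame(row)) row <- unlist(row[vapply(row, is.numeric, TRUE)])
  missing <- setdiff(rules$variables, names(row))
  if (length(missing))
    stop("row is missing variable(s): ", paste(missing, collapse = ", "))
  matches <- vapply(rules$application_order, function(o) {
    all(vapply(rules$origins[[o]],
               function(r) range_matches(r, row[[r$variable]]), logical(1)))
  }, logical(1))
  if (sum(matches) == 0L) rules$fallback_label
  else if (sum(matches) == 1L) rules$application_order[matches]
  else "ambiguous"
}

#' @export
predict.indicator_rules <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  vapply(seq_len(nrow(newdata)),
         function(i) apply_rules(object, newdata[i, , drop = FALSE]),
         character(1))
}

#' Evaluate a rule set against a labeled peak table
#'
#' Applies [apply_rules] to every row and tabulates true origin against the
#' predicted label (including the fallback and `"ambiguous"` sentinels).
#' Also re-evaluates under the reversed application order and reports
#' whether the labels are unchanged (they always are unless two origins'
#' ranges overlap, which surfaces as `"ambiguous"`).
#'
#' @param rules An [indicator_rules] object.
#' @param table Labeled [peak_table].
#' @return A `rules_evaluation`: list with `predictions` (data frame),
#'   `table` (contingency), `counts` (per predicted label), and
#'   `order_invariant` (logical).
#' @export
evaluate_rules <- function(rules, table) {
  table <- as.data.frame(table)
  if (!nrow(table)) {
    out <- list(predictions = data.frame(), table = table(character(0)),
                counts = integer(0), order_invariant = TRUE)
    class(out) <- "rules_evaluation"
    return(out)
  }
  pred <- predict(rules, table)
  swapped <- rules
  swapped$application_order <- rev(rules$application_order)
  pred_swap <- predict(swapped, table)
  preds <- data.frame(sample_id = table$sample_id %||% seq_len(nrow(table)),
                      origin = table$origin, predicted = pred,
                      stringsAsFactors = FALSE)
  out <- list(predictions = preds,
              table = table(origin = table$origin, predicted = pred),
              counts = table(factor(pred, levels = c(
                rules$application_order, rules$fallback_label, "ambiguous"))),
              order_invariant = identical(pred, pred_swap))
  class(out) <- "rules_evaluation"
  out
}

#' @export
print.rules_evaluation <- function(x, ...) {
  cat("Indicator-rule evaluation\n")
  if (length(x$counts)) {
    print(x$table)
    cat("Counts:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
    cat("Order-swap invariant:", x$order_invariant, "\n")
  } else cat("  (empty table)\n")
  invisible(x)
}
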