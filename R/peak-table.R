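#' Construct or validate a peak table
#'
#' A peak table holds one row per sample: a `sample_id` column, an optional
#' `origin` label, and normalized second-derivative peak variables in columns
#' named `P1`...`P18`. Values are dimensionless ratios to the 1008 cm^-1
#' reference band (P19), which is excluded by construction (its normalized
#' value is identically 1).
#'
#' @param x A data frame with `sample_id`, optionally `origin`, and one or
#'   more `P<k>` columns.
#' @return `x` with class `peak_table` prepended.
#' @export
peak_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("peak table needs a sample_id column")
  if (!"origin" %in% names(x)) x$origin <- NA_character_
  pv <- grep("^P[0-9]+$", names(x), value = TRUE)
  if (!length(pv)) stop("peak table has no peak-variable columns (P1...P18)")
  if ("P19" %in% pv)
    stop("P19 is the normalizer and must not appear in a peak table")
  vals <- as.matrix(x[pv])
  if (!all(is.finite(vals))) stop("peak table contains non-finite values")
  if (any(vals < 0)) stop("peak variables are absolute amplitudes; negative ",
                          "values are not allowed")
  class(x) <- unique(c("peak_table", class(x)))
  x
}

#' Peak-variable column names of a peak table
#' @param table A [peak_table] (or plain data frame).
#' @return Character vector of `P<k>` column names, in numeric order.
#' @export
peak_vars <- function(table) {
  pv <- grep("^P[0-9]+$", names(table), value = TRUE)
  pv[order(as.integer(sub("^P", "", pv)))]
}

#' Write a peak table to CSV
#'
#' One row per sample with columns `sample_id`, `origin`, then the peak
#' variables; numeric values rendered with 9 significant digits so that
#' write/read round-trips preserve them well beyond reporting precision.
#'
#' @param table A [peak_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  table <- peak_table(table)
  pv <- peak_vars(table)
  if (!nrow(table)) stop("refusing to write an empty peak table")
  out <- data.frame(sample_id = table$sample_id, origin = table$origin,
                    stringsAsFactors = FALSE)
  for (v in pv) out[[v]] <- sprintf("%.9g", table[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a peak table from CSV
#' @param path CSV path as written by [write_peak_table] (or hand-made with
#'   the same columns).
#' @return A [peak_table].
#' @export
read_peak_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$origin[x$origin %in% c("", "unknown")] <- NA_character_
  peak_table(x)
}

#' @export
print.peak_table <- function(x, ...) {
  pv <- peak_vars(x)
  cat(sprintf("Peak table: %d samples x %d variables (%s)\n", nrow(x),
              length(pv), paste(range(pv), collapse = "-")))
  tab <- table(x$origin, useNA = "ifany")
  cat("  origins:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  NextMethod()
}

# values of one variable split by origin, dropping unlabeled rows
split_by_origin <- function(table, variable) {
  lab <- !is.na(table$origin)
  split(table[[variable]][lab], table$origin[lab])
}
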