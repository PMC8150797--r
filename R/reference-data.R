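#' Packaged reference statistics and blind samples
#'
#' Small published reference tables shipped with the package:
#' `reference_group_tests()` returns the per-variable group-mean equality
#' statistics (Wilks' lambda, F, degrees of freedom) for the eight
#' homogeneous peak variables of the 86-sample red pepper study set;
#' `reference_structure_matrix()` the corresponding variables x functions
#' structure matrix; `reference_blind_peaks()` the indicator-variable values
#' of the 19 blind red pepper samples with their true origins.
#'
#' @return A data frame (see Details above); `reference_structure_matrix`
#'   returns a numeric matrix with variable rownames.
#' @export
reference_group_tests <- function() {
  utils::read.csv(system.file("extdata", "group_mean_tests.csv",
                              package = "ftirorigin"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_group_tests
#' @export
reference_structure_matrix <- function() {
  x <- utils::read.csv(system.file("extdata", "structure_matrix.csv",
                                   package = "ftirorigin"),
                       stringsAsFactors = FALSE)
  m <- as.matrix(x[c("function1", "function2")])
  rownames(m) <- x$variable
  m
}

#' @rdname reference_group_tests
#' @export
reference_blind_peaks <- function() {
  read_peak_table(system.file("extdata", "blind_peaks.csv",
                              package = "ftirorigin"))
}
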