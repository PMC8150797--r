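#' Canonical discriminant analysis
#'
#' Fits canonical discriminant functions: linear combinations of the peak
#' variables that maximize between-group relative to within-group scatter.
#' The generalized eigenproblem `B a = lambda W a` (B between-groups, W
#' within-groups scatter) is solved through a Cholesky factorization of the
#' pooled within-group covariance for numerical stability. With k groups at
#' most `k - 1` functions exist (two for the three-origin problem).
#' Coefficients are scaled so canonical scores have unit pooled within-group
#' variance and zero pooled within-group correlation between functions; each
#' function is signed so its largest-magnitude coefficient is positive.
#'
#' @param x A formula such as `origin ~ P5 + P7 + P8` (or `origin ~ .` over
#'   all peak variables), or a data frame / matrix of predictor columns.
#' @param ... Further arguments passed to methods.
#' @return An object of class `cda` with components `variables`, `groups`,
#'   `counts`, `prior`, `means` (group means), `grand_mean`, `pooled_cov`,
#'   `coefficients` (raw canonical coefficients, variables x functions),
#'   `constants`, `eigenvalues`, `pct_variance`, `centroids` (group mean
#'   scores), `structure` (pooled within-group variable-score correlations),
#'   `scores` and `labels` (training scores/labels, for plotting), `call`.
#' @examples
#' tbl <- simulate_peak_table(seed = 1)
#' fit <- cda(origin ~ P8 + P12 + P14 + P17, data = tbl)
#' summary(fit)
#' head(predict(fit)$class)
#' @export
cda <- function(x, ...) UseMethod("cda")

#' @rdname cda
#' @param formula Model formula with the grouping factor on the left.
#' @param data A labeled [peak_table] (or data frame).
#' @param priors `"equal"` (default), `"proportional"`, or a numeric vector
#'   of prior probabilities over groups (summing to 1).
#' @export
cda.formula <- function(formula, data, priors = "equal", ...) {
  data <- as.data.frame(data)
  if (length(formula) == 3L && identical(as.character(formula[[3]]), ".")) {
    pv <- grep("^P[0-9]+$", names(data), value = TRUE)
    formula <- stats::reformulate(pv, response = formula[[2]])
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  grouping <- factor(mf[[1]])
  xm <- as.matrix(mf[-1])
  fit <- cda_core(xm, grouping, priors = priors)
  fit$call <- match.call()
  if ("sample_id" %in% names(data)) fit$sample_id <- data$sample_id
  fit
}

#' @rdname cda
#' @param grouping Factor of group labels (default method).
#' @export
cda.default <- function(x, grouping, priors = "equal", ...) {
  fit <- cda_core(as.matrix(x), factor(grouping), priors = priors)
  fit$call <- match.call()
  fit
}

cda_core <- function(x, grouping, priors = "equal") {
  if (anyNA(x) || anyNA(grouping)) stop("missing values in predictors/labels")
  grouping <- droplevels(grouping)
  groups <- levels(grouping)
  k <- length(groups); p <- ncol(x); n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  vars <- colnames(x)
  counts <- as.integer(table(grouping))
  if (any(counts < 2L)) stop("every group needs at least 2 samples")
  prior <- resolve_priors(priors, counts, groups)

  means <- rowsum(x, grouping) / counts          # k x p group means
  grand <- colMeans(x)
  xc <- x - means[as.integer(grouping), , drop = FALSE]
  W <- crossprod(xc)                             # within-groups scatter
  Sw <- W / (n - k)                              # pooled within covariance
  md <- sweep(means, 2, grand)
  B <- crossprod(md * sqrt(counts))              # between-groups scatter

  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < sqrt(.Machine$double.eps) * max(diag(R)))) {
    qrW <- qr(Sw)
    bad <- vars[-qrW$pivot[seq_len(qrW$rank)]]
    stop("pooled within-group scatter is singular; collinear variables: ",
         paste(if (length(bad)) bad else "(numerically rank-deficient)",
               collapse = ", "))
  }
  Ri <- backsolve(R, diag(p))
  K <- crossprod(Ri, B %*% Ri) / (n - k)         # symmetric; eig = lambda
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  m <- min(k - 1L, p)
  lambda <- pmax(eg$values[seq_len(m)], 0)       # eigenvalues of W^-1 B
  A <- Ri %*% eg$vectors[, seq_len(m), drop = FALSE]  # a' Sw a = I

  # deterministic sign: largest-|coefficient| positive per function
  for (j in seq_len(m)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(vars, paste0("LD", seq_len(m)))
  constants <- -as.numeric(crossprod(A, grand))
  names(constants) <- colnames(A)

  scores <- sweep(x %*% A, 2, -constants)        # x %*% A + constants
  centroids <- rowsum(scores, grouping) / counts
  dimnames(centroids) <- list(groups, colnames(A))

  structure_mat <- pooled_structure(x, scores, grouping)

  out <- list(variables = vars, groups = groups, counts = counts,
              prior = prior, means = means, grand_mean = grand,
              pooled_cov = Sw, coefficients = A, constants = constants,
              eigenvalues = lambda,
              pct_variance = if (sum(lambda) > 0) 100 * lambda / sum(lambda)
                             else rep(0, m),
              centroids = centroids, structure = structure_mat,
              scores = scores, labels = grouping, df_within = n - k)
  class(out) <- "cda"
  out
}

resolve_priors <- function(priors, counts, groups) {
  k <- length(groups)
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    pr <- if (priors == "equal") rep(1 / k, k) else counts / sum(counts)
  } else {
    pr <- as.numeric(priors)
    if (length(pr) != k || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("numeric priors must be one non-negative value per group, summing to 1")
  }
  stats::setNames(pr, groups)
}

# pooled within-group correlation of each variable with each score
pooled_structure <- function(x, scores, grouping) {
  counts <- as.integer(table(grouping))
  xm <- rowsum(x, grouping) / counts
  sm <- rowsum(scores, grouping) / counts
  xr <- x - xm[as.integer(grouping), , drop = FALSE]
  sr <- scores - sm[as.integer(grouping), , drop = FALSE]
  num <- crossprod(xr, sr)
  vx <- colSums(xr^2); vs <- colSums(sr^2)
  st <- num / sqrt(outer(vx, vs))
  st[vx == 0, ] <- NA_real_
  dimnames(st) <- list(colnames(x), colnames(scores))
  st
}

#' Structure matrix of a fitted CDA model
#'
#' Pooled within-group Pearson correlations between each (group-mean
#' centered) variable and each canonical score; the standard aid for
#' interpreting which bands drive each function. By default the training
#' data stored in the fit are used; `total = TRUE` gives plain total-sample
#' correlations instead.
#'
#' @param model A [cda] fit.
#' @param table Optional data to recompute on (must contain the model
#'   variables and origin labels).
#' @param total Use total-sample rather than pooled within-group
#'   correlations.
#' @return Variables x functions matrix of correlations.
#' @export
structure_matrix <- function(model, table = NULL, total = FALSE) {
  stopifnot(inherits(model, "cda"))
  if (is.null(table)) {
    if (!total) return(model$structure)
    x <- NULL # recompute from stored scores is not possible without raw x
    stop("total-sample correlations require the training table")
  }
  x <- as.matrix(as.data.frame(table)[model$variables])
  sc <- project(model, table)
  if (total) return(stats::cor(x, sc))
  g <- factor(table$origin, levels = model$groups)
  pooled_structure(x, sc, g)
}

#' Project rows into canonical-score space
#'
#' `scores = X %*% coefficients + constants`; an affine map, so projecting a
#' group-centroid variable vector returns that group's centroid scores.
#'
#' @param model A [cda] fit.
#' @param newdata Data frame (or named vector for one row) containing the
#'   model variables.
#' @return Numeric matrix of scores (rows x functions).
#' @export
project <- function(model, newdata) {
  stopifnot(inherits(model, "cda"))
  if (is.null(dim(newdata)) && !is.data.frame(newdata))
    newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(model$variables, colnames(newdata))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[model$variables])
  sweep(x %*% model$coefficients, 2, -model$constants)
}

#' Classify samples with a fitted CDA model
#'
#' Posterior probabilities follow the linear discriminant model in
#' canonical-score space, where the pooled within-group covariance is the
#' identity by construction:
#' `posterior_g = prior_g * exp(-d_g^2 / 2) / sum_h prior_h * exp(-d_h^2 / 2)`
#' with `d_g` the Euclidean distance to centroid g.
#'
#' @param object A [cda] fit.
#' @param newdata Data containing the model variables; defaults to the
#'   training scores (resubstitution).
#' @param prior Optional prior override (as in [cda]).
#' @param ... Unused.
#' @return List with `class` (factor), `posterior` (rows x groups matrix)
#'   and `x` (canonical scores), mirroring the classic discriminant
#'   predict convention.
#' @export
predict.cda <- function(object, newdata = NULL, prior = NULL, ...) {
  sc <- if (is.null(newdata)) object$scores else project(object, newdata)
  pr <- if (is.null(prior)) object$prior
        else resolve_priors(prior, object$counts, object$groups)
  k <- length(object$groups)
  d2 <- sapply(seq_len(k), function(g) {
    rowSums(sweep(sc, 2, object$centroids[g, ])^2)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  logpost <- sweep(-d2 / 2, 2, log(pr), "+")
  logpost <- logpost - apply(logpost, 1, max)
  post <- exp(logpost) / rowSums(exp(logpost))
  colnames(post) <- object$groups
  cls <- factor(object$groups[max.col(post, ties.method = "first")],
                levels = object$groups)
  list(class = cls, posterior = post, x = sc)
}

#' Resubstitution confusion matrix of a CDA model
#'
#' Classifies every (training) row with the model fitted on all rows and
#' tabulates true origin against prediction.
#'
#' @param model A [cda] fit.
#' @param table Optional labeled table to classify (defaults to the training
#'   data).
#' @return A `cda_confusion`: list with `table` (origin x predicted),
#'   `accuracy` per group (percent), and `overall` (percent).
#' @export
reclassify <- function(model, table = NULL) {
  stopifnot(inherits(model, "cda"))
  if (is.null(table)) {
    truth <- model$labels
    pred <- predict(model)$class
  } else {
    truth <- factor(table$origin, levels = model$groups)
    pred <- predict(model, table)$class
  }
  confusion(truth, pred, model$groups)
}

#' Leave-one-out cross-validation of a CDA model
#'
#' For each row the model is refitted on the remaining rows (a full refit;
#' no shortcut) and the held-out row classified. A fold whose refit fails
#' (e.g. singular within-scatter) is counted as misclassified-unknown, with
#' a warning.
#'
#' @param table Labeled [peak_table].
#' @param variables Variables to use (default: all peak variables).
#' @param priors As in [cda].
#' @return A `cda_confusion` (the `table` gains an `<unknown>` column when
#'   folds failed).
#' @export
loo_crossvalidate <- function(table, variables = peak_vars(table),
                              priors = "equal") {
  table <- as.data.frame(table)
  if (anyNA(table$origin)) stop("LOO requires origin labels on all rows")
  g <- factor(table$origin)
  if (any(table(g) <= 2L)) stop("every group needs > 2 samples for LOO")
  n <- nrow(table)
  x <- as.matrix(table[variables])
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(cda_core(x[-i, , drop = FALSE], g[-i], priors = priors),
                      error = function(e) NULL)
    if (is.null(fit_i)) {
      warning(sprintf("LOO fold %d: refit failed; counted as unknown", i))
      next
    }
    pred[i] <- as.character(predict(fit_i,
                                    as.data.frame(table[i, , drop = FALSE]))$class)
  }
  lev <- levels(g)
  predf <- factor(ifelse(is.na(pred), "<unknown>", pred),
                  levels = c(lev, if (anyNA(pred)) "<unknown>"))
  confusion(g, predf, lev)
}

confusion <- function(truth, pred, groups) {
  tab <- table(origin = truth, predicted = pred)
  acc <- 100 * vapply(groups, function(g) {
    i <- truth == g
    if (!any(i)) return(NA_real_)
    mean(pred[i] == g)
  }, numeric(1))
  out <- list(table = tab, accuracy = acc,
              overall = 100 * mean(as.character(pred) == as.character(truth)))
  class(out) <- "cda_confusion"
  out
}

#' @export
print.cda_confusion <- function(x, ...) {
  print(x$table)
  cat(sprintf("Overall accuracy: %.1f%%  (per group: %s)\n", x$overall,
              paste(sprintf("%s %.1f%%", names(x$accuracy), x$accuracy),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.cda <- function(x, digits = 4, ...) {
  cat("Canonical discriminant analysis\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("Groups: %s (n = %s)\n",
              paste(x$groups, collapse = ", "),
              paste(x$counts, collapse = "/")))
  cat("Proportion of variance:",
      paste(sprintf("%s %.1f%%", colnames(x$coefficients), x$pct_variance),
            collapse = ", "), "\n")
  cat("Raw canonical coefficients:\n")
  print(round(rbind(x$coefficients, `(constant)` = x$constants), digits))
  invisible(x)
}

#' @export
coef.cda <- function(object, ...) object$coefficients

#' @export
summary.cda <- function(object, ...) {
  structure(list(fit = object, resub = reclassify(object)),
            class = "summary.cda")
}

#' @export
print.summary.cda <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nEigenvalues:", paste(signif(x$fit$eigenvalues, digits),
                              collapse = ", "), "\n")
  cat("\nStructure matrix (pooled within-group correlations):\n")
  print(round(x$fit$structure, 3))
  cat("\nGroup centroids:\n")
  print(round(x$fit$centroids, digits))
  cat("\nResubstitution:\n")
  print(x$resub)
  invisible(x)
}

#' Score plot of a fitted CDA model
#'
#' Scatter of the first two canonical scores with group centroids marked.
#'
#' @param x A [cda] fit.
#' @param ... Passed to [graphics::plot].
#' @export
plot.cda <- function(x, ...) {
  sc <- x$scores
  if (ncol(sc) < 2L) {
    graphics::stripchart(sc[, 1] ~ x$labels, method = "jitter",
                         xlab = colnames(sc)[1], ...)
    return(invisible(x))
  }
  cols <- seq_along(x$groups)
  graphics::plot(sc[, 1], sc[, 2], col = cols[as.integer(x$labels)],
                 pch = 19, xlab = paste0(colnames(sc)[1], sprintf(
                   " (%.1f%%)", x$pct_variance[1])),
                 ylab = paste0(colnames(sc)[2], sprintf(
                   " (%.1f%%)", x$pct_variance[2])), ...)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 8, cex = 2,
                   col = cols)
  graphics::legend("topright", legend = x$groups, col = cols, pch = 19)
  invisible(x)
}

#' Serialize a CDA model to JSON
#'
#' Full double precision; the counterpart [read_cda] reconstructs a model
#' usable for [project] and [predict.cda] (training scores are not stored).
#'
#' @param model A [cda] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cda <- function(model, path) {
  stopifnot(inherits(model, "cda"))
  obj <- list(groups = model$groups, variables = model$variables,
              counts = model$counts, prior = as.numeric(model$prior),
              means = model$means, grand_mean = model$grand_mean,
              pooled_cov = model$pooled_cov,
              coefficients = model$coefficients,
              constants = as.numeric(model$constants),
              eigenvalues = model$eigenvalues,
              pct_variance = model$pct_variance,
              centroids = model$centroids, structure = model$structure,
              df_within = model$df_within)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized CDA model
#' @param path JSON path written by [write_cda].
#' @return A [cda] object (without training scores).
#' @export
read_cda <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mknum <- function(m, rn, cn) {
    m <- matrix(as.numeric(m), nrow = length(rn), byrow = FALSE,
                dimnames = list(rn, cn))
    m
  }
  fn <- paste0("LD", seq_along(o$eigenvalues))
  out <- list(variables = o$variables, groups = o$groups,
              counts = as.integer(o$counts),
              prior = stats::setNames(o$prior, o$groups),
              means = mknum(o$means, o$groups, o$variables),
              grand_mean = stats::setNames(o$grand_mean, o$variables),
              pooled_cov = mknum(o$pooled_cov, o$variables, o$variables),
              coefficients = mknum(o$coefficients, o$variables, fn),
              constants = stats::setNames(o$constants, fn),
              eigenvalues = o$eigenvalues, pct_variance = o$pct_variance,
              centroids = mknum(o$centroids, o$groups, fn),
              structure = mknum(o$structure, o$variables, fn),
              df_within = o$df_within)
  class(out) <- "cda"
  out
}
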