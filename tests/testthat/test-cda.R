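sel8 <- c("P5", "P7", "P8", "P10", "P12", "P14", "P16", "P17")

test_that("two-group CDA direction matches the pooled-covariance closed form", {
  tbl <- two_group_table()
  fit <- cda(origin ~ P1 + P2, data = tbl)
  expect_equal(ncol(fit$coefficients), 1L)

  x <- as.matrix(as.data.frame(tbl)[c("P1", "P2")])
  g <- tbl$origin
  m1 <- colMeans(x[g == "A", ]); m2 <- colMeans(x[g == "B", ])
  xc <- rbind(sweep(x[g == "A", ], 2, m1), sweep(x[g == "B", ], 2, m2))
  Sp <- crossprod(xc) / (nrow(x) - 2)
  dir_oracle <- solve(Sp, m2 - m1)
  a <- fit$coefficients[, 1]
  cosang <- abs(sum(a * dir_oracle)) /
    sqrt(sum(a^2) * sum(dir_oracle^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("canonical scores have identity pooled within-group covariance", {
  tbl <- simulate_peak_table(seed = 5)
  fit <- cda(origin ~ ., data = tbl)
  g <- fit$labels
  sc <- fit$scores
  cm <- rowsum(sc, g) / as.integer(table(g))
  r <- sc - cm[as.integer(g), ]
  within_cov <- crossprod(r) / fit$df_within
  expect_equal(unname(within_cov), diag(ncol(sc)), tolerance = 1e-8)
  expect_equal(sum(fit$pct_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  expect_equal(ncol(fit$coefficients), 2L)   # min(k-1, p) with k = 3
})

test_that("collinear group means concentrate variance on one function", {
  set.seed(6)
  n <- 15
  centers <- c(0, 4, 8)                       # on a line in (P1, P2)
  rows <- do.call(rbind, lapply(1:3, function(g)
    data.frame(sample_id = sprintf("g%d_%d", g, 1:n),
               origin = c("A", "B", "C")[g],
               P1 = rnorm(n, centers[g] + 5, 0.5),
               P2 = rnorm(n, 2 * centers[g] + 5, 0.5))))
  fit <- cda(origin ~ P1 + P2, data = peak_table(rows))
  expect_gt(fit$pct_variance[1], 99)
  expect_lt(fit$eigenvalues[2], 0.05 * fit$eigenvalues[1])
})

test_that("projection is affine and matches direct matrix multiplication", {
  tbl <- simulate_peak_table(seed = 13)
  fit <- cda(origin ~ ., data = tbl)
  # centroid in variable space projects to centroid scores
  for (g in fit$groups)
    expect_equal(project(fit, fit$means[g, ])[1, ],
                 fit$centroids[g, ], tolerance = 1e-10)
  # affinity
  x <- unlist(tbl[3, fit$variables]); y <- unlist(tbl[40, fit$variables])
  al <- 0.3
  expect_equal(project(fit, al * x + (1 - al) * y),
               al * project(fit, x) + (1 - al) * project(fit, y),
               tolerance = 1e-10)
  # direct multiply oracle
  expect_equal(project(fit, x)[1, ],
               drop(x %*% fit$coefficients) + fit$constants,
               tolerance = 1e-12)
  expect_error(project(fit, x[-1]), "missing variable")
})

test_that("posteriors follow the score-space linear discriminant model", {
  tbl <- simulate_peak_table(seed = 14)
  fit <- cda(origin ~ ., data = tbl)
  pr <- predict(fit, fit$means["Korean", , drop = FALSE] |> as.data.frame())
  expect_equal(as.character(pr$class), "Korean")
  expect_gt(pr$posterior[1, "Korean"], 1 / 3)
  expect_equal(rowSums(pr$posterior), 1, ignore_attr = TRUE,
               tolerance = 1e-9)

  # two-group 1-D logistic closed form
  t2 <- two_group_table(n = 20, delta = c(2, 0), seed = 3)
  f2 <- cda(origin ~ P1, data = t2)
  row <- data.frame(P1 = 5.7)
  sc <- project(f2, row)[1, 1]
  d2 <- (sc - f2$centroids[, 1])^2
  oracle <- 1 / (1 + exp((d2["A"] - d2["B"]) / 2))
  expect_equal(unname(predict(f2, row)$posterior[1, "A"]), unname(oracle),
               tolerance = 1e-10)
})

test_that("fits are equivariant under invertible affine variable transforms", {
  tbl <- simulate_peak_table(seed = 15)
  fit <- cda(origin ~ P5 + P8 + P12 + P17, data = tbl)
  p0 <- predict(fit)

  set.seed(16)
  A <- matrix(rnorm(16), 4); while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
  b <- rnorm(4)
  vars <- c("P5", "P8", "P12", "P17")
  xt <- as.matrix(as.data.frame(tbl)[vars]) %*% A
  xt <- sweep(xt, 2, -b) + 10      # keep values positive-ish; shift is affine
  tbl2 <- tbl
  tbl2[vars] <- xt
  fit2 <- cda(as.data.frame(tbl2)[vars], tbl2$origin)
  p1 <- predict(fit2)
  expect_identical(as.character(p0$class), as.character(p1$class))
  expect_equal(p0$posterior, p1$posterior, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("CDA classifications agree with an independent discriminant fit", {
  skip_if_not_installed("MASS")
  # proportional priors align the between-scatter weighting conventions of
  # the two implementations, so directions as well as posteriors comparable
  tbl <- simulate_peak_table(seed = 17)
  fit <- cda(origin ~ ., data = tbl, priors = "proportional")
  ld <- MASS::lda(origin ~ ., data = as.data.frame(tbl)[c("origin",
                                                          peak_vars(tbl))])
  pl <- predict(ld)
  pc <- predict(fit)
  expect_identical(as.character(pc$class), as.character(pl$class))
  expect_equal(pc$posterior[, colnames(pl$posterior)], pl$posterior,
               tolerance = 1e-6, ignore_attr = TRUE)
  # discriminant directions proportional
  for (j in 1:2)
    expect_equal(abs(stats::cor(fit$coefficients[rownames(ld$scaling), j],
                                ld$scaling[, j])), 1, tolerance = 1e-6)
})

test_that("reclassification is perfect for separated data and chance for permuted labels", {
  # clearly separated clusters (~8 sigma min pairwise); at the default
  # calibration (~4 sigma) a ~2% per-sample error makes 100% a coin flip
  tbl <- simulate_peak_table(sim_config(profiles = separated_profiles()),
                             seed = 18)
  fit <- cda(stats::reformulate(sel8, "origin"), data = tbl)
  rc <- reclassify(fit)
  expect_equal(rc$overall, 100)
  expect_equal(unname(rc$accuracy), rep(100, 3))

  # single-origin subset classifies trivially
  k_only <- peak_table(as.data.frame(tbl)[tbl$origin == "Korean", ])
  expect_equal(reclassify(fit, k_only)$accuracy[["Korean"]], 100)

  set.seed(19)
  tblp <- tbl
  tblp$origin <- sample(tblp$origin)
  # cross-validated accuracy is the unbiased chance-level estimate
  # (resubstitution on permuted labels carries an overfitting optimism)
  cv <- loo_crossvalidate(tblp, sel8)
  expect_lt(cv$overall, 100 * (50 / 86) + 3 * 100 * sqrt(0.58 * 0.42 / 86))
})

test_that("LOO equals an explicit refit loop and never beats resubstitution on noisy data", {
  tbl <- three_group_table(n = c(5, 5, 5), sep = 2.5, seed = 23)
  vars <- peak_vars(tbl)
  loo <- loo_crossvalidate(tbl, vars)
  # brute-force oracle: N independent fits through the public interface
  pred <- character(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    f <- cda(origin ~ P1 + P2 + P3, data = tbl[-i, ])
    pred[i] <- as.character(predict(f, tbl[i, ])$class)
  }
  oracle_overall <- 100 * mean(pred == tbl$origin)
  expect_equal(loo$overall, oracle_overall)
  expect_equal(unname(as.matrix(loo$table)),
               unname(as.matrix(table(tbl$origin, pred))))

  hold <- logical(0)
  for (seed in 1:12) {
    t2 <- three_group_table(n = c(12, 10, 8), sep = 1.2, seed = seed)
    fit <- cda(origin ~ ., data = t2)
    hold <- c(hold,
              loo_crossvalidate(t2, peak_vars(t2))$overall <=
                reclassify(fit)$overall)
  }
  expect_gte(mean(hold), 10 / 12)
})

test_that("structure matrix equals pooled within-group correlations by definition", {
  tbl <- simulate_peak_table(seed = 25)
  fit <- cda(origin ~ P5 + P8 + P12 + P17, data = tbl)
  sc <- fit$scores
  g <- fit$labels
  oracle <- matrix(NA_real_, 4, 2)
  vars <- c("P5", "P8", "P12", "P17")
  for (i in 1:4) for (j in 1:2) {
    v <- as.data.frame(tbl)[[vars[i]]]
    vres <- v - ave(v, g)
    sres <- sc[, j] - ave(sc[, j], g)
    oracle[i, j] <- sum(vres * sres) / sqrt(sum(vres^2) * sum(sres^2))
  }
  expect_equal(unname(fit$structure), oracle, tolerance = 1e-10)
  expect_equal(structure_matrix(fit, tbl), fit$structure, tolerance = 1e-10)

  # zero within-group variance: correlation undefined, reported missing
  tbl2 <- tbl
  tbl2$P5 <- as.numeric(factor(tbl2$origin))   # constant within each group
  st <- structure_matrix(fit, tbl2)
  expect_true(all(is.na(st["P5", ])))

  # two-group single-variable limit: |correlation| = 1
  t2 <- two_group_table(n = 10, seed = 31)
  f1 <- cda(origin ~ P1, data = t2)
  expect_equal(abs(unname(f1$structure[1, 1])), 1, tolerance = 1e-10)
})

test_that("singular within-group scatter is reported with the collinear variable", {
  tbl <- simulate_peak_table(seed = 26)
  tbl$P1 <- 2 * tbl$P8 + 1
  expect_error(cda(origin ~ P8 + P12 + P1, data = tbl), "singular")
})

test_that("models survive JSON serialization at full precision", {
  tbl <- simulate_peak_table(seed = 27)
  fit <- cda(origin ~ P5 + P8 + P12 + P17, data = tbl)
  f <- withr::local_tempfile(fileext = ".json")
  write_cda(fit, f)
  fit2 <- read_cda(f)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-15)
  p1 <- predict(fit, tbl)
  p2 <- predict(fit2, tbl)
  expect_identical(as.character(p1$class), as.character(p2$class))
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
})

test_that("parameter recovery: fitted centroid separations track the generator", {
  pr <- default_origin_profiles()
  tbl <- simulate_peak_table(seed = 28)
  fit <- cda(origin ~ P5 + P7 + P8 + P10 + P12 + P14 + P16 + P17, data = tbl)
  # population Mahalanobis separation on the 4 indicators alone bounds the
  # canonical-space centroid separation from below
  d_kc <- sqrt(sum(((pr$means["Korean", c("P8", "P12", "P14", "P17")] -
                     pr$means["Chinese", c("P8", "P12", "P14", "P17")]) /
                    pr$sds["Korean", c("P8", "P12", "P14", "P17")])^2))
  got <- sqrt(sum((fit$centroids["Korean", ] - fit$centroids["Chinese", ])^2))
  expect_gt(got, 0.6 * d_kc)
  expect_lt(got, 2.5 * d_kc)
})
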