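test_that("single-copy matrix keeps 1-to-1 columns and drops constants", {
  counts <- cbind(og1 = c(1, 1, 1), og2 = c(2, 1, 0), og3 = c(1, 0, 1),
                  og4 = c(0, 1, 1))
  rownames(counts) <- c("A", "B", "C")
  m <- build_single_copy_matrix(counts)
  expect_equal(colnames(m), c("og3", "og4"))  # og2 multi-copy, og1 constant
  expect_equal(unname(m[, "og3"]), c(1, 0, 1))
})

test_that("chi-square screen matches the Pearson formula", {
  # independence: balanced table
  x <- rep(c(0, 1), each = 50)
  y <- rep(c(0, 1, 0, 1), each = 25)
  r <- chi2_screen(x, y)
  expect_equal(unname(r["statistic"]), 0)
  expect_equal(unname(r["p"]), 1)
  # perfect association of size n has statistic n
  r2 <- chi2_screen(rep(c(0, 1), each = 30), rep(c(0, 1), each = 30))
  expect_equal(unname(r2["statistic"]), 60)
  # degenerate margin
  expect_true(is.na(chi2_screen(rep(1, 10), rep(c(0, 1), 5))["p"]))
})

test_that("SP110 x sociality from the printed table matches the oracle to 1e-9", {
  df <- table1_fixture()
  r <- chi2_screen(df$SP110, df$sociality)
  tab <- table(factor(df$SP110, 0:1), factor(df$sociality, 0:1))
  expect_equal(unname(r["statistic"]), pearson_chi2(tab), tolerance = 1e-9)
  expect_equal(unname(r["statistic"]), 12.11157, tolerance = 1e-4)
  expect_lt(r["p"], 0.001)
  expect_gt(r["p"], 1e-4)
})

test_that("lasso null threshold zeroes every coefficient", {
  set.seed(61)
  X <- simulate_presence_matrix(80, 20)
  y <- stats::rbinom(80, 1, 0.5)
  Xs <- scale(X, scale = apply(X, 2, function(v) stats::sd(v) * sqrt(79 / 80)))
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / 80
  fit <- l1_logistic(X, y, lambda = lam_max * 1.01)
  expect_true(all(fit$coef == 0))
  expect_length(fit$selected, 0)
})

test_that("unpenalized limit matches the logistic MLE", {
  set.seed(62)
  x <- rep(c(0, 1), each = 40)
  y <- stats::rbinom(80, 1, stats::plogis(-0.4 + 1.2 * x))
  fit <- l1_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "tf")), y,
                     lambda = 0)
  ml <- stats::glm(y ~ x, family = stats::binomial())
  sdx <- stats::sd(x) * sqrt(79 / 80)
  expect_equal(unname(fit$coef["tf"]), unname(stats::coef(ml)["x"]) * sdx,
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(stats::coef(ml)["(Intercept)"]),
               tolerance = 1e-4)
})

test_that("a trait equal to one presence column is selected with dominant weight", {
  set.seed(63)
  pm <- simulate_presence_matrix(96, 30, c(0.4, 0.6))
  y <- pm[, 7]
  res <- suppressWarnings(associate_trait(pm, y, nfolds = 5, seed = 1))
  expect_true(colnames(pm)[7] %in% res$selected)
  cf <- res$table$coef
  expect_equal(res$table$tf_id[which.max(abs(cf))], colnames(pm)[7])
})

test_that("permuted traits select far fewer regulators than planted signal", {
  set.seed(64)
  pm <- simulate_presence_matrix(96, 60, c(0.4, 0.8))
  causal <- colnames(pm)[1:3]
  y <- simulate_traits(pm, causal, c(2, -2, 2), beta0 = 0)
  res_true <- suppressWarnings(associate_trait(pm, y, nfolds = 5, seed = 2))
  n_perm <- vapply(1:8, function(i) {
    yp <- stats::setNames(sample(as.integer(y)), names(y))
    rp <- suppressWarnings(associate_trait(pm, yp, nfolds = 5, seed = i))
    length(rp$selected)
  }, numeric(1))
  expect_gt(length(res_true$selected), 0)
  expect_lt(mean(n_perm), max(10, length(res_true$selected) * 3))
})

test_that("the printed sociality table reproduces the prescreen decisions", {
  df <- table1_fixture()
  pm <- as.matrix(df[, c("NACC1", "SP110", "EPM2A")])
  scr <- screen_columns(pm, df$sociality)
  # SP110 passes p < 0.05; NACC1/EPM2A share the same 2x2 table, their
  # exact p decides survival and is reported either way
  expect_true(scr$pass[scr$tf_id == "SP110"])
  expect_equal(scr$p[scr$tf_id == "NACC1"], scr$p[scr$tf_id == "EPM2A"])
  expect_false(any(is.na(scr$p)))
  res <- suppressWarnings(associate_trait(pm, stats::setNames(df$sociality, rownames(df)),
                                          nfolds = 5, seed = 3))
  # negative presence coefficient = loss associates with solitariness
  expect_true(all(!is.na(res$table$p)))
})
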