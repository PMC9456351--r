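# Trait association stage: species x regulator presence/absence (restricted
# to single-copy orthologs) against binary life-history traits — Pearson
# chi-square prescreen (p < 0.05, no continuity correction) followed by
# L1-penalized logistic regression (glmnet), penalty chosen by
# cross-validated deviance.
#
# Species are treated as independent observations; this mirrors the original
# regression design and is *not* a phylogenetically corrected test. A warning
# reminds the user on every fit.

#' Build the single-copy presence/absence matrix
#'
#' Keeps ortholog groups with at most one copy in every species; presence is
#' 1 iff exactly one copy. Columns constant across species carry no signal
#' for association and are dropped.
#'
#' @param counts species x OG copy-count matrix
#' @param drop_constant drop constant columns (default TRUE)
#' @return binary matrix (species x OG)
#' @export
build_single_copy_matrix <- function(counts, drop_constant = TRUE) {
  single <- apply(counts, 2, function(x) all(x <= 1))
  m <- (counts[, single, drop = FALSE] == 1) * 1L
  if (drop_constant && ncol(m)) {
    keep <- apply(m, 2, function(x) length(unique(x)) > 1L)
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' Pearson chi-square screen of one presence column against a binary trait
#'
#' 2x2 Pearson chi-square, 1 df, no continuity correction. Missing trait
#' values are excluded pairwise; a degenerate margin yields NA (the column is
#' skipped by the caller).
#'
#' @param x binary presence vector
#' @param y binary trait vector (NA allowed)
#' @return named numeric: statistic, p
#' @export
chi2_screen <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(c(statistic = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  c(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Screen all presence columns against a trait
#' @param pm binary presence matrix (species x OG)
#' @param y binary trait (named by species or aligned with rows)
#' @param alpha screen level (default 0.05)
#' @return data.frame tf_id, statistic, p, pass
#' @export
screen_columns <- function(pm, y, alpha = 0.05) {
  res <- t(apply(pm, 2, chi2_screen, y = y))
  out <- data.frame(tf_id = colnames(pm), statistic = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pass <- !is.na(out$p) & out$p < alpha
  out
}

#' L1-penalized logistic regression of a trait on presence columns
#'
#' Columns are standardized before penalization (coefficients are reported on
#' the standardized scale); the intercept is unpenalized. When `lambda` is
#' NULL it is chosen by k-fold cross-validated deviance (`lambda.min`, or
#' `lambda.1se` with `rule = "1se"`).
#'
#' @param X numeric matrix of prescreen survivors (species x TF)
#' @param y binary response
#' @param lambda optional penalty; NULL for cross-validation
#' @param nfolds CV folds (default 10)
#' @param rule `"min"` or `"1se"`
#' @param seed optional RNG seed for fold assignment
#' @return list: `coef` (named, standardized scale), `intercept`, `lambda`,
#'   `selected` (names with nonzero coefficient)
#' @export
l1_logistic <- function(X, y, lambda = NULL, nfolds = 10, rule = c("min", "1se"),
                        seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, .pad = 0)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = nfolds,
                            type.measure = "deviance", standardize = TRUE)
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, y, family = "binomial", standardize = TRUE)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                               family = "binomial", standardize = TRUE))
  names(cf) <- c("(Intercept)", colnames(X))
  beta <- cf[-1]
  # report on the standardized (per-sd) scale glmnet penalizes on
  sds <- apply(X, 2, function(x) stats::sd(x) * sqrt((length(x) - 1) / length(x)))
  beta_std <- beta * sds
  if (pad) beta_std <- beta_std[names(beta_std) != ".pad"]
  list(coef = beta_std, intercept = unname(cf[1]), lambda = lambda,
       selected = names(beta_std)[beta_std != 0])
}

#' Associate one binary trait with regulator presence/absence
#'
#' Chi-square prescreen (p < `alpha`) then lasso logistic regression on the
#' survivors. A negative presence coefficient means that *loss* of the
#' regulator associates with trait = 1.
#'
#' @param pm binary presence matrix (species x OG)
#' @param y binary trait, named by species (NA dropped)
#' @param alpha prescreen level
#' @param lambda,nfolds,rule,seed passed to [l1_logistic()]
#' @return `association_result`: per-TF table (tf_id, statistic, p, coef),
#'   `selected`, `lambda`, `n_species`
#' @export
associate_trait <- function(pm, y, alpha = 0.05, lambda = NULL, nfolds = 10,
                            rule = "min", seed = NULL) {
  warning("species are treated as independent observations; no phylogenetic correction is applied",
          call. = FALSE)
  if (!is.null(names(y))) {
    common <- intersect(rownames(pm), names(y))
    pm <- pm[common, , drop = FALSE]
    y <- y[common]
  }
  keep <- !is.na(y)
  pm <- pm[keep, , drop = FALSE]; y <- y[keep]
  scr <- screen_columns(pm, y, alpha)
  tab <- scr[, c("tf_id", "statistic", "p")]
  tab$coef <- NA_real_
  surv <- scr$tf_id[scr$pass]
  sel <- character(0); lam <- NA_real_
  if (length(surv) == 0) {
    message("no column survives the chi-square prescreen")
  } else {
    fit <- l1_logistic(pm[, surv, drop = FALSE], y, lambda, nfolds, rule, seed)
    tab$coef[match(names(fit$coef), tab$tf_id)] <- fit$coef
    sel <- fit$selected
    lam <- fit$lambda
  }
  structure(list(table = tab, selected = sel, lambda = lam,
                 n_species = length(y)), class = "association_result")
}

#' Planted-signal recovery experiment for the association pipeline
#'
#' Simulates a presence matrix, plants `n_causal` causal regulators with
#' coefficients of magnitude `beta_abs` (alternating sign, intercept chosen
#' so the trait is roughly balanced), runs the screen-then-lasso pipeline and
#' scores the selected set against the planted truth. Causal columns are
#' drawn among identifiable ones (minority class at least 20% of species):
#' a signal planted on a near-constant column is unrecoverable by design.
#'
#' @param n_species,n_og,n_causal,beta_abs experiment dimensions
#' @param n_seeds replicate count
#' @param nfolds CV folds for the lasso penalty
#' @param seed master seed (replicate r uses `seed + r`)
#' @return list: mean `recall`, mean `precision`, mean `n_selected`, and the
#'   per-replicate data.frame `per_seed`
#' @export
association_recovery <- function(n_species = 96, n_og = 200, n_causal = 5,
                                 beta_abs = 2, n_seeds = 50, nfolds = 10,
                                 seed = 1) {
  per <- data.frame(seed = seq_len(n_seeds), recall = NA_real_,
                    precision = NA_real_, n_selected = NA_integer_)
  for (r in seq_len(n_seeds)) {
    set.seed(seed + r)
    pm <- simulate_presence_matrix(n_species, n_og)
    minor <- pmin(colSums(pm), colSums(1 - pm))
    causal <- sample(colnames(pm)[minor >= 0.2 * n_species], n_causal)
    beta <- beta_abs * rep_len(c(1, -1), n_causal)
    beta0 <- -sum(beta * colMeans(pm[, causal, drop = FALSE]))
    y <- simulate_traits(pm, causal, beta, beta0)
    res <- suppressWarnings(suppressMessages(
      associate_trait(pm, y, nfolds = nfolds, seed = seed + r)
    ))
    sel <- res$selected
    per$recall[r] <- length(intersect(sel, causal)) / n_causal
    per$precision[r] <- if (length(sel)) length(intersect(sel, causal)) / length(sel) else NA
    per$n_selected[r] <- length(sel)
  }
  list(recall = mean(per$recall), precision = mean(per$precision, na.rm = TRUE),
       n_selected = mean(per$n_selected), per_seed = per)
}

#' @export
print.association_result <- function(x, ...) {
  cat("trait association:", nrow(x$table), "TFs screened,",
      sum(!is.na(x$table$coef)), "survivors,",
      length(x$selected), "selected (lambda =", format(x$lambda, digits = 4), ")\n")
  invisible(x)
}
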