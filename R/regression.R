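#' Weighted logistic regression via IRLS with sandwich variance
#'
#' Fits a binary logistic model by maximising the survey-weight-multiplied
#' Bernoulli log-likelihood with iteratively reweighted least squares
#' (relative deviance tolerance `tol`, at most `max_iter` iterations).
#' Standard errors come from the sandwich (robust) estimator: score
#' contributions are aggregated within `cluster` when cluster ids are
#' given (cluster-robust, the stand-in for full survey-design Taylor
#' linearisation), else per-record (heteroscedasticity-robust);
#' `se = "model"` gives the model-based inverse-Fisher SEs instead. Point
#' estimates are invariant to rescaling all weights by a constant; robust
#' SEs are too, model-based SEs are not.
#'
#' @param x Design matrix (including the intercept column); must be full
#'   rank after dropping reference levels.
#' @param y Binary 0/1 outcome vector.
#' @param weights Positive weights (default all 1).
#' @param cluster Optional vector of cluster ids for cluster-robust SEs.
#' @param se `"robust"` (default) or `"model"`.
#' @param max_iter,tol IRLS controls.
#' @return A `morb_logit`: list with `coefficients` table (term, beta, se,
#'   or, ci_lo, ci_hi — Wald 95% intervals on the OR scale), `vcov`,
#'   `se_type`, `n`, `iterations`, `deviance`.
#' @export
#' @examples
#' x <- cbind(1, c(rep(0, 100), rep(1, 100)))
#' y <- c(rep(c(0, 1), c(70, 30)), rep(c(0, 1), c(50, 50)))
#' fit <- fit_weighted_logistic(x, y)
#' exp(fit$coefficients$beta[2])  # (30/70)/(50/50) cross-product OR
fit_weighted_logistic <- function(x, y, weights = NULL, cluster = NULL,
                                  se = c("robust", "model"),
                                  max_iter = 50, tol = 1e-8) {
  se <- match.arg(se)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(weights)) weights <- rep(1, n)
  .assert(length(y) == n && length(weights) == n,
          "x, y and weights must have matching lengths")
  .assert(all(y %in% c(0, 1)), "outcome must be binary 0/1")
  .assert(all(weights > 0), "weights must be strictly positive")
  qx <- qr(x)
  .assert(qx$rank == p,
          "design matrix is rank deficient (rank %d < %d columns): %s",
          qx$rank, p, paste(colnames(x), collapse = ", "))

  beta <- rep(0, p)
  dev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    wv <- weights * v
    z <- eta + (y - mu) / v
    fit <- tryCatch(
      solve(crossprod(x, x * wv), crossprod(x, wv * z)),
      error = function(e) stop("IRLS normal equations are singular: ",
                               conditionMessage(e), call. = FALSE))
    beta <- drop(fit)
    if (max(abs(beta)) > 15) {
      worst <- colnames(x)[which.max(abs(beta))]
      stop(sprintf("separation detected: coefficient for '%s' is diverging",
                   worst), call. = FALSE)
    }
    mu_new <- stats::plogis(drop(x %*% beta))
    dev_new <- -2 * sum(weights *
                          (y * log(pmax(mu_new, 1e-300)) +
                             (1 - y) * log(pmax(1 - mu_new, 1e-300))))
    trace <- c(trace, dev_new)
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance trace: %s)",
                 max_iter, paste(signif(trace, 8), collapse = " -> ")),
         call. = FALSE)
  }

  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  wv <- weights * pmax(mu * (1 - mu), 1e-12)
  bread <- solve(crossprod(x, x * wv))
  if (se == "model") {
    V <- bread
  } else {
    U <- x * (weights * (y - mu))
    if (!is.null(cluster)) U <- rowsum(U, group = cluster)
    V <- bread %*% crossprod(U) %*% bread
  }
  sehat <- sqrt(diag(V))
  coefs <- data.frame(term = colnames(x), beta = beta, se = sehat,
                      or = exp(beta),
                      ci_lo = exp(beta - 1.96 * sehat),
                      ci_hi = exp(beta + 1.96 * sehat),
                      row.names = NULL)
  structure(list(coefficients = coefs, vcov = V,
                 se_type = if (se == "model") "model-based"
                           else if (is.null(cluster)) "heteroscedasticity-robust"
                           else "cluster-robust",
                 n = n, iterations = it, deviance = dev),
            class = "morb_logit")
}

#' @export
print.morb_logit <- function(x, ...) {
  cat(sprintf("<morb_logit: n = %d, %s SE, %d IRLS iterations>\n",
              x$n, x$se_type, x$iterations))
  tab <- x$coefficients
  tab$or <- sprintf("%.2f (%.2f, %.2f)", tab$or, tab$ci_lo, tab$ci_hi)
  print.data.frame(tab[c("term", "beta", "se", "or")], digits = 3)
  invisible(x)
}

# reference level for each model term (first level = reference)
.term_levels <- function() {
  list(
    age_group = .age_levels,
    sex = .sex_levels,
    marital = c("married", "other"),
    income = c("high", "low", "middle"),
    working = c("employed", "unemployed"),
    education = c("college", "elementary", "secondary"),
    bmi_cat = c("normal", "underweight", "overweight", "obesity"),
    smoking = c("no", "yes"),
    drinking = c("no", "yes"),
    walking = c("yes", "no"),
    sleeping = c("optimal", "short", "long"),
    stress = c("no", "yes"),
    multimorbidity = .morb_cat_levels
  )
}

# assemble the outcome/design frame for poor-HRQoL models
.model_frame <- function(cohort, terms) {
  df <- as.data.frame(cohort)
  df$multimorbidity <- count_morbidities(cohort)$category
  refs <- .term_levels()
  out <- data.frame(.y = as.integer(cohort$hrqol == "poor"))
  for (tm in terms) {
    .assert(tm %in% names(df), "unknown model term '%s'", tm)
    x <- df[[tm]]
    out[[tm]] <- if (tm %in% names(refs)) {
      factor(as.character(x), levels = refs[[tm]])
    } else if (is.character(x)) {
      factor(x)
    } else {
      x
    }
  }
  out$.w <- cohort$weight
  out
}

#' Poor-HRQoL logistic regression on multimorbidity and covariates
#'
#' Convenience wrapper around [fit_weighted_logistic()]: models the odds of
#' poor HRQoL (vs normal or good) on the multimorbidity category and any
#' categorical covariates, with survey weights by default. Reference
#' levels follow the survey convention (age 65-69, male, married, high
#' income, employed, college educated, normal BMI, non-smoker, non-drinker,
#' walking, optimal sleep, no stress, no disease). Records missing any
#' model term are dropped listwise with a message.
#'
#' @param cohort A `morb_cohort`.
#' @param terms Character vector of model terms; `"multimorbidity"` refers
#'   to the none/1/2/3+ category.
#' @param weighted Use survey weights (default `TRUE`).
#' @param cluster Optional column name holding cluster ids.
#' @return A `morb_logit` (see [fit_weighted_logistic()]).
#' @export
regress_poor_hrqol <- function(cohort, terms = "multimorbidity",
                               weighted = TRUE, cluster = NULL) {
  mf <- .model_frame(cohort, terms)
  cl <- if (!is.null(cluster)) as.data.frame(cohort)[[cluster]]
  keep <- stats::complete.cases(mf)
  if (any(!keep)) {
    message(sprintf("listwise deletion: dropping %d record(s) with missing model terms",
                    sum(!keep)))
    mf <- mf[keep, , drop = FALSE]
    cl <- cl[keep]
  }
  x <- stats::model.matrix(
    stats::reformulate(terms),
    data = mf)
  fit_weighted_logistic(x, mf$.y,
                        weights = if (weighted) mf$.w else NULL,
                        cluster = cl)
}

#' Univariable screen of poor-HRQoL associations
#'
#' One single-term weighted logistic fit per covariate, using the same
#' machinery and reference coding as the multivariable model.
#'
#' @inheritParams regress_poor_hrqol
#' @return Named list of `morb_logit` fits, one per term.
#' @export
univariable_screen <- function(cohort, terms, weighted = TRUE,
                               cluster = NULL) {
  fits <- lapply(terms, function(tm) {
    regress_poor_hrqol(cohort, terms = tm, weighted = weighted,
                       cluster = cluster)
  })
  stats::setNames(fits, terms)
}

#' Export a regression result as CSV
#'
#' @param fit A `morb_logit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regression <- function(fit, path) {
  stopifnot(inherits(fit, "morb_logit"))
  utils::write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}
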