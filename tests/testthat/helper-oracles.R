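# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (loops, closed forms, generic optimisers)
# and never call the code paths they check.

# build a valid cohort around a 0/1 disease matrix
make_cohort <- function(dz, sex = "male", index = 0.9, weight = 1,
                        id = NULL, ...) {
  dz <- as.matrix(dz)
  n <- nrow(dz)
  colnames(dz) <- paste0("dz_", disease_panel())
  df <- data.frame(
    id = if (is.null(id)) sprintf("r%04d", seq_len(n)) else id,
    sex = rep_len(sex, n),
    age_group = "65-69",
    weight = rep_len(weight, n),
    eq5d_index = rep_len(index, n),
    dz, ...
  )
  suppressMessages(morb_cohort(df))
}

# disease matrix with named columns set from a per-record pattern list
pattern_matrix <- function(patterns) {
  m <- matrix(0L, length(patterns), length(disease_panel()),
              dimnames = list(NULL, disease_panel()))
  for (i in seq_along(patterns)) m[i, patterns[[i]]] <- 1L
  m
}

# exhaustive brute-force enumeration of all 210 directed rules: explicit
# double loop over disease pairs, direct sums over records
brute_force_rules <- function(dz) {
  d <- disease_panel()
  n <- nrow(dz)
  out <- list()
  for (i in seq_along(d)) {
    for (j in seq_along(d)) {
      if (i == j) next
      n_x <- sum(dz[, i])
      n_y <- sum(dz[, j])
      n_xy <- sum(dz[, i] * dz[, j])
      out[[length(out) + 1]] <- data.frame(
        antecedent = d[i], consequent = d[j],
        support = n_xy / n,
        confidence = if (n_x > 0) n_xy / n_x else NA_real_,
        lift = if (n_x > 0 && n_y > 0) (n_xy / n) / ((n_x / n) * (n_y / n))
               else NA_real_)
    }
  }
  do.call(rbind, out)
}

# textbook chi-square statistic, sum over cells of (O - E)^2 / E
chisq_by_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# weighted Bernoulli log-likelihood maximised by a generic optimiser
logistic_by_optim <- function(x, y, w = rep(1, length(y))) {
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  stats::optim(rep(0, ncol(x)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$par
}

# bivariate normal lower-orthant probability P(Z1 < a, Z2 < b; rho)
# by one-dimensional quadrature of the conditional normal
bvn_orthant <- function(a, b, rho) {
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# random small cohort disease matrix for property tests
random_dz <- function(n, prev = NULL) {
  d <- length(disease_panel())
  if (is.null(prev)) prev <- stats::runif(d, 0.02, 0.6)
  m <- matrix(stats::rbinom(n * d, 1, rep(prev, each = n)), n, d)
  colnames(m) <- disease_panel()
  m
}
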