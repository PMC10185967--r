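test_that("latent-Gaussian thresholding calibrates marginals exactly", {
  x <- sample_correlated_binary(c(0.3, 0.5), diag(2), n = 1e5, seed = 101)
  expect_lt(abs(mean(x[, 1]) - 0.3), 0.01)
  expect_lt(abs(mean(x[, 2]) - 0.5), 0.01)
})

test_that("pair co-occurrence matches the bivariate-normal orthant oracle", {
  rho <- 0.5
  p <- 0.4
  x <- sample_correlated_binary(c(p, p), matrix(c(1, rho, rho, 1), 2),
                                n = 1e5, seed = 202)
  joint <- mean(x[, 1] * x[, 2])
  oracle <- bvn_orthant(qnorm(p), qnorm(p), rho)  # numeric quadrature
  expect_lt(abs(joint - oracle), 4 * sqrt(oracle * (1 - oracle) / 1e5))
  # independence: empirical lift of the pair within 1 +/- 0.02
  xi <- sample_correlated_binary(c(0.5, 0.5), diag(2), n = 1e5, seed = 203)
  lift <- mean(xi[, 1] * xi[, 2]) / (mean(xi[, 1]) * mean(xi[, 2]))
  expect_lt(abs(lift - 1), 0.02)
})

test_that("expected lift is monotone in the latent correlation", {
  lifts <- sapply(c(0, 0.3, 0.6), function(rho) {
    x <- sample_correlated_binary(c(0.3, 0.3),
                                  matrix(c(1, rho, rho, 1), 2),
                                  n = 5e4, seed = 300)
    mean(x[, 1] * x[, 2]) / (mean(x[, 1]) * mean(x[, 2]))
  })
  expect_true(all(diff(lifts) > 0))
})

test_that("degenerate marginals and invalid correlations are rejected", {
  expect_error(sample_correlated_binary(c(0, 0.5), diag(2), 10), "degenerate")
  expect_error(sample_correlated_binary(c(1, 0.5), diag(2), 10), "degenerate")
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(sample_correlated_binary(rep(0.5, 3), bad, 10),
               "positive semi-definite")
})

test_that("mildly non-PSD latent correlations are repaired with a warning", {
  d <- 15
  R <- default_latent_corr()
  # push the matrix just past PSD
  ev <- eigen(R, symmetric = TRUE)
  R_bad <- ev$vectors %*% diag(ev$values - min(ev$values) - 0.02) %*%
    t(ev$vectors)
  R_bad <- stats::cov2cor((R_bad + t(R_bad)) / 2)
  P <- matrix(0.2, 2, d, dimnames = list(c("male", "female"), disease_panel()))
  expect_warning(
    cfg <- sim_config(n_per_stratum = c(male = 100, female = 100),
                      marginal_prev = P, latent_corr = R_bad, seed = 1),
    "repaired")
  expect_gt(min(eigen(cfg$latent_corr, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
})

test_that("stratified cohorts recover per-stratum target prevalences", {
  cfg <- default_sim_config("stratified", n_total = 12000, seed = 42)
  co <- suppressMessages(generate_cohort(cfg))
  for (s in rownames(cfg$marginal_prev)) {
    parts <- strsplit(s, ":")[[1]]
    pt <- prevalence_table(co, stratum_spec(parts[1], parts[2]))
    n_s <- pt$n[1]
    target <- cfg$marginal_prev[s, pt$disease]
    bound <- 3 * sqrt(target * (1 - target) / n_s)
    expect_true(all(abs(pt$pct / 100 - target) <= bound),
                label = sprintf("stratum %s within 3-sigma of targets", s))
  }
})

test_that("generation is deterministic and stamped with provenance", {
  cfg <- suppressWarnings(
    default_sim_config("stratified", n_total = 600, seed = 9))
  c1 <- suppressMessages(generate_cohort(cfg))
  c2 <- suppressMessages(generate_cohort(cfg))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "provenance")$seed, 9L)
  expect_identical(attr(c1, "provenance")$config_hash,
                   attr(c2, "provenance")$config_hash)
  # a different seed gives a different cohort
  cfg2 <- suppressWarnings(
    default_sim_config("stratified", n_total = 600, seed = 10))
  c3 <- suppressMessages(generate_cohort(cfg2))
  expect_false(identical(as.data.frame(c1)$eq5d_index,
                         as.data.frame(c3)$eq5d_index))
})

test_that("EQ-5D index structure matches the HRQoL architecture", {
  cfg <- default_sim_config("stratified", n_total = 3000, seed = 5)
  co <- suppressMessages(generate_cohort(cfg))
  idx <- co$eq5d_index
  expect_true(all(idx[co$hrqol == "good"] == 1))
  expect_true(all(idx[co$hrqol == "poor"] <= 0.721))
  expect_true(all(idx[co$hrqol == "normal"] > 0.721 &
                    idx[co$hrqol == "normal"] < 1))
  expect_true(all(idx >= cfg$index_floor))
  # left skew of the continuous part
  cont <- idx[idx < 1]
  expect_lt(mean((cont - mean(cont))^3) / stats::sd(cont)^3, 0)
  # weights: positive, mean one
  expect_true(all(co$weight > 0))
  expect_equal(mean(co$weight), 1, tolerance = 1e-12)
})

test_that("linked mode hits its group shares and null link gives OR 1", {
  cfg <- default_sim_config("linked", n_total = 20000, seed = 77,
                            hrqol_link_beta = c(0, 0, 0, 0))
  co <- suppressMessages(generate_cohort(cfg))
  shares <- prop.table(table(co$hrqol))
  expect_lt(abs(shares[["poor"]] - cfg$poor_frac), 0.01)
  expect_lt(abs(shares[["good"]] - cfg$good_mass), 0.015)
  # with a null link, the >=3 vs none odds ratio CI covers 1
  fit <- suppressMessages(
    regress_poor_hrqol(co, c("multimorbidity", "sex")))
  row <- fit$coefficients[fit$coefficients$term == "multimorbidity>=3", ]
  expect_true(row$ci_lo <= 1 && 1 <= row$ci_hi)
})

test_that("configs validate stratum structure and sizes", {
  P <- matrix(0.3, 2, 15, dimnames = list(c("male", "female"),
                                          disease_panel()))
  expect_error(sim_config(c(male = 100), P, seed = 1), "names must match")
  expect_error(sim_config(c(male = 100, female = 100),
                          pmax(P, 1), seed = 1), "strictly inside")
  expect_error(sim_config(c(male = 100, female = 100), P), "seed")
  expect_warning(sim_config(c(male = 10, female = 100), P, seed = 1),
                 "fewer than 30")
  expect_error(sim_config(c(male = 100, female = 100), P, seed = 1,
                          hrqol_link_beta = c(0.1, 1, 1, 1)),
               "first entry 0")
})
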