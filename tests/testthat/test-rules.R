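test_that("pair counts match hand counting", {
  co <- make_cohort(pattern_matrix(list(
    c("arthritis", "asthma"), "arthritis", "asthma")))
  pc <- pair_counts(co)
  expect_identical(pc$n, 3L)
  expect_equal(unname(pc$marginal[c("arthritis", "asthma")]), c(2, 2))
  expect_equal(pc$joint["arthritis", "asthma"], 1)
  expect_equal(pc$joint, t(pc$joint))
  # disjoint diseases have zero joint count
  co2 <- make_cohort(pattern_matrix(list("arthritis", "asthma")))
  pc2 <- pair_counts(co2)
  expect_equal(pc2$joint["arthritis", "asthma"], 0)
})

test_that("rule statistics reproduce the worked diabetes-hypertension cell", {
  # poor-HRQoL male stratum: n = 457, n_HTN = 255, n_DM = 139, joint = 95
  rs <- rule_stats("diabetes", "hypertension", 457, 139, 255, 95)
  expect_equal(rs$support_pct, 20.8)
  expect_equal(rs$confidence_pct, 68.3)
  expect_equal(rs$lift_fmt, 1.2)
  rev <- rule_stats("hypertension", "diabetes", 457, 255, 139, 95)
  expect_equal(rev$support_pct, 20.8)
  expect_equal(rev$confidence_pct, 37.3)
  expect_equal(rev$lift_fmt, 1.2)
  # subset case: confidence exactly 1
  expect_equal(rule_stats("a", "b", 100, 20, 50, 20)$confidence, 1)
  # inconsistent counts are rejected
  expect_error(rule_stats("a", "b", 100, 20, 50, 30), "inconsistent")
})

test_that("mined rules equal brute-force enumeration to machine precision", {
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    dz <- random_dz(n)
    co <- make_cohort(dz)
    mined <- as.data.frame(mine_rules(co))
    oracle <- brute_force_rules(dz)
    merged <- merge(mined, oracle, by = c("antecedent", "consequent"),
                    suffixes = c("", "_oracle"))
    expect_identical(nrow(merged), 210L)
    expect_equal(merged$support, merged$support_oracle, tolerance = 1e-14)
    expect_equal(merged$confidence, merged$confidence_oracle,
                 tolerance = 1e-14)
    expect_equal(merged$lift, merged$lift_oracle, tolerance = 1e-13)
  }
})

test_that("rule identities hold exactly pre-rounding", {
  set.seed(505)
  co <- make_cohort(random_dz(200))
  rules <- mine_rules(co)
  # lift * P(Y) = confidence and confidence * P(X) = support
  ok <- !is.na(rules$lift)
  expect_equal(rules$lift[ok] * rules$n_y[ok] / rules$n[ok],
               rules$confidence[ok], tolerance = 1e-13)
  expect_equal(rules$confidence[ok] * rules$n_x[ok] / rules$n[ok],
               rules$support[ok], tolerance = 1e-13)
  # support and lift are direction-invariant
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  k <- key(rules$antecedent, rules$consequent)
  expect_true(all(tapply(rules$support, k, function(v) diff(range(v)) == 0)))
  # bounds
  expect_true(all(rules$support <= pmin(rules$n_x, rules$n_y) / rules$n))
  expect_true(all(rules$lift[ok] <=
                    rules$n[ok] / pmax(rules$n_x[ok], rules$n_y[ok]) + 1e-12))
})

test_that("rule ordering is deterministic and keeps pair-mates adjacent", {
  set.seed(606)
  dz <- random_dz(150)
  co <- make_cohort(dz)
  r1 <- mine_rules(co)
  # shuffling records changes nothing
  co2 <- make_cohort(dz[sample(nrow(dz)), ])
  r2 <- mine_rules(co2)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # supports are non-increasing, and each odd row pairs with the next
  expect_true(all(diff(r1$support) <= 1e-15))
  odd <- seq(1, nrow(r1), by = 2)
  expect_identical(r1$antecedent[odd], r1$consequent[odd + 1])
  expect_identical(r1$consequent[odd], r1$antecedent[odd + 1])
})

test_that("top_rules truncates by pairs under the documented tie-break", {
  set.seed(707)
  co <- make_cohort(random_dz(200))
  rules <- mine_rules(co)
  top4 <- top_rules(rules, 4)
  expect_identical(nrow(top4), 4L)
  expect_identical(as.data.frame(top4), as.data.frame(rules)[1:4, ])
  # odd k rounds up to a whole pair
  expect_identical(nrow(top_rules(rules, 5)), 6L)
  # k beyond the table returns it unchanged
  expect_identical(as.data.frame(top_rules(rules, 10000)),
                   as.data.frame(rules))
  expect_error(top_rules(rules, 0), "at least 1")
})

test_that("min_support prunes pairs and is validated", {
  co <- make_cohort(pattern_matrix(list(
    c("arthritis", "asthma"), c("arthritis", "asthma"), "cancer", "cancer")))
  rules <- mine_rules(co, min_support = 0.4)
  expect_identical(sort(unique(c(rules$antecedent, rules$consequent))),
                   c("arthritis", "asthma"))
  expect_error(mine_rules(co, min_support = 1.5), "min_support")
  expect_error(mine_rules(co, min_support = -0.1), "min_support")
})

test_that("lift matrix equals elementwise recomputation and masks zeros", {
  set.seed(808)
  dz <- random_dz(300)
  dz[, "thyroid"] <- 0L  # absent disease: masked, never 0
  co <- make_cohort(dz)
  lm <- lift_matrix(co)
  pc <- pair_counts(co)
  for (i in 1:15) {
    for (j in 1:15) {
      if (i == j) {
        expect_true(is.na(lm[i, j]))
      } else if (pc$marginal[i] * pc$marginal[j] == 0) {
        expect_true(is.na(lm[i, j]))
      } else {
        expect_equal(unname(lm[i, j]),
                     unname(pc$n * pc$joint[i, j] /
                              (pc$marginal[i] * pc$marginal[j])))
      }
    }
  }
  expect_equal(unclass(lm), t(unclass(lm)))
})

test_that("rule tables export with the documented columns", {
  set.seed(909)
  co <- make_cohort(random_dz(100))
  rules <- top_rules(mine_rules(co), 6)
  path <- tempfile(fileext = ".csv")
  write_rules(rules, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("antecedent", "consequent", "n", "n_x", "n_y", "n_xy",
                     "support_pct", "confidence_pct", "lift"))
  expect_identical(nrow(back), 6L)
  expect_equal(back$support_pct, rules$support_pct)
})
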