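test_that("multimorbidity count and category follow the burden thresholds", {
  flags <- function(...) {
    v <- integer(15)
    v[match(c(...), disease_panel())] <- 1L
    v
  }
  cm <- count_morbidities(rbind(
    integer(15),
    flags("hypertension", "diabetes"),
    flags("hypertension", "arthritis", "depression", "stroke"),
    flags("asthma")
  ))
  expect_identical(cm$count, c(0L, 2L, 4L, 1L))
  expect_identical(as.character(cm$category), c("0", "2", ">=3", "1"))
})

test_that("CKD flag uses a strict eGFR threshold", {
  expect_identical(ckd_from_egfr(c(59.9, 60, 95)), c(1L, 0L, 0L))
  expect_identical(ckd_from_egfr(59.999), 1L)
  expect_error(ckd_from_egfr(0), "positive")
  expect_error(ckd_from_egfr(-5), "positive")
})

test_that("prevalence tables count exactly and respect weights", {
  m <- pattern_matrix(list(c("diabetes", "hypertension"), "diabetes",
                           "hypertension", character(0)))
  co <- make_cohort(m)
  pt <- prevalence_table(co)
  expect_identical(pt$count[pt$disease == "diabetes"], 2)
  expect_equal(pt$pct[pt$disease == "diabetes"], 50)
  # a disease absent everywhere is 0, not NA
  expect_identical(pt$count[pt$disease == "cancer"], 0)
  expect_equal(pt$pct_fmt[pt$disease == "cancer"], 0)
  # equal weights reproduce the unweighted percentages
  ptw <- prevalence_table(co, weighted = TRUE)
  expect_equal(ptw$pct, pt$pct)
  # unequal weights shift them
  co2 <- make_cohort(m, weight = c(3, 1, 1, 1))
  ptw2 <- prevalence_table(co2, weighted = TRUE)
  expect_equal(ptw2$pct[ptw2$disease == "diabetes"], 100 * 4 / 6)
  # reference-style cell: 139 of 457 -> 30.4%
  expect_equal(round_half_up(100 * 139 / 457, 1), 30.4)
})

test_that("prevalence is permutation-invariant and empty strata error", {
  set.seed(11)
  m <- random_dz(60)
  co <- make_cohort(m)
  perm <- sample(nrow(m))
  co_p <- make_cohort(m[perm, ])
  expect_equal(prevalence_table(co), prevalence_table(co_p))
  expect_error(prevalence_table(co, stratum_spec("female", "poor")),
               "stratum 'female:poor' is empty")
})

test_that("across-group chi-square matches the textbook formula", {
  # perfectly proportional table: statistic 0, p = 1
  prop_tab <- rbind(c(10, 20), c(30, 60), c(5, 10))
  res <- compare_groups(prop_tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand-computed 2x2
  tab <- rbind(c(10, 90), c(50, 50))
  hand <- chisq_by_hand(tab)
  res <- compare_groups(tab)
  expect_equal(res$statistic, hand$statistic)
  expect_equal(res$df, hand$df)
  expect_equal(res$p_value, hand$p_value)
  # stroke prevalence across the three male HRQoL groups is wildly unequal
  stroke <- c(126, 164, 98)
  totals <- c(3098, 1907, 457)
  res <- compare_groups(cbind(stroke, totals - stroke))
  expect_equal(res$df, 2)
  expect_lt(res$p_value, 0.001)
  # tiny expected cells still return, with a warning
  expect_warning(res2 <- compare_groups(rbind(c(1, 500), c(0, 400))),
                 "below 1")
  expect_true(is.finite(res2$p_value))
})

test_that("characteristics table buckets missing values and sums to n", {
  set.seed(3)
  m <- random_dz(80)
  idx <- c(rep(1, 30), runif(30, 0.75, 0.99), runif(20, 0, 0.721))
  smoking <- sample(c("yes", "no", NA), 80, replace = TRUE,
                    prob = c(0.2, 0.7, 0.1))
  co <- make_cohort(m, index = idx, smoking = smoking)
  tab <- suppressWarnings(   # tiny fixture: expected cells below 1 are fine
    characteristics_table(co, variables = c("smoking", "multimorbidity")))
  smoke_rows <- tab[tab$variable == "smoking", ]
  expect_true("missing" %in% smoke_rows$level)
  for (g in c("poor", "normal", "good")) {
    expect_identical(sum(smoke_rows[[paste0(g, "_count")]]),
                     sum(co$hrqol == g))
  }
})

test_that("cohort construction validates and rederives HRQoL", {
  m <- pattern_matrix(list("diabetes", character(0)))
  co <- make_cohort(m, index = c(0.5, 1))
  expect_identical(as.character(co$hrqol), c("poor", "good"))
  # weights must be positive
  expect_error(make_cohort(m, weight = c(1, 0)), "strictly positive")
  # disease flags must be 0/1
  bad <- m
  bad[1, 1] <- 2L
  expect_error(make_cohort(bad), "0/1")
  # records without an index are dropped with a message
  df <- as.data.frame(make_cohort(m))
  df$eq5d_index[1] <- NA
  expect_message(co2 <- morb_cohort(df), "dropping 1 record")
  expect_identical(nrow(co2), 1L)
  # responses are scored when the index is absent
  df2 <- as.data.frame(make_cohort(m))
  df2$eq5d_index <- NULL
  df2[paste0("eq5d_", c("mo", "sc", "ua", "pd", "ad"))] <-
    rep(list(c(1, 1)), 5)
  co3 <- morb_cohort(df2, value_set = load_value_set("toy"))
  expect_equal(co3$eq5d_index, c(1, 1))
})

test_that("cohort files round-trip losslessly and validate the dialect", {
  set.seed(21)
  m <- random_dz(40)
  co <- make_cohort(m, index = c(rep(1, 10), runif(30, 0.3, 0.99)),
                    extra_score = runif(40))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_message(co2 <- read_cohort(path), "passthrough.*extra_score")
  expect_equal(as.data.frame(co2), as.data.frame(co),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(attr(co2, "passthrough"), "extra_score")

  # a file with neither responses nor index is rejected
  df <- as.data.frame(co)
  df$eq5d_index <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "eq5d_index")

  # an unknown disease column is an error listing the expected panel
  df2 <- as.data.frame(co)
  df2$dz_gout <- 0L
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "dz_gout.*expected panel")
})
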