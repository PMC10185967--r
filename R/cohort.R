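#' Stratum specification (sex x HRQoL analysis cell)
#'
#' Analyses are run in cells of the sex-by-HRQoL grid; `"all"` in either
#' margin pools over it. The six elementary strata plus the marginals
#' enumerate every analysis cell used by the stratified prevalence, rule and
#' network outputs.
#'
#' @param sex `"male"`, `"female"` or `"all"`.
#' @param hrqol `"poor"`, `"normal"`, `"good"` or `"all"`.
#' @return An object of class `stratum_spec`.
#' @export
#' @examples
#' stratum_spec("male", "poor")
stratum_spec <- function(sex = "all", hrqol = "all") {
  sex <- match.arg(sex, c("all", .sex_levels))
  hrqol <- match.arg(hrqol, c("all", .hrqol_levels))
  structure(list(sex = sex, hrqol = hrqol), class = "stratum_spec")
}

#' @export
format.stratum_spec <- function(x, ...) paste0(x$sex, ":", x$hrqol)

#' @export
print.stratum_spec <- function(x, ...) {
  cat("<stratum:", format(x), ">\n")
  invisible(x)
}

#' Construct and validate a multimorbidity cohort
#'
#' Wraps a participant-level data frame into a validated `morb_cohort`.
#' Required columns: `id`, `sex` (male/female), `age_group`, `weight`
#' (strictly positive survey weight), the 15 disease flags `dz_<name>`
#' (0/1, names from [disease_panel()]), and either `eq5d_index` or the five
#' response columns `eq5d_mo`, `eq5d_sc`, `eq5d_ua`, `eq5d_pd`, `eq5d_ad`
#' (levels 1-3; scored via `value_set` when the index is absent). The HRQoL
#' group column `hrqol` is (re)derived from the index via [classify_hrqol()]
#' so it can never be inconsistent. Records without a usable EQ-5D index are
#' dropped with a message (item-missing covariates are retained as `NA` and
#' surface as an explicit "missing" level in descriptive tables).
#' Optional design labels `stratum_id` / `cluster_id` and the standard
#' categorical covariates (`marital`, `income`, `working`, `education`,
#' `bmi_cat`, `smoking`, `drinking`, `walking`, `sleeping`, `stress`) pass
#' through; any further columns are preserved and recorded as passthrough.
#'
#' @param data A data.frame as described above.
#' @param value_set An [`eq5d_value_set`][value_set()] used when only
#'   responses are present (default: the bundled synthetic Korean-style set).
#' @param poor_cutoff Poor-HRQoL index threshold (default 0.721).
#' @return A `morb_cohort` (a data.frame subclass) with attributes
#'   `diseases` (panel order) and `passthrough` (extra column names).
#' @export
morb_cohort <- function(data, value_set = NULL, poor_cutoff = 0.721) {
  data <- as.data.frame(data)
  dz_cols <- paste0("dz_", disease_panel())
  resp_cols <- paste0("eq5d_", c("mo", "sc", "ua", "pd", "ad"))

  for (col in c("id", "sex", "age_group", "weight")) {
    .assert(col %in% names(data), "cohort is missing required column '%s'", col)
  }
  unknown_dz <- setdiff(grep("^dz_", names(data), value = TRUE), dz_cols)
  .assert(length(unknown_dz) == 0,
          "unknown disease column(s) %s; expected panel: %s",
          paste(unknown_dz, collapse = ", "), paste(dz_cols, collapse = ", "))
  missing_dz <- setdiff(dz_cols, names(data))
  .assert(length(missing_dz) == 0,
          "cohort is missing disease column(s): %s; expected panel: %s",
          paste(missing_dz, collapse = ", "), paste(dz_cols, collapse = ", "))

  has_index <- "eq5d_index" %in% names(data)
  has_resp <- all(resp_cols %in% names(data))
  .assert(has_index || has_resp,
          "cohort must contain 'eq5d_index' or all five EQ-5D response columns (%s)",
          paste(resp_cols, collapse = ", "))
  if (!has_index) {
    if (is.null(value_set)) value_set <- load_value_set("korean_3l_synthetic")
    complete <- stats::complete.cases(data[resp_cols])
    data$eq5d_index <- NA_real_
    data$eq5d_index[complete] <-
      score_eq5d(data[complete, resp_cols], value_set)
  }
  n_drop <- sum(!is.finite(data$eq5d_index))
  if (n_drop > 0) {
    message(sprintf("dropping %d record(s) without a usable EQ-5D index", n_drop))
    data <- data[is.finite(data$eq5d_index), , drop = FALSE]
  }
  .assert(nrow(data) > 0, "no records left after EQ-5D exclusions")

  dz <- as.matrix(data[dz_cols])
  .assert(!anyNA(dz) && all(dz == 0 | dz == 1),
          "disease flags must be 0/1 with no missing values")
  .assert(all(is.finite(data$weight)) && all(data$weight > 0),
          "survey weights must be strictly positive")
  data$sex <- factor(as.character(data$sex), levels = .sex_levels)
  .assert(!anyNA(data$sex), "sex must be 'male' or 'female'")
  data$hrqol <- classify_hrqol(data$eq5d_index, poor_cutoff)

  known <- c("id", "sex", "age_group", "weight", "stratum_id", "cluster_id",
             .covariate_names(), dz_cols, resp_cols, "eq5d_index", "hrqol")
  passthrough <- setdiff(names(data), known)
  if (length(passthrough) > 0) {
    message("passthrough column(s) preserved: ",
            paste(passthrough, collapse = ", "))
  }
  structure(data,
            class = c("morb_cohort", "data.frame"),
            diseases = disease_panel(),
            poor_cutoff = poor_cutoff,
            passthrough = passthrough)
}

.covariate_names <- function() {
  c("marital", "income", "working", "education", "bmi_cat",
    "smoking", "drinking", "walking", "sleeping", "stress")
}

#' @export
print.morb_cohort <- function(x, ...) {
  cat(sprintf("<morb_cohort: %d participants, %d diseases>\n",
              nrow(x), length(attr(x, "diseases"))))
  tab <- table(x$sex, x$hrqol)
  print(tab)
  invisible(x)
}

#' Extract the n x 15 disease indicator matrix
#'
#' @param cohort A `morb_cohort`.
#' @return Integer matrix, columns named and ordered by [disease_panel()].
#' @export
disease_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "morb_cohort"))
  m <- as.matrix(as.data.frame(cohort)[paste0("dz_", disease_panel())])
  storage.mode(m) <- "integer"
  colnames(m) <- disease_panel()
  m
}

#' Subset a cohort to one analysis stratum
#'
#' @param cohort A `morb_cohort`.
#' @param stratum A [stratum_spec()] (or arguments coercible via
#'   `stratum_spec(sex, hrqol)`).
#' @param allow_empty If `FALSE` (default) an empty stratum is an error
#'   naming the stratum.
#' @return The subset `morb_cohort`.
#' @export
filter_stratum <- function(cohort, stratum, allow_empty = FALSE) {
  stopifnot(inherits(cohort, "morb_cohort"), inherits(stratum, "stratum_spec"))
  keep <- rep(TRUE, nrow(cohort))
  if (stratum$sex != "all") keep <- keep & cohort$sex == stratum$sex
  if (stratum$hrqol != "all") keep <- keep & cohort$hrqol == stratum$hrqol
  out <- cohort[keep, , drop = FALSE]
  if (!allow_empty) {
    .assert(nrow(out) > 0, "stratum '%s' is empty", format(stratum))
  }
  out
}

#' Multimorbidity count and category
#'
#' Multimorbidity is the coexistence of two or more chronic diseases. The
#' count is the sum of the 15 panel flags; the category collapses it to the
#' conventional none / 1 / 2 / 3-or-more burden classes used throughout the
#' descriptive tables and the HRQoL regression.
#'
#' @param x A `morb_cohort`, a 0/1 disease matrix, or a single record's
#'   length-15 flag vector.
#' @return A data.frame with integer `count` and factor `category`
#'   (levels `0`, `1`, `2`, `>=3`), one row per record.
#' @export
#' @examples
#' count_morbidities(c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
count_morbidities <- function(x) {
  m <- if (inherits(x, "morb_cohort")) {
    disease_matrix(x)
  } else if (is.null(dim(x))) {
    matrix(x, nrow = 1L)
  } else {
    as.matrix(x)
  }
  .assert(ncol(m) == length(disease_panel()),
          "expected %d disease flags, got %d", length(disease_panel()), ncol(m))
  .assert(!anyNA(m) && all(m == 0 | m == 1), "disease flags must be 0/1")
  count <- as.integer(rowSums(m))
  category <- cut(count, breaks = c(-1, 0, 1, 2, Inf),
                  labels = .morb_cat_levels)
  data.frame(count = count, category = category)
}

#' Chronic kidney disease flag from eGFR
#'
#' CKD is defined by an estimated glomerular filtration rate strictly below
#' the threshold (default 60 mL/min/1.73 m^2); the boundary value itself is
#' not CKD.
#'
#' @param egfr Positive numeric vector, mL/min/1.73 m^2.
#' @param threshold eGFR threshold (default 60).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' ckd_from_egfr(c(59.9, 60, 95))
ckd_from_egfr <- function(egfr, threshold = 60) {
  .assert(all(is.finite(egfr)) && all(egfr > 0),
          "eGFR values must be positive")
  as.integer(egfr < threshold)
}

#' Stratified disease prevalence table
#'
#' Counts and percentages of each panel disease within one sex-by-HRQoL
#' stratum. The default (and the convention of the reference descriptive
#' tables) is unweighted counts over survey participants; `weighted = TRUE`
#' uses survey-weight sums instead. Percentages are carried at full
#' precision in `pct`; use `pct_fmt` (half-up, one decimal) for display.
#'
#' @param cohort A `morb_cohort`.
#' @param stratum A [stratum_spec()]; default pools everyone.
#' @param weighted Use survey-weight sums instead of counts.
#' @return A data.frame with one row per disease: `disease`, `n` (stratum
#'   size), `count`, `pct`, `pct_fmt`.
#' @export
prevalence_table <- function(cohort, stratum = stratum_spec(),
                             weighted = FALSE) {
  sub <- filter_stratum(cohort, stratum)
  m <- disease_matrix(sub)
  if (weighted) {
    w <- sub$weight
    count <- as.numeric(crossprod(m, w))
    denom <- sum(w)
  } else {
    count <- as.numeric(colSums(m))
    denom <- nrow(m)
  }
  pct <- 100 * count / denom
  data.frame(disease = disease_panel(),
             n = if (weighted) denom else nrow(m),
             count = count,
             pct = pct,
             pct_fmt = round_half_up(pct, 1),
             row.names = NULL)
}

#' Across-group chi-square comparison
#'
#' Pearson chi-square test of independence (no continuity correction) on a
#' groups-by-levels contingency table of counts, as used to compare disease
#' prevalence or covariate distributions across HRQoL groups. Expected
#' cells below 1 trigger a warning but the result is still returned.
#'
#' @param counts A G x K matrix (or table) of nonnegative integer counts,
#'   one row per group.
#' @return A list with `statistic`, `df` = (G-1)(K-1), and `p_value`.
#' @export
#' @examples
#' # disease present/absent across three HRQoL groups
#' compare_groups(cbind(present = c(126, 164, 98),
#'                      absent = c(3098, 1907, 457) - c(126, 164, 98)))
compare_groups <- function(counts) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) >= 2 && ncol(counts) >= 2,
          "need at least a 2x2 table of counts")
  .assert(all(counts >= 0), "counts must be nonnegative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1)) {
    warning("some expected cell counts are below 1; ",
            "the chi-square approximation may be poor")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Descriptive characteristics table across HRQoL groups
#'
#' Tabulates categorical covariates (plus age group, sex and multimorbidity
#' category) by HRQoL group, with counts, column percentages and an
#' across-group chi-square p-value per characteristic. Missing covariate
#' values form their own `missing` bucket so that counts always sum to the
#' stratum size, but the `missing` row is excluded from the test.
#'
#' @param cohort A `morb_cohort`.
#' @param variables Character vector of columns to tabulate; defaults to
#'   age group, sex, the standard covariates present, and the
#'   multimorbidity category.
#' @return A data.frame with columns `variable`, `level`, one
#'   `<group>_count` / `<group>_pct` pair per HRQoL group, and `p_value`
#'   (repeated within a variable).
#' @export
characteristics_table <- function(cohort, variables = NULL) {
  stopifnot(inherits(cohort, "morb_cohort"))
  df <- as.data.frame(cohort)
  df$multimorbidity <- count_morbidities(cohort)$category
  if (is.null(variables)) {
    variables <- intersect(c("age_group", "sex", .covariate_names(),
                             "multimorbidity"), names(df))
  }
  groups <- .hrqol_levels
  out <- list()
  for (v in variables) {
    x <- as.character(df[[v]])
    x[is.na(x)] <- "missing"
    lv <- unique(c(setdiff(sort(unique(x)), "missing"),
                   intersect("missing", x)))
    tab <- table(factor(x, levels = lv), factor(df$hrqol, levels = groups))
    test_tab <- t(tab[setdiff(rownames(tab), "missing"), , drop = FALSE])
    p <- if (nrow(test_tab) >= 2 && ncol(test_tab) >= 2) {
      compare_groups(test_tab)$p_value
    } else {
      NA_real_
    }
    block <- data.frame(variable = v, level = lv, row.names = NULL)
    for (g in groups) {
      block[[paste0(g, "_count")]] <- as.integer(tab[, g])
      block[[paste0(g, "_pct")]] <-
        round_half_up(100 * tab[, g] / sum(df$hrqol == g), 1)
    }
    block$p_value <- p
    out[[v]] <- block
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
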