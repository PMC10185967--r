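#' Bundled reference tables (Korean older-adult survey)
#'
#' The package ships plain-text reference tables distilled from a national
#' health survey of Korean adults aged 65 and over (n = 12,657), used for
#' worked examples and cross-consistency checks of the rule engine:
#' per-stratum disease counts and node strengths by sex and HRQoL group,
#' and the top-20 association rules (by support) in the poor-HRQoL group by
#' sex.
#'
#' @return `reference_stratum_sizes()`: data.frame `sex`, `hrqol`, `n` (six
#'   strata). `reference_prevalence()`: data.frame `sex`, `hrqol`,
#'   `disease`, `count`, `node_strength`, plus stratum `n` and the percent
#'   `pct`. `reference_rules()`: data.frame `sex`, `antecedent`,
#'   `consequent`, `support_pct`, `confidence_pct`, `lift` (poor-HRQoL
#'   stratum, printed one-decimal values).
#' @export
#' @examples
#' head(reference_prevalence())
reference_prevalence <- function() {
  path <- system.file("extdata", "reference_prevalence.csv",
                      package = "morbnet")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  sz <- reference_stratum_sizes()
  df$n <- sz$n[match(paste(df$sex, df$hrqol), paste(sz$sex, sz$hrqol))]
  df$pct <- 100 * df$count / df$n
  df
}

#' @rdname reference_prevalence
#' @export
reference_stratum_sizes <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 3),
    hrqol = rep(c("good", "normal", "poor"), 2),
    n = c(3098L, 1907L, 457L, 2579L, 3270L, 1346L)
  )
}

#' @rdname reference_prevalence
#' @export
reference_rules <- function() {
  path <- system.file("extdata", "reference_rules.csv", package = "morbnet")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute reference rule statistics from printed counts
#'
#' Cross-consistency reconstruction: takes the printed per-stratum marginal
#' disease counts and the printed support of each reference rule, recovers
#' the joint count as the nearest integer to support x n, and recomputes
#' confidence and lift through [rule_stats()]. Agreement of the recomputed
#' one-decimal values with the printed ones validates the rule engine
#' against the published table without access to the underlying microdata.
#'
#' @param sex `"male"` or `"female"` (poor-HRQoL stratum).
#' @return The printed rules joined with recomputed `support_pct_calc`,
#'   `confidence_pct_calc`, `lift_calc` columns.
#' @export
#' @examples
#' rr <- reconstruct_reference_rules("male")
#' all(rr$confidence_pct == rr$confidence_pct_calc)
reconstruct_reference_rules <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  rules <- reference_rules()
  rules <- rules[rules$sex == sex, , drop = FALSE]
  prev <- reference_prevalence()
  prev <- prev[prev$sex == sex & prev$hrqol == "poor", , drop = FALSE]
  n <- prev$n[1]
  marg <- stats::setNames(prev$count, prev$disease)
  n_xy <- floor(rules$support_pct / 100 * n + 0.5)
  rs <- rule_stats(rules$antecedent, rules$consequent, n,
                   marg[rules$antecedent], marg[rules$consequent], n_xy)
  rules$support_pct_calc <- rs$support_pct
  rules$confidence_pct_calc <- rs$confidence_pct
  rules$lift_calc <- rs$lift_fmt
  rownames(rules) <- NULL
  rules
}

#' Overall disease prevalence reconstructed from stratum counts
#'
#' Sums the six sex-by-HRQoL stratum counts of the bundled reference table
#' to the whole-population disease prevalences (n = 12,657).
#'
#' @return A data.frame `disease`, `count`, `n`, `pct`, `pct_fmt`.
#' @export
reference_overall_prevalence <- function() {
  prev <- reference_prevalence()
  agg <- stats::aggregate(count ~ disease, data = prev, FUN = sum)
  n <- sum(reference_stratum_sizes()$n)
  agg$n <- n
  agg$pct <- 100 * agg$count / n
  agg$pct_fmt <- round_half_up(agg$pct, 1)
  agg[order(agg$disease), ]
}
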