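#' Directed pairwise rule statistics from counts
#'
#' The three association-rule measurements for a directed disease pair
#' X -> Y in a stratum of size n, computed exactly from counts:
#' support = n_XY / n (prevalence of co-occurrence, P(X,Y)),
#' confidence = n_XY / n_X (conditional prevalence of Y among those with X,
#' P(Y|X)), and lift = n.n_XY / (n_X.n_Y) (observed-to-expected
#' co-occurrence ratio, P(X,Y) / (P(X)P(Y))). Lift above 1 means the two
#' diseases co-occur more often than expected under independence. When a
#' marginal count is zero the affected statistic is undefined and returned
#' as `NA` (never 0).
#'
#' All arguments are vectorised; this is also the low-level entry point for
#' recomputing rule statistics from printed marginal and joint counts.
#'
#' @param antecedent,consequent Disease labels (X and Y).
#' @param n Stratum size.
#' @param n_x,n_y,n_xy Marginal and joint counts.
#' @return A data.frame with one row per rule: labels, counts, `support`,
#'   `confidence`, `lift` (proportions at full precision), and the
#'   report-scale `support_pct`, `confidence_pct`, `lift_fmt` (half-up, one
#'   decimal).
#' @export
#' @examples
#' rule_stats("diabetes", "hypertension", n = 457, n_x = 139, n_y = 255,
#'            n_xy = 95)
rule_stats <- function(antecedent, consequent, n, n_x, n_y, n_xy) {
  .assert(all(n_xy <= pmin(n_x, n_y)) && all(pmax(n_x, n_y) <= n),
          "inconsistent counts: need n_xy <= min(n_x, n_y) <= n")
  support <- n_xy / n
  confidence <- ifelse(n_x > 0, n_xy / n_x, NA_real_)
  lift <- ifelse(n_x > 0 & n_y > 0, (n_xy * n) / (n_x * n_y), NA_real_)
  data.frame(antecedent = antecedent, consequent = consequent,
             n = n, n_x = n_x, n_y = n_y, n_xy = n_xy,
             support = support, confidence = confidence, lift = lift,
             support_pct = round_half_up(100 * support, 1),
             confidence_pct = round_half_up(100 * confidence, 1),
             lift_fmt = round_half_up(lift, 1),
             row.names = NULL)
}

#' Pairwise joint and marginal disease counts in a stratum
#'
#' @param cohort A `morb_cohort`.
#' @param stratum A [stratum_spec()]; default pools everyone.
#' @return A list with `n` (stratum size), `marginal` (named length-15
#'   count vector) and `joint` (symmetric 15 x 15 count matrix whose
#'   diagonal holds the marginals).
#' @export
pair_counts <- function(cohort, stratum = stratum_spec()) {
  sub <- filter_stratum(cohort, stratum)
  m <- disease_matrix(sub)
  joint <- crossprod(m)
  list(n = nrow(m), marginal = diag(joint), joint = joint)
}

.pair_index <- function() {
  d <- disease_panel()
  idx <- utils::combn(length(d), 2)
  data.frame(i = idx[1, ], j = idx[2, ])
}

#' Mine all pairwise disease association rules in a stratum
#'
#' Emits both directed rules (X -> Y and Y -> X) for every unordered
#' disease pair whose support reaches `min_support`; statistics exactly per
#' [rule_stats()]. Mining is always exhaustive over the 105 pairs; any
#' top-k truncation is presentation-layer ([top_rules()]). Rules are
#' ordered by (support desc, lift desc, antecedent, consequent), which
#' keeps the two directions of a pair adjacent and makes ties
#' deterministic.
#'
#' @param cohort A `morb_cohort`.
#' @param stratum A [stratum_spec()].
#' @param min_support Minimum support in \[0, 1\] (default 0: no pruning).
#' @return A `rule_table`: the [rule_stats()] data.frame with attributes
#'   `stratum` and `n`.
#' @export
mine_rules <- function(cohort, stratum = stratum_spec(), min_support = 0) {
  .assert(is.numeric(min_support) && min_support >= 0 && min_support <= 1,
          "min_support must be in [0, 1]")
  pc <- pair_counts(cohort, stratum)
  rules_from_counts(pc$joint, pc$n, stratum = stratum,
                    min_support = min_support)
}

#' Build a rule table from a joint-count matrix
#'
#' Low-level companion to [mine_rules()] for when pairwise counts come from
#' somewhere other than record-level data (for example, reconstruction from
#' printed tables).
#'
#' @param joint Symmetric disease-by-disease count matrix with marginal
#'   counts on the diagonal (as from [pair_counts()]).
#' @param n Stratum size.
#' @param stratum Optional [stratum_spec()] label.
#' @param min_support Minimum support in \[0, 1\].
#' @return A `rule_table`.
#' @export
rules_from_counts <- function(joint, n, stratum = stratum_spec(),
                              min_support = 0) {
  d <- disease_panel()
  .assert(all(dim(joint) == length(d)),
          "joint must be a %d x %d count matrix", length(d), length(d))
  pi <- .pair_index()
  marg <- diag(joint)
  fwd <- rule_stats(d[pi$i], d[pi$j], n, marg[pi$i], marg[pi$j],
                    joint[cbind(pi$i, pi$j)])
  rev <- rule_stats(d[pi$j], d[pi$i], n, marg[pi$j], marg[pi$i],
                    joint[cbind(pi$i, pi$j)])
  rules <- rbind(fwd, rev)
  rules <- rules[rules$support >= min_support, , drop = FALSE]
  # support desc, lift desc, then alphabetical pair key so that the two
  # directions of a pair stay adjacent even under ties
  ord <- order(-rules$support, -ifelse(is.na(rules$lift), -Inf, rules$lift),
               pmin(rules$antecedent, rules$consequent),
               pmax(rules$antecedent, rules$consequent),
               rules$antecedent)
  rules <- rules[ord, , drop = FALSE]
  rownames(rules) <- NULL
  structure(rules, class = c("rule_table", "data.frame"),
            stratum = stratum, n = n)
}

#' Keep the top-k rules by support
#'
#' Truncates a rule table to its k highest-support directed rules under the
#' deterministic ordering of [mine_rules()]. The two directions of a pair
#' are never separated, so an odd `k` is rounded up to whole pairs; `k`
#' beyond the table returns it unchanged.
#'
#' @param rules A `rule_table`.
#' @param k Number of directed rules to keep (default 20, i.e. 10 pairs).
#' @return The truncated `rule_table`.
#' @export
top_rules <- function(rules, k = 20) {
  stopifnot(inherits(rules, "rule_table"))
  .assert(k >= 1, "k must be at least 1")
  n_pairs <- ceiling(min(k, nrow(rules)) / 2)
  out <- rules[seq_len(min(nrow(rules), 2 * n_pairs)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(rules), stratum = attr(rules, "stratum"),
            n = attr(rules, "n"))
}

#' @export
print.rule_table <- function(x, ...) {
  st <- attr(x, "stratum")
  cat(sprintf("<rule_table: %d directed rules, stratum %s, n = %d>\n",
              nrow(x), if (is.null(st)) "?" else format(st), attr(x, "n")))
  print.data.frame(utils::head(
    x[c("antecedent", "consequent", "support_pct", "confidence_pct",
        "lift_fmt")], 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rules\n", nrow(x) - 10))
  invisible(x)
}

#' Pairwise lift matrix (heatmap values)
#'
#' The symmetric 15 x 15 matrix of pairwise lifts underlying the lift
#' heatmap. The diagonal is `NA` (undefined), as is any pair involving a
#' disease absent from the stratum (zero marginal count) — masked, never 0.
#'
#' @inheritParams mine_rules
#' @return A 15 x 15 numeric matrix with disease-name dimnames, class
#'   `lift_matrix`.
#' @export
lift_matrix <- function(cohort, stratum = stratum_spec()) {
  pc <- pair_counts(cohort, stratum)
  marg <- pc$marginal
  expected <- outer(marg, marg) / pc$n
  lm <- ifelse(expected > 0, pc$joint / expected, NA_real_)
  diag(lm) <- NA_real_
  dimnames(lm) <- list(disease_panel(), disease_panel())
  structure(lm, class = c("lift_matrix", "matrix"))
}

#' Export a rule table as CSV
#'
#' Columns: antecedent, consequent, n, n_x, n_y, n_xy, support_pct,
#' confidence_pct, lift — a superset of the printed rule-table layout.
#'
#' @param rules A `rule_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_table"))
  out <- as.data.frame(rules)[c("antecedent", "consequent", "n", "n_x",
                                "n_y", "n_xy", "support_pct",
                                "confidence_pct", "lift")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a lift matrix as a square CSV
#'
#' @param m A `lift_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lift_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
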