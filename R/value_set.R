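#' Construct an additive EQ-5D-3L value set
#'
#' An EQ-5D-3L value set maps a five-dimension health state (mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression; levels
#' 1-3) to a utility index via the additive "N3" model:
#' \deqn{index = 1 - c \cdot [any > 1] - \sum_d \delta_{d,level_d} -
#'   n3 \cdot [any = 3]}
#' where \eqn{c} is a constant deducted as soon as any dimension departs from
#' full health, \eqn{\delta} are per-dimension level-2/level-3 deductions,
#' and \eqn{n3} is deducted once if any dimension is at level 3. Full health
#' (1,1,1,1,1) always scores exactly 1.0 and the worst state (3,3,3,3,3)
#' scores the set's floor.
#'
#' @param name Label for the value set.
#' @param intercept_deduction Constant deduction if any dimension > 1.
#' @param level2_deductions,level3_deductions Numeric length-5 vectors of
#'   nonnegative deductions, in dimension order MO, SC, UA, PD, AD.
#' @param n3_deduction Deduction applied once if any dimension equals 3.
#' @return An object of class `eq5d_value_set`.
#' @export
#' @examples
#' vs <- value_set("toy", 0.05, rep(0.04, 5), rep(0.1, 5), 0.2)
#' score_eq5d(c(1, 2, 1, 1, 1), vs)  # 1 - 0.05 - 0.04 = 0.91
value_set <- function(name, intercept_deduction, level2_deductions,
                      level3_deductions, n3_deduction) {
  dims <- c("MO", "SC", "UA", "PD", "AD")
  .assert(length(level2_deductions) == 5L && length(level3_deductions) == 5L,
          "level2/level3 deductions must each have length 5")
  dd <- c(intercept_deduction, level2_deductions, level3_deductions,
          n3_deduction)
  .assert(all(is.finite(dd)) && all(dd >= 0),
          "all value-set deductions must be finite and nonnegative")
  vs <- structure(list(
    name = as.character(name),
    intercept_deduction = as.numeric(intercept_deduction),
    level2_deductions = stats::setNames(as.numeric(level2_deductions), dims),
    level3_deductions = stats::setNames(as.numeric(level3_deductions), dims),
    n3_deduction = as.numeric(n3_deduction)
  ), class = "eq5d_value_set")
  vs$floor <- score_eq5d(c(3, 3, 3, 3, 3), vs)
  vs
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat(sprintf("<eq5d_value_set: %s>\n", x$name))
  cat(sprintf("  intercept deduction: %.3f   N3 deduction: %.3f\n",
              x$intercept_deduction, x$n3_deduction))
  cat("  level-2:", paste(sprintf("%s=%.3f", names(x$level2_deductions),
                                  x$level2_deductions), collapse = " "), "\n")
  cat("  level-3:", paste(sprintf("%s=%.3f", names(x$level3_deductions),
                                  x$level3_deductions), collapse = " "), "\n")
  cat(sprintf("  index range: [%.3f, 1.000]\n", x$floor))
  invisible(x)
}

#' Load a bundled or on-disk value set
#'
#' Two sets ship with the package as editable YAML under
#' `inst/extdata/`:
#' \describe{
#'   \item{`"korean_3l_synthetic"`}{A synthetic Korean-style N3 value set.
#'     The published Korean tariff coefficients are not redistributed here;
#'     these coefficients are synthetic stand-ins constrained so that the
#'     worst state (3,3,3,3,3) scores exactly -0.17, reproducing the
#'     documented index range of the Korean EQ-5D-3L scale (-0.17 to 1.00).}
#'   \item{`"toy"`}{A small round-number set used in examples and tests
#'     (intercept 0.05, all level-2 deductions 0.04, all level-3 deductions
#'     0.30, N3 0.20).}
#' }
#'
#' @param name Bundled set name, or a path to a YAML file with fields
#'   `name`, `intercept_deduction`, `level2_deductions`, `level3_deductions`
#'   (each a 5-element MO/SC/UA/PD/AD map), `n3_deduction`, and optionally a
#'   declared `floor` that is verified against the computed worst-state score.
#' @return An `eq5d_value_set`.
#' @export
#' @examples
#' vs <- load_value_set("korean_3l_synthetic")
#' vs$floor  # -0.17
load_value_set <- function(name = "korean_3l_synthetic") {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", paste0("value_set_", name, ".yaml"),
                     package = "morbnet")
    .assert(nzchar(p), "unknown value set '%s' and no such file exists", name)
    p
  }
  y <- yaml::read_yaml(path)
  vs <- value_set(y$name,
                  y$intercept_deduction,
                  unlist(y$level2_deductions)[c("MO", "SC", "UA", "PD", "AD")],
                  unlist(y$level3_deductions)[c("MO", "SC", "UA", "PD", "AD")],
                  y$n3_deduction)
  if (!is.null(y$floor)) {
    .assert(abs(vs$floor - y$floor) < 1e-9,
            "declared floor %.4f does not match computed worst-state score %.4f",
            y$floor, vs$floor)
  }
  vs
}

#' Score EQ-5D-3L responses to a utility index
#'
#' Pure additive scoring under [value_set()]: exact arithmetic to value-set
#' precision, vectorised over records. Records with missing responses are
#' expected to be excluded upstream; `NA` levels raise an error here.
#'
#' @param responses Either a length-5 vector (one health state) or an n x 5
#'   matrix/data.frame of levels in \{1, 2, 3\}, columns in MO, SC, UA, PD,
#'   AD order.
#' @param value_set An `eq5d_value_set`.
#' @return Numeric utility index (length n), 1.0 for full health.
#' @export
#' @examples
#' vs <- load_value_set("toy")
#' score_eq5d(c(1, 1, 1, 1, 1), vs)
#' score_eq5d(rbind(c(1, 2, 1, 1, 1), c(3, 3, 3, 3, 3)), vs)
score_eq5d <- function(responses, value_set) {
  stopifnot(inherits(value_set, "eq5d_value_set"))
  r <- if (is.null(dim(responses))) {
    matrix(as.numeric(responses), nrow = 1L)
  } else {
    as.matrix(responses)
  }
  .assert(ncol(r) == 5L, "responses must have 5 dimensions, got %d", ncol(r))
  .assert(!anyNA(r) && all(r %in% c(1, 2, 3)),
          "all responses must be levels 1, 2 or 3")
  l2 <- (r == 2) %*% value_set$level2_deductions
  l3 <- (r == 3) %*% value_set$level3_deductions
  any_gt1 <- apply(r > 1, 1L, any)
  any_3 <- apply(r == 3, 1L, any)
  idx <- 1 - value_set$intercept_deduction * any_gt1 - l2 - l3 -
    value_set$n3_deduction * any_3
  as.numeric(idx)
}

#' Classify an EQ-5D index into poor / normal / good HRQoL
#'
#' The three HRQoL groups partition the attainable index range:
#' poor is `index <= poor_cutoff` (ties at the cutoff are poor), good is
#' exactly full health (`index == 1`), normal is strictly between. The
#' default cutoff 0.721 is the lowest-5% cutpoint of the Korean adult
#' survey population's EQ-5D index distribution.
#'
#' @param index Numeric vector of utility indices.
#' @param poor_cutoff Poor-HRQoL threshold (default 0.721).
#' @return Factor with levels `poor`, `normal`, `good`.
#' @export
#' @examples
#' classify_hrqol(c(0.721, 0.86, 1.0))
classify_hrqol <- function(index, poor_cutoff = 0.721) {
  .assert(all(is.finite(index)), "index contains non-finite values")
  .assert(poor_cutoff < 1, "poor_cutoff must be below full health")
  out <- ifelse(index <= poor_cutoff, "poor",
                ifelse(index == 1, "good", "normal"))
  factor(out, levels = .hrqol_levels)
}

#' Empirical poor-HRQoL cutoff from an index distribution
#'
#' Returns the empirical `quantile`-fraction cutpoint of a vector of EQ-5D
#' indices, using the inverse empirical CDF (order-statistic, `type = 1`)
#' convention: the smallest observed value v with F(v) >= quantile, so that
#' "the lowest 5%" is the set `index <= derive_cutoff(index)`. The fixed
#' default cutoff 0.721 used elsewhere in the package bypasses this
#' function; deriving 0.721 itself would require the full national adult
#' survey microdata and is documented as context only.
#'
#' @param indices Nonempty numeric vector of utility indices.
#' @param quantile Fraction in (0, 1) (default 0.05).
#' @return The cutoff utility.
#' @export
#' @examples
#' derive_cutoff(seq(0.01, 1, by = 0.01))  # 0.05
derive_cutoff <- function(indices, quantile = 0.05) {
  .assert(length(indices) > 0, "cannot derive a cutoff from an empty vector")
  .assert(quantile > 0 && quantile < 1, "quantile must be in (0,1)")
  unname(stats::quantile(indices, probs = quantile, type = 1, names = FALSE))
}
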