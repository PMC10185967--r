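#' Write a cohort to a delimited text file
#'
#' Plain CSV, one row per participant, with a two-line `#` comment header
#' documenting the dialect: disease flags are the 0/1 columns
#' `dz_<disease>` in panel order, EQ-5D responses (if present) are
#' `eq5d_mo` .. `eq5d_ad`, the utility index is `eq5d_index`, and missing
#' values are empty cells. Any passthrough columns are written as-is.
#'
#' @param cohort A `morb_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "morb_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# morbnet-cohort v1: CSV, one row per participant; missing = empty cell",
    paste0("# diseases (dz_* columns, 0/1, panel order): ",
           paste(disease_panel(), collapse = ","))
  ), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from a delimited text file
#'
#' Inverse of [write_cohort()]: reads the CSV (ignoring `#` comment lines)
#' and revalidates through [morb_cohort()], so disease columns are checked
#' against the expected panel, the HRQoL group is rederived from the index,
#' and unknown `dz_*` columns raise an error listing the panel. Extra
#' covariate columns are preserved and flagged as passthrough.
#'
#' @param path Input file path.
#' @inheritParams morb_cohort
#' @return A `morb_cohort`.
#' @export
read_cohort <- function(path, value_set = NULL, poor_cutoff = 0.721) {
  .assert(file.exists(path), "no such cohort file: %s", path)
  df <- utils::read.csv(path, comment.char = "#", na.strings = "",
                        stringsAsFactors = FALSE)
  morb_cohort(df, value_set = value_set, poor_cutoff = poor_cutoff)
}
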