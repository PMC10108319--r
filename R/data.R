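# Effect-size datasets: one row per effect size with the raw summary
# statistics of the two groups. Missing SDs are NA (never 0; an observed SD
# of 0 is data). Extra columns are carried through untouched.

required_columns <- c("study_id", "effect_id", "m1", "sd1", "n1", "m2", "sd2", "n2")

#' Validate and classify an effect-size data frame
#'
#' Checks the schema and row-level invariants of a meta-analytic dataset
#' (positive means, integer sample sizes >= 2, nonnegative or missing SDs)
#' and returns it classed as \code{effect_data} with an \code{sd_missing}
#' indicator column (TRUE when either group's SD is NA).
#'
#' @param data A data frame with columns \code{study_id}, \code{effect_id},
#'   \code{m1}, \code{sd1}, \code{n1}, \code{m2}, \code{sd2}, \code{n2}.
#'   Additional columns are preserved.
#' @return The validated data frame, classed \code{c("effect_data",
#'   "data.frame")}, with a logical \code{sd_missing} column.
#' @export
as_effect_data <- function(data) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(required_columns, names(data))
  if (length(missing_cols) > 0) {
    lnrr_error("schema", sprintf(
      "missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("m1", "sd1", "m2", "sd2")) data[[col]] <- as.double(data[[col]])
  for (col in c("n1", "n2")) data[[col]] <- as.numeric(data[[col]])
  for (col in c("m1", "n1", "m2", "n2")) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0) {
      lnrr_error("value", sprintf("column %s has missing/non-finite value in row %d",
                                  col, bad[1]))
    }
  }
  for (col in c("m1", "m2")) {
    bad <- which(data[[col]] <= 0)
    if (length(bad) > 0) {
      lnrr_error("value", sprintf(
        "nonpositive mean in column %s, row %d (lnRR requires ratio-scale data)",
        col, bad[1]))
    }
  }
  for (col in c("n1", "n2")) {
    bad <- which(data[[col]] < 2 | data[[col]] != round(data[[col]]))
    if (length(bad) > 0) {
      lnrr_error("value", sprintf("column %s must be an integer >= 2; bad value in row %d",
                                  col, bad[1]))
    }
  }
  for (col in c("sd1", "sd2")) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(bad) > 0) {
      lnrr_error("value", sprintf("negative SD in column %s, row %d", col, bad[1]))
    }
  }
  dup <- duplicated(data[c("study_id", "effect_id")])
  if (any(dup)) {
    lnrr_error("value", sprintf("duplicated (study_id, effect_id) in row %d",
                                which(dup)[1]))
  }
  data$sd_missing <- is.na(data$sd1) | is.na(data$sd2)
  class(data) <- unique(c("effect_data", class(data)))
  data
}

#' Read an effect-size dataset from delimited text
#'
#' Reads a CSV with header columns \code{study_id, effect_id, m1, sd1, n1,
#' m2, sd2, n2} (extra columns pass through). Empty SD cells and the token
#' \code{NA} parse as missing; \code{0} is a valid observed SD, distinct from
#' missing.
#'
#' @param path Path to a CSV file.
#' @return An \code{effect_data} data frame (see \code{\link{as_effect_data}}).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    lnrr_error("schema", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  as_effect_data(raw)
}

#' Write an effect-size dataset to CSV
#'
#' Inverse of \code{\link{read_dataset}}: missing SDs are written as empty
#' cells, full numeric precision is kept, and the derived \code{sd_missing}
#' column is dropped so that a read/write round trip is value-identical.
#'
#' @param data An \code{effect_data} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  out <- as.data.frame(data)
  out$sd_missing <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep only effect sizes with complete SDs
#'
#' The subset a "complete-case" analysis would retain: rows where both
#' groups report an SD, in their original order. May be empty.
#'
#' @param data An \code{effect_data} data frame.
#' @return The complete-SD subset, still classed \code{effect_data}.
#' @export
complete_case_filter <- function(data) {
  data <- as_effect_data(data)
  data[!data$sd_missing, , drop = FALSE]
}
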