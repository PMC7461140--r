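#' Column schema shared by all regenerant tables
#'
#' One row per regenerated plant: two integrated band absorbances
#' (710--690 and 1010--940 cm-1), their sum, the metAFLP demethylation
#' characteristics (total, CG-context, CHG-context, all in percent), the
#' sequence-variation percentage, the trial label and the culture time.
#' @keywords internal
#' @noRd
regenerant_columns <- c(
  "sample_no", "trial", "f710_690", "f1010_940", "f_combined",
  "dmv", "cg_dmv", "chg_dmv", "sv", "time_days"
)

regenerant_numeric <- setdiff(regenerant_columns, "trial")

#' The 35-regenerant barley dataset
#'
#' Integrated ATR-FTIR band absorbances and metAFLP quantitative
#' characteristics for 35 barley plants regenerated by in vitro anther
#' culture under nine trials (M1--M9) differing in Cu2+/Ag+ supplementation
#' and culture duration (21, 28 or 35 days). `f710_690` and `f1010_940` are
#' areas under the area-normalized absorbance curve over 710--690 and
#' 1010--940 cm-1; `f_combined` is their sum. `dmv`, `cg_dmv`, `chg_dmv` are
#' demethylation percentages (total, CG context, CHG context); `sv` is the
#' sequence-variation percentage between donor and regenerant.
#'
#' One typographical defect in the source table (row 35, a space inside the
#' total-demethylation value) is repaired to `2.0940`, the only reading
#' consistent with the column format and with `dmv = cg_dmv + chg_dmv`
#' within tolerance.
#'
#' @return A validated tibble with 35 rows and the columns listed above.
#' @examples
#' reg <- regenerant_data()
#' dplyr::count(reg, trial, time_days)
#' @export
regenerant_data <- function() {
  path <- system.file("extdata", "barley_regenerants.csv",
                      package = "spectromed", mustWork = TRUE)
  read_regenerant_table(path)
}

#' Read and validate a regenerant table
#'
#' Reads a CSV in the schema of [regenerant_data()] and validates every row
#' against the schema invariants: culture time in \{21, 28, 35\} days,
#' `f_combined = f710_690 + f1010_940` (tolerance 1e-4, the rounding
#' granularity of a 4-decimal table), `dmv = cg_dmv + chg_dmv` (tolerance
#' 5e-3), and non-negative absorbances and percentages.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping standard column
#'   names (names) to the column names used in the file (values), for files
#'   whose headers differ from the canonical schema.
#' @return A validated tibble.
#' @seealso [write_regenerant_table()], [validate_regenerants()]
#' @export
read_regenerant_table <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("Schema maps to columns absent from file: ",
                   paste(missing_src, collapse = ", ")),
            class = "spectromed_schema_error")
    }
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  missing <- setdiff(regenerant_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "spectromed_schema_error")
  }
  raw <- raw[regenerant_columns]
  bad_num <- regenerant_numeric[!vapply(raw[regenerant_numeric], is.numeric, logical(1))]
  if (length(bad_num) > 0) {
    abort(paste0("Non-numeric values in column(s): ", paste(bad_num, collapse = ", ")),
          class = "spectromed_parse_error")
  }
  validate_regenerants(raw)
}

#' Validate regenerant records against the schema invariants
#'
#' @param data A data frame in the [regenerant_data()] schema.
#' @param tol_combined Absolute tolerance on
#'   `f_combined - (f710_690 + f1010_940)`. The default, 1e-4, is the
#'   rounding step of a 4-decimal table, so independently rounded columns
#'   can disagree by exactly one unit in the last place.
#' @param tol_dmv Absolute tolerance on `dmv - (cg_dmv + chg_dmv)`.
#' @return The input as a tibble, invisibly validated (an error lists every
#'   offending row otherwise).
#' @export
validate_regenerants <- function(data, tol_combined = 1e-4, tol_dmv = 5e-3) {
  data <- as_tibble(data)
  problems <- character()
  row_err <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " (row ", paste(rows, collapse = ", "), ")"))
    }
  }
  if (anyNA(data[regenerant_numeric])) {
    row_err(which(!complete.cases(data[regenerant_numeric])), "missing numeric value")
  }
  row_err(which(!data$time_days %in% c(21, 28, 35)),
          "time_days outside {21, 28, 35}")
  # inclusive comparison with a float guard so a printed-table discrepancy of
  # exactly one rounding unit still validates
  d_comb <- abs(data$f_combined - data$f710_690 - data$f1010_940)
  row_err(which(d_comb > tol_combined + 1e-12), "f_combined != f710_690 + f1010_940")
  d_dmv <- abs(data$dmv - data$cg_dmv - data$chg_dmv)
  row_err(which(d_dmv > tol_dmv + 1e-12), "dmv != cg_dmv + chg_dmv")
  neg <- c("f710_690", "f1010_940", "f_combined", "dmv", "cg_dmv", "chg_dmv", "sv")
  for (col in neg) {
    row_err(which(data[[col]] < 0), paste0("negative ", col))
  }
  if (anyDuplicated(data$sample_no)) {
    row_err(which(duplicated(data$sample_no)), "duplicated sample_no")
  }
  if (length(problems) > 0) {
    abort(c("Regenerant table fails validation:", problems),
          class = "spectromed_validation_error")
  }
  data
}

#' Write a regenerant table to CSV
#'
#' Writes with the canonical column order and full floating-point precision
#' so that `read_regenerant_table(write_regenerant_table(x))` round-trips
#' exactly.
#'
#' @param data A data frame in the [regenerant_data()] schema (may be empty).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_regenerant_table <- function(data, path) {
  missing <- setdiff(regenerant_columns, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "spectromed_schema_error")
  }
  readr::write_csv(as_tibble(data)[regenerant_columns], path, progress = FALSE)
  invisible(path)
}
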