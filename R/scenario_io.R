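# Convert one side of a scenario row (type rr/or/r + value + optional p0)
# to the risk-ratio scale. `where` names the row/side for error messages.
scenario_side_to_rr <- function(type, value, p0, where) {
  type <- tolower(type)
  if (!type %in% c("rr", "or", "r")) {
    stop(where, ": unknown association type '", type,
         "' (expected rr, or, or r)", call. = FALSE)
  }
  if (type == "rr") {
    return(value)
  }
  or <- if (type == "r") r_to_or(value) else value
  if (is.null(p0) || is.na(p0)) {
    stop(where, ": baseline risk p0 is required to convert ",
         if (type == "r") "a correlation (via OR)" else "an odds ratio",
         " to a risk ratio", call. = FALSE)
  }
  or_to_rr(or, p0)
}

#' Read and validate a confounder-scenario table
#'
#' Expected CSV columns: `name`, `exposure_assoc_type` (`rr`, `or` or `r`),
#' `exposure_assoc_value`, `exposure_p0`, `outcome_assoc_type`,
#' `outcome_assoc_value`, `outcome_p0`. Associations given as odds ratios or
#' correlations are converted onto the risk-ratio scale (correlations via the
#' standardised-mean-difference chain of [r_to_or()], then [or_to_rr()]); a
#' missing baseline risk where one is required is a validation error naming
#' the row. Lines starting with `#` are treated as comments.
#'
#' @param path Path to the CSV file.
#' @return A list of [confounder_scenario()] objects (empty list for an
#'   empty table, with a warning).
#' @export
read_scenario_table <- function(path) {
  if (!file.exists(path)) {
    stop("scenario table not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("name", "exposure_assoc_type", "exposure_assoc_value",
                "outcome_assoc_type", "outcome_assoc_value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("scenario table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"exposure_p0" %in% names(tab)) tab$exposure_p0 <- NA_real_
  if (!"outcome_p0" %in% names(tab)) tab$outcome_p0 <- NA_real_
  if (nrow(tab) == 0) {
    warning("scenario table is empty", call. = FALSE)
    return(list())
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    rr_eu <- scenario_side_to_rr(row$exposure_assoc_type,
                                 row$exposure_assoc_value, row$exposure_p0,
                                 sprintf("row %d ('%s'), exposure side",
                                         i, row$name))
    rr_ud <- scenario_side_to_rr(row$outcome_assoc_type,
                                 row$outcome_assoc_value, row$outcome_p0,
                                 sprintf("row %d ('%s'), outcome side",
                                         i, row$name))
    if (rr_eu < 1 || rr_ud < 1) {
      stop(sprintf(
        "row %d ('%s'): converted associations must be >= 1 (got RR_EU = %.3f, RR_UD = %.3f); orient the scenario first",
        i, row$name, rr_eu, rr_ud), call. = FALSE)
    }
    confounder_scenario(row$name, rr_eu = rr_eu, rr_ud = rr_ud,
                        provenance = sprintf(
                          "exposure: %s = %g; outcome: %s = %g",
                          row$exposure_assoc_type, row$exposure_assoc_value,
                          row$outcome_assoc_type, row$outcome_assoc_value))
  })
}
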