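#' Read a long-format crossover concentration table
#'
#' Reads and validates participant-level naloxone concentration data in
#' the long layout used by the crossover trial: one row per participant,
#' period and nominal sampling time.  Column names can be remapped via
#' `col_map` so deposited tables with different headers can be consumed
#' without editing the file.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping the canonical
#'   names (`participant`, `sequence`, `period`, `arm`, `nominal_time`,
#'   `concentration`, `blq`, and optionally `actual_time`) to the column
#'   names used in the file.
#' @param time_window Half-width (min) of the acceptance window around
#'   each nominal time; rows with an `actual_time` further away are
#'   flagged (`out_of_window = TRUE`), never dropped.
#'
#' @return A `data.frame` with the canonical columns above plus
#'   `out_of_window`; one row per sample.
#' @export
read_trial_table <- function(path, col_map = NULL, time_window = 60) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(raw, col_map = col_map, time_window = time_window)
}

#' Validate an in-memory trial table
#'
#' Same checks as [read_trial_table()] for a data frame already in
#' memory (e.g. output of [generate_trial()]).
#'
#' @inheritParams read_trial_table
#' @param data A data frame.
#' @return Validated data frame with canonical columns.
#' @export
validate_trial_table <- function(data, col_map = NULL, time_window = 60) {
  canonical <- c("participant", "sequence", "period", "arm",
                 "nominal_time", "concentration", "blq")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(data)) {
        names(data)[names(data) == col_map[[nm]]] <- nm
      }
    }
  }
  missing <- setdiff(canonical, names(data))
  if (length(missing)) {
    stop("trial table is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  data$blq <- as.logical(data$blq)
  if (anyNA(data$blq)) stop("column 'blq' must be logical (TRUE/FALSE)")
  bad_conc <- !data$blq & (!is.finite(data$concentration) | data$concentration < 0)
  if (any(bad_conc)) {
    stop("column 'concentration': ", sum(bad_conc),
         " quantifiable rows are negative or non-finite")
  }
  if (!all(data$period %in% 1:3)) stop("column 'period' must be 1, 2 or 3")
  if (!all(data$nominal_time %in% protocol_times())) {
    stop("column 'nominal_time' contains values outside the 16-point protocol grid")
  }
  if ("actual_time" %in% names(data)) {
    data$out_of_window <- is.finite(data$actual_time) &
      abs(data$actual_time - data$nominal_time) > time_window
  } else {
    data$out_of_window <- FALSE
  }
  data[canonical] <- data[canonical]
  data
}
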