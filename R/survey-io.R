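#' Read a long-format vegetation survey CSV
#'
#' The canonical input is a UTF-8 comma-separated file with header
#' `campaign_id,date,plot_id,zone,species,abundance,cover_cm2`, one row per
#' (campaign, plot, species) observation. Plots without individuals in a
#' campaign carry no rows; supply the full panel through `plot_roster` so
#' that empty plots are retained as zeros downstream.
#'
#' @param path file path of the survey CSV.
#' @param plot_roster optional character vector of all monitored plot ids.
#' @param campaign_roster optional data.frame (`campaign_id`, `date`) of
#'   all campaigns in survey order.
#' @param ... passed to [survey_table()] (e.g. `cover_cap`, `strict`).
#' @return a validated [survey_table()].
#' @export
read_survey <- function(path, plot_roster = NULL, campaign_roster = NULL,
                        ...) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character",
                             fileEncoding = "UTF-8")
  required <- c("campaign_id", "date", "plot_id", "zone", "species",
                "abundance", "cover_cm2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("survey file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  suppressWarnings({
    abundance <- as.numeric(records$abundance)
    cover <- as.numeric(records$cover_cm2)
  })
  if (anyNA(abundance) || anyNA(cover)) {
    bad <- which(is.na(abundance) | is.na(cover))
    stop("non-numeric abundance/cover in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  records$abundance <- abundance
  records$cover_cm2 <- cover
  survey_table(records, plots = plot_roster, campaigns = campaign_roster, ...)
}

#' Write a survey table to CSV
#'
#' Writes the record table in the canonical column order; the output
#' round-trips through [read_survey()] to a record-identical table. The
#' writer is deterministic: records are sorted by campaign order, plot and
#' species.
#'
#' @param table a [survey_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  rec <- table$records
  ord <- order(match(rec$campaign_id, table$campaigns$campaign_id),
               rec$plot_id, rec$species)
  rec <- rec[ord, , drop = FALSE]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Flag campaigns whose absolute cover is overestimated
#'
#' Field protocols that measure each overlapping individual separately
#' overestimate total cover. Flagged campaigns are excluded from all
#' statistics that use absolute cover (campaign mean cover, cover
#' seasonality, cover t-tests) but are retained wherever cover enters only
#' as a relative value (the importance value index).
#'
#' @param table a [survey_table()].
#' @param campaigns character vector of campaign ids to flag (may be empty).
#' @return the table with updated `flags`.
#' @export
flag_overestimated_cover <- function(table, campaigns) {
  stopifnot(inherits(table, "survey_table"))
  campaigns <- as.character(campaigns)
  unknown <- setdiff(campaigns, table$campaigns$campaign_id)
  if (length(unknown) > 0) {
    stop("unknown campaign id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table$flags[campaigns] <- TRUE
  table
}

#' Read a monthly climate CSV
#'
#' Expects columns `month` (`YYYY-MM`), `precip_mm`, `temp_c`.
#'
#' @param path file path.
#' @return a [climate_series()] sorted chronologically.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  required <- c("month", "precip_mm", "temp_c")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("climate file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  climate_series(d$month, d$precip_mm, d$temp_c)
}

#' Write a climate series to CSV
#' @param climate a [climate_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(climate, path) {
  stopifnot(inherits(climate, "climate_series"))
  utils::write.csv(as.data.frame(climate), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# "YYYY-MM" -> integer year
month_year <- function(month) as.integer(substr(month, 1, 4))

# "YYYY-MM" -> integer month-of-year
month_of_year <- function(month) as.integer(substr(month, 6, 7))
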