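#' Survey table container
#'
#' A `survey_table` holds long-format repeated vegetation-survey records
#' together with the fixed plot roster (a fixed panel of monitored plots:
#' plots with no records in a campaign are real zeros, not missing data),
#' the ordered campaign roster, and per-campaign data-quality flags for
#' campaigns whose absolute cover measurements are known to be
#' overestimated.
#'
#' @param records data.frame with columns `campaign_id`, `date` (calendar
#'   month, `"YYYY-MM"`), `plot_id`, `zone` (`"low"`, `"medium"` or
#'   `"high"`), `species`, `abundance` (non-negative integer count) and
#'   `cover_cm2` (non-negative area in cm2 per 1 m2 plot).
#' @param plots optional character vector: the full roster of monitored
#'   plot ids. Defaults to the plots present in `records`. Plots in the
#'   roster but absent from a campaign's records contribute zeros to all
#'   per-plot statistics.
#' @param campaigns optional data.frame with columns `campaign_id`, `date`
#'   giving the ordered campaign roster; defaults to the campaigns present
#'   in `records`, ordered by date.
#' @param zones optional named character vector mapping plot_id to
#'   tourist-use zone; defaults to the mapping observed in `records`.
#' @param cover_cap per-record physical cover cap in cm2 (default 10000,
#'   i.e. the plot area). Overlapping perpendicular projections can
#'   legitimately exceed plot area, so exceeding the cap raises a warning
#'   unless `strict = TRUE`, in which case it is an error.
#' @param strict logical; promote the cover-cap warning to an error.
#'
#' @return an object of class `survey_table`: a list with elements
#'   `records`, `plots`, `campaigns`, `zones` and `flags` (named logical,
#'   one per campaign: `TRUE` means absolute cover is overestimated).
#' @seealso [read_survey()], [flag_overestimated_cover()]
#' @export
survey_table <- function(records, plots = NULL, campaigns = NULL,
                         zones = NULL, cover_cap = 10000, strict = FALSE) {
  required <- c("campaign_id", "date", "plot_id", "zone", "species",
                "abundance", "cover_cm2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("survey records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  for (col in c("campaign_id", "date", "plot_id", "zone", "species")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$abundance <- as.numeric(records$abundance)
  records$cover_cm2 <- as.numeric(records$cover_cm2)

  bad <- which(!is.finite(records$abundance) | records$abundance < 0 |
                 records$abundance != round(records$abundance))
  if (length(bad) > 0) {
    stop("abundance must be a non-negative integer count; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$cover_cm2) | records$cover_cm2 < 0)
  if (length(bad) > 0) {
    stop("cover_cm2 must be non-negative; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$abundance == 0 & records$cover_cm2 > 0)
  if (length(bad) > 0) {
    stop("cover must be 0 when abundance is 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_zone <- setdiff(unique(records$zone), c("low", "medium", "high"))
  if (length(bad_zone) > 0) {
    stop("zone must be one of low/medium/high; found: ",
         paste(bad_zone, collapse = ", "), call. = FALSE)
  }
  key <- paste(records$campaign_id, records$plot_id, records$species,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (campaign_id, plot_id, species) record(s); row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  over <- which(records$cover_cm2 > cover_cap)
  if (length(over) > 0) {
    msg <- sprintf("%d record(s) exceed the cover cap of %g cm2 (max %g)",
                   length(over), cover_cap, max(records$cover_cm2[over]))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  if (is.null(campaigns)) {
    campaigns <- unique(records[c("campaign_id", "date")])
    campaigns <- campaigns[order(campaigns$date, campaigns$campaign_id), ,
                           drop = FALSE]
  } else {
    campaigns <- as.data.frame(campaigns)[c("campaign_id", "date")]
    campaigns$campaign_id <- as.character(campaigns$campaign_id)
    campaigns$date <- as.character(campaigns$date)
  }
  rownames(campaigns) <- NULL
  if (anyDuplicated(campaigns$campaign_id)) {
    stop("duplicate campaign_id in campaign roster", call. = FALSE)
  }
  unknown <- setdiff(unique(records$campaign_id), campaigns$campaign_id)
  if (length(unknown) > 0) {
    stop("records reference campaign(s) not in the roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  if (is.null(plots)) {
    plots <- sort(unique(records$plot_id))
  } else {
    plots <- as.character(plots)
    unknown <- setdiff(unique(records$plot_id), plots)
    if (length(unknown) > 0) {
      stop("records reference plot(s) not in the roster: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  if (is.null(zones)) {
    zmap <- unique(records[c("plot_id", "zone")])
    if (anyDuplicated(zmap$plot_id)) {
      stop("plot(s) assigned to more than one zone", call. = FALSE)
    }
    zones <- stats::setNames(zmap$zone, zmap$plot_id)
  }

  flags <- stats::setNames(rep(FALSE, nrow(campaigns)), campaigns$campaign_id)

  structure(
    list(records = records, plots = plots, campaigns = campaigns,
         zones = zones, flags = flags),
    class = "survey_table"
  )
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table>\n")
  cat("  campaigns:", nrow(x$campaigns),
      sprintf("(%s .. %s)", x$campaigns$date[1],
              x$campaigns$date[nrow(x$campaigns)]), "\n")
  cat("  plots:    ", length(x$plots), "\n")
  cat("  species:  ", length(unique(x$records$species)), "\n")
  cat("  records:  ", nrow(x$records), "\n")
  if (any(x$flags)) {
    cat("  cover flagged:", paste(names(x$flags)[x$flags], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Monthly climate series
#'
#' @param month character vector of calendar months, `"YYYY-MM"`.
#' @param precip_mm total monthly precipitation, mm (non-negative).
#' @param temp_c mean monthly temperature, degrees C.
#' @return a data.frame of class `climate_series`, sorted chronologically.
#' @export
climate_series <- function(month, precip_mm, temp_c) {
  month <- as.character(month)
  if (!all(grepl("^\\d{4}-\\d{2}$", month))) {
    bad <- month[!grepl("^\\d{4}-\\d{2}$", month)]
    stop("unparseable month (expect YYYY-MM): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(month)) {
    stop("duplicate month in climate series: ",
         paste(unique(month[duplicated(month)]), collapse = ", "),
         call. = FALSE)
  }
  precip_mm <- as.numeric(precip_mm)
  temp_c <- as.numeric(temp_c)
  if (any(!is.finite(precip_mm) | precip_mm < 0)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  out <- data.frame(month = month, precip_mm = precip_mm, temp_c = temp_c,
                    stringsAsFactors = FALSE)
  out <- out[order(out$month), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("climate_series", "data.frame")
  out
}
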