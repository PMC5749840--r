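#' Seasonality index
#'
#' SI = (august - february) / august * 100: the annual range between the
#' most humid month (August in lomas climatology) and the driest one
#' (February), as a percentage of the humid-month value. SI is at most
#' 100; values near 0 indicate lost seasonality and negative values a
#' complete inversion (the dry month exceeding the humid one). Undefined
#' when the humid-month value is 0.
#'
#' @param feb value of the characteristic in the dry-season campaign.
#' @param aug value in the humid-season campaign (must be non-zero).
#' @return SI in percent.
#' @export
seasonality_index <- function(feb, aug) {
  if (!is.finite(feb) || !is.finite(aug)) {
    stop("seasonality index needs finite endpoint values", call. = FALSE)
  }
  if (aug == 0) {
    stop("seasonality index undefined: humid-month value is 0",
         call. = FALSE)
  }
  (aug - feb) / aug * 100
}

si_characteristics <- c("mean_density", "mean_cover", "mean_alpha",
                        "gamma", "richness")

#' Annual seasonality-index series
#'
#' For each calendar year, pairs the dry-window campaign (January-March)
#' with the humid-window campaign (July-September) and computes SI for
#' each community characteristic. A September campaign stands in for
#' August when that is the year's humid campaign. Years missing either
#' endpoint yield no record. The SI for mean cover is absent for years in
#' which either endpoint campaign is flagged as cover-overestimated, and
#' any SI whose humid-month value is 0 is absent (`NA`), not 0.
#'
#' @param summaries a [campaign_summary_table()] data.frame.
#' @return data.frame: `year`, `characteristic`, `si` (NA when undefined).
#' @export
si_series <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  yr <- month_year(summaries$date)
  mo <- month_of_year(summaries$date)
  window <- ifelse(mo >= 1 & mo <= 3, "dry",
                   ifelse(mo >= 7 & mo <= 9, "humid", NA))
  out <- list()
  for (y in sort(unique(yr))) {
    dry <- which(yr == y & !is.na(window) & window == "dry")
    humid <- which(yr == y & !is.na(window) & window == "humid")
    if (length(dry) > 1 || length(humid) > 1) {
      stop("year ", y, " has more than one campaign in the same seasonal ",
           "window; cannot form a dry/humid pair", call. = FALSE)
    }
    if (length(dry) == 0 || length(humid) == 0) next
    for (ch in si_characteristics) {
      feb <- summaries[[ch]][dry]
      aug <- summaries[[ch]][humid]
      flagged_cover <- ch == "mean_cover" &&
        (isTRUE(summaries$cover_flagged[dry]) ||
           isTRUE(summaries$cover_flagged[humid]))
      si <- if (flagged_cover || is.na(feb) || is.na(aug) || aug == 0) {
        NA_real_
      } else {
        seasonality_index(feb, aug)
      }
      out[[length(out) + 1]] <- data.frame(
        year = y, characteristic = ch, si = si, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(year = integer(), characteristic = character(),
                      si = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect the year seasonality stabilizes
#'
#' The earliest year y such that year y+1 also has a defined SI and
#' |SI_y - SI_{y+1}| <= tol: the reading "the index reached a stable
#' point" made numeric. Returns `NA` when no consecutive pair qualifies
#' (e.g. a steadily drifting series).
#'
#' @param series output of [si_series()].
#' @param characteristic one of `"mean_density"`, `"mean_cover"`,
#'   `"mean_alpha"`, `"gamma"`, `"richness"`.
#' @param tol stabilization tolerance in percentage points (default 10).
#' @return the stabilization year as an integer, or `NA_integer_`.
#' @export
detect_stabilization <- function(series, characteristic, tol = 10) {
  stopifnot(is.data.frame(series))
  characteristic <- match.arg(characteristic, si_characteristics)
  s <- series[series$characteristic == characteristic & !is.na(series$si), ,
              drop = FALSE]
  s <- s[order(s$year), , drop = FALSE]
  if (nrow(s) < 2) return(NA_integer_)
  for (i in seq_len(nrow(s) - 1)) {
    if (s$year[i + 1] == s$year[i] + 1 &&
        abs(s$si[i] - s$si[i + 1]) <= tol) {
      return(as.integer(s$year[i]))
    }
  }
  NA_integer_
}
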