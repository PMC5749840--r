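#' Published campaign summaries from the Lomas de Lachay monitoring
#'
#' Per-campaign plant community characteristics and monthly precipitation
#' from a 31-plot, 15-campaign monitoring of the Lomas de Lachay fog
#' oasis (central Peruvian coast) spanning the 1997-98 El Nino event and
#' the subsequent La Nina (February 1998 - December 2001), transcribed
#' from the published summary table. Mean cover of the February and
#' August 1998 campaigns is known to be overestimated (overlapping
#' individuals measured separately); those two values are kept in
#' `mean_cover_referential` and `mean_cover` is `NA`, mirroring how the
#' pipeline treats flagged campaigns.
#'
#' @return data.frame with one row per campaign: `campaign_id`, `date`,
#'   `enso_phase`, `mean_density`, `min_density`, `max_density`,
#'   `mean_cover` (NA when flagged), `min_cover`, `max_cover`,
#'   `mean_cover_referential`, `mean_alpha`, `min_alpha`, `max_alpha`,
#'   `gamma`, `richness`, `cover_flagged`, `precip_mm`.
#' @export
lachay_campaigns <- function() {
  d <- read.csv(text = "campaign_id,date,enso_phase,mean_density,min_density,max_density,mean_cover_referential,min_cover,max_cover,mean_alpha,min_alpha,max_alpha,gamma,richness,cover_flagged,precip_mm
Feb-98,1998-02,El Nino,75.5,1,847,18912,1646,111440,1.05,0,2.23,2.63,29,TRUE,48
May-98,1998-05,El Nino,16.9,1,62,7952,1500,11000,0.88,0,1.85,2.25,13,FALSE,16.5
Aug-98,1998-08,La Nina,37.3,1,141,16185,2691,104189,1.2,0,2.14,3.11,24,TRUE,46.4
Dec-98,1998-12,La Nina,14.1,1,103,9268,1575,51977,0.57,0,1.5,2.59,15,FALSE,2
Feb-99,1999-02,La Nina,4.4,1,20,5944,122,17671,0.64,0,1.92,3.11,14,FALSE,4.4
May-99,1999-05,La Nina,10.4,1,57,7176,227,44614,0.65,0,1.58,2.41,13,FALSE,18.9
Aug-99,1999-08,La Nina,8.8,0,66,4838,0,13110,0.84,0,2.32,3.1,23,FALSE,18.7
Nov-99,1999-11,La Nina,2.3,0,14,2722,0,20000,0.4,0,1.66,3.32,15,FALSE,8.2
Feb-00,2000-02,La Nina,2.2,0,17,2452,0,8081,0.34,0,1.5,2.64,11,FALSE,0
May-00,2000-05,La Nina,0.6,0,2,892,0,5675,0.06,0,1,1.98,6,FALSE,6.1
Aug-00,2000-08,La Nina,347.7,4,1655,14721,6494,25652,1.58,0,2.91,3.28,41,FALSE,40.2
Nov-00,2000-11,La Nina,1.3,0,6,1489,0,7854,0.19,0,1.58,3,11,FALSE,1.4
Feb-01,2001-02,La Nina,0.5,0,4,983,0,5675,0.09,0,1,1.24,3,FALSE,0.4
Sep-01,2001-09,Normal,347.6,5,1506,11728,1806,22762,1.4,0.21,2.57,3.23,37,FALSE,29.2
Dec-01,2001-12,Normal,1.6,0,13,1304,0,8908,0.13,0,1.5,2.59,9,FALSE,1.2",
                stringsAsFactors = FALSE)
  d$mean_cover <- ifelse(d$cover_flagged, NA_real_,
                         d$mean_cover_referential)
  d[c("campaign_id", "date", "enso_phase", "mean_density", "min_density",
      "max_density", "mean_cover", "min_cover", "max_cover",
      "mean_cover_referential", "mean_alpha", "min_alpha", "max_alpha",
      "gamma", "richness", "cover_flagged", "precip_mm")]
}

#' Climate series for the Lachay campaign months
#'
#' Monthly total precipitation as published per campaign, paired with a
#' SYNTHETIC stand-in for mean monthly temperature built from the site's
#' published climatology (13.5 degC in the humid season to 22.5 degC in
#' the dry season, a smooth annual cycle). Per-campaign temperature
#' observations were not published; the climatological stand-in is
#' defensible here because temperature during the monitoring matched a
#' typical year, but results that depend on it are stand-in results, not
#' reproductions.
#'
#' @return a [climate_series()] with one row per campaign month.
#' @export
lachay_climate <- function() {
  d <- lachay_campaigns()
  climate_series(d$date, d$precip_mm,
                 round(climatology_temp(month_of_year(d$date)), 1))
}
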