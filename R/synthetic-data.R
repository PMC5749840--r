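#' Configuration for the synthetic survey generator
#'
#' The defaults emulate the monitoring design the pipeline targets: a
#' fixed panel of 31 one-m2 plots surveyed 4 times a year (February, May,
#' August, November) for 15 campaigns, 60 species, a lomas climatology
#' where monthly precipitation rises from ~0 mm in the austral summer to
#' ~30 mm in the humid season (July-September), and an ENSO pulse of
#' ~100 mm added to the months of designated campaigns (by default the
#' first year), ten times a typical month and about three times the
#' humid-season maximum.
#'
#' @param n_plots number of plots (default 31).
#' @param n_campaigns number of campaigns, 4 per year (default 15).
#' @param n_species species pool size (default 60).
#' @param seed integer RNG seed; a fixed seed makes the output
#'   bit-identical.
#' @param responder_fraction share of species whose expected abundance
#'   responds to precipitation (default 0.3).
#' @param responder_strength log-scale precipitation coefficient b of
#'   responders: expected count scales as (1 + P)^b (default 1).
#' @param base_abundance scale of expected per-plot counts at zero
#'   precipitation (default 0.05: with 60 species this puts dry-month
#'   plot densities in the single digits and humid-month densities in
#'   the tens to hundreds, the magnitudes seen in lomas panels).
#' @param dominance standard deviation of the lognormal rank-abundance
#'   law for species base abundances; larger means a steeper dominance
#'   structure (default 1.5).
#' @param dispersion negative-binomial size parameter; smaller is more
#'   overdispersed (default 0.7, typical of clumped plant counts).
#' @param cover_size_log_sd lognormal sd of per-individual cover
#'   (default 0.6).
#' @param mean_individual_cover mean cover of one individual, cm2
#'   (default 150).
#' @param seasonal_amplitude_mm humid-season precipitation peak, mm
#'   (default 30).
#' @param enso_pulse_mm ENSO precipitation pulse, mm (default 100).
#' @param enso_campaigns indices of campaigns whose months receive the
#'   pulse (default 1:4, the first survey year).
#' @param plot_effect_sd sd of lognormal plot-to-plot fertility effects
#'   (default 0.3).
#' @param start_year first survey year (default 1998).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_plots = 31, n_campaigns = 15,
                              n_species = 60, seed = 1,
                              responder_fraction = 0.3,
                              responder_strength = 1,
                              base_abundance = 0.05,
                              dominance = 1.5, dispersion = 0.7,
                              cover_size_log_sd = 0.6,
                              mean_individual_cover = 150,
                              seasonal_amplitude_mm = 30,
                              enso_pulse_mm = 100,
                              enso_campaigns = 1:4,
                              plot_effect_sd = 0.3,
                              start_year = 1998) {
  stopifnot(n_plots >= 1, n_campaigns >= 1, n_species >= 1,
            responder_fraction >= 0, responder_fraction <= 1,
            dispersion > 0, dominance >= 0, enso_pulse_mm >= 0,
            seasonal_amplitude_mm >= 0)
  enso_campaigns <- intersect(as.integer(enso_campaigns),
                              seq_len(n_campaigns))
  structure(as.list(environment()), class = "simulation_config")
}

# quarterly campaign calendar: Feb, May, Aug, Nov of successive years
campaign_calendar <- function(n_campaigns, start_year) {
  months <- c(2, 5, 8, 11)
  idx <- seq_len(n_campaigns) - 1
  data.frame(
    campaign_id = sprintf("C%02d", seq_len(n_campaigns)),
    date = sprintf("%04d-%02d", start_year + idx %/% 4,
                   months[idx %% 4 + 1]),
    stringsAsFactors = FALSE
  )
}

# smooth lomas climatology: dry austral summer, humid July-September
climatology_precip <- function(mo, amplitude) {
  amplitude * exp(-((mo - 8)^2) / (2 * 1.5^2))
}

climatology_temp <- function(mo) {
  18 + 4.5 * cos(2 * pi * (mo - 2) / 12)
}

#' Simulate a vegetation survey with known ground truth
#'
#' Species base abundances follow a lognormal rank-abundance law
#' (`dominance`); the expected count of species i in plot j at campaign t
#' is `exp(a_i + b_i * log(1 + P_t) + e_j)` with P_t the campaign-month
#' precipitation and e_j a plot effect; counts are negative-binomial
#' (`dispersion`), so dry months produce the structural zeros of real
#' surveys through the collapsed seasonal mean rather than a separate
#' mixture. Cover of a record is its count times a lognormal individual
#' size. The returned ground truth records each species' precipitation
#' coefficient, so screens can be checked against the planted signal.
#'
#' @param config a [simulation_config()].
#' @return list with `survey` (a [survey_table()]), `climate`
#'   (a [climate_series()] over the survey years) and `truth` (list:
#'   `a`, `b`, `responders`, `plot_effect`, `campaign_precip`, `config`).
#' @export
simulate_survey <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cal <- campaign_calendar(config$n_campaigns, config$start_year)
  years <- sort(unique(month_year(cal$date)))
  months <- as.vector(outer(sprintf("%02d", 1:12), years,
                            function(m, y) paste0(y, "-", m)))
  months <- sort(months)
  mo <- month_of_year(months)
  precip <- climatology_precip(mo, config$seasonal_amplitude_mm) +
    stats::rgamma(length(mo), shape = 2, scale = 1)
  pulse <- months %in% cal$date[config$enso_campaigns]
  precip[pulse] <- precip[pulse] + config$enso_pulse_mm
  temp <- climatology_temp(mo) + stats::rnorm(length(mo), 0, 0.5)
  climate <- climate_series(months, round(precip, 1), round(temp, 1))

  n_resp <- round(config$responder_fraction * config$n_species)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  a <- stats::rnorm(config$n_species, mean = log(config$base_abundance),
                    sd = config$dominance)
  b <- rep(0, config$n_species)
  responders <- character(0)
  if (n_resp > 0) {
    idx <- sample.int(config$n_species, n_resp)
    b[idx] <- config$responder_strength
    responders <- species[idx]
  }
  names(a) <- names(b) <- species

  plots <- sprintf("P%02d", seq_len(config$n_plots))
  zone_pool <- rep(c("low", "medium", "high"),
                   length.out = config$n_plots)
  zones <- stats::setNames(zone_pool, plots)
  plot_effect <- stats::setNames(
    stats::rnorm(config$n_plots, 0, config$plot_effect_sd), plots)

  campaign_precip <- precip[match(cal$date, months)]
  size_meanlog <- log(config$mean_individual_cover) -
    config$cover_size_log_sd^2 / 2

  recs <- vector("list", config$n_campaigns)
  for (t in seq_len(config$n_campaigns)) {
    lp <- log1p(campaign_precip[t])
    mu <- exp(outer(a + b * lp, plot_effect, "+"))  # species x plot
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
      nrow = config$n_species)
    hit <- which(counts > 0, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    cnt <- counts[hit]
    size <- stats::rlnorm(length(cnt), meanlog = size_meanlog,
                          sdlog = config$cover_size_log_sd)
    recs[[t]] <- data.frame(
      campaign_id = cal$campaign_id[t], date = cal$date[t],
      plot_id = plots[hit[, 2]], zone = zone_pool[hit[, 2]],
      species = species[hit[, 1]], abundance = cnt,
      cover_cm2 = round(cnt * size, 1), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  survey <- survey_table(records, plots = plots, campaigns = cal,
                         zones = zones, cover_cap = Inf)
  truth <- list(a = a, b = b, responders = responders,
                plot_effect = plot_effect,
                campaign_precip = stats::setNames(campaign_precip,
                                                  cal$campaign_id),
                config = config)
  list(survey = survey, climate = climate, truth = truth)
}

#' Small deterministic fixture survey
#'
#' A hand-built 3-campaign x 4-plot x 5-species table whose metrics are
#' hand-computable: plot P1 of campaign C1 has abundances (2, 1, 1)
#' (Shannon alpha 1.5 bits) and campaign richness is (5, 3, 2) by
#' construction.
#'
#' @return a [survey_table()].
#' @export
fixture_small <- function() {
  rec <- function(cid, date, plot, zone, sp, n, cov) {
    data.frame(campaign_id = cid, date = date, plot_id = plot,
               zone = zone, species = sp, abundance = n, cover_cm2 = cov,
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("C1", "1998-02", "P1", "low", "S1", 2, 20),
    rec("C1", "1998-02", "P1", "low", "S2", 1, 10),
    rec("C1", "1998-02", "P1", "low", "S3", 1, 10),
    rec("C1", "1998-02", "P2", "low", "S4", 3, 30),
    rec("C1", "1998-02", "P3", "medium", "S5", 2, 50),
    rec("C1", "1998-02", "P3", "medium", "S1", 1, 10),
    rec("C2", "1998-05", "P1", "low", "S1", 4, 40),
    rec("C2", "1998-05", "P1", "low", "S2", 2, 20),
    rec("C2", "1998-05", "P2", "low", "S3", 1, 10),
    rec("C2", "1998-05", "P3", "medium", "S1", 1, 10),
    rec("C3", "1998-08", "P1", "low", "S1", 1, 10),
    rec("C3", "1998-08", "P2", "low", "S2", 5, 60)
  )
  plots <- c("P1", "P2", "P3", "P4")
  zones <- stats::setNames(c("low", "low", "medium", "high"), plots)
  campaigns <- data.frame(campaign_id = c("C1", "C2", "C3"),
                          date = c("1998-02", "1998-05", "1998-08"),
                          stringsAsFactors = FALSE)
  survey_table(records, plots = plots, campaigns = campaigns,
               zones = zones)
}
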