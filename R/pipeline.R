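#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis so a run is fully
#' reproducible from the configuration plus the input files.
#'
#' @param survey path to the survey CSV (see [read_survey()]).
#' @param climate path to the climate CSV (see [read_climate()]).
#' @param out_dir output directory (created if needed).
#' @param flag_cover campaign ids whose absolute cover is overestimated.
#' @param plot_roster optional full plot roster.
#' @param cover_cap per-record cover warning cap in cm2 passed to
#'   [read_survey()] (default 10000; use `Inf` for protocols where
#'   overlapping projections above plot area are expected).
#' @param transform log rule for the paired tests (default `"log10p1"`).
#' @param si_tol stabilization tolerance, percentage points (default 10).
#' @param k_species species screened against climate (default 20, capped
#'   at the number observed).
#' @param dca_segments detrending segments (default 26).
#' @param dca_downweight downweight rare species before the DCA (default
#'   TRUE).
#' @param shannon_base Shannon log base (default 2, bits).
#' @param alpha_level significance level on adjusted p-values.
#' @return list of class `run_config`.
#' @export
run_config <- function(survey, climate, out_dir,
                       flag_cover = character(),
                       plot_roster = NULL,
                       cover_cap = 10000,
                       transform = "log10p1",
                       si_tol = 10,
                       k_species = 20,
                       dca_segments = 26,
                       dca_downweight = TRUE,
                       shannon_base = 2,
                       alpha_level = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

write_matrix_tsv <- function(m, path, label) {
  d <- data.frame(rownames(m), as.data.frame(unclass(m)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- label
  write_tsv(d, path)
}

#' Run the full analysis pipeline
#'
#' survey_io -> community metrics -> ordination -> seasonality ->
#' climate association -> group comparisons, writing every module output
#' (TSV) plus a machine-readable `summary.json` into `out_dir`. A failure
#' in any stage aborts with a stage-named error and removes partial
#' outputs. Outputs are byte-stable given fixed inputs and configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage progress messages on stderr.
#' @return the run summary, invisibly (a list, also written as JSON).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[lomaspulse] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(name, " (", sprintf("%.2fs", proc.time()[["elapsed"]] - t0), ")")
    out
  }

  survey <- stage("survey_io", {
    s <- read_survey(config$survey, plot_roster = config$plot_roster,
                     cover_cap = config$cover_cap)
    flag_overestimated_cover(s, config$flag_cover)
  })
  climate <- stage("climate_io", read_climate(config$climate))

  metrics <- stage("community_metrics",
                   all_plot_metrics(survey, base = config$shannon_base))
  summaries <- stage("campaign_summaries",
                     campaign_summary_table(survey,
                                            base = config$shannon_base))
  ivi_m <- stage("ivi", ivi_matrix(survey))

  ord <- stage("ordination",
               dca(ivi_m, n_axes = 2,
                   downweight = config$dca_downweight,
                   n_segments = config$dca_segments))

  si <- stage("seasonality", si_series(summaries))
  stab <- stage("stabilization", {
    lapply(stats::setNames(nm = si_characteristics), function(ch) {
      detect_stabilization(si, ch, tol = config$si_tol)
    })
  })

  k <- min(config$k_species,
           length(unique(survey$records$species[
             survey$records$abundance > 0])))
  cors_ch <- stage("climate_association",
                   characteristic_screen(summaries, climate,
                                         alpha = config$alpha_level))
  cors_sp <- stage("species_screen",
                   species_screen(survey, climate, k = k,
                                  alpha = config$alpha_level))

  pairwise <- stage("group_comparisons", {
    lapply(stats::setNames(nm = c("density", "cover", "alpha")),
           function(ch) {
             paired_campaign_tests(metrics, ch, table = survey,
                                   transform = config$transform,
                                   alpha = config$alpha_level)
           })
  })
  zones <- stage("zone_tests", {
    do.call(rbind, lapply(c("density", "cover", "alpha"), function(ch) {
      kruskal_zones(metrics, ch, campaign_id = "all")
    }))
  })

  summary <- list(
    package = "lomaspulse",
    version = as.character(utils::packageVersion("lomaspulse")),
    config = config[setdiff(names(config), "plot_roster")],
    n_campaigns = nrow(survey$campaigns),
    n_plots = length(survey$plots),
    n_species = nrow(ivi_m),
    n_records = nrow(survey$records),
    flagged_cover = names(survey$flags)[survey$flags],
    stabilization_year = stab,
    dca_eigenvalues = unname(ord$eigenvalues),
    dca_inertia_fraction = unname(ord$axis_inertia_fraction),
    headline = list(
      gamma_uncorrelated_with_precipitation = !isTRUE(
        cors_ch$significant[cors_ch$response == "gamma" &
                              cors_ch$predictor == "precipitation"]),
      any_zone_difference = any(zones$p < config$alpha_level)
    )
  )

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail_cleanup <- function() unlink(written)
  tryCatch({
    written <- c(written, write_tsv(
      summaries, file.path(config$out_dir, "campaign_summary.tsv")))
    written <- c(written, write_tsv(
      metrics, file.path(config$out_dir, "plot_metrics.tsv")))
    written <- c(written, write_matrix_tsv(
      ivi_m, file.path(config$out_dir, "ivi_matrix.tsv"), "species"))
    written <- c(written, write_tsv(
      si, file.path(config$out_dir, "seasonality.tsv")))
    written <- c(written, write_matrix_tsv(
      ord$site_scores, file.path(config$out_dir, "dca_site_scores.tsv"),
      "campaign_id"))
    written <- c(written, write_matrix_tsv(
      ord$species_scores,
      file.path(config$out_dir, "dca_species_scores.tsv"), "species"))
    written <- c(written, write_tsv(
      data.frame(axis = seq_along(ord$eigenvalues),
                 eigenvalue = unname(ord$eigenvalues),
                 inertia_fraction = unname(ord$axis_inertia_fraction)),
      file.path(config$out_dir, "dca_eigenvalues.tsv")))
    written <- c(written, write_tsv(
      cors_ch,
      file.path(config$out_dir, "correlations_characteristics.tsv")))
    written <- c(written, write_tsv(
      cors_sp, file.path(config$out_dir, "correlations_species.tsv")))
    for (ch in names(pairwise)) {
      written <- c(written, write_tsv(
        pairwise[[ch]],
        file.path(config$out_dir,
                  paste0("pairwise_tests_", ch, ".tsv"))))
      written <- c(written, write_tsv(
        campaign_letters(pairwise[[ch]]),
        file.path(config$out_dir, paste0("letters_", ch, ".tsv"))))
    }
    written <- c(written, write_tsv(
      zones, file.path(config$out_dir, "zone_tests.tsv")))
    stab_path <- file.path(config$out_dir, "stabilization.json")
    jsonlite::write_json(stab, stab_path, auto_unbox = TRUE, null = "null",
                         na = "null")
    written <- c(written, stab_path)
    summary_path <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         null = "null", na = "null", digits = NA)
    written <- c(written, summary_path)
  }, error = function(e) {
    on_fail_cleanup()
    stop("stage 'write_outputs' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  say("wrote ", length(written), " files to ", config$out_dir)
  invisible(summary)
}
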