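#' Shannon diversity of an abundance vector
#'
#' H = -sum(p_i log(p_i)) over species with positive abundance, in bits
#' (log base 2) by default. Returns 0 for an empty vector or a single
#' species: a plot with at most one species carries no diversity.
#'
#' @param abundance numeric vector of non-negative abundances.
#' @param base logarithm base; 2 (bits) by default, `exp(1)` for nats.
#' @return Shannon diversity, `>= 0`, at most `log(S, base)` for S species.
#' @export
shannon <- function(abundance, base = 2) {
  abundance <- abundance[abundance > 0]
  if (length(abundance) <= 1) return(0)
  p <- abundance / sum(abundance)
  -sum(p * log(p, base = base))
}

#' Per-plot community metrics for one campaign
#'
#' Density (individuals per m2) is the summed abundance of all species in
#' the plot; cover (cm2 per m2) the summed species cover; alpha diversity
#' the Shannon index of within-plot relative abundances. Every roster plot
#' yields a row: plots with no records contribute density 0, cover 0,
#' alpha 0 (a fixed panel design, not missing data).
#'
#' @param table a [survey_table()].
#' @param campaign_id campaign to summarize.
#' @param base Shannon logarithm base (default 2, bits).
#' @return data.frame: `campaign_id`, `plot_id`, `zone`, `density`,
#'   `cover`, `alpha`, one row per roster plot.
#' @export
plot_metrics <- function(table, campaign_id, base = 2) {
  stopifnot(inherits(table, "survey_table"))
  if (!campaign_id %in% table$campaigns$campaign_id) {
    stop("unknown campaign id: ", campaign_id, call. = FALSE)
  }
  rec <- table$records[table$records$campaign_id == campaign_id, ,
                       drop = FALSE]
  plots <- table$plots
  density <- cover <- alpha <- stats::setNames(numeric(length(plots)), plots)
  if (nrow(rec) > 0) {
    sp <- split(rec, rec$plot_id)
    for (pid in names(sp)) {
      density[pid] <- sum(sp[[pid]]$abundance)
      cover[pid] <- sum(sp[[pid]]$cover_cm2)
      alpha[pid] <- shannon(sp[[pid]]$abundance, base = base)
    }
  }
  zone <- unname(table$zones[plots])
  data.frame(campaign_id = campaign_id, plot_id = plots, zone = zone,
             density = unname(density), cover = unname(cover),
             alpha = unname(alpha), stringsAsFactors = FALSE)
}

#' Per-plot metrics for all campaigns
#'
#' @inheritParams plot_metrics
#' @return row-bound [plot_metrics()] over the campaign roster.
#' @export
all_plot_metrics <- function(table, base = 2) {
  do.call(rbind, lapply(table$campaigns$campaign_id, function(cid) {
    plot_metrics(table, cid, base = base)
  }))
}

#' Campaign-level summary of community characteristics
#'
#' Means and ranges are taken over the full plot roster (empty plots
#' contribute zeros). Gamma diversity is the Shannon index on species
#' abundances pooled across all plots of the campaign; total richness is
#' the number of species with pooled abundance > 0. Mean cover and its
#' range are `NA` for campaigns flagged as cover-overestimated.
#'
#' @inheritParams plot_metrics
#' @return one-row data.frame: `campaign_id`, `date`, `mean_density`,
#'   `min_density`, `max_density`, `mean_cover`, `min_cover`, `max_cover`,
#'   `mean_alpha`, `min_alpha`, `max_alpha`, `gamma`, `richness`,
#'   `cover_flagged`.
#' @export
campaign_summary <- function(table, campaign_id, base = 2) {
  pm <- plot_metrics(table, campaign_id, base = base)
  rec <- table$records[table$records$campaign_id == campaign_id, ,
                       drop = FALSE]
  pooled <- tapply(rec$abundance, rec$species, sum)
  pooled <- pooled[!is.na(pooled) & pooled > 0]
  flagged <- isTRUE(table$flags[[campaign_id]])
  date <- table$campaigns$date[table$campaigns$campaign_id == campaign_id]
  out <- data.frame(
    campaign_id = campaign_id, date = date,
    mean_density = mean(pm$density),
    min_density = min(pm$density), max_density = max(pm$density),
    mean_cover = if (flagged) NA_real_ else mean(pm$cover),
    min_cover = if (flagged) NA_real_ else min(pm$cover),
    max_cover = if (flagged) NA_real_ else max(pm$cover),
    mean_alpha = mean(pm$alpha),
    min_alpha = min(pm$alpha), max_alpha = max(pm$alpha),
    gamma = shannon(as.numeric(pooled), base = base),
    richness = length(pooled),
    cover_flagged = flagged,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Campaign summaries for the whole survey
#'
#' @inheritParams plot_metrics
#' @return data.frame with one [campaign_summary()] row per campaign, in
#'   roster order.
#' @export
campaign_summary_table <- function(table, base = 2) {
  do.call(rbind, lapply(table$campaigns$campaign_id, function(cid) {
    campaign_summary(table, cid, base = base)
  }))
}

#' Importance value index for one campaign
#'
#' IVI_i = (n_i / N_t + c_i / C_t) / 2: the mean of a species' relative
#' abundance (regeneration proxy) and relative cover (biomass proxy)
#' within the campaign, so the index lies in [0, 1] and sums to 1 over
#' species. Relative cover is unaffected by a uniform overestimation
#' bias, so flagged campaigns are included.
#'
#' @inheritParams plot_metrics
#' @return named numeric vector of IVI values over the species present in
#'   the campaign (sums to 1).
#' @export
ivi <- function(table, campaign_id) {
  stopifnot(inherits(table, "survey_table"))
  if (!campaign_id %in% table$campaigns$campaign_id) {
    stop("unknown campaign id: ", campaign_id, call. = FALSE)
  }
  rec <- table$records[table$records$campaign_id == campaign_id &
                         table$records$abundance > 0, , drop = FALSE]
  n_i <- tapply(rec$abundance, rec$species, sum)
  c_i <- tapply(rec$cover_cm2, rec$species, sum)
  if (length(n_i) == 0 || sum(n_i) == 0) {
    stop("IVI undefined: campaign ", campaign_id,
         " has zero total abundance", call. = FALSE)
  }
  if (sum(c_i) == 0) {
    stop("IVI undefined: campaign ", campaign_id, " has zero total cover",
         call. = FALSE)
  }
  if (any(c_i == 0)) {
    warning("species with individuals but zero cover in campaign ",
            campaign_id, "; they contribute to the abundance term only",
            call. = FALSE)
  }
  v <- (n_i / sum(n_i) + c_i / sum(c_i)) / 2
  v <- v[order(names(v))]
  stats::setNames(as.numeric(v), names(v))
}

#' Species x campaign IVI matrix
#'
#' @inheritParams plot_metrics
#' @return numeric matrix of class `ivi_matrix` (rows = species observed
#'   anywhere, columns = campaigns in roster order); entries of species
#'   absent from a campaign are 0 and each column sums to 1.
#' @export
ivi_matrix <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  species <- sort(unique(table$records$species[table$records$abundance > 0]))
  campaigns <- table$campaigns$campaign_id
  m <- matrix(0, nrow = length(species), ncol = length(campaigns),
              dimnames = list(species, campaigns))
  for (cid in campaigns) {
    v <- ivi(table, cid)
    m[names(v), cid] <- v
  }
  class(m) <- c("ivi_matrix", class(m))
  m
}

#' Most abundant species over the whole survey
#'
#' Species ranked by total abundance summed over all campaigns and plots;
#' ties are broken lexicographically by species label so the ranking is
#' deterministic.
#'
#' @param table a [survey_table()].
#' @param k number of species to return.
#' @return character vector of length `k`, most abundant first.
#' @export
top_abundant_species <- function(table, k) {
  stopifnot(inherits(table, "survey_table"))
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  rec <- table$records[table$records$abundance > 0, , drop = FALSE]
  totals <- tapply(rec$abundance, rec$species, sum)
  if (k > length(totals)) {
    stop("k (", k, ") exceeds the number of observed species (",
         length(totals), ")", call. = FALSE)
  }
  ord <- order(-as.numeric(totals), names(totals))
  names(totals)[ord][seq_len(k)]
}
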