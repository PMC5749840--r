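#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks (average ranks for ties);
#' the two-sided p-value uses the t-approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom, the
#' conventional default at moderate n. An exact permutation p-value is
#' available for small samples (`exact = TRUE`, n <= 10), enumerating all
#' n! orderings.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @param exact logical; exact permutation p-value (n <= 10 only).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman rho undefined for a constant series", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p-value limited to n <= 10",
                     call. = FALSE)
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

# all permutations of 1..n as a matrix (n! rows); recursion, small n only
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m family size (defaults to `length(p)`).
#' @return `pmin(1, m * p)`, exactly.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

# join campaign dates to climate months; error on a missing month
climate_for_campaigns <- function(dates, climate, lag = 0) {
  stopifnot(inherits(climate, "climate_series"))
  months <- dates
  if (lag != 0) {
    y <- month_year(dates)
    m <- month_of_year(dates) - lag
    y <- y + (m - 1) %/% 12
    m <- (m - 1) %% 12 + 1
    months <- sprintf("%04d-%02d", y, m)
  }
  idx <- match(months, climate$month)
  if (anyNA(idx)) {
    stop("campaign month(s) missing from climate series: ",
         paste(months[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  climate[idx, , drop = FALSE]
}

#' Climate screen of campaign-level community characteristics
#'
#' Spearman correlation of each of the five community characteristics
#' (mean density, mean cover, mean alpha, gamma, richness) against
#' same-month total precipitation and mean temperature, Bonferroni-
#' corrected within the family of 5 x 2 = 10 tests. Campaigns with the
#' cover-overestimation flag are dropped from the mean-cover pairs only.
#'
#' @param summaries a [campaign_summary_table()] data.frame.
#' @param climate a [climate_series()] covering every campaign month.
#' @param lag months of climate lag (default 0: the campaign's own month).
#' @param alpha significance level applied to the adjusted p (default
#'   0.05).
#' @return data.frame: `response`, `predictor`, `rho`, `p`, `p_bonf`, `n`,
#'   `m`, `significant`.
#' @export
characteristic_screen <- function(summaries, climate, lag = 0,
                                  alpha = 0.05) {
  clim <- climate_for_campaigns(summaries$date, climate, lag = lag)
  predictors <- list(precipitation = clim$precip_mm,
                     temperature = clim$temp_c)
  rows <- list()
  for (ch in si_characteristics) {
    v <- summaries[[ch]]
    keep <- !is.na(v)
    for (pr in names(predictors)) {
      res <- spearman_rho(v[keep], predictors[[pr]][keep])
      rows[[length(rows) + 1]] <- data.frame(
        response = ch, predictor = pr, rho = res$rho, p = res$p,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_bonf <- bonferroni(out$p, out$m)
  out$significant <- out$p_bonf < alpha
  out[c("response", "predictor", "rho", "p", "p_bonf", "n", "m",
        "significant")]
}

#' Climate screen of the most abundant species
#'
#' Per-campaign density of each of the `k` most abundant species (pooled
#' individuals over all plots divided by the plot count, ind per m2)
#' correlated against same-month precipitation and temperature;
#' Bonferroni within the family of `2k` tests. Note rho is invariant to
#' the 1/plot-count scaling, so pooled vs per-plot density give identical
#' screens.
#'
#' @param table a [survey_table()].
#' @param climate a [climate_series()].
#' @param k number of species screened (default 20).
#' @param lag months of climate lag (default 0).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame as in [characteristic_screen()], one pair of rows
#'   per species.
#' @export
species_screen <- function(table, climate, k = 20, lag = 0, alpha = 0.05) {
  stopifnot(inherits(table, "survey_table"))
  species <- top_abundant_species(table, k)
  campaigns <- table$campaigns$campaign_id
  clim <- climate_for_campaigns(table$campaigns$date, climate, lag = lag)
  n_plots <- length(table$plots)
  rec <- table$records
  rows <- list()
  for (sp in species) {
    dens <- vapply(campaigns, function(cid) {
      sum(rec$abundance[rec$campaign_id == cid & rec$species == sp]) /
        n_plots
    }, numeric(1))
    for (pr in c("precipitation", "temperature")) {
      xy <- if (pr == "precipitation") clim$precip_mm else clim$temp_c
      res <- tryCatch(spearman_rho(dens, xy),
                      error = function(e) list(rho = NA_real_, p = NA_real_,
                                               n = length(dens)))
      rows[[length(rows) + 1]] <- data.frame(
        response = sp, predictor = pr, rho = res$rho, p = res$p,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_bonf <- bonferroni(out$p, out$m)
  out$significant <- out$p_bonf < alpha
  out[c("response", "predictor", "rho", "p", "p_bonf", "n", "m",
        "significant")]
}
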