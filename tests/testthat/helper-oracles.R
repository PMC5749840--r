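# Small builders and brute-force oracles shared across tests.
# Oracles are deliberately independent of the package's code paths.

# one survey record
rec1 <- function(cid, date, plot, sp, n, cov, zone = "low") {
  data.frame(campaign_id = cid, date = date, plot_id = plot, zone = zone,
             species = sp, abundance = n, cover_cm2 = cov,
             stringsAsFactors = FALSE)
}

# random small survey table: counts Poisson, cover 10x count
random_survey <- function(seed, n_campaigns = 3, n_plots = 4,
                          n_species = 6) {
  set.seed(seed)
  cal <- data.frame(
    campaign_id = sprintf("C%d", seq_len(n_campaigns)),
    date = sprintf("1998-%02d", seq_len(n_campaigns)),
    stringsAsFactors = FALSE)
  plots <- sprintf("P%d", seq_len(n_plots))
  zones <- setNames(rep(c("low", "medium", "high"),
                        length.out = n_plots), plots)
  rows <- list()
  for (cid in cal$campaign_id) {
    for (p in plots) {
      for (s in sprintf("S%d", seq_len(n_species))) {
        n <- rpois(1, 1.2)
        if (n > 0) {
          rows[[length(rows) + 1]] <- rec1(
            cid, cal$date[match(cid, cal$campaign_id)], p, s, n,
            n * round(runif(1, 5, 40), 1), zone = zones[[p]])
        }
      }
    }
  }
  survey_table(do.call(rbind, rows), plots = plots, campaigns = cal,
               zones = zones)
}

# Shannon by naive direct summation over a record list (base 2)
oracle_shannon <- function(abund) {
  abund <- abund[abund > 0]
  if (length(abund) <= 1) return(0)
  total <- sum(abund)
  h <- 0
  for (a in abund) h <- h - (a / total) * log2(a / total)
  h
}

# Kruskal-Wallis H by direct rank computation (with ties correction)
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tie <- table(values)
  h / (1 - sum(tie^3 - tie) / (n^3 - n))
}
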