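#' Paired t-test (closed form)
#'
#' One-sample t on the paired differences: t = mean(d) / (sd(d)/sqrt(n)),
#' df = n - 1, two-sided p. When every difference is zero the test is
#' degenerate and reported as t = 0, p = 1 rather than an error: two
#' identical campaigns are maximally non-different.
#'
#' @param a,b numeric vectors of paired observations (same plots).
#' @return list with `t`, `df`, `p`, `n`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length",
                                   call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (all(d == 0)) {
    return(list(t = 0, df = n - 1L, p = 1, n = n, degenerate = TRUE))
  }
  s <- stats::sd(d)
  if (s == 0) {
    # constant nonzero shift: infinitely strong evidence
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, n = n,
                degenerate = FALSE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  list(t = tstat, df = n - 1L, p = p, n = n, degenerate = FALSE)
}

#' All-pairs paired t-tests between campaigns
#'
#' Tests every unordered pair of campaigns on per-plot values of one
#' characteristic, pairing by plot (the repeated-measures unit). Values
#' are log10(x + 1)-transformed by default (+1 because empty plots carry
#' exact zeros). For cover, campaigns flagged as overestimated are
#' excluded before pairing, shrinking the family (15 campaigns give 105
#' pairs; 13 give 78). Bonferroni is applied within the family of pairs
#' actually tested for this characteristic.
#'
#' @param metrics an [all_plot_metrics()] data.frame.
#' @param characteristic `"density"`, `"cover"` or `"alpha"`.
#' @param table optional [survey_table()]; supplies campaign order and the
#'   cover flags. If omitted, campaign order follows first appearance and
#'   no campaign is excluded.
#' @param transform transformation applied before differencing; one of
#'   `"log10p1"` (default), `"log1p"` (natural log of x + 1) or
#'   `"identity"`.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame: `campaign_a`, `campaign_b`, `characteristic`, `t`,
#'   `df`, `p`, `p_bonf`, `n_pairs`, `m`, `significant`. Swapping a and b
#'   would flip the sign of `t` and leave `p` unchanged.
#' @export
paired_campaign_tests <- function(metrics, characteristic,
                                  table = NULL,
                                  transform = c("log10p1", "log1p",
                                                "identity"),
                                  alpha = 0.05) {
  characteristic <- match.arg(characteristic, c("density", "cover", "alpha"))
  transform <- match.arg(transform)
  f <- switch(transform,
              log10p1 = function(x) log10(x + 1),
              log1p = log1p,
              identity = identity)
  campaigns <- if (!is.null(table)) table$campaigns$campaign_id else
    unique(metrics$campaign_id)
  if (characteristic == "cover" && !is.null(table)) {
    campaigns <- campaigns[!table$flags[campaigns]]
  }
  if (length(campaigns) < 2) stop("need at least 2 campaigns",
                                  call. = FALSE)
  vals <- lapply(campaigns, function(cid) {
    sub <- metrics[metrics$campaign_id == cid, , drop = FALSE]
    stats::setNames(f(sub[[characteristic]]), sub$plot_id)
  })
  names(vals) <- campaigns
  pairs <- utils::combn(campaigns, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ca <- pairs[1, i]; cb <- pairs[2, i]
    shared <- intersect(names(vals[[ca]]), names(vals[[cb]]))
    res <- paired_t(vals[[ca]][shared], vals[[cb]][shared])
    data.frame(campaign_a = ca, campaign_b = cb,
               characteristic = characteristic,
               t = res$t, df = res$df, p = res$p, n_pairs = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_bonf <- bonferroni(out$p, out$m)
  out$significant <- out$p_bonf < alpha
  out[c("campaign_a", "campaign_b", "characteristic", "t", "df", "p",
        "p_bonf", "n_pairs", "m", "significant")]
}

#' Kruskal-Wallis H (closed form with ties correction)
#'
#' H = 12/(N(N+1)) * sum(R_j^2 / n_j) - 3(N+1) on midranks, divided by the
#' ties correction 1 - sum(t^3 - t)/(N^3 - N); p from the chi-square
#' approximation on g - 1 degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`, >= 2 distinct.
#' @return list with `h`, `df`, `p`, `n`.
#' @export
kruskal_h <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  g <- unique(groups)
  if (length(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  rsum <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr else h <- 0
  df <- length(g) - 1L
  p <- stats::pchisq(h, df = df, lower.tail = FALSE)
  list(h = h, df = df, p = p, n = n)
}

#' Kruskal-Wallis test of a characteristic across tourist-use zones
#'
#' Compares per-plot values between the tourist-use zones, either within
#' one campaign or pooling all campaigns (`campaign_id = "all"`, each
#' plot-campaign value one observation).
#'
#' @param metrics an [all_plot_metrics()] data.frame (has a `zone`
#'   column).
#' @param characteristic `"density"`, `"cover"` or `"alpha"`.
#' @param campaign_id a campaign id, or `"all"` to pool campaigns.
#' @return one-row data.frame: `characteristic`, `campaign_id`, `h`,
#'   `df`, `p`, `n`.
#' @export
kruskal_zones <- function(metrics, characteristic,
                          campaign_id = "all") {
  characteristic <- match.arg(characteristic, c("density", "cover", "alpha"))
  sub <- if (identical(campaign_id, "all")) metrics else
    metrics[metrics$campaign_id == campaign_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("no observations for campaign ", campaign_id,
                           call. = FALSE)
  res <- kruskal_h(sub[[characteristic]], sub$zone)
  data.frame(characteristic = characteristic, campaign_id = campaign_id,
             h = res$h, df = res$df, p = res$p, n = res$n,
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise test results
#'
#' Greedy alphabetical letter assignment: campaigns sharing a letter are
#' not significantly different. A reporting convenience for boxplot
#' panels, not an inferential method.
#'
#' @param tests output of [paired_campaign_tests()].
#' @return data.frame: `campaign_id`, `letters`.
#' @export
campaign_letters <- function(tests) {
  camps <- unique(c(tests$campaign_a, tests$campaign_b))
  sig <- matrix(FALSE, length(camps), length(camps),
                dimnames = list(camps, camps))
  for (i in seq_len(nrow(tests))) {
    if (isTRUE(tests$significant[i])) {
      sig[tests$campaign_a[i], tests$campaign_b[i]] <- TRUE
      sig[tests$campaign_b[i], tests$campaign_a[i]] <- TRUE
    }
  }
  groups <- list()  # each group: campaigns that may share a letter
  for (cm in camps) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (!any(sig[cm, groups[[k]]])) {
        groups[[k]] <- c(groups[[k]], cm)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- cm
  }
  letter_of <- vapply(camps, function(cm) {
    paste(letters[which(vapply(groups, function(g) cm %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  data.frame(campaign_id = camps, letters = unname(letter_of),
             stringsAsFactors = FALSE)
}
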