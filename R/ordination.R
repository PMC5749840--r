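#' Correspondence analysis of a species x site matrix
#'
#' The eigen-engine inside detrended correspondence analysis. The matrix
#' of proportions P = X/sum(X) with row masses r and column masses c is
#' chi-square standardized, S = (P - r c') / sqrt(r c'), and singular-
#' value-decomposed; eigenvalues are the squared singular values, each in
#' (0, 1]. Site scores are principal coordinates (their c-weighted
#' variance on axis k equals the eigenvalue); species scores are the
#' abundance-weighted means of the standard site coordinates (the
#' reciprocal-averaging relation), which equals the species principal
#' coordinate. Axis orientation is arbitrary in the algebra and is fixed
#' here by requiring a non-negative score for the lexicographically
#' smallest site label (first site with a nonzero score breaks ties), so
#' repeated runs and permuted inputs agree.
#'
#' @param mat nonnegative numeric matrix, species in rows, sites in
#'   columns, with dimnames. All-zero rows/columns are dropped with a
#'   warning.
#' @param n_axes number of axes to return (default 2); silently reduced
#'   with a warning when the matrix rank supports fewer.
#' @return object of class `ordination_result`: list with `site_scores`
#'   (site x axis), `species_scores` (species x axis), `eigenvalues`,
#'   `axis_inertia_fraction`, `total_inertia`, `detrended`,
#'   `downweighted`.
#' @export
correspondence_analysis <- function(mat, n_axes = 2) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be nonnegative", call. = FALSE)
  if (n_axes < 1) stop("n_axes must be >= 1", call. = FALSE)
  zr <- rowSums(mat) == 0
  zc <- colSums(mat) == 0
  if (any(zr) || any(zc)) {
    warning(sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s) dropped before the eigenanalysis",
            call. = FALSE)
    mat <- mat[!zr, !zc, drop = FALSE]
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 non-empty species and 2 non-empty sites",
         call. = FALSE)
  }
  P <- mat / sum(mat)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- 1e-10
  rank <- sum(sv$d > tol)
  total_inertia <- sum(sv$d[sv$d > tol]^2)
  if (rank < n_axes) {
    warning("matrix supports only ", rank, " axes (", n_axes,
            " requested)", call. = FALSE)
    n_axes <- rank
  }
  k <- seq_len(n_axes)
  d <- sv$d[k]
  # standard coordinates: chi-square metric, weighted variance 1
  site_std <- sweep(sv$v[, k, drop = FALSE], 1, sqrt(cc), "/")
  # principal site coordinates: weighted variance = eigenvalue
  site_scores <- sweep(site_std, 2, d, "*")
  # species scores by reciprocal averaging on standard site coordinates
  profiles <- mat / rowSums(mat)
  species_scores <- profiles %*% site_std
  dimnames(site_scores) <- list(colnames(mat), paste0("CA", k))
  dimnames(species_scores) <- list(rownames(mat), paste0("CA", k))
  # deterministic orientation, per axis
  anchor <- order(colnames(mat))
  for (j in k) {
    s <- site_scores[anchor, j]
    first <- which(abs(s) > tol)[1]
    if (!is.na(first) && s[first] < 0) {
      site_scores[, j] <- -site_scores[, j]
      species_scores[, j] <- -species_scores[, j]
    }
  }
  structure(
    list(site_scores = site_scores, species_scores = species_scores,
         eigenvalues = d^2,
         axis_inertia_fraction = d^2 / total_inertia,
         total_inertia = total_inertia,
         detrended = FALSE, downweighted = FALSE),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result>",
      if (x$detrended) "(detrended)" else "(plain CA)",
      if (x$downweighted) "rare species downweighted" else "", "\n")
  cat("  sites:", nrow(x$site_scores), " species:",
      nrow(x$species_scores), "\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  cat("  inertia fraction:",
      paste(signif(x$axis_inertia_fraction, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Downweight rare species before ordination
#'
#' Hill's rule as used in the classic detrended-correspondence-analysis
#' program: each species' effective frequency is (sum of its abundances
#' over sites)^2 divided by the sum of its squared abundances (equal to
#' its number of occurrences when all nonzero abundances are equal).
#' Species whose effective frequency falls below 1/`fraction` of the
#' maximum are scaled down in proportion to frequency / threshold. Works
#' on relative matrices (e.g. importance values) because only frequencies
#' of occurrence, not absolute magnitudes, drive the rule.
#'
#' @param mat nonnegative species x site matrix.
#' @param fraction threshold divisor (default 5: threshold is a fifth of
#'   the commonest species' effective frequency).
#' @return the matrix with rare species' rows scaled down; scaling
#'   factors in attribute `"weights"`.
#' @export
downweight_rare <- function(mat, fraction = 5) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be nonnegative", call. = FALSE)
  rs <- rowSums(mat)
  rs2 <- rowSums(mat^2)
  freq <- ifelse(rs2 > 0, rs^2 / rs2, 0)
  threshold <- max(freq) / fraction
  w <- rep(1, nrow(mat))
  down <- freq < threshold
  w[down] <- freq[down] / threshold
  out <- mat * w
  attr(out, "weights") <- stats::setNames(w, rownames(mat))
  out
}

#' Detrend axis-2 scores by segments
#'
#' The defining step of detrended correspondence analysis: the axis-1
#' range is cut into `n_segments` equal-width segments and within each
#' segment the axis-2 scores are centered by subtracting the segment
#' mean, after the segment means are smoothed by a running average over
#' adjacent segments (weights 1/4, 1/2, 1/4). Segment means for empty
#' segments are filled by linear interpolation between neighbouring
#' non-empty segments before smoothing, which is the practical equivalent
#' of merging empty segments with their neighbours.
#'
#' @param axis1 site scores on the first axis.
#' @param axis2 site scores on the second axis (same length).
#' @param n_segments number of segments (default 26, the classic
#'   default).
#' @return detrended axis-2 scores.
#' @export
detrend_by_segments <- function(axis1, axis2, n_segments = 26) {
  if (length(axis1) != length(axis2)) stop("axis score lengths differ",
                                           call. = FALSE)
  if (n_segments < 2) stop("need at least 2 segments", call. = FALSE)
  rng <- range(axis1)
  if (diff(rng) == 0) stop("axis-1 scores span a zero range",
                           call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_segments + 1)
  seg <- findInterval(axis1, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  means <- rep(NA_real_, n_segments)
  agg <- tapply(axis2, seg, mean)
  means[as.integer(names(agg))] <- agg
  if (anyNA(means)) {
    filled <- which(!is.na(means))
    means <- stats::approx(filled, means[filled], xout = seq_len(n_segments),
                           rule = 2)$y
  }
  sm <- means
  if (n_segments >= 3) {
    inner <- 2:(n_segments - 1)
    sm[inner] <- 0.25 * means[inner - 1] + 0.5 * means[inner] +
      0.25 * means[inner + 1]
    sm[1] <- (2 * means[1] + means[2]) / 3
    sm[n_segments] <- (means[n_segments - 1] + 2 * means[n_segments]) / 3
  }
  axis2 - sm[seg]
}

#' Detrended correspondence analysis of an IVI matrix
#'
#' Optional rare-species downweighting, then correspondence analysis,
#' then detrending of every axis beyond the first against axis 1 (with
#' `n_axes = 1` no detrending is performed and the pure CA axis is
#' returned). Nonlinear rescaling of axis lengths is intentionally not
#' implemented: eigenvalue shares of total inertia are reported instead,
#' which is reproducible across program dialects.
#'
#' @param ivi species x campaign matrix (an [ivi_matrix()] or any
#'   nonnegative matrix with dimnames).
#' @param n_axes number of ordination axes (default 2).
#' @param downweight apply [downweight_rare()] first (default TRUE).
#' @param n_segments segments for [detrend_by_segments()] (default 26).
#' @return an `ordination_result` with `detrended = TRUE` when axes
#'   beyond the first were detrended.
#' @export
dca <- function(ivi, n_axes = 2, downweight = TRUE, n_segments = 26) {
  mat <- unclass(as.matrix(ivi))
  if (downweight) mat <- downweight_rare(mat)
  res <- correspondence_analysis(mat, n_axes = n_axes)
  res$downweighted <- downweight
  if (n_axes >= 2 && ncol(res$site_scores) >= 2) {
    for (j in 2:ncol(res$site_scores)) {
      res$site_scores[, j] <- detrend_by_segments(
        res$site_scores[, 1], res$site_scores[, j],
        n_segments = n_segments)
    }
    res$detrended <- TRUE
  }
  res
}
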