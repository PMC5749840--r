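# single-gradient community: Gaussian species responses along a known
# site ordering; the classic test bed for correspondence methods
gradient_matrix <- function(n_species = 20, n_sites = 12, seed = 1,
                            sd = 1.2) {
  set.seed(seed)
  grad <- seq(0, 10, length.out = n_sites)
  optima <- runif(n_species, 0, 10)
  m <- outer(optima, grad, function(o, g) {
    100 * exp(-(o - g)^2 / (2 * sd^2))
  })
  m <- matrix(rpois(length(m), m), nrow = n_species,
              dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                              sprintf("t%02d", seq_len(n_sites))))
  m[rowSums(m) > 0, , drop = FALSE]
}

test_that("CA eigenvalues match a dense eigendecomposition oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rpois(30, 3), 6, 5,
                dimnames = list(paste0("s", 1:6), paste0("t", 1:5)))
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 2 || ncol(m) < 2) next
    res <- correspondence_analysis(m, n_axes = min(dim(m)) - 1)
    # oracle: full eigendecomposition of the chi-square cross-product
    P <- m / sum(m); r <- rowSums(P); cc <- colSums(P)
    S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
    ev <- eigen(t(S) %*% S, symmetric = TRUE)$values
    ev <- ev[ev > 1e-10]
    expect_equal(unname(res$eigenvalues), ev[seq_along(res$eigenvalues)],
                 tolerance = 1e-10)
    expect_true(all(res$eigenvalues > 0 & res$eigenvalues <= 1))
    expect_true(all(diff(res$eigenvalues) <= 1e-12))
    expect_lte(sum(res$axis_inertia_fraction), 1 + 1e-12)
    # eigenvalues invariant to a positive rescaling of the matrix
    res2 <- correspondence_analysis(m * 3.7,
                                    n_axes = length(res$eigenvalues))
    expect_equal(res2$eigenvalues, res$eigenvalues, tolerance = 1e-12)
  }
})

test_that("CA structure: blocks, duplicates, label equivariance", {
  # block-diagonal: axis 1 separates the two site blocks by sign
  b <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6),
                                       paste0("t", 1:6)))
  b[1:3, 1:3] <- 5; b[4:6, 4:6] <- 5
  res <- correspondence_analysis(b, n_axes = 1)
  s1 <- res$site_scores[, 1]
  expect_true(all(s1[1:3] * s1[4:6][1] < 0))
  expect_equal(abs(unname(res$eigenvalues[1])), 1, tolerance = 1e-10)

  # duplicate sites get identical scores
  m <- gradient_matrix(seed = 3)
  md <- cbind(m, dup = m[, 4])
  resd <- correspondence_analysis(md, n_axes = 2)
  expect_equal(unname(resd$site_scores["dup", ]),
               unname(resd$site_scores[colnames(m)[4], ]),
               tolerance = 1e-9)

  # permuting site columns permutes scores identically
  perm <- c(5, 1, 12, 3, 2, 8, 11, 4, 10, 7, 6, 9)
  res0 <- correspondence_analysis(m, n_axes = 2)
  resp <- correspondence_analysis(m[, perm], n_axes = 2)
  expect_equal(resp$site_scores[rownames(res0$site_scores), ],
               res0$site_scores, tolerance = 1e-9)

  # reciprocal averaging: species scores are profile-weighted means of
  # standard site coordinates; cross-check against the SVD solution
  P <- m / sum(m); r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  k <- 1:2
  spp <- sweep(sv$u[, k] / sqrt(r), 2, sv$d[k], "*")
  # orientation-free comparison
  for (j in k) {
    expect_equal(abs(unname(res0$species_scores[, j])),
                 abs(unname(spp[, j])), tolerance = 1e-8)
  }

  expect_warning(
    correspondence_analysis(rbind(m, zero = 0), n_axes = 2),
    "all-zero")
  expect_error(correspondence_analysis(-m, n_axes = 1), "nonnegative")
})

test_that("rare-species downweighting follows Hill's rule", {
  # all species share the same effective frequency: unchanged
  m <- matrix(4, 3, 4, dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  expect_equal(unclass(downweight_rare(m))[, ], m[, ], tolerance = 0)

  # hand transcription on a 3x3 case, fraction = 2:
  # effective frequency f_i = (sum x)^2 / sum x^2: (3, 1, 2);
  # threshold = 3/2; only species 2 is below, scaled by 1/(3/2) = 2/3
  h <- rbind(s1 = c(4, 4, 4), s2 = c(1, 0, 0), s3 = c(2, 2, 0))
  colnames(h) <- paste0("t", 1:3)
  out <- downweight_rare(h, fraction = 2)
  expect_equal(unname(out["s2", ]), c(2 / 3, 0, 0), tolerance = 1e-12)
  expect_equal(out["s1", ], h["s1", ], tolerance = 0)
  expect_equal(out["s3", ], h["s3", ], tolerance = 0)

  # direction: an infrequent species is scaled down, a common one is not
  # (common: effective frequency 6; threshold 6/5; rare: frequency 1)
  m2 <- rbind(common = rep(50, 6), rare = c(1, 0, 0, 0, 0, 0))
  colnames(m2) <- paste0("t", 1:6)
  w <- attr(downweight_rare(m2), "weights")
  expect_lt(w[["rare"]], 1)
  expect_equal(w[["common"]], 1)

  # agreement with the reference implementation (site x species layout)
  skip_if_not_installed("vegan")
  set.seed(4)
  big <- matrix(rpois(80, 2), 8, 10,
                dimnames = list(paste0("sp", 1:8), paste0("t", 1:10)))
  ref <- t(vegan::downweight(t(big)))
  expect_equal(unclass(downweight_rare(big))[, ], ref[, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("detrending removes the axis-1 dependence of axis 2", {
  x <- seq(-2, 2, length.out = 40)
  # fixed point: axis 2 identically centered (all zeros)
  expect_equal(detrend_by_segments(x, rep(0, 40)), rep(0, 40))
  # axis 2 equal to axis 1: a pure trend is flattened
  d <- detrend_by_segments(x, x)
  expect_lt(max(abs(d)), 0.25 * sd(x))
  # arch proxy: quadratic dependence mostly removed
  arch <- x^2
  darch <- detrend_by_segments(x, arch)
  expect_lt(abs(cor(x, darch)), 0.2)
  expect_error(detrend_by_segments(rep(1, 5), rnorm(5)), "zero range")
  expect_error(detrend_by_segments(x, x[1:3]), "lengths differ")
})

test_that("dca recovers a planted single gradient", {
  m <- gradient_matrix(n_species = 30, n_sites = 15, seed = 11)
  # convert to an IVI-like relative matrix: columns sum to 1
  ivi_like <- sweep(m, 2, colSums(m), "/")
  res <- dca(ivi_like, n_axes = 2)
  expect_true(res$detrended)
  expect_true(res$downweighted)
  ord <- res$site_scores[, 1]
  planted <- seq_len(ncol(m))
  rc <- abs(cor(rank(ord), planted, method = "spearman"))
  expect_gte(rc, 0.9)
  # site scores axis variance equals the eigenvalue before detrending
  ca <- correspondence_analysis(downweight_rare(ivi_like), n_axes = 1)
  P <- downweight_rare(ivi_like); P <- P / sum(P)
  wt <- colSums(P)
  wv <- sum(wt * ca$site_scores[, 1]^2)
  expect_equal(wv, unname(ca$eigenvalues[1]), tolerance = 1e-10)

  # n_axes = 1: pure CA, no detrending
  res1 <- dca(ivi_like, n_axes = 1)
  expect_false(res1$detrended)
  expect_equal(ncol(res1$site_scores), 1)
})
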