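test_that("spearman rho on canonical cases", {
  expect_equal(spearman_rho(1:3, c(2, 4, 9))$rho, 1)
  expect_equal(spearman_rho(1:3, c(9, 4, 2))$rho, -1)
  # hand-ranked: d = (0, 1, -1, 0), rho = 1 - 6*2/(4*15)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "missing")
})

test_that("rho and t-approximation p match the stats oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) round(rnorm(n)) else rnorm(n)  # force some ties
    if (sd(rank(y)) == 0) y <- y + seq_len(n)
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_rho(x, 3 * y - 2)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_rho(x, atan(y))$rho, base, tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with direct enumeration", {
  x <- c(3, 1, 4, 2); y <- c(2, 1, 4, 3)
  mine <- spearman_rho(x, y, exact = TRUE)
  # independent enumeration over all 4! orderings
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  hits <- sum(apply(perms, 1, function(p)
    abs(cor(rx, ry[unlist(p)])) >= obs - 1e-12))
  expect_equal(mine$p, hits / nrow(perms))
  expect_error(spearman_rho(1:11, rnorm(11), exact = TRUE), "n <= 10")
})

test_that("bonferroni is exactly min(1, m p)", {
  p <- c(0, 1e-4, 0.02, 0.2, 1)
  expect_identical(bonferroni(p, 10), pmin(1, 10 * p))
  expect_identical(bonferroni(0.5), 0.5)
})

test_that("characteristic screen wiring: families, joins, planted signal", {
  sim <- simulate_survey(simulation_config(seed = 21, n_plots = 6,
                                           n_species = 12))
  s <- campaign_summary_table(sim$survey)
  # plant a perfect signal: density equal to precipitation
  s$mean_density <- sim$truth$campaign_precip
  out <- characteristic_screen(s, sim$climate)
  expect_equal(nrow(out), 10)
  expect_true(all(out$m == 10))
  row <- out[out$response == "mean_density" &
               out$predictor == "precipitation", ]
  expect_equal(row$rho, 1)
  expect_true(all(out$p_bonf >= out$p))

  # flagged cover campaigns shrink the mean-cover pairs only
  tb <- flag_overestimated_cover(sim$survey, c("C01", "C03"))
  s2 <- campaign_summary_table(tb)
  out2 <- characteristic_screen(s2, sim$climate)
  expect_equal(unique(out2$n[out2$response == "mean_cover"]), 13)
  expect_equal(unique(out2$n[out2$response != "mean_cover"]), 15)

  # missing campaign month in the climate table is a join error
  expect_error(characteristic_screen(s, sim$climate[-1 * (1:48), ]),
               "missing from climate")
})

test_that("species screen uses the top-k family and finds responders", {
  cfg <- simulation_config(seed = 5, responder_fraction = 0.4,
                           responder_strength = 1.5)
  sim <- simulate_survey(cfg)
  out <- species_screen(sim$survey, sim$climate, k = 20)
  expect_equal(nrow(out), 40)
  expect_true(all(out$m == 40))
  screened <- unique(out$response)
  expect_length(screened, 20)
  # a strongly planted responder among the top species is flagged
  top_resp <- intersect(screened, sim$truth$responders)
  expect_gt(length(top_resp), 0)
  hits <- out$significant[out$response %in% top_resp &
                            out$predictor == "precipitation"]
  expect_gt(mean(hits), 0.5)
  # species absent everywhere cannot enter the ranking
  expect_false(any(!screened %in% sim$survey$records$species))
})
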