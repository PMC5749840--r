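test_that("plot-level Shannon alpha matches hand values", {
  # single species: zero diversity regardless of count
  expect_equal(shannon(10), 0)
  # 4 equiprobable species: log2(4) bits
  expect_equal(shannon(c(5, 5, 5, 5)), 2)
  # abundances (2,1,1): -sum(p log2 p), p = (1/2, 1/4, 1/4)
  expect_equal(shannon(c(2, 1, 1)), 1.5)
  # natural-log option
  expect_equal(shannon(c(1, 1), base = exp(1)), log(2))

  tb <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 10, 100)))
  pm <- plot_metrics(tb, "C1")
  expect_equal(pm$density, 10)
  expect_equal(pm$alpha, 0)
  expect_error(plot_metrics(tb, "C9"), "unknown campaign")
})

test_that("campaign summary pools correctly and handles empty campaigns", {
  # two plots with disjoint single species: pooling raises diversity
  tb <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 1, 10),
                           rec1("C1", "1998-02", "P2", "S2", 1, 10)))
  s <- campaign_summary(tb, "C1")
  expect_equal(s$richness, 2)
  expect_equal(s$gamma, 1)
  expect_equal(s$mean_alpha, 0)

  # campaign in the roster with no records at all
  cal <- data.frame(campaign_id = c("C1", "C2"),
                    date = c("1998-02", "1998-05"))
  tb2 <- survey_table(rec1("C1", "1998-02", "P1", "S1", 1, 10),
                      plots = c("P1", "P2"), campaigns = cal)
  s2 <- campaign_summary(tb2, "C2")
  expect_equal(s2$mean_density, 0)
  expect_equal(s2$gamma, 0)
  expect_equal(s2$richness, 0)

  # gamma equals alpha when only one plot is non-empty
  tb3 <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 2, 20),
                            rec1("C1", "1998-02", "P1", "S2", 1, 10),
                            rec1("C1", "1998-02", "P1", "S3", 1, 10)),
                      plots = c("P1", "P2", "P3"))
  s3 <- campaign_summary(tb3, "C1")
  expect_equal(s3$gamma, max(plot_metrics(tb3, "C1")$alpha))
  expect_equal(s3$gamma, 1.5)
})

test_that("alpha and gamma agree with a brute-force oracle", {
  for (seed in 1:8) {
    tb <- random_survey(seed)
    for (cid in tb$campaigns$campaign_id) {
      rec <- tb$records[tb$records$campaign_id == cid, ]
      pm <- plot_metrics(tb, cid)
      for (p in tb$plots) {
        expect_equal(pm$alpha[pm$plot_id == p],
                     oracle_shannon(rec$abundance[rec$plot_id == p]),
                     tolerance = 1e-12)
      }
      pooled <- tapply(rec$abundance, rec$species, sum)
      expect_equal(campaign_summary(tb, cid)$gamma,
                   oracle_shannon(as.numeric(pooled)), tolerance = 1e-12)
    }
  }
})

test_that("IVI definition, normalization and degenerate cases", {
  tb <- survey_table(rec1("C1", "1998-02", "P1", "S1", 7, 70))
  expect_equal(unname(ivi(tb, "C1")), 1)

  # counts (3,1), covers (10,30): (0.75 + 0.25)/2 symmetry
  tb2 <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 3, 10),
                            rec1("C1", "1998-02", "P1", "S2", 1, 30)))
  expect_equal(unname(ivi(tb2, "C1")), c(0.5, 0.5))

  cal <- data.frame(campaign_id = "C1", date = "1998-02")
  empty <- survey_table(rec1("C1", "1998-02", "P1", "S1", 0, 0),
                        campaigns = cal)
  expect_error(ivi(empty, "C1"), "zero total abundance")

  # abundance without cover: abundance term only, with a warning
  tb3 <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 1, 0),
                            rec1("C1", "1998-02", "P1", "S2", 1, 10)))
  expect_warning(v <- ivi(tb3, "C1"), "zero cover")
  expect_equal(unname(v), c(0.25, 0.75))

  # column sums of the matrix are exactly 1
  m <- ivi_matrix(random_survey(5))
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("scale equivariance of metrics", {
  tb <- random_survey(9)
  scaled <- tb
  scaled$records$cover_cm2 <- scaled$records$cover_cm2 * 17
  expect_equal(ivi_matrix(scaled), ivi_matrix(tb), tolerance = 1e-12)

  k <- 3
  mult <- tb
  mult$records$abundance <- mult$records$abundance * k
  s0 <- campaign_summary_table(tb)
  s1 <- campaign_summary_table(mult)
  expect_equal(s1$mean_alpha, s0$mean_alpha, tolerance = 1e-12)
  expect_equal(s1$gamma, s0$gamma, tolerance = 1e-12)
  expect_equal(s1$mean_density, k * s0$mean_density, tolerance = 1e-12)
  expect_equal(ivi_matrix(mult), ivi_matrix(tb), tolerance = 1e-12)
})

test_that("top species ranking and argument checks", {
  tb <- survey_table(rbind(rec1("C1", "1998-02", "P1", "S1", 90, 90),
                           rec1("C1", "1998-02", "P1", "S2", 5, 5),
                           rec1("C2", "1998-05", "P1", "S3", 5, 5)),
                     campaigns = data.frame(
                       campaign_id = c("C1", "C2"),
                       date = c("1998-02", "1998-05")))
  expect_equal(top_abundant_species(tb, 1), "S1")
  # tie between S2 and S3 broken lexicographically
  expect_equal(top_abundant_species(tb, 3), c("S1", "S2", "S3"))
  expect_error(top_abundant_species(tb, 0), "positive integer")
  expect_error(top_abundant_species(tb, 4), "exceeds")
})
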