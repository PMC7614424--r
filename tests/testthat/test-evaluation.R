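test_that("patch aggregation is a clipped mean", {
  expect_equal(aggregate_patient_score(c(1, 1, 1)), 1)
  expect_equal(aggregate_patient_score(5), 3)
  expect_equal(aggregate_patient_score(-2), 0)
  v <- runif(37, 0, 3)
  expect_equal(aggregate_patient_score(v), sum(v) / 37)
  expect_error(aggregate_patient_score(numeric(0)), "no patch")
})

test_that("mae matches hand arithmetic and is permutation invariant", {
  expect_equal(mae(c(0.4, 2.0), c(0.5, 1.5)), 0.3)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  p <- runif(25); t <- runif(25)
  o <- sample(25)
  expect_equal(mae(p, t), mae(p[o], t[o]))
  expect_error(mae(numeric(0), numeric(0)), "no score")
})

test_that("exact agreement uses half-up grid rounding", {
  expect_equal(exact_agreement(c(1.24, 1.26), c(1.0, 1.5)), 100)
  expect_equal(exact_agreement(c(1.24, 1.26), c(1.5, 1.0)), 0)
  expect_equal(exact_agreement(c(1, 2, 3), c(1, 2, 3)), 100)
})

test_that("close agreement includes the 0.5 boundary", {
  expect_equal(close_agreement(2.0, 1.5), 100)
  expect_equal(close_agreement(2.6, 1.5), 0)  # rounds to 2.5, gap 1.0
  p <- seq(0, 3, by = 0.5); t <- pmin(p + 0.5, 3)
  expect_equal(close_agreement(p, t), 100)
})

test_that("spearman handles monotone, reversed, tied and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, x^3), 1)
  expect_equal(spearman(x, -x), -1)
  petqc:::with_seed(3, {
    for (i in 1:5) {
      a <- sample(seq(0, 3, 0.5), 20, replace = TRUE)
      b <- runif(20, 0, 3)
      if (sd(a) > 0) {
        expect_equal(spearman(a, b), oracle_spearman(a, b),
                     tolerance = 1e-12)
      }
    }
  })
  expect_warning(r <- spearman(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
  expect_error(spearman(1, 2), ">= 2")
})

test_that("all four metrics agree with brute-force oracles", {
  petqc:::with_seed(11, {
    for (i in 1:200) {
      tb <- random_pair_table(sample(5:40, 1))
      expect_equal(mae(tb$predicted, tb$true),
                   oracle_mae(tb$predicted, tb$true), tolerance = 1e-12)
      expect_equal(exact_agreement(tb$predicted, tb$true),
                   oracle_exact(tb$predicted, tb$true), tolerance = 1e-12)
      expect_equal(close_agreement(tb$predicted, tb$true),
                   oracle_close(tb$predicted, tb$true), tolerance = 1e-12)
      expect_gte(close_agreement(tb$predicted, tb$true),
                 exact_agreement(tb$predicted, tb$true))
    }
  })
})

test_that("mae shifts by exactly |delta| when residuals share sign", {
  p <- c(2, 2.5, 3); t <- c(1, 1.5, 2)  # all residuals positive
  expect_equal(mae(p + 0.25, t), mae(p, t) + 0.25)
  # and by at most |delta| in general
  petqc:::with_seed(5, {
    for (i in 1:20) {
      tb <- random_pair_table(15)
      d <- runif(1, -0.5, 0.5)
      expect_lte(mae(tb$predicted + d, tb$true),
                 mae(tb$predicted, tb$true) + abs(d) + 1e-12)
    }
  })
})

test_that("eval_report summarises per metric and pooled", {
  df <- data.frame(
    metric = rep(c("gqr", "pr", "dc"), each = 4),
    predicted = c(1, 2, 3, 0.4, 1.6, 2.4, 0.9, 1.1, 2.2, 0.6, 1.4, 2.6),
    true = rep(c(1, 2, 3, 0.5), 3)
  )
  rep_ <- eval_report(df)
  expect_equal(rep_$metric, c("gqr", "pr", "dc", "pooled"))
  expect_equal(rep_$n, c(4, 4, 4, 12))
  expect_true(all(rep_$close_pct >= rep_$exact_pct))
  expect_equal(rep_$mae[1], mae(df$predicted[1:4], df$true[1:4]))
  expect_true(all(rep_$exact_pct >= 0 & rep_$exact_pct <= 100))
})

test_that("dose-only baseline recovers a dose-driven score trend", {
  coh <- make_cohort(5, fractions_per_patient = 7, seed = 31,
                     shape = c(32, 32, 32))
  fit <- dose_baseline_fit(coh[1:4])
  preds <- predict(fit, coh[5])
  expect_true(all(preds$predicted >= 0 & preds$predicted <= 3))
  rep_ <- eval_report(preds)
  # dose explains most of the synthetic score signal by construction
  expect_lt(rep_$mae[rep_$metric == "pooled"], 1)
})
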