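test_that("scores are clipped and quantised to the clinical grid", {
  # zero noise, steep slope: full-count score lands above 3 and is clipped
  p <- score_model_params(slope = c(gqr = 5, pr = 5, dc = 5),
                          intercept = c(gqr = 0, pr = 0, dc = 0),
                          noise_sd = c(gqr = 0, pr = 0, dc = 0))
  sc <- assign_scores(1, weight_kg = 75, params = p, seed = 1)
  expect_equal(unname(sc), c(3, 3, 3))
  # and a very low dose is clipped at 0
  p2 <- score_model_params(slope = c(gqr = 5, pr = 5, dc = 5),
                           intercept = c(gqr = -60, pr = -60, dc = -60),
                           noise_sd = c(gqr = 0, pr = 0, dc = 0))
  expect_equal(unname(assign_scores(0.005, 75, p2, seed = 1)), c(0, 0, 0))
})

test_that("quantisation rounds half-up on the 0.5 grid", {
  expect_equal(round_to_half(1.25), 1.5)
  expect_equal(round_to_half(1.24), 1.0)
  expect_equal(round_to_half(c(0.249, 0.25, 2.74, 2.75)),
               c(0, 0.5, 2.5, 3))
  # engineered latent score of exactly 1.25: slope 1, dose_per_kg 10^1.25
  p <- score_model_params(slope = c(gqr = 1, pr = 1, dc = 1),
                          intercept = c(gqr = 0, pr = 0, dc = 0),
                          noise_sd = c(gqr = 0, pr = 0, dc = 0))
  sc <- assign_scores(1, weight_kg = 1, params = p, seed = 1,
                      full_counts = 10^1.25)
  expect_equal(unname(sc), c(1.5, 1.5, 1.5))
})

test_that("expected score is monotone non-decreasing in fraction", {
  p <- score_model_params(noise_sd = c(gqr = 0, pr = 0, dc = 0))
  scores <- t(vapply(unname(dose_fractions()), function(f) {
    assign_scores(f, 75, p, seed = 1, full_counts = 5e6)
  }, numeric(3)))
  for (m in 1:3) expect_true(all(diff(scores[, m]) >= 0))
})

test_that("generated scores always lie on the 0.5 grid in [0, 3]", {
  for (s in 1:50) {
    f <- sample(unname(dose_fractions()), 1)
    sc <- assign_scores(f, runif(1, 45, 120), seed = s)
    expect_true(all(sc >= 0 & sc <= 3))
    expect_true(all(abs(sc * 2 - round(sc * 2)) < 1e-12))
  }
})

test_that("cohort generation matches the transfer-learning dataset shape", {
  coh <- make_cohort(7, fractions_per_patient = 3, seed = 4,
                     shape = c(32, 32, 32))
  expect_length(coh, 7)
  df <- cohort_scores(coh)
  expect_equal(nrow(df), 21)  # 7 patients x 3 dose levels
  expect_true(all(df$fraction %in% dose_fractions()))
  expect_true(all(df$weight_kg >= 45 & df$weight_kg <= 120))
  # one fraction per quality category
  cats <- c(low = 0.01, medium = 0.1, high = 1)
  for (p in coh) {
    fr <- vapply(p$fractions, `[[`, numeric(1), "fraction")
    expect_length(fr, 3)
    expect_true(any(fr <= 0.01) && any(fr %in% c(0.05, 0.1)) &&
                  any(fr >= 0.25))
  }
  expect_length(make_cohort(1, seed = 1, shape = c(32, 32, 32)), 1)
})

test_that("cohorts are fully reproducible under a fixed seed", {
  a <- make_cohort(2, fractions_per_patient = 3, seed = 9,
                   shape = c(32, 32, 32))
  b <- make_cohort(2, fractions_per_patient = 3, seed = 9,
                   shape = c(32, 32, 32))
  expect_identical(cohort_scores(a), cohort_scores(b))
  expect_identical(a[[1]]$fractions[[2]]$volume,
                   b[[1]]$fractions[[2]]$volume)
  expect_identical(a[[2]]$activity$voxels, b[[2]]$activity$voxels)
})
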