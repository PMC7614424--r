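# Training loop, gradient correctness, freezing and pipeline plumbing.

make_toy_data <- function(n, seed, outputs = 3) {
  petqc:::with_seed(seed, {
    list(x = array(runif(32 * 32 * n), dim = c(32, 32, n)),
         y = matrix(runif(n * outputs, 0, 3), n, outputs))
  })
}

test_that("analytic gradients match finite differences", {
  m <- build_backbone(tiny_spec(), head_spec("clinical"), seed = 3)
  m <- apply_freeze(m, freeze_policy(5))
  x <- petqc:::with_seed(8, array(runif(32 * 32 * 3 * 2),
                                  dim = c(32, 32, 3, 2)))
  y <- matrix(c(0.5, 1, 1.5, 2, 2.5, 3), 2, 3)
  fw <- petqc:::model_forward(m, x, want_cache = TRUE)
  gr <- petqc:::model_backward(m, fw, 2 * (fw$out - y) / length(fw$out))
  eps <- 1e-6
  loss_at <- function(mm) {
    mean((petqc:::model_forward(mm, x)$out - y)^2)
  }
  probes <- list(c(1, 1, 1), c(5, 4, 2), c(13, 10, 1))
  for (p in probes) {
    li <- p[1]
    mm <- m; mm$params$conv[[li]]$W[p[2], p[3]] <- mm$params$conv[[li]]$W[p[2], p[3]] + eps
    up <- loss_at(mm)
    mm <- m; mm$params$conv[[li]]$W[p[2], p[3]] <- mm$params$conv[[li]]$W[p[2], p[3]] - eps
    dn <- loss_at(mm)
    expect_equal(gr$conv[[li]]$W[p[2], p[3]], (up - dn) / (2 * eps),
                 tolerance = 1e-4)
  }
  mm <- m; mm$params$head$b[1] <- mm$params$head$b[1] + eps
  up <- loss_at(mm)
  mm <- m; mm$params$head$b[1] <- mm$params$head$b[1] - eps
  dn <- loss_at(mm)
  expect_equal(gr$head$b[1], (up - dn) / (2 * eps), tolerance = 1e-4)
})

test_that("frozen blocks stay bit-identical through optimisation", {
  tr <- make_toy_data(20, 1)
  va <- make_toy_data(10, 2)
  for (k in c(0L, 2L)) {
    m <- build_backbone(tiny_spec(), head_spec("clinical"), seed = 4)
    m <- apply_freeze(m, freeze_policy(k))
    before <- m$params$conv
    cfg <- train_config(learning_rate = 1e-3, batch_size = 4,
                        max_epochs = 1, seed = 7)
    fit <- train(m, tr, va, cfg)  # 5 optimisation steps (20 / 4)
    after <- fit$model$params$conv
    for (li in seq_along(before)) {
      if (before[[li]]$block <= 5L - k) {
        expect_identical(after[[li]]$W, before[[li]]$W)
        expect_identical(after[[li]]$b, before[[li]]$b)
      } else {
        expect_false(identical(after[[li]]$W, before[[li]]$W))
      }
    }
    # head always trains
    expect_false(identical(fit$model$params$head$W, m$params$head$W))
  }
})

test_that("checkpoint selection returns the argmin validation loss", {
  tr <- make_toy_data(20, 3)
  va <- make_toy_data(8, 4)
  m <- build_backbone(tiny_spec(), head_spec("clinical"), seed = 1)
  m <- apply_freeze(m, freeze_policy(0))
  fit <- train(m, tr, va, train_config(learning_rate = 1e-2,
                                       batch_size = 5, max_epochs = 8,
                                       seed = 2))
  expect_lte(nrow(fit$history), 8)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # the returned checkpoint reproduces that validation loss
  out <- predict(fit$model, va$x)
  expect_equal(mean((out - va$y)^2), min(fit$history$val_loss),
               tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  tr <- make_toy_data(16, 5)
  va <- make_toy_data(8, 6)
  run <- function() {
    m <- build_backbone(tiny_spec(), head_spec("clinical"), seed = 11)
    m <- apply_freeze(m, freeze_policy(2))
    train(m, tr, va, train_config(batch_size = 4, max_epochs = 2,
                                  seed = 13))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a constant-target head converges to that constant", {
  tr <- make_toy_data(30, 7, outputs = 1)
  tr$y[] <- 0.6
  va <- make_toy_data(10, 8, outputs = 1)
  va$y[] <- 0.6
  m <- build_backbone(tiny_spec(), head_spec("dose"), seed = 2)
  m <- apply_freeze(m, freeze_policy(0))
  fit <- train(m, tr, va, train_config(learning_rate = 1e-2,
                                       batch_size = 10, max_epochs = 150,
                                       seed = 3))
  pred <- predict(fit$model, va$x)
  expect_lt(mean(abs(pred - 0.6)), 0.05)
})

test_that("degenerate inputs are rejected", {
  tr <- make_toy_data(10, 9)
  m <- build_backbone(tiny_spec(), head_spec("clinical"), seed = 1)
  empty <- list(x = array(0, dim = c(32, 32, 0)),
                y = matrix(0, 0, 3))
  expect_error(train(m, empty, tr, train_config()), "empty training")
  expect_error(train(m, tr, empty, train_config()), "empty validation")
  bad <- tr; bad$y <- tr$y[, 1:2]
  expect_error(train(m, tr, bad, train_config()), "empty|match")
  expect_error(train_config(learning_rate = 0), "positive")
})

test_that("pretext target scaling is unit-range and monotone", {
  raw <- c(0.005, 0.01, 0.05, 0.1, 0.25, 0.5, 1) * 5e6 / 75
  sc <- pretext_scaling(raw)
  u <- apply_pretext_scaling(sc, raw)
  expect_equal(min(u), 0)
  expect_equal(max(u), 1)
  expect_true(all(diff(u) > 0))
  # log spacing: neighbouring low fractions remain separated
  expect_gt(u[2] - u[1], 0.1)
  # single-level cohort collapses to the constant 0 without dividing by 0
  sc1 <- pretext_scaling(rep(3, 5))
  expect_equal(apply_pretext_scaling(sc1, rep(3, 5)), rep(0, 5))
  # linear option preserved
  scl <- pretext_scaling(raw, log = FALSE)
  ul <- apply_pretext_scaling(scl, raw)
  expect_equal(ul, (raw - min(raw)) / (max(raw) - min(raw)))
})

test_that("split hygiene is enforced before pipelines run", {
  coh <- make_cohort(3, fractions_per_patient = 1, seed = 2,
                     shape = c(32, 32, 32))
  expect_error(assert_split_hygiene(train = coh[1:2], test = coh[2:3]),
               "P02")
  expect_silent(assert_split_hygiene(train = coh[1], test = coh[2:3]))
  expect_error(
    run_pipeline("a", clinical_train = coh[1:2], clinical_val = coh[2]),
    "more than one split")
  expect_error(
    run_pipeline("a", clinical_train = structure(list(),
                                                 class = "qc_cohort"),
                 clinical_val = coh[1]),
    "empty")
  # pipeline b fails explicitly without the optional weights
  expect_error(
    run_pipeline("b", clinical_train = coh[1], clinical_val = coh[2]),
    "weights")
  expect_error(
    run_pipeline("c", clinical_train = coh[1], clinical_val = coh[2]),
    "pretext")
})
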