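test_that("candidates stay in bounds and are reproducible", {
  vol <- small_volume(1)
  cand <- extract_candidates(vol, n = 500, size = 32, seed = 3)
  expect_equal(nrow(cand), 500)
  for (pl in unique(cand$plane)) {
    pd <- petqc:::plane_dims(dim(vol), pl)
    sel <- cand$plane == pl
    expect_true(all(cand$slice[sel] >= 1 & cand$slice[sel] <= pd[3]))
    expect_true(all(cand$row[sel] + 32 - 1 <= pd[1]))
    expect_true(all(cand$col[sel] + 32 - 1 <= pd[2]))
  }
  expect_identical(cand, extract_candidates(vol, n = 500, size = 32,
                                            seed = 3))
  expect_equal(nrow(extract_candidates(vol, n = 0, size = 32, seed = 1)), 0)
})

test_that("patch size auto-reduces to a feasible multiple of 16", {
  vol <- small_volume(2)  # 48 x 48 x 32
  expect_warning(sz <- resolve_patch_size(dim(vol), 80), "reduced")
  expect_equal(sz, 32)
  expect_silent(expect_equal(resolve_patch_size(dim(vol), 32), 32))
  expect_error(resolve_patch_size(c(10, 10, 10), 80), "feasible")
})

test_that("background threshold follows the one-eighth rule", {
  expect_false(passes_background_threshold(matrix(0, 4, 4), 0.2))
  expect_true(passes_background_threshold(matrix(0.2, 4, 4), 0.2))
  # exact equality survives
  expect_true(passes_background_threshold(matrix(0.025, 4, 4), 0.2))
  expect_error(passes_background_threshold(matrix(1, 2, 2), 0), "positive")
})

test_that("surviving counts match a brute-force recount", {
  for (s in 1:5) {
    vol <- small_volume(s)
    cand <- extract_candidates(vol, n = 150, size = 32, seed = s)
    pkg_count <- sum(petqc:::candidate_means(vol, cand) >= mean(vol) / 8)
    expect_equal(pkg_count, oracle_threshold_count(vol, cand))
  }
})

test_that("balanced sampling yields exact per-plane counts that all pass", {
  vol <- small_volume(3)
  ps <- extract_patches(vol, n_candidates = 400, size = 32, per_plane = 20,
                        seed = 5)
  expect_equal(nrow(ps$info), 60)
  expect_equal(as.integer(table(ps$info$plane)), rep(20L, 3))
  vm <- mean(vol)
  for (i in seq_len(nrow(ps$info))) {
    expect_true(passes_background_threshold(ps$pixels[, , i], vm))
    expect_true(all(ps$pixels[, , i] >= 0 & ps$pixels[, , i] <= 1))
  }
  # per_plane = 0 gives an empty set
  cand <- extract_candidates(vol, n = 50, size = 32, seed = 1)
  empty <- sample_balanced(cand, per_plane = 0, seed = 1, volume = vol)
  expect_equal(nrow(empty$info), 0)
})

test_that("sampling from exactly per_plane survivors returns them all", {
  vol <- small_volume(4)
  cand <- extract_candidates(vol, n = 2000, size = 32, seed = 2)
  keep <- petqc:::candidate_means(vol, cand) >= mean(vol) / 8
  surv <- cand[keep, ]
  surv <- surv[!duplicated(surv[c("plane", "slice", "row", "col")]), ]
  nmin <- min(table(surv$plane))
  picked <- list()
  for (pl in unique(surv$plane)) {
    sp <- surv[surv$plane == pl, ][seq_len(nmin), ]
    picked[[pl]] <- sp
  }
  cand_exact <- do.call(rbind, picked)
  for (seed in c(1, 99)) {
    ps <- sample_balanced(cand_exact, per_plane = nmin, seed = seed,
                          volume = vol)
    got <- ps$info[order(ps$info$plane, ps$info$slice, ps$info$row,
                         ps$info$col), c("plane", "slice", "row", "col")]
    want <- cand_exact[order(cand_exact$plane, cand_exact$slice,
                             cand_exact$row, cand_exact$col),
                       c("plane", "slice", "row", "col")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("pure-background patches are rejected, cortical patches kept", {
  ph <- generate_phantom(6, shape = c(64, 64, 48))
  vol <- normalize_volume(simulate_dose_fraction(ph, 5e6, 1, seed = 7))
  vm <- mean(vol)
  # a corner patch lies wholly in the zero background of the phantom
  corner <- vol[1:16, 1:16, 2]
  expect_false(passes_background_threshold(corner, vm))
  # a central patch crosses the cortical shell / white matter
  centre <- vol[25:40, 25:40, 24]
  expect_true(passes_background_threshold(centre, vm))
})

test_that("top-up redraws fill a plane short of survivors", {
  vol <- small_volume(5)
  # tiny candidate pool: some plane will fall short of 10 survivors
  cand <- extract_candidates(vol, n = 12, size = 32, seed = 8)
  expect_error(sample_balanced(cand, per_plane = 10, seed = 1,
                               volume = vol, top_up = FALSE), "plane")
  ps <- sample_balanced(cand, per_plane = 10, seed = 1, volume = vol)
  expect_equal(as.integer(table(ps$info$plane)), rep(10L, 3))
})

test_that("three-channel replication is exact", {
  px <- matrix(runif(16), 4, 4)
  x3 <- to_three_channel(px)
  expect_equal(dim(x3), c(4, 4, 3))
  for (c in 1:3) expect_identical(x3[, , c], px)
  expect_identical(apply(x3, c(1, 2), mean), px)
  expect_true(all(to_three_channel(matrix(0, 4, 4)) == 0))
})
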