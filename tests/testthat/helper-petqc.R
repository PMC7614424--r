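# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately avoid the package's own code
# paths (explicit loops, manual rank computation).

oracle_mae <- function(predicted, true) {
  s <- 0
  for (i in seq_along(predicted)) s <- s + abs(predicted[i] - true[i])
  s / length(predicted)
}

oracle_round_half <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- floor(x[i] * 2 + 0.5) / 2
  out
}

oracle_exact <- function(predicted, true) {
  r <- oracle_round_half(predicted)
  hits <- 0
  for (i in seq_along(r)) if (isTRUE(all.equal(r[i], true[i]))) hits <- hits + 1
  100 * hits / length(r)
}

oracle_close <- function(predicted, true) {
  r <- oracle_round_half(predicted)
  hits <- 0
  for (i in seq_along(r)) if (abs(r[i] - true[i]) <= 0.5 + 1e-9) hits <- hits + 1
  100 * hits / length(r)
}

# average ranks computed by hand, then Pearson computed from first
# principles (no stats::cor).
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Random score table: predictions continuous >= 0, truths on the 0.5 grid.
random_pair_table <- function(n = 30) {
  list(predicted = runif(n, 0, 3.5),
       true = sample(seq(0, 3, by = 0.5), n, replace = TRUE))
}

# Small normalised volume fixture with brain-like support.
small_volume <- function(seed = 1, shape = c(48, 48, 32)) {
  ph <- generate_phantom(seed, shape = shape)
  normalize_volume(simulate_dose_fraction(ph, 2e6, 0.25, seed = seed + 1))
}

# Brute-force recount of surviving candidate patches.
oracle_threshold_count <- function(volume, cand) {
  vm <- mean(volume)
  n <- 0
  for (i in seq_len(nrow(cand))) {
    px <- petqc:::get_patch_pixels(volume, cand$plane[i], cand$slice[i],
                                   cand$row[i], cand$col[i], cand$size[i])
    s <- 0
    for (v in px) s <- s + v
    if (s / length(px) >= vm / 8) n <- n + 1
  }
  n
}

tiny_spec <- function(width = 2) backbone_spec(base_width = width,
                                               input_size = 32)

# Small clinical + pretext cohorts shared by the training-scale tests.
make_training_fixture <- function(seed = 21) {
  clin <- make_cohort(10, fractions_per_patient = 3, seed = seed,
                      shape = c(48, 48, 32), id_prefix = "C")
  pretx <- make_cohort(9, fractions_per_patient = 7, seed = seed + 1,
                       shape = c(48, 48, 32), id_prefix = "X")
  list(pretext = pretx[1:8], pretext_val = pretx[9],
       train = clin[1:6], val = clin[7], test = clin[8:10])
}
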