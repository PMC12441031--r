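test_that("window positions stay inside the admissible range", {
  set.seed(1)
  p <- replicate(1000, sample_window_position(22, 4))
  expect_true(all(p >= 1 & p <= 17))
  # singleton range is forced
  expect_true(all(replicate(20, sample_window_position(6, 4)) == 1))
  expect_error(sample_window_position(22, 21), "too large")
})

test_that("residual concatenation preserves order around the window", {
  x <- as.numeric(1:22)
  r5 <- make_residual(x, P = 5, W = 4)
  expect_identical(r5, c(1:5, 10:22) + 0) # window held values 6..9
  expect_length(r5, 18)
  r1 <- make_residual(x, P = 1, W = 4)
  expect_identical(r1, c(1, 6:22) + 0)
  expect_error(make_residual(x, P = 18, W = 4), "outside")
})

test_that("window and residual indices partition the feature set", {
  set.seed(2)
  for (i in 1:50) {
    L <- sample(8:30, 1)
    W <- sample(2:(L - 3), 1)
    P <- sample_window_position(L, W)
    win <- (P + 1):(P + W)
    res <- setdiff(1:L, win)
    expect_length(win, W)
    expect_length(res, L - W)
    expect_identical(sort(c(win, res)), 1:L)
    # ends are always in the residual
    expect_true(1 %in% res && L %in% res)
  }
})

test_that("splicing the window back into the residual recovers the sample", {
  set.seed(3)
  for (i in 1:200) {
    L <- sample(8:30, 1)
    W <- sample(2:(L - 3), 1)
    P <- sample_window_position(L, W)
    x <- rnorm(L)
    expect_identical(splice_back(make_residual(x, P, W),
                                 x[(P + 1):(P + W)], P), x)
  }
})

test_that("with zero noise the auxiliary data is a permutation of the window", {
  set.seed(4)
  cfg <- disturbance_config(noise_sigma = 0)
  x <- rnorm(22)
  for (i in 1:50) {
    P <- sample_window_position(22, 4)
    a <- make_auxiliary(x, P, cfg)
    win <- x[(P + 1):(P + 4)]
    expect_identical(sort(a$auxiliary), sort(win))
    expect_identical(a$auxiliary, win[a$permutation])
  }
})

test_that("mask noise has the configured first two moments", {
  set.seed(5)
  cfg <- disturbance_config(noise_sigma = 1)
  x <- rnorm(22)
  P <- 7
  win <- x[(P + 1):(P + 4)]
  devs <- t(replicate(10000, {
    a <- make_auxiliary(x, P, cfg)
    a$auxiliary - win[a$permutation]
  }))
  expect_true(all(abs(colMeans(devs)) < 0.05))
  expect_true(all(abs(apply(devs, 2, var) - 1) < 0.05))
})

test_that("view generation yields M x views_per_sample fresh records", {
  std <- standardize_features(simulate_feature_table(40, seed = 1))
  v1 <- generate_views(std, seed = 11)
  expect_identical(nrow(v1), 40L)
  expect_identical(v1, generate_views(std, seed = 11)) # seeded determinism
  v25 <- generate_views(std, disturbance_config(views_per_sample = 25),
                        seed = 12)
  expect_identical(nrow(v25), 1000L)
  expect_gt(length(unique(v25$P)), 1)
  # every record partitions: |residual| + |auxiliary| = L
  expect_true(all(lengths(v25$residual) + lengths(v25$auxiliary) == 22L))
  expect_error(generate_views(std[0, ], seed = 1), "rows")
})

test_that("records are reconstructable from residual + de-permuted auxiliary", {
  std <- standardize_features(simulate_feature_table(10, seed = 2))
  v <- generate_views(std, disturbance_config(noise_sigma = 0), seed = 3)
  for (i in seq_len(nrow(v))) {
    win <- numeric(4)
    win[v$permutation[[i]]] <- NA # placement check below
    win <- v$auxiliary[[i]][order(v$permutation[[i]])]
    rebuilt <- splice_back(v$residual[[i]], win, v$P[i])
    expect_equal(rebuilt, v$target[[i]], tolerance = 1e-12)
  }
})
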