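test_that("the default module follows the branch-by-branch length arithmetic", {
  # oracle: floor((n - V)/s) + 1 per stage, branches concatenated by length
  expect_identical(oracle_mvccm_len(18, c(2, 3, 4), c(1, 2, 3)), 36L)
  set.seed(1)
  cfg <- encoder_config()
  mods <- ssdfrn:::encoder_modules_init(cfg)
  out <- mvccm_forward(matrix(rnorm(3 * 18), 3, 18), mods$m1,
                       cfg$modules[[1]])
  expect_identical(dim(out), c(3L, 36L, 16L))
  # default two-module encoder flattens to 576 and projects to 18
  expect_identical(
    oracle_encoder_flatten(18, cfg$modules, cfg$pool_window,
                           cfg$pool_stride), 576L)
  expect_identical(ssdfrn:::encoder_flatten_width(18, mods, cfg), 576L)
  h <- mvcnn_forward(matrix(rnorm(2 * 18), 2, 18),
                     list(modules = mods,
                          proj = ssdfrn:::fc_init(576, 18)), cfg)
  expect_identical(dim(h), c(2L, 18L))
})

test_that("zero weights give zero outputs of the correct shape", {
  set.seed(2)
  cfg <- encoder_config()
  mods <- ssdfrn:::encoder_modules_init(cfg)
  zmods <- ssdfrn:::zero_weights(mods)
  out <- mvccm_forward(matrix(rnorm(2 * 18), 2, 18), zmods$m1,
                       cfg$modules[[1]])
  expect_identical(dim(out), c(2L, 36L, 16L))
  expect_true(all(out == 0))
  # zero projection weights blank the hidden representation
  h <- mvcnn_forward(matrix(rnorm(2 * 18), 2, 18),
                     list(modules = mods,
                          proj = list(W = matrix(0, 576, 18),
                                      b = numeric(18))), cfg)
  expect_true(all(h == 0))
})

test_that("forward passes are deterministic given weights and input", {
  set.seed(3)
  cfg <- encoder_config()
  mods <- ssdfrn:::encoder_modules_init(cfg)
  proj <- ssdfrn:::fc_init(576, 18)
  x <- matrix(rnorm(4 * 18), 4, 18)
  p <- list(modules = mods, proj = proj)
  expect_identical(mvcnn_forward(x, p, cfg), mvcnn_forward(x, p, cfg))
})

test_that("parameter counts are exact and input-length invariant", {
  set.seed(4)
  # single conv, kernel 2, 1 -> 1 channels, with bias
  expect_identical(count_parameters(list(C = ssdfrn:::conv_init(1, 1, 2))), 3L)
  cfg <- encoder_config()
  mods <- ssdfrn:::encoder_modules_init(cfg)
  # conv stacks do not grow with input length (weight sharing)
  n_convs <- count_parameters(mods)
  expect_identical(n_convs, count_parameters(mods)) # same tree, same count
  # closed form: per branch S: V1*in*K + K, M: V2*K*K + K, B: V3*K*K + K
  closed <- function(in_ch, K) {
    3 * ((2 * in_ch * K + K) + (3 * K * K + K) + (4 * K * K + K))
  }
  expect_identical(n_convs, as.integer(closed(1, 16) + closed(16, 32)))
  # doubling K roughly quadruples the K x K conv parameters
  m16 <- closed(16, 16)
  m32 <- closed(16, 32)
  expect_gt(m32 / m16, 3)
  expect_lt(m32 / m16, 4.2)
})

test_that("permuting kernels with matching downstream weights is a no-op", {
  # channel-order sanity check on one branch: permute the K outputs of the
  # small conv and the corresponding input slots of the medium conv
  set.seed(5)
  K <- 4
  S <- ssdfrn:::conv_init(1, K, 2)
  M <- ssdfrn:::conv_init(K, K, 3)
  x <- matrix(rnorm(2 * 15), 2, 15)
  fwd <- function(S, M) {
    s <- ssdfrn:::conv1d_forward(ssdfrn:::as_tensor(x), S, 1L)
    r <- ssdfrn:::relu_forward(s$out)
    ssdfrn:::conv1d_forward(r$out, M, 1L)$out
  }
  base <- fwd(S, M)
  perm <- sample(K)
  S2 <- S
  S2$W <- S$W[, perm, drop = FALSE]
  S2$b <- S$b[perm]
  M2 <- M
  # medium rows are offset-major blocks of K input channels
  for (v in 1:3) {
    rows <- ((v - 1) * K + 1):(v * K)
    M2$W[rows, ] <- M$W[rows, ][perm, ]
  }
  expect_equal(fwd(S2, M2), base, tolerance = 1e-12)
})

test_that("a collapsing branch is reported with its stage", {
  set.seed(6)
  cfg <- encoder_config(modules = list(mvccm_config(V = c(2, 3, 4),
                                                    strides = c(1, 2, 3),
                                                    K = 2)))
  mods <- ssdfrn:::encoder_modules_init(cfg)
  expect_error(mvccm_forward(matrix(rnorm(4), 1, 4), mods$m1,
                             cfg$modules[[1]]),
               "collapses")
})

test_that("the plain ablation encoder produces the projected width too", {
  set.seed(7)
  cfg <- encoder_config(type = "plain", projection_width = 18)
  mods <- ssdfrn:::encoder_modules_init(cfg)
  fw <- ssdfrn:::encoder_flatten_width(18, mods, cfg)
  h <- mvcnn_forward(matrix(rnorm(3 * 18), 3, 18),
                     list(modules = mods, proj = ssdfrn:::fc_init(fw, 18)),
                     cfg)
  expect_identical(dim(h), c(3L, 18L))
})
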