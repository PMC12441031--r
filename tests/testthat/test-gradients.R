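# Central-difference checks of the analytic gradients on a scaled-down
# architecture. Truncation error of the scheme is O(eps^2), so relative
# agreement around 1e-6 is the best attainable at eps = 1e-6.

test_that("stage-1 analytic gradients match finite differences", {
  set.seed(101)
  enc_cfg <- encoder_config(modules = list(mvccm_config(K = 2)),
                            projection_width = 18)
  dec_cfg <- decoder_config(blocks = list(list(K = 2, V = 3, S = 1)),
                            output_width = 22)
  mods <- ssdfrn:::encoder_modules_init(enc_cfg)
  fw <- ssdfrn:::encoder_flatten_width(18, mods, enc_cfg)
  params <- list(enc = list(modules = mods, proj = ssdfrn:::fc_init(fw, 18)),
                 dec = ssdfrn:::decoder_init(dec_cfg, 22))
  n <- 3
  res <- matrix(rnorm(n * 18), n, 18)
  aux <- matrix(rnorm(n * 4), n, 4)
  P <- c(3, 11, 17)
  target <- matrix(rnorm(n * 22), n, 22)

  loss_fn <- function(params) {
    enc <- ssdfrn:::encoder_fwd(res, params$enc, enc_cfg)
    xde <- ssdfrn:::splice_batch(enc$out, aux, P, 22L)
    dec <- ssdfrn:::decoder_fwd(xde, params$dec, dec_cfg)
    mean((dec$out - target)^2)
  }
  enc <- ssdfrn:::encoder_fwd(res, params$enc, enc_cfg)
  xde <- ssdfrn:::splice_batch(enc$out, aux, P, 22L)
  dec <- ssdfrn:::decoder_fwd(xde, params$dec, dec_cfg)
  dxhat <- 2 * (dec$out - target) / (n * 22)
  db <- ssdfrn:::decoder_bwd(dxhat, params$dec, dec_cfg, dec$cache)
  dh <- ssdfrn:::desplice_batch(matrix(db$dx, n, 22), P, 4L)
  eg <- ssdfrn:::encoder_bwd(dh, params$enc, enc_cfg, enc$cache, TRUE)
  g <- list(enc = list(modules = eg$modules, proj = eg$proj), dec = db$grads)

  eps <- 1e-6
  paths <- list(c("enc", "modules", "m1", "b2", "S", "W"),
                c("enc", "modules", "m1", "b1", "M", "b"),
                c("enc", "modules", "m1", "b3", "B", "W"),
                c("enc", "proj", "W"),
                c("dec", "conv", "c1", "W"),
                c("dec", "fc", "W"))
  for (pth in paths) {
    leaf <- params[[pth]]
    gleaf <- g[[pth]]
    for (i in sample(length(leaf), min(4, length(leaf)))) {
      pp <- params; pp[[pth]][i] <- pp[[pth]][i] + eps
      pm <- params; pm[[pth]][i] <- pm[[pth]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_lt(abs(num - gleaf[i]) /
                  max(1e-8, abs(num) + abs(gleaf[i])), 1e-4)
    }
  }
})

test_that("stage-2 analytic gradients match finite differences", {
  set.seed(102)
  enc_cfg <- encoder_config(modules = list(mvccm_config(K = 2)),
                            projection_width = 18)
  mods <- ssdfrn:::encoder_modules_init(enc_cfg)
  n <- 3
  y <- rnorm(n, 19, 5)
  x22 <- matrix(rnorm(n * 22), n, 22)
  fw2 <- ssdfrn:::encoder_flatten_width(22, mods, enc_cfg)
  p2 <- list(proj = ssdfrn:::fc_init(fw2, 18),
             est = list(fc1 = ssdfrn:::fc_init(18, 7),
                        fc2 = ssdfrn:::fc_init(7, 1)))
  loss2 <- function(p2) {
    enc <- ssdfrn:::encoder_fwd(x22, list(modules = mods, proj = p2$proj),
                                enc_cfg)
    r1 <- ssdfrn:::relu_forward(
      ssdfrn:::fc_forward(enc$out, p2$est$fc1)$out)$out
    yhat <- drop(ssdfrn:::fc_forward(r1, p2$est$fc2)$out)
    mean((yhat - y)^2)
  }
  enc <- ssdfrn:::encoder_fwd(x22, list(modules = mods, proj = p2$proj),
                              enc_cfg)
  f1 <- ssdfrn:::fc_forward(enc$out, p2$est$fc1)
  r1 <- ssdfrn:::relu_forward(f1$out)
  f2 <- ssdfrn:::fc_forward(r1$out, p2$est$fc2)
  err <- drop(f2$out) - y
  b2 <- ssdfrn:::fc_backward(matrix(2 * err / n, n, 1), p2$est$fc2, f2$cache)
  b1 <- ssdfrn:::fc_backward(ssdfrn:::relu_backward(b2$dx, r1$cache),
                             p2$est$fc1, f1$cache)
  eg <- ssdfrn:::encoder_bwd(b1$dx, list(modules = mods, proj = p2$proj),
                             enc_cfg, enc$cache, FALSE)
  g2 <- list(proj = eg$proj, est = list(fc1 = b1$grads, fc2 = b2$grads))

  eps <- 1e-6
  for (pth in list(c("proj", "W"), c("est", "fc1", "W"),
                   c("est", "fc2", "W"), c("est", "fc2", "b"))) {
    leaf <- p2[[pth]]
    gleaf <- g2[[pth]]
    for (i in sample(length(leaf), min(4, length(leaf)))) {
      pp <- p2; pp[[pth]][i] <- pp[[pth]][i] + eps
      pm <- p2; pm[[pth]][i] <- pm[[pth]][i] - eps
      num <- (loss2(pp) - loss2(pm)) / (2 * eps)
      expect_lt(abs(num - gleaf[i]) /
                  max(1e-8, abs(num) + abs(gleaf[i])), 1e-4)
    }
  }
})
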