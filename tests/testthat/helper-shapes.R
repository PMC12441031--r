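# Arithmetic shape oracle, independent of the network code: every valid
# (no-padding) convolution or pooling stage maps a length n to
# floor((n - V) / s) + 1. Returns NA as soon as any stage collapses.

oracle_conv_len <- function(n, V, s) {
  out <- (n - V) %/% s + 1
  if (is.na(out) || out < 1) NA_integer_ else as.integer(out)
}

oracle_mvccm_len <- function(n, V, strides) {
  total <- 0L
  for (s in strides) {
    small <- oracle_conv_len(n, V[1], s)
    med <- oracle_conv_len(small, V[2], s)
    if (is.na(small) || is.na(med)) return(NA_integer_)
    big <- oracle_conv_len(small + med, V[3], s)
    if (is.na(big)) return(NA_integer_)
    total <- total + big
  }
  total
}

# flatten width of the encoder stack for a 1-channel input of length n
oracle_encoder_flatten <- function(n, modules, pool_window, pool_stride) {
  for (m in modules) {
    n <- oracle_mvccm_len(n, m$V, m$strides)
    if (is.na(n)) return(NA_integer_)
    n <- oracle_conv_len(n, pool_window, pool_stride)
    if (is.na(n)) return(NA_integer_)
  }
  n * modules[[length(modules)]]$K
}

oracle_decoder_flatten <- function(n, blocks, pool_window, pool_stride) {
  for (b in blocks) {
    n <- oracle_conv_len(n, b$V, b$S)
    if (is.na(n)) return(NA_integer_)
    n <- oracle_conv_len(n, pool_window, pool_stride)
    if (is.na(n)) return(NA_integer_)
  }
  n * blocks[[length(blocks)]]$K
}

# small random-but-valid architecture generators for property tests
random_mvccm_cfg <- function() {
  V <- sort(sample(1:5, 3))
  if (anyDuplicated(V)) V <- V + 0:2
  mvccm_config(V = V, strides = sample(1:4, 3), K = sample(2:4, 1))
}

random_encoder_case <- function(max_tries = 200) {
  for (i in seq_len(max_tries)) {
    n_mod <- sample(1:2, 1)
    modules <- suppressWarnings(replicate(n_mod, random_mvccm_cfg(),
                                          simplify = FALSE))
    pw <- sample(1:3, 1)
    ps <- sample(1:3, 1)
    len <- sample(12:40, 1)
    fl <- oracle_encoder_flatten(len, modules, pw, ps)
    if (!is.na(fl)) {
      return(list(config = encoder_config(modules = modules,
                                          pool_window = pw, pool_stride = ps,
                                          projection_width = sample(3:20, 1)),
                  input_len = len, flatten = fl))
    }
  }
  stop("could not draw a valid encoder case")
}

random_decoder_case <- function(max_tries = 200) {
  for (i in seq_len(max_tries)) {
    n_blk <- sample(1:2, 1)
    blocks <- replicate(n_blk,
                        list(K = sample(2:4, 1), V = sample(2:4, 1),
                             S = sample(1:2, 1)),
                        simplify = FALSE)
    pw <- sample(1:3, 1)
    ps <- sample(1:3, 1)
    len <- sample(10:30, 1)
    fl <- oracle_decoder_flatten(len, blocks, pw, ps)
    if (!is.na(fl)) {
      return(list(config = decoder_config(blocks = blocks, pool_window = pw,
                                          pool_stride = ps,
                                          output_width = len),
                  input_len = len, flatten = fl))
    }
  }
  stop("could not draw a valid decoder case")
}
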