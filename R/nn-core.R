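# Minimal 1-D convolutional network primitives with explicit backprop.
#
# Tensors are numeric arrays [batch, length, channels]. Convolutions use
# the valid (no-padding) convention, so an input of length n with kernel
# V and stride s produces floor((n - V) / s) + 1 positions; every layer
# checks that its output keeps at least one position and reports the
# offending stage otherwise. All parameter tensors are plain R arrays so
# a parameter tree is just a nested named list, which the Adam walker
# updates in place of a compute graph.

as_tensor <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

conv_out_len <- function(n, V, stride) (n - V) %/% stride + 1L

# fan-in uniform initialisation; draws from the current RNG stream
conv_init <- function(in_ch, K, V) {
  fan_in <- V * in_ch
  lim <- sqrt(1 / fan_in)
  list(W = matrix(stats::runif(fan_in * K, -lim, lim), fan_in, K),
       b = numeric(K), V = V, in_ch = in_ch, K = K)
}

fc_init <- function(n_in, n_out) {
  lim <- sqrt(1 / n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

# gather sliding windows: [b, out_len, V * ch], offset-major rows
im2col <- function(x, V, stride, out_len) {
  d <- dim(x)
  cols <- array(0, c(d[1L], out_len, V * d[3L]))
  starts <- seq.int(1L, by = stride, length.out = out_len)
  for (v in seq_len(V)) {
    cols[, , ((v - 1L) * d[3L] + 1L):(v * d[3L])] <-
      x[, starts + (v - 1L), , drop = FALSE]
  }
  cols
}

conv1d_forward <- function(x, p, stride, stage = "conv") {
  x <- as_tensor(x)
  d <- dim(x)
  out_len <- conv_out_len(d[2L], p$V, stride)
  if (out_len < 1L) {
    stop("stage '", stage, "': input length ", d[2L],
         " collapses under kernel ", p$V, " stride ", stride, call. = FALSE)
  }
  cols <- im2col(x, p$V, stride, out_len)
  Xm <- matrix(cols, d[1L] * out_len, p$V * d[3L])
  out <- Xm %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  list(out = array(out, c(d[1L], out_len, p$K)),
       cache = list(Xm = Xm, dims = d, out_len = out_len, stride = stride))
}

conv1d_backward <- function(dout, p, cache) {
  d <- cache$dims
  out_len <- cache$out_len
  Dm <- matrix(dout, d[1L] * out_len, p$K)
  dW <- crossprod(cache$Xm, Dm)
  db <- colSums(Dm)
  dcols <- array(Dm %*% t(p$W), c(d[1L], out_len, p$V * d[3L]))
  dx <- array(0, d)
  starts <- seq.int(1L, by = cache$stride, length.out = out_len)
  for (v in seq_len(p$V)) {
    pos <- starts + (v - 1L)
    dx[, pos, ] <- dx[, pos, , drop = FALSE] +
      dcols[, , ((v - 1L) * d[3L] + 1L):(v * d[3L]), drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, cache) dout * cache

# max-pooling along the length axis; ties resolved to the earliest slot
pool_forward <- function(x, PW, PS, type = "max", stage = "pool") {
  d <- dim(x)
  out_len <- conv_out_len(d[2L], PW, PS)
  if (out_len < 1L) {
    stop("stage '", stage, "': input length ", d[2L],
         " collapses under pool window ", PW, call. = FALSE)
  }
  starts <- seq.int(1L, by = PS, length.out = out_len)
  if (type == "mean") {
    acc <- array(0, c(d[1L], out_len, d[3L]))
    for (v in seq_len(PW)) {
      acc <- acc + x[, starts + (v - 1L), , drop = FALSE]
    }
    return(list(out = acc / PW,
                cache = list(dims = d, out_len = out_len, PW = PW, PS = PS,
                             type = type, starts = starts)))
  }
  best <- x[, starts, , drop = FALSE]
  arg <- array(1L, dim(best))
  if (PW > 1L) {
    for (v in 2L:PW) {
      sl <- x[, starts + (v - 1L), , drop = FALSE]
      gt <- sl > best
      best[gt] <- sl[gt]
      arg[gt] <- v
    }
  }
  list(out = best,
       cache = list(dims = d, out_len = out_len, PW = PW, PS = PS,
                    type = type, starts = starts, arg = arg))
}

pool_backward <- function(dout, cache) {
  dx <- array(0, cache$dims)
  starts <- cache$starts
  if (cache$type == "mean") {
    share <- dout / cache$PW
    for (v in seq_len(cache$PW)) {
      pos <- starts + (v - 1L)
      dx[, pos, ] <- dx[, pos, , drop = FALSE] + share
    }
    return(dx)
  }
  for (v in seq_len(cache$PW)) {
    pos <- starts + (v - 1L)
    dx[, pos, ] <- dx[, pos, , drop = FALSE] + dout * (cache$arg == v)
  }
  dx
}

fc_forward <- function(x, p) {
  out <- x %*% p$W
  list(out = sweep(out, 2L, p$b, "+"), cache = x)
}

fc_backward <- function(dout, p, cache) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

flatten_tensor <- function(x) {
  d <- dim(x)
  list(out = matrix(x, d[1L], d[2L] * d[3L]), cache = d)
}

unflatten_tensor <- function(dout, dims) array(dout, dims)

# concatenate tensors along the length axis, remembering the cut points
cat_length <- function(xs) {
  lens <- vapply(xs, function(x) dim(x)[2L], integer(1L))
  d1 <- dim(xs[[1L]])
  out <- array(0, c(d1[1L], sum(lens), d1[3L]))
  at <- 0L
  for (x in xs) {
    n <- dim(x)[2L]
    out[, (at + 1L):(at + n), ] <- x
    at <- at + n
  }
  list(out = out, cache = lens)
}

split_length <- function(dout, lens) {
  at <- 0L
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    out[[i]] <- dout[, (at + 1L):(at + lens[i]), , drop = FALSE]
    at <- at + lens[i]
  }
  out
}

# ---- parameter-tree helpers -------------------------------------------

is_param_leaf <- function(p) is.numeric(p)

tree_map <- function(p, f) {
  if (is_param_leaf(p)) f(p) else lapply(p, tree_map, f = f)
}

tree_map2 <- function(p, q, f) {
  if (is_param_leaf(p)) {
    f(p, q)
  } else {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (nm in names(p)) out[[nm]] <- tree_map2(p[[nm]], q[[nm]], f)
    out
  }
}

zeros_like <- function(p) tree_map(p, function(x) x * 0)

# zero the trainable leaves (W, b) of a parameter tree, leaving the
# conv meta fields (kernel size, channel counts) intact
zero_weights <- function(p) {
  if (!is.list(p)) return(p)
  for (nm in names(p)) {
    if (nm %in% c("W", "b")) {
      p[[nm]] <- p[[nm]] * 0
    } else if (is.list(p[[nm]])) {
      p[[nm]] <- zero_weights(p[[nm]])
    }
  }
  p
}

# total trainable scalars in a parameter tree (W and b leaves only)
n_params <- function(p) {
  if (is_param_leaf(p)) return(length(p))
  tot <- 0L
  for (nm in names(p)) {
    if (nm %in% c("W", "b")) {
      tot <- tot + length(p[[nm]])
    } else if (is.list(p[[nm]])) {
      tot <- tot + n_params(p[[nm]])
    }
  }
  tot
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is_param_leaf(p)) return(upd(p, g, m, v))
    rp <- p; rm <- m; rv <- v
    for (nm in names(p)) {
      if (nm %in% c("W", "b") || is.list(p[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        rp[[nm]] <- r$p; rm[[nm]] <- r$m; rv[[nm]] <- r$v
      }
    }
    list(p = rp, m = rm, v = rv)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
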