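#' Simplified reconstruction decoder configuration
#'
#' The decoder receives the spliced length-`L` vector (projected
#' representation with auxiliary data inserted at the disturbance
#' position), runs it through cascaded conv(+ReLU)+pool blocks, flattens,
#' and maps linearly to `L` outputs. The output layer is linear because
#' the reconstruction targets are standardized features of either sign.
#'
#' @param blocks List of blocks, each a list with `K` (kernel count),
#'   `V` (kernel size) and `S` (stride); defaults
#'   `list(list(K=16,V=3,S=1), list(K=32,V=3,S=1))`.
#' @param pool_window,pool_stride Pooling parameters after each block
#'   (defaults 2, 2).
#' @param output_width Length of the reconstructed vector (default 22).
#' @param pool_type `"max"` (default) or `"mean"`.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(blocks = list(list(K = 16L, V = 3L, S = 1L),
                                         list(K = 32L, V = 3L, S = 1L)),
                           pool_window = 2L, pool_stride = 2L,
                           output_width = 22L,
                           pool_type = c("max", "mean")) {
  pool_type <- match.arg(pool_type)
  stopifnot(length(blocks) >= 1L, pool_window >= 1, pool_stride >= 1,
            output_width >= 1)
  for (b in blocks) stopifnot(b$K >= 1, b$V >= 1, b$S >= 1)
  structure(
    list(blocks = blocks, pool_window = as.integer(pool_window),
         pool_stride = as.integer(pool_stride),
         output_width = as.integer(output_width), pool_type = pool_type),
    class = "decoder_config"
  )
}

decoder_init <- function(config, input_len) {
  in_ch <- 1L
  conv <- list()
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    conv[[paste0("c", i)]] <- conv_init(in_ch, b$K, b$V)
    in_ch <- b$K
  }
  params <- list(conv = conv)
  # trace shapes with the real layers to size the output FC
  probe <- array(0, c(1L, input_len, 1L))
  width <- ncol(decoder_stack_fwd(probe, params, config)$out)
  params$fc <- fc_init(width, config$output_width)
  params
}

decoder_stack_fwd <- function(x, params, config) {
  caches <- list()
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    stage <- paste0("decoder", i)
    cv <- conv1d_forward(x, params$conv[[paste0("c", i)]], b$S,
                         paste0(stage, ".conv"))
    rl <- relu_forward(cv$out)
    pl <- pool_forward(rl$out, config$pool_window, config$pool_stride,
                       config$pool_type, paste0(stage, ".pool"))
    caches[[i]] <- list(cv = cv$cache, rl = rl$cache, pl = pl$cache)
    x <- pl$out
  }
  fl <- flatten_tensor(x)
  list(out = fl$out, cache = list(stages = caches, flat = fl$cache))
}

decoder_fwd <- function(x, params, config) {
  stk <- decoder_stack_fwd(as_tensor(x), params, config)
  fc <- fc_forward(stk$out, params$fc)
  list(out = fc$out, cache = list(stack = stk$cache, fc = fc$cache))
}

decoder_bwd <- function(dout, params, config, cache) {
  fb <- fc_backward(dout, params$fc, cache$fc)
  d <- unflatten_tensor(fb$dx, cache$stack$flat)
  conv_grads <- list()
  for (i in rev(seq_along(config$blocks))) {
    st <- cache$stack$stages[[i]]
    d <- pool_backward(d, st$pl)
    d <- relu_backward(d, st$rl)
    cb <- conv1d_backward(d, params$conv[[paste0("c", i)]], st$cv)
    conv_grads[[paste0("c", i)]] <- cb$grads
    d <- cb$dx
  }
  list(dx = d, grads = list(conv = conv_grads, fc = fb$grads))
}

#' Splice the projected representation with auxiliary data
#'
#' Builds the decoder input: the first `P` entries of the projected
#' representation (standing for the features before the shuffle window),
#' then the `W` auxiliary values in the window slots, then the remaining
#' entries (features after the window). Total length `L`.
#'
#' @param hidden Numeric vector of length `L - W` (the projected
#'   representation).
#' @param auxiliary Numeric vector of length `W`.
#' @param P Window position.
#' @return Numeric vector of length `L`.
#' @export
#' @examples
#' splice_decoder_input(1:18 / 10, c(100, 200, 300, 400), P = 5)
splice_decoder_input <- function(hidden, auxiliary, P) {
  splice_back(hidden, auxiliary, P)
}

# batch splice: one row per sample, positions may differ per row
splice_batch <- function(hidden, aux, P, L) {
  W <- ncol(aux)
  xde <- matrix(0, nrow(hidden), L)
  for (p in unique(P)) {
    r <- P == p
    xde[r, seq_len(p)] <- hidden[r, seq_len(p), drop = FALSE]
    xde[r, (p + 1L):(p + W)] <- aux[r, , drop = FALSE]
    if (p + W < L) {
      xde[r, (p + W + 1L):L] <- hidden[r, (p + 1L):(L - W), drop = FALSE]
    }
  }
  xde
}

# adjoint of splice_batch with respect to the hidden entries
desplice_batch <- function(dxde, P, W) {
  L <- ncol(dxde)
  dh <- matrix(0, nrow(dxde), L - W)
  for (p in unique(P)) {
    r <- P == p
    dh[r, seq_len(p)] <- dxde[r, seq_len(p), drop = FALSE]
    if (p + W < L) {
      dh[r, (p + 1L):(L - W)] <- dxde[r, (p + W + 1L):L, drop = FALSE]
    }
  }
  dh
}

#' Decode a spliced input to a reconstructed feature vector
#'
#' @param input Numeric vector of length `L` (from
#'   [splice_decoder_input()]) or a matrix `[batch, L]`.
#' @param params Decoder parameters (field `decoder_params` of a
#'   [pretrain()] result).
#' @param config A [decoder_config()].
#' @return Matrix `[batch, L]` of reconstructed vectors (a 1-row matrix
#'   for vector input).
#' @export
decode <- function(input, params, config) {
  if (is.vector(input)) input <- matrix(input, 1L)
  decoder_fwd(input, params, config)$out
}

#' Reconstruction loss
#'
#' Mean squared reconstruction error over every feature of every sample:
#' `mean((xhat - x)^2)` across the full `M x L` batch, disturbed and
#' undisturbed positions alike. This is the stage-1 pretraining
#' objective.
#'
#' @param xhat,x Numeric matrices of identical dimension `[M, L]`.
#' @return A non-negative scalar, zero iff `xhat == x`.
#' @export
reconstruction_loss <- function(xhat, x) {
  if (!identical(dim(xhat), dim(x))) {
    stop("xhat and x must have identical dimensions", call. = FALSE)
  }
  mean((xhat - x)^2)
}

#' Biomass estimation loss
#'
#' Mean squared estimation error `mean((yhat - y)^2)` over samples; the
#' stage-2 fine-tuning objective. Targets are used on their original
#' biomass scale.
#'
#' @param yhat,y Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
estimation_loss <- function(yhat, y) {
  if (length(yhat) != length(y)) {
    stop("yhat and y must have equal length", call. = FALSE)
  }
  mean((yhat - y)^2)
}
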