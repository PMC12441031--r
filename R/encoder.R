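#' Multi-view cascaded convolution module configuration
#'
#' One MVCCM runs three parallel stride branches over its input. Branch
#' `i` applies a small convolution (kernel `V[1]`, stride `strides[i]`),
#' then a medium convolution (kernel `V[2]`, same stride) on top of it,
#' concatenates the small and medium outputs along the length axis, and
#' passes the result through a large convolution (kernel `V[3]`, same
#' stride). The three branch outputs are concatenated along the length
#' axis, so the module output always has `K` channels. A ReLU follows
#' every convolution.
#'
#' @param V Integer vector of the small/medium/large kernel sizes
#'   (default `c(2, 3, 4)`).
#' @param strides Distinct positive strides of the three branches
#'   (default `c(1, 2, 3)`).
#' @param K Number of kernels per convolution (16 in the first module,
#'   32 in the second, by default).
#' @return An object of class `mvccm_config`.
#' @export
mvccm_config <- function(V = c(2L, 3L, 4L), strides = c(1L, 2L, 3L), K = 16L) {
  V <- as.integer(V); strides <- as.integer(strides); K <- as.integer(K)
  stopifnot(length(V) == 3L, length(strides) == 3L, all(V >= 1),
            all(strides >= 1), K >= 1)
  if (anyDuplicated(strides)) {
    stop("branch strides must be distinct", call. = FALSE)
  }
  if (is.unsorted(V, strictly = TRUE)) {
    warning("kernel sizes are expected to increase (small < medium < large)",
            call. = FALSE)
  }
  structure(list(V = V, strides = strides, K = K), class = "mvccm_config")
}

#' Encoder configuration
#'
#' The encoder ("MVCNN") alternates MVCCMs with pooling layers and ends
#' in a flatten step followed by a linear projection. The projection
#' width defaults to `L - W = 18`, the residual length, so the projected
#' representation can stand in for the undisturbed residual skeleton when
#' it is spliced with auxiliary data. The input side of the projection
#' adapts to whatever flatten width the architecture produces for a given
#' input length.
#'
#' For ablation studies a plain single-branch CNN encoder is available
#' (`type = "plain"`): conv(kernel 3, stride 1) + pool blocks with the
#' same kernel counts, flatten and the same projection.
#'
#' @param modules List of [mvccm_config()]s (default two, K = 16 then 32).
#' @param pool_window,pool_stride Pooling window and stride applied after
#'   each module (defaults 2 and 2).
#' @param projection_width Width of the final linear projection
#'   (default 18).
#' @param pool_type `"max"` (default) or `"mean"`.
#' @param type `"mvcnn"` (default) or `"plain"` for the single-branch
#'   ablation encoder.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(modules = list(mvccm_config(K = 16L),
                                          mvccm_config(K = 32L)),
                           pool_window = 2L, pool_stride = 2L,
                           projection_width = 18L,
                           pool_type = c("max", "mean"),
                           type = c("mvcnn", "plain")) {
  pool_type <- match.arg(pool_type)
  type <- match.arg(type)
  stopifnot(length(modules) >= 1L, pool_window >= 1, pool_stride >= 1,
            projection_width >= 1)
  for (m in modules) {
    if (!inherits(m, "mvccm_config")) {
      stop("`modules` must be a list of mvccm_config objects", call. = FALSE)
    }
  }
  structure(
    list(modules = modules, pool_window = as.integer(pool_window),
         pool_stride = as.integer(pool_stride),
         projection_width = as.integer(projection_width),
         pool_type = pool_type, type = type),
    class = "encoder_config"
  )
}

# ---- parameter initialisation -----------------------------------------

mvccm_init <- function(in_ch, cfg) {
  branch <- function() {
    list(S = conv_init(in_ch, cfg$K, cfg$V[1L]),
         M = conv_init(cfg$K, cfg$K, cfg$V[2L]),
         B = conv_init(cfg$K, cfg$K, cfg$V[3L]))
  }
  list(b1 = branch(), b2 = branch(), b3 = branch())
}

# Initialise conv stacks for an encoder; the projection is created
# separately once the flatten width for a given input length is known.
encoder_modules_init <- function(config) {
  if (config$type == "plain") {
    Ks <- vapply(config$modules, function(m) m$K, integer(1L))
    in_ch <- 1L
    out <- list()
    for (i in seq_along(Ks)) {
      out[[paste0("m", i)]] <- list(C = conv_init(in_ch, Ks[i], 3L))
      in_ch <- Ks[i]
    }
    return(out)
  }
  in_ch <- 1L
  out <- list()
  for (i in seq_along(config$modules)) {
    out[[paste0("m", i)]] <- mvccm_init(in_ch, config$modules[[i]])
    in_ch <- config$modules[[i]]$K
  }
  out
}

# ---- forward / backward -----------------------------------------------

#' One MVCCM forward pass
#'
#' Low-level forward pass through a single multi-view cascaded
#' convolution module. Mostly useful for inspecting shapes; training goes
#' through [pretrain()] / [finetune()].
#'
#' @param x Numeric matrix `[batch, length]` or array
#'   `[batch, length, channels]`.
#' @param params Module parameters from the internal initialiser (a
#'   nested list of conv weights); obtained from a fitted model or
#'   [pretrain()] output.
#' @param config An [mvccm_config()].
#' @return Array `[batch, out_length, K]`.
#' @export
mvccm_forward <- function(x, params, config) {
  mvccm_fwd(as_tensor(x), params, config, stage = "mvccm")$out
}

mvccm_fwd <- function(x, p, cfg, stage) {
  branches <- list()
  caches <- list()
  for (i in 1:3) {
    s <- cfg$strides[i]
    bp <- p[[paste0("b", i)]]
    cS <- conv1d_forward(x, bp$S, s, paste0(stage, ".b", i, ".S"))
    rS <- relu_forward(cS$out)
    cM <- conv1d_forward(rS$out, bp$M, s, paste0(stage, ".b", i, ".M"))
    rM <- relu_forward(cM$out)
    th <- cat_length(list(rS$out, rM$out))
    cB <- conv1d_forward(th$out, bp$B, s, paste0(stage, ".b", i, ".B"))
    rB <- relu_forward(cB$out)
    branches[[i]] <- rB$out
    caches[[i]] <- list(cS = cS$cache, rS = rS$cache, cM = cM$cache,
                        rM = rM$cache, th = th$cache, cB = cB$cache,
                        rB = rB$cache)
  }
  out <- cat_length(branches)
  list(out = out$out, cache = list(branches = caches, cat = out$cache))
}

mvccm_bwd <- function(dout, p, cfg, cache) {
  dbranches <- split_length(dout, cache$cat)
  dx <- NULL
  grads <- list()
  for (i in 1:3) {
    bp <- p[[paste0("b", i)]]
    bc <- cache$branches[[i]]
    d <- relu_backward(dbranches[[i]], bc$rB)
    cB <- conv1d_backward(d, bp$B, bc$cB)
    dth <- split_length(cB$dx, bc$th)
    dM <- relu_backward(dth[[2L]], bc$rM)
    cM <- conv1d_backward(dM, bp$M, bc$cM)
    dS <- relu_backward(dth[[1L]] + cM$dx, bc$rS)
    cS <- conv1d_backward(dS, bp$S, bc$cS)
    grads[[paste0("b", i)]] <- list(S = cS$grads, M = cM$grads, B = cB$grads)
    dx <- if (is.null(dx)) cS$dx else dx + cS$dx
  }
  list(dx = dx, grads = grads)
}

plain_fwd <- function(x, p, cfg, i, stage) {
  cC <- conv1d_forward(x, p$C, 1L, paste0(stage, ".conv"))
  rC <- relu_forward(cC$out)
  list(out = rC$out, cache = list(cC = cC$cache, rC = rC$cache))
}

plain_bwd <- function(dout, p, cache) {
  d <- relu_backward(dout, cache$rC)
  cC <- conv1d_backward(d, p$C, cache$cC)
  list(dx = cC$dx, grads = list(C = cC$grads))
}

# Conv/pool stack shared by the encoder paths; returns the flattened map.
encoder_stack_fwd <- function(x, modules, config) {
  caches <- list()
  for (i in seq_along(config$modules)) {
    stage <- paste0("module", i)
    if (config$type == "plain") {
      f <- plain_fwd(x, modules[[paste0("m", i)]], config$modules[[i]], i,
                     stage)
    } else {
      f <- mvccm_fwd(x, modules[[paste0("m", i)]], config$modules[[i]], stage)
    }
    pl <- pool_forward(f$out, config$pool_window, config$pool_stride,
                       config$pool_type, paste0(stage, ".pool"))
    caches[[i]] <- list(mod = f$cache, pool = pl$cache)
    x <- pl$out
  }
  fl <- flatten_tensor(x)
  list(out = fl$out, cache = list(stages = caches, flat = fl$cache))
}

encoder_stack_bwd <- function(dout, modules, config, cache) {
  d <- unflatten_tensor(dout, cache$flat)
  grads <- list()
  for (i in rev(seq_along(config$modules))) {
    d <- pool_backward(d, cache$stages[[i]]$pool)
    if (config$type == "plain") {
      b <- plain_bwd(d, modules[[paste0("m", i)]], cache$stages[[i]]$mod)
    } else {
      b <- mvccm_bwd(d, modules[[paste0("m", i)]], config$modules[[i]],
                     cache$stages[[i]]$mod)
    }
    grads[[paste0("m", i)]] <- b$grads
    d <- b$dx
  }
  list(dx = d, grads = grads)
}

# Flatten width for a given input length, computed by tracing the stack
# with a zero batch of size 1 (shapes derive from the real layer code).
encoder_flatten_width <- function(input_len, modules, config) {
  probe <- array(0, c(1L, input_len, 1L))
  ncol(encoder_stack_fwd(probe, modules, config)$out)
}

#' Encoder forward pass to the projected representation
#'
#' Runs a 1-channel signal through the alternating MVCCM/pooling stack,
#' flattens, and applies the linear projection. This is the hidden
#' representation consumed by the reconstruction decoder during
#' pretraining and by the biomass head during fine-tuning.
#'
#' @param x Numeric matrix `[batch, input_length]`.
#' @param params Encoder parameters: list with `modules` (conv stacks)
#'   and `proj` (projection weights), as produced by [pretrain()] (field
#'   `encoder_params`) or a fitted model.
#' @param config An [encoder_config()].
#' @return Numeric matrix `[batch, projection_width]`.
#' @export
mvcnn_forward <- function(x, params, config) {
  stk <- encoder_stack_fwd(as_tensor(x), params$modules, config)
  if (ncol(stk$out) != nrow(params$proj$W)) {
    stop("flatten width ", ncol(stk$out), " does not match projection input ",
         nrow(params$proj$W), "; was the encoder built for this input length?",
         call. = FALSE)
  }
  fc_forward(stk$out, params$proj)$out
}

encoder_fwd <- function(x, params, config) {
  stk <- encoder_stack_fwd(as_tensor(x), params$modules, config)
  pr <- fc_forward(stk$out, params$proj)
  list(out = pr$out, cache = list(stack = stk$cache, proj = pr$cache))
}

encoder_bwd <- function(dout, params, config, cache, through_modules = TRUE) {
  pb <- fc_backward(dout, params$proj, cache$proj)
  grads <- list(proj = pb$grads)
  if (through_modules) {
    sb <- encoder_stack_bwd(pb$dx, params$modules, config, cache$stack)
    grads$modules <- sb$grads
  }
  grads
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars (weights and biases) in a parameter
#' tree, e.g. the `encoder_params` of a pretrained model or a full fitted
#' model's stage-2 parameters.
#'
#' @param params A nested parameter list.
#' @return Integer count.
#' @export
count_parameters <- function(params) n_params(params)
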