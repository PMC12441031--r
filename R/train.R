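#' Training configuration
#'
#' Hyperparameters of the two-stage procedure: self-supervised
#' reconstruction pretraining (stage 1) followed by fine-tuning of the
#' biomass estimator head (stage 2). Both stages use Adam at the same
#' learning rate.
#'
#' @param batch_size Minibatch size (default 20).
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs_stage1,epochs_stage2 Epoch counts (default 1000 each).
#' @param seed Integer seed controlling initialisation, view draws and
#'   batch order; fixed seed + fixed config gives bit-identical runs.
#' @param freeze_encoder_in_stage2 When `TRUE` (default) the convolution
#'   kernels learned in stage 1 are frozen during fine-tuning and only
#'   the re-instantiated flatten projection and the estimator head are
#'   updated.
#' @param estimator_hidden_width Hidden width of the two-layer biomass
#'   head (default 200).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 20L, learning_rate = 1e-4,
                         epochs_stage1 = 1000L, epochs_stage2 = 1000L,
                         seed = 1L, freeze_encoder_in_stage2 = TRUE,
                         estimator_hidden_width = 200L) {
  stopifnot(batch_size >= 1, learning_rate >= 0, epochs_stage1 >= 1,
            epochs_stage2 >= 1, estimator_hidden_width >= 1)
  structure(
    list(batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         epochs_stage1 = as.integer(epochs_stage1),
         epochs_stage2 = as.integer(epochs_stage2),
         seed = as.integer(seed),
         freeze_encoder_in_stage2 = isTRUE(freeze_encoder_in_stage2),
         estimator_hidden_width = as.integer(estimator_hidden_width)),
    class = "train_config"
  )
}

# standardize if the table carries no stats; otherwise trust it
ensure_standardized <- function(data, stats = NULL, schema) {
  if (!is.null(attr(data, "feature_stats"))) return(data)
  standardize_features(data, stats = stats, schema = schema)
}

#' Self-supervised reconstruction pretraining (stage 1)
#'
#' Every epoch draws fresh disturbance views (window position,
#' permutation, Gaussian mask) for each sample, encodes the residual
#' data, splices the projected representation with the auxiliary data at
#' the disturbance position, decodes to a full-length reconstruction, and
#' updates all encoder and decoder parameters against the mean squared
#' reconstruction error with Adam.
#'
#' @param data A standardized feature table (raw tables are standardized
#'   on entry). The target column is not used in this stage.
#' @param disturbance A [disturbance_config()].
#' @param encoder An [encoder_config()]; its `projection_width` must
#'   equal `L - W` so the projected representation can be spliced.
#' @param decoder A [decoder_config()] with `output_width = L`.
#' @param train A [train_config()].
#' @param schema A [feature_schema()].
#' @return An object of class `ssdfrn_pretrain`: `encoder_params`
#'   (`modules`, `proj`), `decoder_params`, a `history` tibble with
#'   per-epoch mean reconstruction loss, the configs, the feature stats,
#'   and the encoder flatten width.
#' @export
pretrain <- function(data,
                     disturbance = disturbance_config(),
                     encoder = encoder_config(),
                     decoder = NULL,
                     train = train_config(),
                     schema = mangrove_schema()) {
  data <- ensure_standardized(data, schema = schema)
  stats <- attr(data, "feature_stats")
  x <- feature_matrix(data, schema)
  L <- schema$L
  W <- disturbance$W
  if (L - W - 1L < 1L) {
    stop("window length W = ", W, " too large for L = ", L, call. = FALSE)
  }
  if (encoder$projection_width != L - W) {
    stop("encoder projection_width (", encoder$projection_width,
         ") must equal L - W = ", L - W, " for splicing", call. = FALSE)
  }
  if (is.null(decoder)) decoder <- decoder_config(output_width = L)
  if (decoder$output_width != L) {
    stop("decoder output_width must equal L = ", L, call. = FALSE)
  }
  n_views <- nrow(x) * disturbance$views_per_sample

  with_seed(train$seed, {
    modules <- encoder_modules_init(encoder)
    fw <- encoder_flatten_width(L - W, modules, encoder)
    params <- list(
      enc = list(modules = modules, proj = fc_init(fw, L - W)),
      dec = decoder_init(decoder, L)
    )
    opt <- adam_init(params)
    losses <- numeric(train$epochs_stage1)

    for (epoch in seq_len(train$epochs_stage1)) {
      v <- views_matrix(x, disturbance, L)
      ord <- sample.int(n_views)
      sse <- 0
      for (batch in batch_indices(n_views, train$batch_size, ord)) {
        nb <- length(batch)
        enc <- encoder_fwd(v$res[batch, , drop = FALSE], params$enc, encoder)
        xde <- splice_batch(enc$out, v$aux[batch, , drop = FALSE],
                            v$P[batch], L)
        dec <- decoder_fwd(xde, params$dec, decoder)
        err <- dec$out - v$target[batch, , drop = FALSE]
        sse <- sse + sum(err^2)
        dxhat <- 2 * err / (nb * L)
        db <- decoder_bwd(dxhat, params$dec, decoder, dec$cache)
        dh <- desplice_batch(matrix(db$dx, nb, L), v$P[batch], W)
        eg <- encoder_bwd(dh, params$enc, encoder, enc$cache,
                          through_modules = TRUE)
        grads <- list(enc = list(modules = eg$modules, proj = eg$proj),
                      dec = db$grads)
        step <- adam_step(params, grads, opt, train$learning_rate)
        params <- step$params
        opt <- step$state
      }
      losses[epoch] <- sse / (n_views * L)
      if (!is.finite(losses[epoch])) {
        stop("non-finite reconstruction loss at epoch ", epoch,
             " (learning rate too high or degenerate input)", call. = FALSE)
      }
    }

    structure(
      list(encoder_params = params$enc,
           decoder_params = params$dec,
           history = tibble::tibble(stage = 1L,
                                    epoch = seq_len(train$epochs_stage1),
                                    loss = losses),
           disturbance = disturbance, encoder = encoder, decoder = decoder,
           train = train, schema = schema, stats = stats,
           flatten_width = fw),
      class = "ssdfrn_pretrain"
    )
  })
}

#' Fine-tune the biomass estimator (stage 2)
#'
#' Attaches a two-layer fully connected head (hidden width
#' `estimator_hidden_width`, ReLU; linear scalar output) to the encoder's
#' projected representation of the full, undisturbed standardized feature
#' vector, and minimises the mean squared biomass error. Because the
#' convolutions are length-agnostic, the stage-1 kernels are reused as-is
#' on the length-`L` input; only the flatten projection is re-instantiated
#' for the new flatten width and is always trained in this stage. With
#' `freeze_encoder_in_stage2 = TRUE` (default) the convolution kernels
#' stay fixed; otherwise they are updated too. The output bias of the
#' head is initialised to the mean training target so the head starts at
#' the target scale.
#'
#' @param data A feature table with a `biomass` column. Standardized on
#'   entry with the pretrained stats when available.
#' @param pretrained A [pretrain()] result, or `NULL` to fine-tune from a
#'   randomly initialised encoder (the no-pretraining ablation).
#' @param encoder An [encoder_config()]; ignored (taken from
#'   `pretrained`) when a pretrained encoder is supplied.
#' @param train A [train_config()].
#' @param schema A [feature_schema()].
#' @return An object of class `ssdfrn`; see [ssdfrn_fit()].
#' @export
finetune <- function(data, pretrained = NULL,
                     encoder = encoder_config(),
                     train = train_config(),
                     schema = mangrove_schema()) {
  if (!"biomass" %in% names(data)) {
    stop("fine-tuning requires a `biomass` column", call. = FALSE)
  }
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "ssdfrn_pretrain"))
    encoder <- pretrained$encoder
    schema <- pretrained$schema
    data <- ensure_standardized(data, stats = pretrained$stats,
                                schema = schema)
  } else {
    data <- ensure_standardized(data, schema = schema)
  }
  stats <- attr(data, "feature_stats")
  x <- feature_matrix(data, schema)
  y <- data$biomass
  L <- schema$L
  M <- nrow(x)
  freeze <- train$freeze_encoder_in_stage2

  with_seed(child_seed(train$seed, 2L), {
    modules <- if (is.null(pretrained)) {
      encoder_modules_init(encoder)
    } else {
      pretrained$encoder_params$modules
    }
    fw <- encoder_flatten_width(L, modules, encoder)
    proj <- fc_init(fw, encoder$projection_width)
    est <- list(
      fc1 = fc_init(encoder$projection_width, train$estimator_hidden_width),
      fc2 = fc_init(train$estimator_hidden_width, 1L)
    )
    est$fc2$b <- mean(y)

    params <- if (freeze) {
      list(proj = proj, est = est)
    } else {
      list(modules = modules, proj = proj, est = est)
    }
    opt <- adam_init(params)
    losses <- numeric(train$epochs_stage2)

    for (epoch in seq_len(train$epochs_stage2)) {
      ord <- sample.int(M)
      sse <- 0
      for (batch in batch_indices(M, train$batch_size, ord)) {
        nb <- length(batch)
        enc_par <- list(modules = if (freeze) modules else params$modules,
                        proj = params$proj)
        enc <- encoder_fwd(x[batch, , drop = FALSE], enc_par, encoder)
        f1 <- fc_forward(enc$out, params$est$fc1)
        r1 <- relu_forward(f1$out)
        f2 <- fc_forward(r1$out, params$est$fc2)
        err <- drop(f2$out) - y[batch]
        sse <- sse + sum(err^2)
        dy <- matrix(2 * err / nb, nb, 1L)
        b2 <- fc_backward(dy, params$est$fc2, f2$cache)
        b1 <- fc_backward(relu_backward(b2$dx, r1$cache),
                          params$est$fc1, f1$cache)
        eg <- encoder_bwd(b1$dx, enc_par, encoder, enc$cache,
                          through_modules = !freeze)
        grads <- list(proj = eg$proj,
                      est = list(fc1 = b1$grads, fc2 = b2$grads))
        if (!freeze) grads$modules <- eg$modules
        step <- adam_step(params, grads, opt, train$learning_rate)
        params <- step$params
        opt <- step$state
      }
      losses[epoch] <- sse / M
      if (!is.finite(losses[epoch])) {
        stop("non-finite estimation loss at epoch ", epoch, call. = FALSE)
      }
    }

    structure(
      list(schema = schema, stats = stats,
           encoder = encoder, train = train,
           pretrained = !is.null(pretrained),
           stage1 = pretrained,
           encoder_params = list(
             modules = if (freeze) modules else params$modules,
             proj = params$proj
           ),
           estimator = params$est,
           history = tibble::tibble(stage = 2L,
                                    epoch = seq_len(train$epochs_stage2),
                                    loss = losses),
           flatten_width = fw),
      class = "ssdfrn"
    )
  })
}

#' Fit a self-supervised disturbing-feature reconstruction model
#'
#' End-to-end convenience wrapper: standardizes the training table (the
#' stats are stored in the model and reused at prediction time), runs the
#' self-supervised pretraining stage unless `pretrain = FALSE`, and
#' fine-tunes the biomass estimator.
#'
#' @param data A raw feature table with a `biomass` column.
#' @param pretrain Run stage-1 pretraining (default `TRUE`); `FALSE`
#'   gives the no-pretraining ablation.
#' @param disturbance A [disturbance_config()].
#' @param encoder An [encoder_config()].
#' @param decoder A [decoder_config()] or `NULL` for the default.
#' @param train A [train_config()].
#' @param schema A [feature_schema()].
#' @return An object of class `ssdfrn` supporting [predict()],
#'   [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' \donttest{
#' tbl <- simulate_feature_table(n = 58, seed = 1)
#' fit <- ssdfrn_fit(tbl, train = train_config(epochs_stage1 = 20,
#'                                             epochs_stage2 = 20))
#' predict(fit, tbl[1:3, ])
#' }
ssdfrn_fit <- function(data, pretrain = TRUE,
                       disturbance = disturbance_config(),
                       encoder = encoder_config(),
                       decoder = NULL,
                       train = train_config(),
                       schema = mangrove_schema()) {
  std <- ensure_standardized(data, schema = schema)
  pre <- if (pretrain) {
    pretrain(std, disturbance = disturbance, encoder = encoder,
             decoder = decoder, train = train, schema = schema)
  } else {
    NULL
  }
  finetune(std, pretrained = pre, encoder = encoder, train = train,
           schema = schema)
}

#' Predict biomass for new samples
#'
#' Standardizes the new rows with the stats stored in the model, encodes
#' the full feature vector and applies the two-layer estimator head.
#' Tables that already carry the model's standardization stats (attribute
#' `"feature_stats"`) are used as-is.
#'
#' @param object A fitted `ssdfrn` model.
#' @param newdata A feature table on the raw feature scale.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `.pred`, one row per input row
#'   in input order.
#' @export
predict.ssdfrn <- function(object, newdata, ...) {
  schema <- object$schema
  validate_feature_table(newdata, schema)
  std <- if (is.null(attr(newdata, "feature_stats"))) {
    standardize_features(newdata, stats = object$stats, schema = schema)
  } else {
    newdata
  }
  x <- feature_matrix(std, schema)
  h <- mvcnn_forward(x, object$encoder_params, object$encoder)
  r1 <- relu_forward(fc_forward(h, object$estimator$fc1)$out)$out
  pred <- drop(fc_forward(r1, object$estimator$fc2)$out)
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(newdata)) {
      newdata$sample_id
    } else {
      paste0("s", seq_len(nrow(newdata)))
    },
    .pred = as.numeric(pred)
  )
}

#' @export
print.ssdfrn <- function(x, ...) {
  cat("<ssdfrn> biomass estimation model\n")
  cat("  encoder:", x$encoder$type, "|", length(x$encoder$modules),
      "module(s) | projection width", x$encoder$projection_width, "\n")
  cat("  pretrained:", x$pretrained, "| frozen encoder:",
      x$train$freeze_encoder_in_stage2, "\n")
  cat("  stage-2 epochs:", nrow(x$history),
      "| final loss:", signif(x$history$loss[nrow(x$history)], 4), "\n")
  invisible(x)
}

#' @export
print.ssdfrn_pretrain <- function(x, ...) {
  cat("<ssdfrn_pretrain> self-supervised reconstruction stage\n")
  cat("  epochs:", nrow(x$history),
      "| final loss:", signif(x$history$loss[nrow(x$history)], 4),
      "| flatten width:", x$flatten_width, "\n")
  invisible(x)
}

batch_indices <- function(n, batch_size, ord = seq_len(n)) {
  split(ord, ceiling(seq_along(ord) / batch_size))
}
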