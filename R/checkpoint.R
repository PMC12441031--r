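# JSON checkpoints: plain-text, self-describing, and guarded by a schema
# fingerprint so a saved model refuses to load against a different
# feature inventory.

schema_fingerprint <- function(schema) {
  paste(schema$L, paste(schema$feature_names, collapse = "|"), sep = ":")
}

leaf_to_json <- function(x) {
  list(dim = dim(x), data = as.numeric(x))
}

json_to_leaf <- function(x) {
  if (is.null(x$dim) || length(x$dim) == 0L) {
    as.numeric(x$data)
  } else {
    array(as.numeric(x$data), unlist(x$dim))
  }
}

params_to_json <- function(p) {
  if (is_param_leaf(p)) leaf_to_json(p) else lapply(p, params_to_json)
}

json_to_params <- function(p) {
  if (is.list(p) && identical(sort(names(p)), sort(c("data", "dim"))) ||
      (is.list(p) && identical(names(p), "data"))) {
    json_to_leaf(p)
  } else {
    lapply(p, json_to_params)
  }
}

#' Save a fitted model to a JSON checkpoint
#'
#' Serialises the full model bundle — configs, feature schema
#' fingerprint, standardization stats, encoder/decoder/estimator
#' parameters and loss histories — as plain JSON.
#'
#' @param model A fitted `ssdfrn` model or a [pretrain()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ssdfrn <- function(model, path) {
  kind <- if (inherits(model, "ssdfrn")) {
    "finetuned"
  } else if (inherits(model, "ssdfrn_pretrain")) {
    "pretrained-only"
  } else {
    stop("not an ssdfrn model", call. = FALSE)
  }
  blob <- list(
    kind = kind,
    schema = list(feature_names = model$schema$feature_names),
    fingerprint = schema_fingerprint(model$schema),
    stats = as.list(model$stats),
    encoder = unclass(model$encoder),
    train = unclass(model$train),
    history = as.list(model$history)
  )
  blob$encoder$modules <- lapply(model$encoder$modules, unclass)
  if (kind == "finetuned") {
    blob$encoder_params <- params_to_json(model$encoder_params)
    blob$estimator <- params_to_json(model$estimator)
    blob$pretrained <- model$pretrained
    blob$flatten_width <- model$flatten_width
  } else {
    blob$encoder_params <- params_to_json(model$encoder_params)
    blob$decoder_params <- params_to_json(model$decoder_params)
    blob$decoder <- unclass(model$decoder)
    blob$disturbance <- unclass(model$disturbance)
    blob$flatten_width <- model$flatten_width
  }
  jsonlite::write_json(blob, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path to a file written by [save_ssdfrn()].
#' @param schema The [feature_schema()] the model will be used with; the
#'   load is refused if it does not match the checkpoint's fingerprint.
#' @return A `ssdfrn` or `ssdfrn_pretrain` object.
#' @export
load_ssdfrn <- function(path, schema = mangrove_schema()) {
  blob <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (!identical(blob$fingerprint, schema_fingerprint(schema))) {
    stop("checkpoint was trained under a different feature schema; ",
         "refusing to load", call. = FALSE)
  }
  enc <- blob$encoder
  enc$modules <- lapply(enc$modules, function(m) {
    mvccm_config(V = unlist(m$V), strides = unlist(m$strides), K = m$K)
  })
  encoder <- encoder_config(modules = enc$modules,
                            pool_window = enc$pool_window,
                            pool_stride = enc$pool_stride,
                            projection_width = enc$projection_width,
                            pool_type = enc$pool_type, type = enc$type)
  train <- do.call(train_config, blob$train)
  stats <- tibble::as_tibble(lapply(blob$stats, unlist))
  history <- tibble::as_tibble(lapply(blob$history, unlist))
  if (blob$kind == "finetuned") {
    structure(
      list(schema = schema, stats = stats, encoder = encoder, train = train,
           pretrained = isTRUE(blob$pretrained), stage1 = NULL,
           encoder_params = json_to_params(blob$encoder_params),
           estimator = json_to_params(blob$estimator),
           history = history, flatten_width = blob$flatten_width),
      class = "ssdfrn"
    )
  } else {
    dec <- blob$decoder
    decoder <- decoder_config(blocks = dec$blocks,
                              pool_window = dec$pool_window,
                              pool_stride = dec$pool_stride,
                              output_width = dec$output_width,
                              pool_type = dec$pool_type)
    structure(
      list(encoder_params = json_to_params(blob$encoder_params),
           decoder_params = json_to_params(blob$decoder_params),
           history = history,
           disturbance = do.call(disturbance_config, blob$disturbance),
           encoder = encoder, decoder = decoder, train = train,
           schema = schema, stats = stats,
           flatten_width = blob$flatten_width),
      class = "ssdfrn_pretrain"
    )
  }
}
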