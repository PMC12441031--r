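#' Disturbance configuration for self-supervised views
#'
#' Controls how self-supervised training views are generated: a shuffle
#' window of `W` consecutive features (in schema order) is selected at a
#' random position, its entries are permuted uniformly at random and
#' Gaussian noise is added to form the *auxiliary* data, while the
#' remaining `L - W` features are concatenated in order to form the
#' *residual* data fed to the encoder.
#'
#' @param W Shuffle-window length in features (default 4).
#' @param noise_sigma Standard deviation of the Gaussian mask added to
#'   the permuted window values (default 1; features are assumed
#'   standardized, so this is one feature standard deviation).
#' @param views_per_sample Number of views generated per original sample
#'   per call (default 1). Views are not limited by the sample count:
#'   every view draws a fresh position, permutation and noise.
#' @return An object of class `disturbance_config`.
#' @export
disturbance_config <- function(W = 4L, noise_sigma = 1, views_per_sample = 1L) {
  W <- as.integer(W)
  stopifnot(W >= 1, noise_sigma >= 0, views_per_sample >= 1)
  structure(
    list(W = W, noise_sigma = noise_sigma,
         views_per_sample = as.integer(views_per_sample)),
    class = "disturbance_config"
  )
}

# 1-based feature indices covered by the window at position P.
window_indices <- function(P, W) (P + 1L):(P + W)

#' Draw a shuffle-window position
#'
#' The window position `P` is drawn uniformly from `{1, ..., L - W - 1}`.
#' Under this range the window (which covers features `P + 1` through
#' `P + W` in 1-based schema order) never contains the first feature and
#' never contains the last one, so the residual always retains both ends
#' of the feature vector.
#'
#' @param L Total feature count.
#' @param W Window length; requires `L - W - 1 >= 1`.
#' @return An integer position.
#' @export
sample_window_position <- function(L, W) {
  hi <- L - W - 1L
  if (hi < 1L) {
    stop("window length W = ", W, " too large for L = ", L,
         " features (need W <= L - 2)", call. = FALSE)
  }
  sample.int(hi, 1L)
}

#' Build auxiliary data for one sample
#'
#' Permutes the `W` window entries uniformly at random and adds i.i.d.
#' Gaussian noise: `auxiliary = noise + permuted window`.
#'
#' @param x Numeric feature vector of length `L` (standardized).
#' @param P Window position from [sample_window_position()].
#' @param config A [disturbance_config()].
#' @return A list with `auxiliary` (length `W`) and `permutation` (the
#'   drawn ordering of the window entries).
#' @export
make_auxiliary <- function(x, P, config = disturbance_config()) {
  W <- config$W
  check_position(P, length(x), W)
  idx <- window_indices(P, W)
  perm <- sample.int(W)
  noise <- if (config$noise_sigma > 0) {
    stats::rnorm(W, 0, config$noise_sigma)
  } else {
    numeric(W)
  }
  list(auxiliary = noise + x[idx][perm], permutation = perm)
}

#' Residual data for one sample
#'
#' Concatenates the `L - W` features outside the shuffle window,
#' preserving schema order: features before the window followed by
#' features after it.
#'
#' @inheritParams make_auxiliary
#' @param W Window length.
#' @return Numeric vector of length `L - W`.
#' @export
make_residual <- function(x, P, W) {
  check_position(P, length(x), W)
  x[-window_indices(P, W)]
}

#' Reinsert window values into a residual vector
#'
#' Inverse of the residual/window partition: splices `window_values` back
#' into `residual` at position `P`, recovering a full-length vector. With
#' zero noise and the identity permutation this reconstructs the original
#' sample exactly.
#'
#' @param residual Length `L - W` vector from [make_residual()].
#' @param window_values Length `W` vector occupying the window slots.
#' @param P Window position.
#' @return Numeric vector of length `L`.
#' @export
splice_back <- function(residual, window_values, P) {
  W <- length(window_values)
  L <- length(residual) + W
  check_position(P, L, W)
  c(residual[seq_len(P)], window_values,
    residual[seq(P + 1L, length.out = L - W - P)])
}

check_position <- function(P, L, W) {
  if (length(P) != 1L || P != as.integer(P) || P < 1L || P > L - W - 1L) {
    stop("window position P = ", P, " outside {1, ..., ", L - W - 1L,
         "} for L = ", L, ", W = ", W, call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate self-supervised training views for a table
#'
#' For each sample (and each of `views_per_sample` repetitions) draws an
#' independent window position, permutation and noise vector, and records
#' the auxiliary data, residual data and the original vector as the
#' reconstruction target. Fresh draws are made on every call, so repeated
#' calls across epochs enlarge the effective training set beyond the
#' original sample count.
#'
#' @param data A standardized feature table (see
#'   [standardize_features()]).
#' @param config A [disturbance_config()].
#' @param seed Optional integer seed for reproducible draws; when `NULL`
#'   the current RNG state is used.
#' @param schema A [feature_schema()].
#' @return A tibble with one row per view: `sample_id`, `view`, `P`, and
#'   list-columns `permutation`, `auxiliary`, `residual`, `target`.
#' @export
#' @examples
#' std <- standardize_features(simulate_feature_table(40, seed = 1))
#' views <- generate_views(std, seed = 7)
#' nrow(views)
generate_views <- function(data, config = disturbance_config(), seed = NULL,
                           schema = mangrove_schema()) {
  x <- feature_matrix(data, schema)
  if (nrow(x) < 1L) stop("empty feature table", call. = FALSE)
  draw <- function() views_matrix(x, config, schema$L)
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tibble::tibble(
    sample_id = rep(rownames(x) %||% paste0("s", seq_len(nrow(x))),
                    config$views_per_sample),
    view = rep(seq_len(config$views_per_sample), each = nrow(x)),
    P = v$P,
    permutation = lapply(seq_len(nrow(v$aux)), function(i) v$perm[i, ]),
    auxiliary = lapply(seq_len(nrow(v$aux)), function(i) unname(v$aux[i, ])),
    residual = lapply(seq_len(nrow(v$res)), function(i) unname(v$res[i, ])),
    target = lapply(seq_len(nrow(v$target)),
                    function(i) unname(v$target[i, ]))
  )
}

# Matrix-form view generation used by the training loop: one fresh
# (P, permutation, noise) triple per row of `x` per repetition.
views_matrix <- function(x, config, L) {
  W <- config$W
  if (L - W - 1L < 1L) {
    stop("window length W = ", W, " too large for L = ", L, call. = FALSE)
  }
  reps <- config$views_per_sample
  xs <- x[rep(seq_len(nrow(x)), times = reps), , drop = FALSE]
  n <- nrow(xs)
  P <- sample.int(L - W - 1L, n, replace = TRUE)
  perm <- t(vapply(seq_len(n), function(i) sample.int(W), integer(W)))
  aux <- matrix(0, n, W)
  res <- matrix(0, n, L - W)
  for (i in seq_len(n)) {
    idx <- window_indices(P[i], W)
    aux[i, ] <- xs[i, idx][perm[i, ]]
    res[i, ] <- xs[i, -idx]
  }
  if (config$noise_sigma > 0) {
    aux <- aux + matrix(stats::rnorm(n * W, 0, config$noise_sigma), n, W)
  }
  list(P = P, perm = perm, aux = aux, res = res, target = xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
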