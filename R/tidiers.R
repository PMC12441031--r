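#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's loss history
#'
#' @param x A fitted `ssdfrn` model.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `epoch`, `loss`, covering the
#'   pretraining stage (when run) followed by fine-tuning.
#' @method tidy ssdfrn
#' @export
tidy.ssdfrn <- function(x, ...) {
  out <- x$history
  if (!is.null(x$stage1)) out <- dplyr::bind_rows(x$stage1$history, out)
  out
}

#' One-row summary of a fitted model
#'
#' @param x A fitted `ssdfrn` model.
#' @param ... Unused.
#' @return A tibble with encoder type, pretraining flag, epoch counts,
#'   initial/final losses per stage, and the trainable parameter count.
#' @method glance ssdfrn
#' @export
glance.ssdfrn <- function(x, ...) {
  h2 <- x$history$loss
  h1 <- if (is.null(x$stage1)) NULL else x$stage1$history$loss
  tibble::tibble(
    encoder = x$encoder$type,
    pretrained = x$pretrained,
    epochs_stage1 = length(h1) %||% 0L,
    loss_stage1_first = if (is.null(h1)) NA_real_ else h1[1L],
    loss_stage1_final = if (is.null(h1)) NA_real_ else h1[length(h1)],
    epochs_stage2 = length(h2),
    loss_stage2_first = h2[1L],
    loss_stage2_final = h2[length(h2)],
    n_parameters = count_parameters(x$encoder_params) +
      count_parameters(x$estimator)
  )
}

#' @rdname tidy.ssdfrn
#' @method tidy ssdfrn_pretrain
#' @export
tidy.ssdfrn_pretrain <- function(x, ...) x$history

#' Tidy an evaluation report
#'
#' @param x An [evaluation_report()].
#' @param ... Unused.
#' @return A tibble with one row per scored sample: `sample`, `actual`,
#'   `estimated`, `ae`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(sample = seq_len(x$n) - 1L, actual = x$actual,
                 estimated = x$estimated, ae = x$per_sample_ae)
}

#' Summarise an evaluation report
#'
#' @param x An [evaluation_report()].
#' @param ... Unused.
#' @return A one-row tibble with `split_id`, `n`, `mae`, `rmse`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(split_id = x$split_id, n = x$n, mae = x$mae, rmse = x$rmse)
}
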