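#' Plot training loss histories
#'
#' Per-epoch mean loss of the reconstruction pretraining stage and the
#' fine-tuning stage, on a log scale.
#'
#' @param object A fitted `ssdfrn` model (or a [pretrain()] result).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssdfrn
#' @export
autoplot.ssdfrn <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = c(1L, 2L),
                    labels = c("stage 1: reconstruction",
                               "stage 2: biomass"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean squared loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ssdfrn
#' @method autoplot ssdfrn_pretrain
#' @export
autoplot.ssdfrn_pretrain <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "reconstruction loss",
                  title = "Self-supervised pretraining loss") +
    ggplot2::theme_minimal()
}

#' Plot estimated against actual biomass
#'
#' @param object An [evaluation_report()].
#' @param ... Unused.
#' @return A ggplot object with the identity line for reference.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$actual, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "forestgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "actual biomass", y = "estimated biomass",
                  title = paste0(object$split_id, ": MAE ",
                                 signif(object$mae, 4), ", RMSE ",
                                 signif(object$rmse, 4))) +
    ggplot2::theme_minimal()
}

#' Plot a disturbed-versus-reconstructed feature profile
#'
#' Visual check of the self-supervised task for a single sample: the
#' original standardized features, the disturbed version (auxiliary
#' values in the shuffle window, original values elsewhere) and the
#' decoder reconstruction.
#'
#' @param original,disturbed,reconstructed Numeric length-`L` vectors.
#' @param feature_names Optional feature labels.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(original, disturbed, reconstructed,
                                feature_names = NULL) {
  L <- length(original)
  stopifnot(length(disturbed) == L, length(reconstructed) == L)
  d <- tibble::tibble(
    feature = factor(rep(feature_names %||% seq_len(L), 3L),
                     levels = feature_names %||% seq_len(L)),
    series = rep(c("original", "disturbed", "reconstructed"), each = L),
    value = c(original, disturbed, reconstructed)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$value,
                                  colour = .data$series,
                                  group = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "feature", y = "standardized value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
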