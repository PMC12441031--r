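#' Per-sample absolute errors
#'
#' @param actual,estimated Numeric vectors of equal length.
#' @return `abs(estimated - actual)`, elementwise.
#' @export
absolute_errors <- function(actual, estimated) {
  if (length(actual) != length(estimated)) {
    stop("actual and estimated must have equal length", call. = FALSE)
  }
  abs(estimated - actual)
}

#' Mean absolute error
#'
#' @inheritParams absolute_errors
#' @return A non-negative scalar.
#' @export
mae <- function(actual, estimated) {
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  mean(absolute_errors(actual, estimated))
}

#' Root mean square error
#'
#' @inheritParams absolute_errors
#' @return A non-negative scalar; always at least the MAE.
#' @export
rmse <- function(actual, estimated) {
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  if (length(actual) != length(estimated)) {
    stop("actual and estimated must have equal length", call. = FALSE)
  }
  sqrt(mean((estimated - actual)^2))
}

#' Build an evaluation report
#'
#' Bundles per-sample absolute errors with their MAE and RMSE summary
#' for one model/split pairing.
#'
#' @inheritParams absolute_errors
#' @param split_id Identifier for the split being scored.
#' @return An object of class `eval_report` with fields `actual`,
#'   `estimated`, `per_sample_ae`, `mae`, `rmse`, `n`, `split_id`.
#'   Supports [generics::tidy()] (per-sample rows) and
#'   [generics::glance()] (one summary row).
#' @export
#' @examples
#' rep <- evaluation_report(c(10, 20), c(11, 19), split_id = "demo")
#' rep$mae
evaluation_report <- function(actual, estimated, split_id = "test") {
  ae <- absolute_errors(actual, estimated)
  structure(
    list(actual = actual, estimated = estimated, per_sample_ae = ae,
         mae = mae(actual, estimated), rmse = rmse(actual, estimated),
         n = length(ae), split_id = split_id),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$split_id, "| n =", x$n,
      "| MAE =", signif(x$mae, 4), "| RMSE =", signif(x$rmse, 4), "\n")
  invisible(x)
}

#' Score a fitted model on a table
#'
#' Predicts biomass for every row of `data` with [predict.ssdfrn()] and
#' summarises the errors.
#'
#' @param data A feature table with a `biomass` column.
#' @param model A fitted `ssdfrn` model.
#' @param split_id Label recorded in the report.
#' @return An [evaluation_report()].
#' @export
evaluate_model <- function(data, model, split_id = "test") {
  if (!"biomass" %in% names(data)) {
    stop("evaluation requires a `biomass` column", call. = FALSE)
  }
  pred <- predict(model, data)
  evaluation_report(data$biomass, pred$.pred, split_id = split_id)
}

#' Build a data-split plan
#'
#' Holdout mode reserves `floor(train_frac * n)` samples for training
#' (for 58 samples at the default 0.7 that is 40 training and 18 test
#' plots) after a seeded shuffle. K-fold mode shuffles once and cuts the
#' shuffled order into `folds` contiguous blocks used as test folds in
#' turn; fold sizes are balanced so for 58 samples the five test folds
#' hold 12, 12, 12, 11 and 11 plots.
#'
#' @param n Sample count.
#' @param mode `"holdout"` or `"kfold"`.
#' @param seed Integer seed for the shuffle.
#' @param train_frac Training share for holdout mode (default 0.7).
#' @param folds Number of folds for k-fold mode (default 5).
#' @return An object of class `split_plan`: `mode`, `seed` and `folds`,
#'   a list whose elements each hold sorted `train` and `test` index
#'   vectors. Test folds partition `1:n` in k-fold mode.
#' @export
#' @examples
#' plan <- make_split(58, "holdout", seed = 1)
#' lengths(plan$folds[[1]])
make_split <- function(n, mode = c("holdout", "kfold"), seed = 1L,
                       train_frac = 0.7, folds = 5L) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  if (mode == "kfold" && n < folds) {
    stop("need at least `folds` samples for k-fold splitting", call. = FALSE)
  }
  out <- with_seed(seed, {
    ord <- sample.int(n)
    if (mode == "holdout") {
      ntr <- floor(train_frac * n)
      if (ntr < 1L || ntr >= n) {
        stop("train_frac leaves an empty split", call. = FALSE)
      }
      list(list(train = sort(ord[seq_len(ntr)]),
                test = sort(ord[(ntr + 1L):n])))
    } else {
      sizes <- rep(n %/% folds, folds)
      extra <- n %% folds
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      ends <- cumsum(sizes)
      starts <- c(1L, ends[-folds] + 1L)
      lapply(seq_len(folds), function(k) {
        te <- ord[starts[k]:ends[k]]
        list(train = sort(setdiff(ord, te)), test = sort(te))
      })
    }
  })
  structure(list(mode = mode, seed = as.integer(seed), folds = out),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", x$mode, "| seed", x$seed, "|",
      length(x$folds), "fold(s):",
      paste(vapply(x$folds, function(f) length(f$test), integer(1L)),
            collapse = "/"),
      "test sample(s)\n")
  invisible(x)
}

#' Ablation study over model variants
#'
#' Runs up to three variants on identical seeded 70/30 splits of the same
#' table and scores each on the held-out plots:
#'
#' * `"full"` — self-supervised pretraining + multi-view cascaded
#'   encoder;
#' * `"no_mvccm"` — pretraining kept, but the multi-view encoder is
#'   replaced by a plain single-branch CNN (conv kernel 3, stride 1,
#'   matched kernel counts);
#' * `"no_pretrain"` — multi-view encoder fine-tuned from random
#'   initialisation, no pretraining stage.
#'
#' @param data A feature table with `biomass`.
#' @param tasks Character subset of the three variants above.
#' @param seeds Integer vector; each seed drives one split + training
#'   run per task.
#' @param disturbance,train Configs shared across tasks.
#' @param schema A [feature_schema()].
#' @return A tibble with columns `task`, `seed`, `mae`, `rmse`, one row
#'   per task/seed, plus a `"summary"` attribute with per-task median
#'   MAE/RMSE.
#' @export
run_ablation <- function(data,
                         tasks = c("full", "no_mvccm", "no_pretrain"),
                         seeds = 1:10,
                         disturbance = disturbance_config(),
                         train = train_config(),
                         schema = mangrove_schema()) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (!"biomass" %in% names(data)) {
    stop("ablation requires a `biomass` column", call. = FALSE)
  }
  enc_mv <- encoder_config(projection_width = schema$L - disturbance$W)
  enc_pl <- encoder_config(projection_width = schema$L - disturbance$W,
                           type = "plain")
  rows <- list()
  for (s in seeds) {
    plan <- make_split(nrow(data), "holdout", seed = s)
    tr <- data[plan$folds[[1]]$train, ]
    te <- data[plan$folds[[1]]$test, ]
    std_tr <- standardize_features(tr, schema = schema)
    tcfg <- train
    tcfg$seed <- as.integer(s)
    for (task in tasks) {
      fit <- switch(
        task,
        full = {
          pre <- pretrain(std_tr, disturbance = disturbance,
                          encoder = enc_mv, train = tcfg, schema = schema)
          finetune(std_tr, pretrained = pre, train = tcfg, schema = schema)
        },
        no_mvccm = {
          pre <- pretrain(std_tr, disturbance = disturbance,
                          encoder = enc_pl, train = tcfg, schema = schema)
          finetune(std_tr, pretrained = pre, train = tcfg, schema = schema)
        },
        no_pretrain = finetune(std_tr, pretrained = NULL, encoder = enc_mv,
                               train = tcfg, schema = schema)
      )
      rep <- evaluate_model(te, fit, split_id = paste0("seed", s))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(task = task, seed = s, mae = rep$mae, rmse = rep$rmse)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(median_mae = stats::median(.data$mae),
                     median_rmse = stats::median(.data$rmse),
                     .groups = "drop")
  out
}

#' Reference test-set biomass pairs
#'
#' The 18 published actual/estimated aboveground-biomass pairs for the
#' held-out Kandelia plots of the Ximen Island study, shipped as a
#' plain-text fixture. Used to regression-test the error metrics against
#' their published summary values (MAE 1.145, RMSE 1.396).
#'
#' @return A tibble with columns `sample`, `actual`, `estimated`.
#' @export
#' @examples
#' pairs <- reference_test_pairs()
#' rmse(pairs$actual, pairs$estimated)
reference_test_pairs <- function() {
  path <- system.file("extdata", "kandelia_test_estimates.csv",
                      package = "ssdfrn", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
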