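#' Grid-search experiment over feature extractors and KNN parameters
#'
#' End-to-end driver: per-class stratified split, optional SNV
#' preprocessing, discriminant fitting on the training rows only, KNN
#' classification of the held-out rows, over a grid of neighbourhood
#' sizes k (all methods) and fuzzifiers m (fmlda only). One split is
#' shared by all grid cells of a given train fraction, so methods are
#' compared on identical partitions. Everything is deterministic given
#' `seed`.
#'
#' @param data a [spectra_set()], or a [synthetic_config()] from which
#'   one is generated (seeded by `seed`).
#' @param methods subset of `c("dlda", "mlda", "fmlda")`.
#' @param k_values KNN neighbourhood sizes (default odd 1..9).
#' @param m_values fuzzifier grid for fmlda (default 1.1 to 5.0 by 0.1;
#'   the membership exponent 2/(m-1) is undefined at m = 1, so the grid
#'   starts above it).
#' @param train_fractions one or more train fractions in (0, 1].
#' @param seed integer seed driving the split (and data generation when
#'   `data` is a config).
#' @param preprocess `"snv"` (default) or `"none"`.
#' @param ncomp discriminant vectors per fit; default c - 1.
#' @param fcm an [fcm_control()] for the fmlda fits (its fuzzifier is
#'   set per grid cell).
#' @param output_dir if non-NULL, report CSVs are written there:
#'   `results_long.csv` (every grid cell), `summary_best.csv` (best
#'   cell per method and fraction), `summary_by_ratio.csv` (best
#'   accuracy per method for each train/test ratio), and
#'   `resolved_config.yaml` (the full parameter set actually run, when
#'   the yaml package is available; otherwise `resolved_config.txt`).
#' @return A list of class `grid_experiment`: `results` (long data
#'   frame: train_fraction, train_n, test_n, method, model, k, m,
#'   correct, total, accuracy, accuracy_pct), `best`, `by_ratio`,
#'   `splits`, and `config`.
#' @export
run_experiment <- function(data,
                           methods = c("dlda", "mlda", "fmlda"),
                           k_values = c(1L, 3L, 5L, 7L, 9L),
                           m_values = seq(1.1, 5, by = 0.1),
                           train_fractions = 0.7,
                           seed = 1L,
                           preprocess = c("snv", "none"),
                           ncomp = NULL,
                           fcm = fcm_control(),
                           output_dir = NULL) {
  preprocess <- match.arg(preprocess)
  methods <- match.arg(methods, c("dlda", "mlda", "fmlda"), several.ok = TRUE)
  if (length(k_values) == 0L || any(k_values < 1))
    stop("k_values must be a non-empty set of positive integers")
  if ("fmlda" %in% methods && (length(m_values) == 0L || any(m_values <= 1)))
    stop("m_values must be non-empty with every m > 1")
  if (length(train_fractions) == 0L ||
      any(train_fractions <= 0 | train_fractions > 1))
    stop("train_fractions must lie in (0, 1]")
  if (inherits(data, "synthetic_config")) data <- synthetic_spectra(data, seed)
  stopifnot(inherits(data, "spectra_set"))

  X <- if (preprocess == "snv") snv(data$absorbance) else data$absorbance
  labels <- data$labels
  tag <- function(method) paste0(if (preprocess == "snv") "SNV-" else "",
                                 toupper(method), "-KNN")
  rows <- list(); splits <- list()
  for (fr in train_fractions) {
    sp <- stratified_split(labels, fr, seed)
    splits[[as.character(fr)]] <- sp
    Xtr <- X[sp$train_indices, , drop = FALSE]
    Xte <- X[sp$test_indices, , drop = FALSE]
    ytr <- droplevels(labels[sp$train_indices])
    yte <- labels[sp$test_indices]
    eval_fit <- function(fit, m_val) {
      scores_te <- predict(fit, Xte)
      do.call(rbind, lapply(k_values, function(k) {
        pred <- knn_predict(fit$scores, fit$labels,
                            scores_te, k = k, allow_even = TRUE)
        rep_ <- evaluate_classification(pred, yte)
        data.frame(train_fraction = fr,
                   train_n = length(sp$train_indices),
                   test_n = length(sp$test_indices),
                   method = fit$method, model = tag(fit$method),
                   k = as.integer(k), m = m_val,
                   correct = rep_$correct_count, total = rep_$total,
                   accuracy = rep_$accuracy,
                   accuracy_pct = rep_$accuracy_pct,
                   stringsAsFactors = FALSE)
      }))
    }
    for (method in methods) {
      if (method == "fmlda") {
        for (m in m_values) {
          fc <- fcm; fc$fuzzifier <- m
          fit <- fmlda(Xtr, ytr, method = "fmlda", ncomp = ncomp, fcm = fc)
          rows[[length(rows) + 1L]] <- eval_fit(fit, m)
        }
      } else {
        fit <- fmlda(Xtr, ytr, method = method, ncomp = ncomp)
        rows[[length(rows) + 1L]] <- eval_fit(fit, NA_real_)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  pick_best <- function(df) df[which.max(df$accuracy), , drop = FALSE]
  key <- interaction(results$train_fraction, results$method, drop = TRUE)
  best <- do.call(rbind, lapply(split(results, key), pick_best))
  best <- best[order(best$train_fraction, match(best$method, methods)), ]
  rownames(best) <- NULL
  by_ratio <- best[, c("train_fraction", "train_n", "test_n", "model",
                       "k", "m", "accuracy_pct")]

  out <- structure(list(results = results, best = best, by_ratio = by_ratio,
                        splits = splits,
                        config = list(methods = methods, k_values = k_values,
                                      m_values = m_values,
                                      train_fractions = train_fractions,
                                      preprocess = preprocess, ncomp = ncomp,
                                      seed = as.integer(seed))),
                   class = "grid_experiment")
  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

#' Write grid-experiment report files
#'
#' @param x a `grid_experiment` from [run_experiment()].
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_experiment <- function(x, output_dir) {
  stopifnot(inherits(x, "grid_experiment"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$results, file.path(output_dir, "results_long.csv"),
                   row.names = FALSE)
  utils::write.csv(x$best[, c("model", "k", "m", "correct", "accuracy_pct")],
                   file.path(output_dir, "summary_best.csv"), row.names = FALSE)
  ratio <- x$by_ratio
  ratio$train_test <- paste0(ratio$train_n, "/", ratio$test_n)
  utils::write.csv(ratio[, c("train_test", "model", "accuracy_pct")],
                   file.path(output_dir, "summary_by_ratio.csv"),
                   row.names = FALSE)
  cfg <- x$config
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(cfg, file.path(output_dir, "resolved_config.yaml"))
  } else {
    writeLines(utils::capture.output(utils::str(cfg)),
               file.path(output_dir, "resolved_config.txt"))
  }
  invisible(output_dir)
}

#' @export
print.grid_experiment <- function(x, ...) {
  cat("Grid experiment: ", nrow(x$results), " cells (",
      paste(unique(x$results$model), collapse = ", "), ")\n", sep = "")
  cat("Best per method and train fraction:\n")
  print(x$best[, c("train_fraction", "model", "k", "m", "correct", "total",
                   "accuracy_pct")], row.names = FALSE)
  invisible(x)
}
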