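#' Classification accuracy
#' @param predictions,labels Equal-length vectors of class labels.
#' @return Proportion of exact matches.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (!length(labels)) stop("need at least one prediction")
  mean(as.character(predictions) == as.character(labels))
}

#' Cohen's kappa from accuracy
#'
#' Chance-corrected agreement `kappa = (p0 - pe) / (1 - pe)`.  For a
#' balanced two-class task the chance level `pe` is 0.5, which makes
#' kappa the linear map `2 * p0 - 1` of the accuracy.
#'
#' @param p0 Observed accuracy (proportion in `[0, 1]`).
#' @param pe Chance accuracy (proportion in `[0, 1)`).
#' @return Dimensionless kappa in `[-pe/(1-pe), 1]`.
#' @examples
#' kappa_score(0.907)   # 0.814
#' @export
kappa_score <- function(p0, pe = 0.5) {
  if (any(p0 < 0 | p0 > 1)) stop("p0 must be in [0, 1]")
  if (any(pe >= 1) || any(pe < 0)) stop("pe must be in [0, 1)")
  (p0 - pe) / (1 - pe)
}

# deterministic stratified fold assignment: within each class, a
# seeded permutation is dealt round-robin into `folds` groups
stratified_folds <- function(labels, folds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Repeated stratified k-fold cross-validation
#'
#' The evaluation protocol: `reps` independent repetitions of
#' stratified `folds`-fold cross-validation.  Repetition `r` reshuffles
#' the fold assignment with seed `seed + r - 1`; within a repetition
#' every trial is tested exactly once.  The summary accuracy is the
#' mean over all `reps * folds` fold accuracies; its dispersion is the
#' standard deviation across the `reps` repetition means.  Kappa
#' follows by the linear map of [kappa_score()] with `pe = 0.5`.
#'
#' `fit_predict` receives `(train_x, train_y, test_x, fold_seed)` and
#' returns predicted labels for `test_x`; all model fitting and any
#' cross-trial statistics must happen inside it, so nothing leaks from
#' test folds.
#'
#' @param x Images (`H x W x N` array) or any object subsettable by
#'   `x[, , idx]`.
#' @param y Labels of length `N`.
#' @param fit_predict Function `(train_x, train_y, test_x, fold_seed)
#'   -> predicted labels`.
#' @param folds,reps Protocol size (10 x 10 by default).
#' @param seed Base seed.
#' @param variant Label stored on the report.
#' @return An object of class `"mi_eval"`: per-fold accuracy matrix
#'   (`reps` x `folds`), summary statistics, and the protocol
#'   parameters.
#' @export
cross_validate <- function(x, y, fit_predict, folds = 10, reps = 10,
                           seed = 1, variant = "IS-CBAM-CNN") {
  y <- as.character(y)
  n <- length(y)
  if (dim(x)[3] != n) stop("x and y sizes disagree")
  if (min(table(y)) < folds)
    stop("need at least `folds` trials of each class")
  acc <- matrix(NA_real_, reps, folds)
  for (r in seq_len(reps)) {
    assignment <- stratified_folds(y, folds, seed + r - 1)
    for (k in seq_len(folds)) {
      test <- assignment == k
      fold_seed <- (seed + r - 1) * 100 + k
      pred <- fit_predict(x[, , !test, drop = FALSE], y[!test],
                          x[, , test, drop = FALSE], fold_seed)
      acc[r, k] <- accuracy(pred, y[test])
    }
  }
  rep_means <- rowMeans(acc)
  structure(list(per_fold_accuracy = acc,
                 mean_accuracy = mean(acc),
                 accuracy_std = stats::sd(rep_means),
                 mean_kappa = kappa_score(mean(acc)),
                 kappa_std = 2 * stats::sd(rep_means),
                 variant = variant, folds = folds, reps = reps,
                 seed = seed, n = n),
            class = "mi_eval")
}

#' @export
print.mi_eval <- function(x, ...) {
  cat(sprintf("<mi_eval> %s: %dx%d-fold CV on %d trials\n",
              x$variant, x$reps, x$folds, x$n))
  cat(sprintf("  accuracy %.1f%% +/- %.1f%%   kappa %.3f +/- %.3f\n",
              100 * x$mean_accuracy, 100 * x$accuracy_std,
              x$mean_kappa, x$kappa_std))
  invisible(x)
}

#' Fold-fitting function for the CNN pipeline
#'
#' Builds the `fit_predict` closure [cross_validate()] expects: inside
#' each fold it trains a fresh [cbam_cnn()] (seeded with the fold
#' seed, so repetitions are reproducible and variants are paired) and
#' predicts the test images.
#'
#' @param config A [model_config()]; its `seed` is replaced per fold.
#' @return A function `(train_x, train_y, test_x, fold_seed)`.
#' @export
cnn_fit_predict <- function(config) {
  function(train_x, train_y, test_x, fold_seed) {
    cfg <- config
    cfg$seed <- as.integer(fold_seed)
    fit <- cbam_cnn(train_x, train_y, cfg)
    predict(fit, test_x)
  }
}

#' Ablation harness: UD-CNN, IS-CNN, IS-CBAM-CNN
#'
#' Evaluates up to three pipeline variants on one dataset under
#' *identical* fold assignments and per-fold model seeds, so the
#' comparison is paired:
#' \describe{
#'   \item{UD-CNN}{vertically stacked C3/C4 images, plain CNN
#'     (no attention).}
#'   \item{IS-CNN}{subtracted images, plain CNN.}
#'   \item{IS-CBAM-CNN}{subtracted images, CNN with CBAM after each
#'     convolution block.}
#' }
#'
#' @param trials A list of labeled [mi_trial()] objects.
#' @param variants Subset of `c("UD-CNN", "IS-CNN", "IS-CBAM-CNN")`.
#' @param model A [model_config()]; its `cbam` field is overridden per
#'   variant (`"none"` for UD/IS, `"both"` for IS-CBAM).
#' @param cwt A [cwt_config()] for the time-frequency step.
#' @param folds,reps,seed Protocol controls, as in [cross_validate()].
#' @return Named list of [cross_validate()] reports.
#' @export
run_ablation <- function(trials,
                         variants = c("UD-CNN", "IS-CNN", "IS-CBAM-CNN"),
                         model = model_config(), cwt = cwt_config(),
                         folds = 10, reps = 10, seed = 1) {
  known <- c("UD-CNN", "IS-CNN", "IS-CBAM-CNN")
  if (!all(variants %in% known))
    stop("unknown variant(s): ",
         paste(setdiff(variants, known), collapse = ", "))
  y <- trial_labels(trials)
  imgs <- list()
  if (any(variants != "UD-CNN"))
    imgs$subtract <- trials_to_images(trials, "subtract", cwt)
  if ("UD-CNN" %in% variants)
    imgs$stack <- trials_to_images(trials, "stack", cwt)
  out <- list()
  for (v in variants) {
    cfg <- model
    cfg$cbam <- if (v == "IS-CBAM-CNN") "both" else "none"
    cfg$cbam_blocks <- if (v == "IS-CBAM-CNN") c(TRUE, TRUE)
                       else c(FALSE, FALSE)
    x <- if (v == "UD-CNN") imgs$stack else imgs$subtract
    out[[v]] <- cross_validate(x, y, cnn_fit_predict(cfg),
                               folds = folds, reps = reps, seed = seed,
                               variant = v)
  }
  out
}

#' Aggregate per-subject results into a benchmark summary
#'
#' Given per-subject mean accuracies (and optionally their standard
#' deviations) for one or more methods, computes the row of summary
#' statistics benchmark tables print: per-method average of subject
#' means, average of subject standard deviations, the max - min spread
#' across subjects, and pairwise differences of method averages.
#'
#' @param means Numeric matrix or data frame, subjects x methods, of
#'   mean accuracies (any consistent unit; typically percent).
#' @param stds Optional matrix like `means` with per-subject standard
#'   deviations.
#' @return A list with `average` (named per-method means), `mean_std`,
#'   `spread` (max - min per method), and `diff` (matrix of pairwise
#'   differences of averages, row minus column).
#' @export
aggregate_subjects <- function(means, stds = NULL) {
  means <- as.matrix(means)
  avg <- colMeans(means)
  spread <- apply(means, 2, function(v) max(v) - min(v))
  d <- outer(avg, avg, "-")
  dimnames(d) <- list(names(avg), names(avg))
  out <- list(average = avg, spread = spread, diff = d)
  if (!is.null(stds)) out$mean_std <- colMeans(as.matrix(stds))
  out
}

#' Format a benchmark table of mean +/- std entries
#'
#' Renders per-subject accuracies (percent, one decimal) or kappas
#' (three decimals) in the conventional `mean +/- std` layout, with an
#' Average row.
#'
#' @param means,stds Subjects x methods matrices; `stds` may be `NULL`
#'   or contain `NA` columns for methods reported without dispersion.
#' @param digits Decimals per entry (1 for percent accuracy, 3 for
#'   kappa).
#' @return A character data frame, one row per subject plus "Average".
#' @export
format_benchmark_table <- function(means, stds = NULL, digits = 1) {
  means <- as.matrix(means)
  fmt <- function(m, s) {
    if (is.null(s) || all(is.na(s))) sprintf("%.*f", digits, m)
    else sprintf("%.*f ± %.*f", digits, m, digits, s)
  }
  body <- sapply(colnames(means), function(j) {
    s <- if (is.null(stds)) NULL else as.matrix(stds)[, j]
    fmt(means[, j], s)
  })
  agg <- aggregate_subjects(means, stds)
  avg_row <- sapply(colnames(means), function(j) {
    s <- if (is.null(stds) || all(is.na(as.matrix(stds)[, j]))) NULL
         else agg$mean_std[j]
    fmt(agg$average[j], s)
  })
  out <- rbind(body, Average = avg_row)
  data.frame(Subject = c(rownames(means) %||% seq_len(nrow(means)),
                         "Average"),
             out, check.names = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published benchmark accuracies and kappas
#'
#' Loads the bundled tables of published per-subject results on BCI
#' Competition IV dataset 2b (accuracy and kappa for CapsNet, BP-SVM,
#' Twin-SVM, FBCSP, CNN-SAE, and IS-CBAM-CNN) and the single-subject
#' BCI Competition II dataset III comparison.  These are reference
#' values for the table aggregator and for checking kappa arithmetic;
#' the package never recomputes them from raw competition data.
#'
#' @param table One of `"iv2b_accuracy"`, `"iv2b_kappa"`,
#'   `"ii3"`.
#' @return A data frame.
#' @export
published_benchmarks <- function(table = c("iv2b_accuracy", "iv2b_kappa",
                                           "ii3")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("bench_", table, ".csv"),
                      package = "mibci")
  utils::read.csv(path, check.names = FALSE)
}

#' Write an evaluation report to JSON/CSV
#' @param report A [cross_validate()] report (class `mi_eval`).
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
  if (!is.null(csv_path)) {
    df <- as.data.frame(report$per_fold_accuracy)
    names(df) <- paste0("fold", seq_len(report$folds))
    df <- cbind(rep = seq_len(report$reps), df)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}
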