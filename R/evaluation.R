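# Confusion-table metrics, stratified cross-validation, parameter sweeps,
# and the end-to-end pipeline.

#' Confusion counts for binary labels
#'
#' @param y_true,y_pred label vectors of equal length drawn from at most two
#'   distinct labels.
#' @param positive_label the label treated as positive.
#' @return A list of class `confusion_counts` with integer `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred, positive_label) {
  if (length(y_true) != length(y_pred)) stop("y_true/y_pred length mismatch")
  labs <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(labs) > 2L) stop("more than 2 distinct labels: ",
                              paste(labs, collapse = ", "))
  tp_ <- as.character(y_true) == positive_label
  pp_ <- as.character(y_pred) == positive_label
  structure(list(tp = sum(tp_ & pp_), tn = sum(!tp_ & !pp_),
                 fp = sum(!tp_ & pp_), fn = sum(tp_ & !pp_)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' SN = TP/(FN+TP); SP = TN/(FP+TN); ACC = (TN+TP)/total;
#' MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TP+FN)(TN+FP)(TP+FP)).
#' Any metric whose denominator is zero is defined as 0.
#'
#' @param counts a `confusion_counts` object (or list with `tp`,`tn`,`fp`,`fn`).
#' @return A list of class `metrics_report` with `sn`, `sp`, `acc`, `mcc`, and
#'   `counts`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(as.numeric(tn + fn) * (tp + fn) * (tn + fp) * (tp + fp))
  structure(list(
    sn = safe_div(tp, fn + tp),
    sp = safe_div(tn, fp + tn),
    acc = (tn + tp) / total,
    mcc = safe_div(tp * as.numeric(tn) - fp * as.numeric(fn), mcc_den),
    counts = counts
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SN = %.4f  SP = %.4f  ACC = %.4f  MCC = %.4f\n",
              x$sn, x$sp, x$acc, x$mcc))
  cat(sprintf("(TP = %d, TN = %d, FP = %d, FN = %d)\n",
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  invisible(x)
}

# Stratified fold ids: within each class, shuffled round-robin assignment.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) {
      stop("class '", cl, "' has ", length(idx),
           " samples; too few for ", n_folds, "-fold stratification")
    }
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Stratified cross-validation of the GHKNN classifier
#'
#' Splits the data into `n_folds` stratified folds (seeded shuffle), predicts
#' each held-out fold with [ghknn_predict()], and pools the confusion counts
#' over folds into a single report (micro averaging). When `resample` is
#' enabled, SMOTE is by default applied to the training portion of each fold
#' only, after the split, so synthetic points never enter a test fold;
#' `resample_all = TRUE` instead balances the whole dataset before splitting
#' (the leakage-prone protocol some studies use — supported for comparison,
#' not endorsed).
#'
#' @param X numeric feature matrix.
#' @param y binary label vector.
#' @param params a [ghknn_params()] object.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for fold assignment and resampling.
#' @param resample `NULL`/`FALSE` for none, `TRUE` for SMOTE with defaults, or
#'   a list with any of `k_neighbors` and `target`.
#' @param resample_all balance the full dataset before splitting instead of
#'   per-training-fold (default `FALSE`).
#' @param positive_label label treated as positive; default the first of the
#'   declared label order (factor levels, else sorted unique labels).
#' @return A `metrics_report` with attributes `predictions` (data.frame of
#'   per-sample fold, truth, prediction) and `seed`.
#' @export
cross_validate <- function(X, y, params = ghknn_params(), n_folds = 5L,
                           seed = NULL, resample = NULL, resample_all = FALSE,
                           positive_label = NULL) {
  X <- as.matrix(X)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (nrow(X) != length(y)) stop("X/y length mismatch")
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(classes) != 2L) stop("cross_validate requires exactly 2 classes")
  if (is.null(positive_label)) positive_label <- classes[1L]
  rs <- if (isTRUE(resample)) list() else if (is.list(resample)) resample else NULL
  rs_k <- if (!is.null(rs) && !is.null(rs$k_neighbors)) rs$k_neighbors else 5L
  rs_target <- if (!is.null(rs) && !is.null(rs$target)) rs$target else "match"

  run <- function() {
    synthetic <- rep(FALSE, length(y))
    if (!is.null(rs) && resample_all) {
      bal <- balance_dataset(X, y, target = rs_target, k_neighbors = rs_k)
      X <- bal$X; y <- bal$y; synthetic <- bal$synthetic
    }
    folds <- stratified_folds(y, n_folds)
    truth <- character(0); pred <- character(0); fold_id <- integer(0)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
      if (!is.null(rs) && !resample_all) {
        bal <- balance_dataset(Xtr, ytr, target = rs_target, k_neighbors = rs_k)
        Xtr <- bal$X; ytr <- bal$y
      }
      p <- ghknn_predict(X[test, , drop = FALSE], Xtr,
                         factor(ytr, levels = classes), params)
      truth <- c(truth, y[test])
      pred <- c(pred, p$labels)
      fold_id <- c(fold_id, rep(f, sum(test)))
    }
    rep_ <- classification_metrics(confusion(truth, pred, positive_label))
    attr(rep_, "predictions") <- data.frame(fold = fold_id, truth = truth,
                                            pred = pred,
                                            stringsAsFactors = FALSE)
    attr(rep_, "synthetic_in_pool") <- any(synthetic)
    rep_
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "seed") <- seed
  out
}

#' One-parameter-at-a-time cross-validated sweep
#'
#' Re-runs [cross_validate()] for each value of a grid over one of `lam`,
#' `gamma`, `mu`, holding the other parameters at their configured values.
#'
#' @param X,y data as in [cross_validate()].
#' @param params baseline [ghknn_params()].
#' @param which one of `"lam"`, `"gamma"`, `"mu"`.
#' @param grid numeric vector of parameter values (positive for `lam`/`gamma`,
#'   non-negative for `mu`).
#' @param n_folds,seed,resample,positive_label passed to [cross_validate()].
#' @return A data.frame with columns `value`, `sn`, `sp`, `acc`, `mcc`.
#' @export
sweep_parameter <- function(X, y, params = ghknn_params(),
                            which = c("lam", "gamma", "mu"), grid,
                            n_folds = 5L, seed = NULL, resample = NULL,
                            positive_label = NULL) {
  which <- match.arg(which)
  if (length(grid) == 0L) stop("grid must be non-empty")
  low <- if (which == "mu") 0 else .Machine$double.xmin
  if (any(!is.finite(grid)) || any(grid < low)) {
    stop("invalid grid values for '", which, "'",
         if (which != "mu") " (must be > 0)" else " (must be >= 0)")
  }
  rows <- lapply(grid, function(v) {
    p <- params
    p[[which]] <- v
    m <- cross_validate(X, y, p, n_folds = n_folds, seed = seed,
                        resample = resample, positive_label = positive_label)
    data.frame(value = v, sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc)
  })
  do.call(rbind, rows)
}

#' Run the full extract / balance / evaluate pipeline
#'
#' Executes the end-to-end protocol on a validated [parse_config()] object:
#' feature extraction from FASTA (or a pre-computed feature table), optional
#' SMOTE balancing, cross-validated GHKNN evaluation, and optional parameter
#' sweeps. Writes the feature table, a metrics JSON, sweep CSVs, and a log
#' recording all parameters, seeds and input digests to `config$out_dir`.
#'
#' @param config a `pipeline_config` from [parse_config()].
#' @return Invisibly, a named list of output file paths plus the
#'   `metrics_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(parse_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  inputs <- character(0)

  if (!is.null(config$features)) {
    tab <- read_feature_table(config$features, sep = config$delim)
    ids <- tab$ids; X <- tab$X; y <- tab$labels
    inputs <- config$features
  } else if (!is.null(config$fasta)) {
    records <- read_fasta(config$fasta)
    lab <- utils::read.table(config$labels, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% names(lab))) {
      stop("labels file must have 'id' and 'label' columns")
    }
    m <- match(records$id, lab$id)
    if (anyNA(m)) stop("labels missing for: ",
                       paste(utils::head(records$id[is.na(m)]), collapse = ", "))
    X <- extract_features(records, descriptor = config$descriptor)
    ids <- records$id
    y <- lab$label[m]
    inputs <- c(config$fasta, config$labels)
  } else {
    stop("config must name either 'features' or 'fasta' + 'labels' inputs")
  }
  if (isTRUE(config$scale)) X <- minmax_scale(X)

  params <- ghknn_params(lam = config$lam, gamma = config$gamma,
                         mu = config$mu, k = config$k, kernel = config$kernel)

  paths$features <- file.path(config$out_dir, "features.tsv")
  write_feature_table(ids, X, y, paths$features, sep = config$delim)

  if (isTRUE(config$balance)) {
    bal <- balance_dataset(X, y, target = config$target,
                           k_neighbors = config$smote_k, seed = config$seed)
    paths$features_balanced <- file.path(config$out_dir, "features_balanced.tsv")
    write_feature_table(
      sprintf("row%06d", seq_along(bal$y)), bal$X, bal$y,
      paths$features_balanced, sep = config$delim)
  }

  resample <- if (config$resample != "none") {
    list(k_neighbors = config$smote_k, target = config$target)
  } else NULL
  report <- cross_validate(X, y, params, n_folds = config$n_folds,
                           seed = config$seed, resample = resample,
                           resample_all = identical(config$resample, "all"),
                           positive_label = config$positive_label)

  paths$metrics <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(
    list(sn = report$sn, sp = report$sp, acc = report$acc, mcc = report$mcc,
         tp = report$counts$tp, tn = report$counts$tn,
         fp = report$counts$fp, fn = report$counts$fn,
         params = unclass(params), n_folds = config$n_folds,
         resample = config$resample, seed = config$seed),
    paths$metrics, auto_unbox = TRUE, digits = NA)

  if (!is.null(config$sweep)) {
    for (w in names(config$sweep)) {
      tabw <- sweep_parameter(X, y, params, which = w,
                              grid = config$sweep[[w]],
                              n_folds = config$n_folds, seed = config$seed,
                              resample = resample,
                              positive_label = config$positive_label)
      p <- file.path(config$out_dir, paste0("sweep_", w, ".csv"))
      utils::write.csv(tabw, p, row.names = FALSE, quote = FALSE)
      paths[[paste0("sweep_", w)]] <- p
    }
  }

  paths$log <- file.path(config$out_dir, "run.log")
  digests <- if (length(inputs)) tools::md5sum(inputs) else character(0)
  writeLines(c(
    paste0("snareid run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("params: lam=", params$lam, " gamma=", params$gamma,
           " mu=", params$mu, " k=", params$k, " kernel=", params$kernel),
    paste0("n_folds: ", config$n_folds, " resample: ", config$resample,
           " balance: ", isTRUE(config$balance), " scale: ",
           isTRUE(config$scale)),
    paste0("input ", names(digests), " md5=", digests)
  ), paths$log)

  paths$report <- report
  invisible(paths)
}

#' Min-max scale feature columns to [0, 1]
#'
#' Optional preprocessing (off by default everywhere: the tuned default
#' bandwidth presumes raw descriptor magnitudes). Constant columns map to 0.
#'
#' @param X numeric matrix.
#' @return Scaled matrix of the same shape.
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2L, rng[1L, ]), 2L, span, "/")
}
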