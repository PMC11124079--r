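# Toxicity QSAR protocols: leave-one-out linear regression (LDH release),
# stratified k-fold logistic classification with minority oversampling, and
# feature assembly that concatenates fingerprint sections onto a
# physicochemical feature table (the Test1 / Test2 / Test3 designs:
# base features only / fingerprint sections only / both).

#' Construct a QSAR dataset
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param target numeric response (real for regression, 0/1 for
#'   classification).
#' @param feature_names optional column names (defaults to colnames).
#' @param group_ids optional per-row nanocompound identifiers.
#' @return object of class `qsar_dataset`.
#' @export
qsar_dataset <- function(features, target, feature_names = NULL, group_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(features)))
  if (ncol(features) > 0) colnames(features) <- feature_names
  if (nrow(features) != length(target)) {
    stop("features and target disagree on sample count", call. = FALSE)
  }
  if (anyNA(features) || anyNA(target)) stop("missing values are not allowed", call. = FALSE)
  structure(
    list(features = features, feature_names = feature_names,
         target = as.numeric(target), group_ids = group_ids),
    class = "qsar_dataset"
  )
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset: %d samples x %d features>\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Read a QSAR dataset from CSV
#'
#' @param path CSV with one column per feature plus the response column.
#' @param target_col name of the response column.
#' @return a [qsar_dataset()].
#' @export
read_qsar_csv <- function(path, target_col) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!target_col %in% names(df)) {
    stop("no column '", target_col, "' in ", path, call. = FALSE)
  }
  y <- df[[target_col]]
  x <- df[setdiff(names(df), target_col)]
  qsar_dataset(as.matrix(x), y, feature_names = names(x))
}

#' Append fingerprint sections to a feature table
#'
#' Implements the concatenation designs: with `sections = integer(0)` the
#' dataset is returned unchanged (base features only); with only fingerprint
#' sections requested on an empty base, the result is fingerprint-only; the
#' full concatenation appends the chosen sections' slots as extra columns in
#' section order. All fingerprints must share `max_bonds`.
#'
#' @param base a [qsar_dataset()] (possibly with zero feature columns).
#' @param fingerprints list of `nano_fingerprint`, one per row of `base`.
#' @param sections subset of `1:4` selecting fingerprint sections.
#' @return a [qsar_dataset()] with appended columns named by slot label.
#' @export
assemble_features <- function(base, fingerprints, sections = c(1L, 2L)) {
  stopifnot(inherits(base, "qsar_dataset"))
  sections <- sort(unique(as.integer(sections)))
  if (length(sections) == 0) return(base)
  if (!all(sections %in% 1:4)) stop("sections must be a subset of 1:4", call. = FALSE)
  if (length(fingerprints) != nrow(base$features)) {
    stop("need one fingerprint per dataset row", call. = FALSE)
  }
  maxes <- vapply(fingerprints, function(f) f$max_bonds, integer(1))
  if (length(unique(maxes)) != 1) stop("fingerprints have mixed max_bonds", call. = FALSE)
  m <- maxes[1]
  w <- m + 1L
  ranges <- list(
    `1` = 1:6,
    `2` = 6L + seq_len(2L * m),
    `3` = 6L + 2L * m + seq_len(2L * w^2),
    `4` = 6L + 2L * m + 2L * w^2 + seq_len(3L * w^4)
  )
  cols <- unlist(ranges[as.character(sections)], use.names = FALSE)
  block <- t(vapply(fingerprints, function(f) f$vector[cols], numeric(length(cols))))
  colnames(block) <- paste0("fp_", gsub("[(),-]", "_", label_of(cols, m)))
  qsar_dataset(cbind(base$features, block), base$target,
               group_ids = base$group_ids)
}

# Drop zero-variance columns (constant fingerprint slots make lm/glm designs
# rank-deficient). Returns the kept column indices; reports via message.
drop_zero_variance <- function(x, quiet = TRUE) {
  keep <- which(apply(x, 2, function(col) stats::var(col) > 0))
  if (!quiet && length(keep) < ncol(x)) {
    message(sprintf("dropped %d zero-variance feature(s)", ncol(x) - length(keep)))
  }
  keep
}

#' Leave-one-out evaluation of a linear QSAR
#'
#' For each sample, an ordinary-least-squares model is fitted on the
#' remaining n-1 samples and used to predict the held-out response. Reported
#' are the mean of the squared prediction errors (`mse`) and their standard
#' deviation (`std`).
#'
#' @param data a [qsar_dataset()] with a real-valued target.
#' @param drop_constant drop zero-variance columns before fitting.
#' @return object of class `eval_report` with `mse`, `std`, `predictions`.
#' @export
evaluate_loo_linear <- function(data, drop_constant = TRUE) {
  stopifnot(inherits(data, "qsar_dataset"))
  x <- data$features
  y <- data$target
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for leave-one-out", call. = FALSE)
  if (drop_constant) x <- x[, drop_zero_variance(x), drop = FALSE]
  if (n <= ncol(x) + 1) {
    stop("more coefficients than leave-one-out training samples", call. = FALSE)
  }
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    bad <- colnames(x)[qrx$pivot[seq(qrx$rank + 1, ncol(x) + 1)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    df_tr <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    preds[i] <- stats::predict(fit, newdata = data.frame(x[i, , drop = FALSE]))
  }
  sq <- (preds - y)^2
  structure(list(kind = "regression", mse = mean(sq), std = stats::sd(sq),
                 predictions = preds),
            class = "eval_report")
}

#' Stratified k-fold evaluation of a logistic QSAR
#'
#' Stratified k-fold cross-validation of an (unpenalised) maximum-likelihood
#' logistic regression. With `oversample = TRUE`, minority-class rows of each
#' TRAINING fold are duplicated with replacement until the classes balance —
#' evaluation folds are never touched, so the class imbalance correction
#' cannot leak. Fold metrics are averaged; balanced accuracy is
#' `(TPR + TNR) / 2`; false positives / negatives are mean counts per fold.
#'
#' @param data a [qsar_dataset()] with a 0/1 target.
#' @param folds number of folds, >= 2.
#' @param oversample balance training folds by duplicating minority rows.
#' @param seed integer seed for fold assignment and oversampling.
#' @param ridge use a small-lambda ridge fit (glmnet) instead of plain
#'   maximum likelihood; useful for wide fingerprint blocks.
#' @param drop_constant drop zero-variance columns before fitting.
#' @return object of class `eval_report` with `balanced_accuracy`,
#'   `precision`, `recall`, `false_positives`, `false_negatives` (mean counts
#'   per fold) and the per-fold `confusion` matrix.
#' @export
evaluate_cv_logistic <- function(data, folds = 10, oversample = TRUE, seed = 1,
                                 ridge = FALSE, drop_constant = TRUE) {
  stopifnot(inherits(data, "qsar_dataset"))
  y <- data$target
  if (!all(y %in% c(0, 1))) stop("target must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("target has a single class", call. = FALSE)
  folds <- as.integer(folds)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  x <- data$features
  if (drop_constant) x <- x[, drop_zero_variance(x), drop = FALSE]
  n <- length(y)

  set.seed(seed)
  fold_id <- integer(n)
  for (cls in c(0, 1)) {                      # stratified assignment
    members <- which(y == cls)
    idx <- members[sample.int(length(members))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }

  conf <- matrix(0, folds, 4, dimnames = list(NULL, c("tp", "tn", "fp", "fn")))
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k)
    te <- which(fold_id == k)
    if (length(te) == 0 || length(unique(y[tr])) < 2) next
    if (oversample) {
      n1 <- sum(y[tr] == 1); n0 <- sum(y[tr] == 0)
      minority <- if (n1 < n0) 1 else 0
      deficit <- abs(n0 - n1)
      if (deficit > 0) {
        pool <- tr[y[tr] == minority]
        tr <- c(tr, pool[sample.int(length(pool), deficit, replace = TRUE)])
      }
    }
    if (ridge) {
      if (!requireNamespace("glmnet", quietly = TRUE)) {
        stop("ridge = TRUE requires the glmnet package", call. = FALSE)
      }
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 0, lambda = 1e-3)
      p <- as.numeric(stats::predict(fit, newx = x[te, , drop = FALSE],
                                     type = "response"))
    } else {
      df_tr <- data.frame(y = y[tr], x[tr, , drop = FALSE])
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
      p <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(x[te, , drop = FALSE]),
                       type = "response"))
    }
    pred <- as.integer(p >= 0.5)
    conf[k, "tp"] <- sum(pred == 1 & y[te] == 1)
    conf[k, "tn"] <- sum(pred == 0 & y[te] == 0)
    conf[k, "fp"] <- sum(pred == 1 & y[te] == 0)
    conf[k, "fn"] <- sum(pred == 0 & y[te] == 1)
  }

  metrics <- classification_metrics(conf)
  structure(c(list(kind = "classification", confusion = conf), metrics),
            class = "eval_report")
}

# Fold-averaged classification metrics from a folds x {tp,tn,fp,fn} matrix.
# Folds where a rate is undefined (empty class) are dropped from that rate's
# mean.
classification_metrics <- function(conf) {
  tpr <- conf[, "tp"] / (conf[, "tp"] + conf[, "fn"])
  tnr <- conf[, "tn"] / (conf[, "tn"] + conf[, "fp"])
  prec <- conf[, "tp"] / (conf[, "tp"] + conf[, "fp"])
  list(
    balanced_accuracy = mean((tpr + tnr) / 2, na.rm = TRUE),
    precision = mean(prec, na.rm = TRUE),
    recall = mean(tpr, na.rm = TRUE),
    accuracy = mean((conf[, "tp"] + conf[, "tn"]) / rowSums(conf), na.rm = TRUE),
    false_positives = mean(conf[, "fp"]),
    false_negatives = mean(conf[, "fn"])
  )
}

#' @export
print.eval_report <- function(x, ...) {
  if (identical(x$kind, "regression")) {
    cat(sprintf("<eval_report (regression): MSE %.4g, STD %.4g>\n", x$mse, x$std))
  } else {
    cat(sprintf(
      "<eval_report (classification): bal.acc %.3f, precision %.3f, recall %.3f, FP %.1f, FN %.1f>\n",
      x$balanced_accuracy, x$precision, x$recall,
      x$false_positives, x$false_negatives))
  }
  invisible(x)
}

#' Fit a linear toxicity model on a full dataset
#'
#' Plain OLS of the response on all feature columns; the returned object can
#' be used with [predict_ldh()] to score new particles.
#'
#' @param data a [qsar_dataset()] with a real-valued target.
#' @return object of class `fitted_qsar`: `kind`, `intercept`,
#'   `coefficients` (named), `protocol`.
#' @export
fit_linear_qsar <- function(data) {
  stopifnot(inherits(data, "qsar_dataset"))
  df <- data.frame(y = data$target, data$features)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  structure(
    list(kind = "linear", intercept = unname(cf[1]),
         coefficients = cf[-1], feature_names = colnames(data$features),
         protocol = "full-data OLS"),
    class = "fitted_qsar"
  )
}

#' @export
print.fitted_qsar <- function(x, ...) {
  cat(sprintf("<fitted_qsar (%s): %d coefficients>\n", x$kind,
              length(x$coefficients)))
  invisible(x)
}

#' Predict LDH release for a particle
#'
#' Scores a fitted linear model at the supplied feature values; every feature
#' the model was trained on must be provided. `size_nm` and
#' `concentration_mg_L` fill features named `size` and `concentration` when
#' present; any remaining features come from `extra`.
#'
#' @param model a `fitted_qsar` of kind `"linear"`.
#' @param size_nm particle size, nm.
#' @param concentration_mg_L exposure concentration, mg/L.
#' @param extra named list/vector of further feature values.
#' @return predicted LDH release (numeric scalar).
#' @export
predict_ldh <- function(model, size_nm = NULL, concentration_mg_L = NULL,
                        extra = NULL) {
  stopifnot(inherits(model, "fitted_qsar"))
  if (model$kind != "linear") stop("predict_ldh needs a linear model", call. = FALSE)
  vals <- as.list(extra %||% list())
  if (!is.null(size_nm)) vals$size <- size_nm
  if (!is.null(concentration_mg_L)) vals$concentration <- concentration_mg_L
  # lm mangles names through data.frame; match on the mangled names
  need <- names(model$coefficients)
  supplied <- names(vals)
  missing <- setdiff(need, make.names(supplied))
  if (length(missing) > 0) {
    stop("missing feature value(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  xv <- vapply(need, function(nm) as.numeric(vals[[match(nm, make.names(supplied))]]),
               numeric(1))
  unname(model$intercept + sum(model$coefficients * xv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
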