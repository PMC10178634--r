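#' Classifier registry
#'
#' Named presets approximating common point-and-click classifier
#' configurations: kernel SVMs (`csvm` cubic, `qsvm` quadratic, `lsvm`
#' linear, `mgsvm` RBF), `fknn` (1-nearest-neighbour) and small
#' feed-forward neural networks (`nnn` narrow, `mnn` medium, `wnn` wide,
#' `bnn`, `tnn`). The network presets differ in hidden width; exact parity
#' with any external toolbox's presets is not promised. Each entry is a
#' function `(train_x, train_y, test_x) -> factor of predictions`.
#'
#' @return Named list of classifier functions.
#' @export
classifier_registry <- function() {
  svm_pred <- function(kernel, degree = 3L, gamma = NULL) {
    function(train_x, train_y, test_x) {
      # coef0 = 1 gives the inhomogeneous polynomial kernel (u.v + 1)^d,
      # the usual quadratic/cubic SVM preset; the homogeneous form is
      # sign-blind for even degrees
      args <- list(x = train_x, y = factor(train_y), kernel = kernel,
                   degree = degree, coef0 = 1, scale = FALSE)
      if (!is.null(gamma)) args$gamma <- gamma
      fit <- do.call(e1071::svm, args)
      stats::predict(fit, test_x)
    }
  }
  nnet_pred <- function(size) {
    function(train_x, train_y, test_x) {
      y <- factor(train_y)
      fit <- nnet::nnet(train_x, nnet::class.ind(y), size = size,
                        softmax = TRUE, trace = FALSE, maxit = 200L,
                        MaxNWts = 100000L)
      pred <- stats::predict(fit, test_x, type = "class")
      factor(pred, levels = levels(y))
    }
  }
  list(
    fknn = function(train_x, train_y, test_x) {
      class::knn(train_x, test_x, cl = factor(train_y), k = 1L)
    },
    csvm  = svm_pred("polynomial", degree = 3L),
    qsvm  = svm_pred("polynomial", degree = 2L),
    lsvm  = svm_pred("linear"),
    mgsvm = svm_pred("radial"),
    nnn = nnet_pred(10L),
    mnn = nnet_pred(25L),
    wnn = nnet_pred(100L),
    bnn = nnet_pred(15L),
    tnn = nnet_pred(20L)
  )
}

#' Stratified k-fold cross-validated confusion matrix
#'
#' Trains the requested classifier on each fold complement and aggregates
#' the out-of-fold predictions into a single confusion matrix (rows =
#' truth, columns = prediction). Fold assignment is stratified and seeded.
#'
#' @param X A [feature_matrix()].
#' @param classifier Name from [classifier_registry()] or a classifier
#'   function with the registry signature.
#' @param k Number of folds (>= 2); every class must have >= k members.
#' @param seed Integer seed (fold assignment and any classifier
#'   randomness).
#' @return An integer matrix of class `confusion_matrix` with attributes
#'   `classifier` and `elapsed` (wall seconds, informational only).
#' @export
kfold_evaluate <- function(X, classifier = "fknn", k = 10L, seed = 0L) {
  if (is.character(classifier)) {
    reg <- classifier_registry()
    if (!classifier %in% names(reg)) {
      stop("unknown classifier '", classifier, "'; available: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    clf_name <- classifier
    classifier <- reg[[classifier]]
  } else {
    clf_name <- "custom"
  }
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  labels <- factor(fm_labels(X))
  values <- fm_values(X)
  t0 <- proc.time()[["elapsed"]]
  cm <- withr::with_seed(as.integer(seed), {
    fold <- make_folds(as.character(labels), k)
    pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (f in sort(unique(fold))) {
      test <- fold == f
      p <- classifier(values[!test, , drop = FALSE], labels[!test],
                      values[test, , drop = FALSE])
      pred[test] <- factor(as.character(p), levels = levels(labels))
    }
    table(truth = labels, prediction = pred)
  })
  cm <- unclass(as.matrix(cm))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix", "array"),
            classifier = clf_name,
            elapsed = proc.time()[["elapsed"]] - t0)
}

#' Confusion matrix from truth/prediction vectors or a plain matrix
#'
#' @param truth,prediction Equal-length label vectors, or pass a square
#'   matrix as `truth` (rows = truth) to tag an existing matrix.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, prediction = NULL) {
  if (is.matrix(truth) && is.null(prediction)) {
    cm <- truth
    if (nrow(cm) != ncol(cm)) stop("matrix must be square", call. = FALSE)
    if (is.null(rownames(cm))) {
      dimnames(cm) <- list(seq_len(nrow(cm)), seq_len(ncol(cm)))
    }
  } else {
    lev <- sort(unique(c(as.character(truth), as.character(prediction))))
    cm <- table(truth = factor(truth, lev), prediction = factor(prediction, lev))
    cm <- unclass(as.matrix(cm))
  }
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Metric suite from a confusion matrix
#'
#' Computes accuracy, macro-averaged precision, sensitivity (recall), F1
#' and false-positive rate, Cohen's kappa
#' \eqn{(p_o - p_e)/(1 - p_e)} and the multi-class Matthews correlation
#' coefficient (generalised correlation form). All metrics are reported in
#' percent except FPR, which is a fraction. Per-class metrics with a zero
#' denominator are set to 0 and flagged.
#'
#' @param cm A `confusion_matrix` (square, rows = truth).
#' @return A list of class `metrics_report`: the seven metrics,
#'   `per_class` correct-rates, `degenerate` flag, `classifier`, `elapsed`
#'   and the confusion matrix itself.
#' @export
compute_metrics <- function(cm) {
  m <- unclass(cm)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  if (!is.matrix(m) || nrow(m) != ncol(m) || sum(m) == 0) {
    stop("need a non-empty square confusion matrix", call. = FALSE)
  }
  total <- sum(m)
  tp <- diag(m)
  row_s <- rowSums(m)   # truth totals
  col_s <- colSums(m)   # prediction totals
  fp <- col_s - tp
  fn <- row_s - tp
  tn <- total - tp - fp - fn

  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (any(den == 0)) degenerate <<- TRUE
    ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  }
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * sensitivity, precision + sensitivity)
  fpr <- safe_div(fp, fp + tn)

  accuracy <- sum(tp) / total
  po <- accuracy
  pe <- sum(row_s * col_s) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1

  # multi-class MCC (generalised correlation between truth and prediction)
  s <- total; c_ <- sum(tp)
  num <- c_ * s - sum(row_s * col_s)
  den <- sqrt(s^2 - sum(col_s^2)) * sqrt(s^2 - sum(row_s^2))
  mcc <- if (den > 0) num / den else 0

  per_class <- safe_div(tp, row_s)
  structure(list(
    accuracy = 100 * accuracy,
    precision = 100 * mean(precision),
    sensitivity = 100 * mean(sensitivity),
    f1 = 100 * mean(f1),
    fpr = mean(fpr),
    kappa = 100 * kappa,
    mcc = 100 * mcc,
    per_class = 100 * per_class,
    degenerate = degenerate,
    classifier = attr(cm, "classifier") %||% NA_character_,
    elapsed = attr(cm, "elapsed") %||% NA_real_,
    confusion = m
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report", if (!is.na(x$classifier)) paste0("(", x$classifier, ")"),
      "\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a metrics report into a long metric/value tibble
#'
#' @param x A [compute_metrics()] result.
#' @param ... Unused.
#' @return Tibble with columns `metric` and `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("precision", "sensitivity", "f1", "fpr", "kappa", "mcc",
               "accuracy"),
    value = c(x$precision, x$sensitivity, x$f1, x$fpr, x$kappa, x$mcc,
              x$accuracy)
  )
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, precision = x$precision,
                 sensitivity = x$sensitivity, f1 = x$f1, fpr = x$fpr,
                 kappa = x$kappa, mcc = x$mcc, accuracy = x$accuracy,
                 time_s = x$elapsed)
}

#' Heat-map plot of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Margin of error of a set of metric values
#'
#' Standard normal-quantile confidence half-width around the sample mean:
#' `half = z * sd / sqrt(n)` with `z = 1` at the 68.3% level and
#' `z = 1.960` at 95% (other levels map through the normal quantile).
#'
#' @param values Numeric vector of >= 2 metric values (e.g. kappa per
#'   classifier).
#' @param confidence Confidence level in (0, 1). Default 0.95.
#' @return Tibble with `center` (mean), `half_width`, `percent`
#'   (half-width as % of the center), `z`, `n` and `confidence`.
#' @export
margin_of_error <- function(values, confidence = 0.95) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  z <- if (isTRUE(all.equal(confidence, 0.683))) 1.0
       else if (isTRUE(all.equal(confidence, 0.95))) 1.960
       else stats::qnorm((1 + confidence) / 2)
  center <- mean(values)
  half <- z * stats::sd(values) / sqrt(length(values))
  tibble::tibble(center = center, half_width = half,
                 percent = if (center != 0) 100 * half / abs(center) else NA_real_,
                 z = z, n = length(values), confidence = confidence)
}
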