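#' Serial (column-wise) feature fusion
#'
#' Concatenates two feature matrices column-wise: the fused matrix has
#' `d1 + d2` feature columns and the shared label vector. Rows must align
#' (same length and identical labels in the same order).
#'
#' @param f1,f2 [feature_matrix()] tibbles with identical labels.
#' @return A [feature_matrix()] with `d1 + d2` columns; column names are
#'   prefixed `a_` / `b_` to record which input each came from.
#' @export
serial_fuse <- function(f1, f2) {
  if (nrow(f1) != nrow(f2)) {
    stop("row counts differ: ", nrow(f1), " vs ", nrow(f2), call. = FALSE)
  }
  if (!identical(fm_labels(f1), fm_labels(f2))) {
    stop("label vectors differ between the two feature matrices", call. = FALSE)
  }
  v1 <- fm_values(f1); v2 <- fm_values(f2)
  if (ncol(v1)) colnames(v1) <- paste0("a_", colnames(v1))
  if (ncol(v2)) colnames(v2) <- paste0("b_", colnames(v2))
  vals <- cbind(v1, v2)
  out <- dplyr::bind_cols(tibble::tibble(label = fm_labels(f1)),
                          tibble::as_tibble(vals))
  attr(out, "backbone_id") <- attr(f1, "backbone_id")
  attr(out, "source_id") <- paste(attr(f1, "source_id"),
                                  attr(f2, "source_id"), sep = "+")
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Per-column summary scores
#'
#' One score per feature column of a fused matrix, used for the mid-value
#' threshold. The default is the column mean activation; `max` and
#' `median` are available alternatives.
#'
#' @param fused A [feature_matrix()].
#' @param statistic `"mean"`, `"max"` or `"median"`.
#' @return Named numeric vector of length `d`.
#' @export
column_scores <- function(fused, statistic = c("mean", "max", "median")) {
  statistic <- match.arg(statistic)
  v <- fm_values(fused)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty feature matrix", call. = FALSE)
  switch(statistic,
    mean   = colMeans(v),
    max    = apply(v, 2L, max),
    median = apply(v, 2L, stats::median)
  )
}

#' Mid-value of a score vector
#'
#' The midpoint between the lowest and highest score,
#' \eqn{(lw + hw) / 2}.
#'
#' @param scores Non-empty numeric vector.
#' @return Scalar mid-value.
#' @export
mid_value <- function(scores) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  (min(scores) + max(scores)) / 2
}

#' Mid-value threshold fusion
#'
#' Serially fuses two feature matrices, scores every column, and keeps
#' exactly the columns whose score is greater than or equal to the
#' mid-value threshold (boundary inclusive). The retained set is never
#' empty: the maximum-score column always satisfies the threshold.
#'
#' @param f1,f2 [feature_matrix()] inputs (see [serial_fuse()]).
#' @param statistic Column score statistic (see [column_scores()]).
#' @return A list of class `fused_feature_set` with elements `data` (the
#'   retained [feature_matrix()]), `retained` (strictly increasing column
#'   indices into the concatenated matrix), `threshold` (the mid-value),
#'   `scores` and `statistic`.
#' @export
threshold_fuse <- function(f1, f2, statistic = "mean") {
  fused <- serial_fuse(f1, f2)
  scores <- column_scores(fused, statistic = statistic)
  thr <- mid_value(scores)
  retained <- which(scores >= thr)
  v <- fm_values(fused)[, retained, drop = FALSE]
  data <- dplyr::bind_cols(tibble::tibble(label = fm_labels(fused)),
                           tibble::as_tibble(v))
  attr(data, "backbone_id") <- attr(fused, "backbone_id")
  attr(data, "source_id") <- attr(fused, "source_id")
  class(data) <- c("feature_matrix", class(data))
  structure(list(data = data, retained = retained, threshold = thr,
                 scores = scores, statistic = statistic),
            class = "fused_feature_set")
}

#' @export
print.fused_feature_set <- function(x, ...) {
  cat("Mid-value fused feature set\n")
  cat("  retained:", length(x$retained), "of", length(x$scores),
      "columns (threshold", format(x$threshold, digits = 6), ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fused feature set: one row per concatenated column
#'
#' @param x A [threshold_fuse()] result.
#' @param ... Unused.
#' @return Tibble with columns `column`, `score`, `retained`.
#' @export
tidy.fused_feature_set <- function(x, ...) {
  tibble::tibble(column = names(x$scores) %||% seq_along(x$scores),
                 score = unname(x$scores),
                 retained = seq_along(x$scores) %in% x$retained)
}

#' @rdname tidy.fused_feature_set
#' @export
glance.fused_feature_set <- function(x, ...) {
  tibble::tibble(n_columns = length(x$scores),
                 n_retained = length(x$retained),
                 threshold = x$threshold,
                 statistic = x$statistic)
}
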