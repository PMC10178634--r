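#' Feature matrix container
#'
#' Feature matrices are tibbles with a `label` column followed by numeric
#' feature columns, plus provenance attributes (`backbone_id`, `source_id`).
#' This constructor validates shape and finiteness.
#'
#' @param values Numeric matrix (rows = samples).
#' @param labels Class label per row.
#' @param backbone_id,source_id Provenance tags (e.g. backbone name;
#'   `"original"` or `"enhanced"`).
#' @param prefix Feature column name prefix.
#' @return A tibble of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, backbone_id = NA_character_,
                           source_id = NA_character_, prefix = "f") {
  values <- as.matrix(values)
  if (nrow(values) != length(labels)) {
    stop("number of rows must equal number of labels", call. = FALSE)
  }
  if (ncol(values) >= 1L && any(!is.finite(values))) {
    stop("feature values must be finite", call. = FALSE)
  }
  colnames(values) <- sprintf("%s%04d", prefix, seq_len(ncol(values)))
  out <- dplyr::bind_cols(tibble::tibble(label = as.character(labels)),
                          tibble::as_tibble(values))
  attr(out, "backbone_id") <- backbone_id
  attr(out, "source_id") <- source_id
  class(out) <- c("feature_matrix", class(out))
  out
}

#' @export
#' @rdname feature_matrix
#' @param x A feature matrix tibble.
fm_values <- function(x) {
  as.matrix(x[, setdiff(names(x), c("label", "partition")), drop = FALSE])
}

#' @export
#' @rdname feature_matrix
fm_labels <- function(x) x$label

#' Deterministic toy feature backbone
#'
#' A stand-in extractor so fusion and selection are testable without any
#' trained network: images are bilinearly resized to
#' `input_size x input_size`, flattened, passed through a fixed seeded
#' random linear projection (no bias) to `d` dimensions, and squashed with
#' `tanh`. Bit-reproducible for a given seed; the zero image maps to the
#' zero row.
#'
#' @param seed Integer seed fixing the projection.
#' @param d Output dimension (>= 1); 2048 mirrors the width of a GAP layer
#'   on a ResNet-style network.
#' @param input_size Side length images are resized to before projection.
#' @return A list of class `backbone_spec`.
#' @export
toy_backbone <- function(seed = 0L, d = 64L, input_size = 32L) {
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  p <- as.integer(input_size)^2
  W <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(p * d, sd = 1 / sqrt(p)), p, d))
  structure(list(id = sprintf("toy-s%d-d%d", as.integer(seed), d),
                 d = d, input_size = as.integer(input_size),
                 seed = as.integer(seed), deterministic = TRUE,
                 project = function(v) tanh(as.numeric(v %*% W))),
            class = "backbone_spec")
}

#' Extract per-image feature vectors
#'
#' Applies a backbone to each image (after bilinear resize to the
#' backbone's input size, and rescaling intensities to `[0, 1]`), returning
#' one row per image in input order with provenance recorded.
#'
#' @param images List of numeric matrices.
#' @param labels Class label per image.
#' @param backbone A [toy_backbone()] (or any `backbone_spec` whose
#'   `project` maps a flattened image to a length-`d` vector).
#' @param source_id Provenance tag, e.g. `"original"` or `"enhanced"`.
#' @param L Intensity level count used for rescaling.
#' @return A [feature_matrix()] with `length(images)` rows and
#'   `backbone$d` columns.
#' @export
extract_features <- function(images, labels, backbone,
                             source_id = "original", L = 256L) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (length(images) != length(labels)) {
    stop("`images` and `labels` must have equal length", call. = FALSE)
  }
  rows <- purrr::map(images, function(img) {
    v <- as.numeric(resize_bilinear(img, backbone$input_size)) / (L - 1)
    out <- backbone$project(v)
    if (length(out) != backbone$d) {
      stop("backbone returned ", length(out), " values, expected ",
           backbone$d, call. = FALSE)
    }
    out
  })
  feature_matrix(do.call(rbind, rows), labels,
                 backbone_id = backbone$id, source_id = source_id)
}

#' Read / write feature matrices as CSV with a provenance sidecar
#'
#' The CSV has a header row and a `label` column; provenance is written to
#' `<path>.json`.
#'
#' @param x A [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or a [feature_matrix()] (read).
#' @export
write_features <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(
    list(backbone_id = attr(x, "backbone_id"),
         source_id = attr(x, "source_id"),
         n = nrow(x), d = ncol(x) - 1L),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"))
  } else list()
  fm <- feature_matrix(as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
                       df$label,
                       backbone_id = meta$backbone_id %||% NA_character_,
                       source_id = meta$source_id %||% NA_character_)
  fm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
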