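#' Synthetic mammogram-like image fixtures
#'
#' Generates low-contrast grayscale images with bright lesion blobs and
#' ground-truth labels/masks, purely as a test vehicle (no clinical
#' realism claimed): `"benign"` images carry a smooth additive Gaussian
#' blob, `"malignant"` a blob with radial spikes (a crude spiculation
#' analogue), `"normal"` no blob. Bit-reproducible under the seed.
#'
#' @param n_per_class Images per class.
#' @param classes Character vector of class names drawn from
#'   `"benign"`, `"malignant"`, `"normal"`.
#' @param size Image side length in pixels.
#' @param background Background intensity level.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param contrast Peak lesion intensity above background (> 0 required
#'   for lesion classes).
#' @param radius_range Lesion radius range in pixels.
#' @param L Intensity level count.
#' @param seed Integer seed.
#' @return A list with `images` (named list of matrices), `labels`,
#'   `masks` (logical lesion masks, `NULL` for normals) and the spec echo.
#' @export
make_images <- function(n_per_class = 10L,
                        classes = c("benign", "malignant", "normal"),
                        size = 64L, background = 60, noise_sd = 5,
                        contrast = 60, radius_range = c(5, 12),
                        L = 256L, seed = 0L) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (contrast <= 0 && any(classes != "normal")) {
    stop("`contrast` must be > 0 for lesion classes", call. = FALSE)
  }
  size <- as.integer(size)
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  withr::with_seed(as.integer(seed), {
    images <- list(); labels <- character(0); masks <- list()
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        img <- matrix(background, size, size) +
          matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
        mask <- NULL
        if (cl != "normal") {
          r <- stats::runif(1, radius_range[1], radius_range[2])
          cx <- stats::runif(1, r + 1, size - r)
          cy <- stats::runif(1, r + 1, size - r)
          dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
          blob <- contrast * exp(-(dist / r)^2)
          if (cl == "malignant") {
            ang <- atan2(ys - cy, xs - cx)
            spikes <- 0.5 * contrast * pmax(cos(8 * ang), 0) *
              exp(-((dist - r) / (0.5 * r))^2)
            blob <- blob + spikes
          }
          img <- img + blob
          mask <- dist <= r
        }
        img <- pmin(pmax(img, 0), L - 1)
        name <- sprintf("%s_%03d", cl, i)
        images[[name]] <- img
        labels <- c(labels, cl)
        masks[[name]] <- mask
      }
    }
    names(labels) <- names(images)
    list(images = images, labels = labels, masks = masks,
         spec = list(n_per_class = n_per_class, classes = classes,
                     size = size, background = background,
                     noise_sd = noise_sd, contrast = contrast,
                     radius_range = radius_range, L = L, seed = seed))
  })
}

#' Synthetic feature matrices with planted informative columns
#'
#' Gaussian class-conditional features: informative columns have class
#' means spaced `effect` within-class standard deviations apart (sigma =
#' 1), noise columns are standard Gaussian independent of class. Column
#' order is shuffled (seeded) so informative columns are scattered; the
#' ground-truth index set is recorded as the `informative` attribute.
#'
#' @param n_per_class Samples per class.
#' @param d_informative Number of class-informative columns (>= 1).
#' @param d_noise Number of pure-noise columns.
#' @param effect Class-mean separation in units of within-class sigma
#'   (>= 0).
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return A [feature_matrix()] with attribute `informative` (integer
#'   column indices of the planted features, 1-based among feature
#'   columns).
#' @export
make_features <- function(n_per_class = 100L, d_informative = 5L,
                          d_noise = 45L, effect = 2, n_classes = 2L,
                          seed = 0L) {
  if (d_informative < 1L) stop("`d_informative` must be >= 1", call. = FALSE)
  if (effect < 0) stop("`effect` must be >= 0", call. = FALSE)
  d <- d_informative + d_noise
  n <- n_per_class * n_classes
  withr::with_seed(as.integer(seed), {
    labels <- rep(sprintf("class%d", seq_len(n_classes)), each = n_per_class)
    X <- matrix(stats::rnorm(n * d), n, d)
    class_id <- rep(seq_len(n_classes), each = n_per_class)
    for (j in seq_len(d_informative)) {
      X[, j] <- X[, j] + (class_id - 1) * effect
    }
    perm <- sample(d)
    X <- X[, perm, drop = FALSE]
    informative <- sort(match(seq_len(d_informative), perm))
    fm <- feature_matrix(X, labels, backbone_id = "synthetic",
                         source_id = "planted")
    attr(fm, "informative") <- informative
    fm
  })
}

#' Planted-feature recovery benchmark for the selector
#'
#' Runs [fpcrf_select()] across seeds on freshly generated planted-feature
#' matrices and reports, per seed, the recall and precision of
#' planted-column recovery, the selected-set size and two error deltas
#' versus the all-features baseline: `improvement`, measured with the
#' selector's own cross-validated fitness (the quantity the algorithm
#' optimises), and `holdout_improvement`, measured on an equally sized set
#' of rows the selector never saw. The hold-out delta is the unbiased
#' generalisation measure: under a null (zero-effect) generator it is
#' centred on zero, whereas the internal delta is optimistically biased by
#' construction.
#'
#' @param config An [fpcrf_config()]; its seed is re-derived per run.
#' @param n_per_class,d_informative,d_noise,effect,n_classes Passed to
#'   [make_features()].
#' @param n_seeds Number of independent repeats.
#' @param base_seed Seed offset; run `s` uses `base_seed + s` for both the
#'   data and the selector.
#' @return A tibble of class `recovery_benchmark`, one row per seed, with
#'   columns `seed`, `recall`, `precision`, `n_selected`, `cv_error`,
#'   `baseline_error`, `improvement`, `holdout_error`, `holdout_baseline`,
#'   `holdout_improvement` and `trace_monotone`.
#' @export
planted_recovery_benchmark <- function(config = fpcrf_config(),
                                       n_per_class = 100L,
                                       d_informative = 5L, d_noise = 45L,
                                       effect = 2, n_classes = 2L,
                                       n_seeds = 10L, base_seed = 0L) {
  rows <- purrr::map(seq_len(n_seeds), function(s) {
    seed <- base_seed + s
    # draw twice the rows and hold half back: the error delta is judged on
    # rows the selector never saw, so under a null generator the
    # improvement is centred on zero rather than inflated by selection
    full <- make_features(n_per_class = 2L * n_per_class,
                          d_informative = d_informative, d_noise = d_noise,
                          effect = effect, n_classes = n_classes, seed = seed)
    planted <- attr(full, "informative")
    class_id <- rep(seq_len(n_classes), each = 2L * n_per_class)
    sel_ix <- unlist(lapply(seq_len(n_classes), function(g) {
      which(class_id == g)[seq_len(n_per_class)]
    }))
    vals <- fm_values(full); labs <- fm_labels(full)
    fm <- feature_matrix(vals[sel_ix, , drop = FALSE], labs[sel_ix])
    fm_eval <- feature_matrix(vals[-sel_ix, , drop = FALSE], labs[-sel_ix])
    cfg <- config
    cfg$seed <- seed
    res <- fpcrf_select(fm, cfg)
    eval_cfg <- cfg
    eval_cfg$seed <- seed + 100003L
    holdout_error <- fitness(res$mask, fm_eval, eval_cfg)
    holdout_baseline <- fitness(rep(TRUE, ncol(vals)), fm_eval, eval_cfg)
    tibble::tibble(
      seed = seed,
      recall = length(intersect(res$selected, planted)) / length(planted),
      precision = if (length(res$selected))
        length(intersect(res$selected, planted)) / length(res$selected)
      else 0,
      n_selected = length(res$selected),
      cv_error = res$fitness,
      baseline_error = res$baseline_fitness,
      improvement = res$baseline_fitness - res$fitness,
      holdout_error = holdout_error,
      holdout_baseline = holdout_baseline,
      holdout_improvement = holdout_baseline - holdout_error,
      trace_monotone = all(diff(res$trace) <= 0)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_benchmark", class(out))
  out
}

#' @rdname planted_recovery_benchmark
#' @param x A benchmark tibble.
#' @param ... Unused.
#' @export
glance.recovery_benchmark <- function(x, ...) {
  tibble::tibble(mean_recall = mean(x$recall),
                 mean_precision = mean(x$precision),
                 mean_n_selected = mean(x$n_selected),
                 mean_improvement = mean(x$improvement),
                 prop_improved = mean(x$improvement > 0),
                 mean_holdout_improvement = mean(x$holdout_improvement),
                 n_seeds = nrow(x))
}
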