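#' Run the full desk-scale pipeline on synthetic fixtures
#'
#' Chains every stage end to end: simulate images, enhance, extract toy
#' backbone features from the original and enhanced sets, mid-value
#' threshold fusion, FPcRF feature selection and k-fold evaluation. All
#' randomness flows from `seed`, so a repeated run is bit-identical.
#' Outputs (fused features CSV, selection JSON, metrics JSON) are written
#' under `out_dir` when given.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional output directory.
#' @param n_per_class Images per class for the synthetic set.
#' @param size Image side length.
#' @param backbone_dim Toy backbone output dimension.
#' @param iters,pop FPcRF iterations and population size.
#' @param folds Evaluation folds.
#' @param classifier Evaluation classifier name.
#' @return A list with `fused` (a `fused_feature_set`), `selection`
#'   (an `fpcrf_result`), `metrics` (a `metrics_report`) and `report`
#'   (a plain list mirror of the numbers written to disk).
#' @export
run_pipeline <- function(seed = 0L, out_dir = NULL, n_per_class = 6L,
                         size = 64L, backbone_dim = 64L, iters = 10L,
                         pop = 10L, folds = 5L, classifier = "fknn") {
  seed <- as.integer(seed)
  sim <- make_images(n_per_class = n_per_class, size = size, seed = seed)
  params <- enhance_params()
  enhanced <- purrr::map(sim$images, enhance, params = params)

  bb <- toy_backbone(seed = seed, d = backbone_dim)
  f_orig <- extract_features(sim$images, sim$labels, bb,
                             source_id = "original")
  f_enh <- extract_features(enhanced, sim$labels, bb, source_id = "enhanced")

  fused <- threshold_fuse(f_orig, f_enh)
  cfg <- fpcrf_config(pop = pop, iters = iters, folds = folds, seed = seed)
  sel <- fpcrf_select(fused$data, cfg)

  selected_fm <- feature_matrix(fm_values(fused$data)[, sel$selected,
                                                      drop = FALSE],
                                fm_labels(fused$data),
                                backbone_id = bb$id, source_id = "selected")
  cm <- kfold_evaluate(selected_fm, classifier = classifier, k = folds,
                       seed = seed)
  metrics <- compute_metrics(cm)

  report <- list(
    seed = seed,
    n_images = length(sim$images),
    fusion = list(n_columns = length(fused$scores),
                  n_retained = length(fused$retained),
                  threshold = fused$threshold),
    selection = list(n_selected = length(sel$selected),
                     selected = sel$selected,
                     Vn = sel$Vn,
                     cv_error = sel$fitness,
                     baseline_cv_error = sel$baseline_fitness,
                     trace = sel$trace),
    metrics = list(classifier = metrics$classifier,
                   accuracy = metrics$accuracy,
                   precision = metrics$precision,
                   sensitivity = metrics$sensitivity,
                   f1 = metrics$f1, fpr = metrics$fpr,
                   kappa = metrics$kappa, mcc = metrics$mcc,
                   confusion = unclass(metrics$confusion))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(fused$data, file.path(out_dir, "fused.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(fused = fused, selection = sel, metrics = metrics, report = report)
}
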