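#' FPcRF configuration
#'
#' Configuration for flower-pollination-controlled regula-falsi feature
#' selection: a population of continuous positions in the unit hypercube is
#' evolved by Levy-flight global pollination and uniform local pollination,
#' scored by the cross-validated error of a 1-nearest-neighbour classifier
#' on the thresholded (binarised) feature subset, and finished with a
#' regula-falsi refinement of the binarisation threshold.
#'
#' @param pop Population size `n` (>= 2). Default 20.
#' @param iters Iteration count; the algorithm always runs all of them (no
#'   early stopping). Default 50.
#' @param p Switch probability of global vs local pollination, in `[0, 1]`.
#'   Default 0.8.
#' @param theta Scaling factor of the global-pollination step (> 0).
#'   Default 0.01.
#' @param lambda Levy exponent in (1, 3). Default 1.5.
#' @param tau0 Initial binarisation threshold in (0, 1). Default 0.5.
#' @param folds Cross-validation folds of the wrapper fitness. Default 5
#'   (10-fold is reserved for final evaluation).
#' @param seed Integer seed controlling every random draw.
#' @param rf_tol,rf_max_iter Regula-falsi stopping tolerance on `|f|` and
#'   iteration cap.
#' @param canonical If `TRUE` use the textbook pollination orientation
#'   `theta * L * (B - y)`; the default keeps `theta * L * (y - B)`.
#' @return A list of class `fpcrf_config`.
#' @export
fpcrf_config <- function(pop = 20L, iters = 50L, p = 0.8, theta = 0.01,
                         lambda = 1.5, tau0 = 0.5, folds = 5L, seed = 0L,
                         rf_tol = 1e-6, rf_max_iter = 50L,
                         canonical = FALSE) {
  pop <- as.integer(pop); iters <- as.integer(iters)
  if (pop < 2L) stop("`pop` must be >= 2", call. = FALSE)
  if (iters < 1L) stop("`iters` must be >= 1", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (lambda <= 1 || lambda >= 3) stop("`lambda` must be in (1, 3)", call. = FALSE)
  if (tau0 <= 0 || tau0 >= 1) stop("`tau0` must be in (0, 1)", call. = FALSE)
  structure(list(pop = pop, iters = iters, p = p, theta = theta,
                 lambda = lambda, tau0 = tau0, folds = as.integer(folds),
                 seed = as.integer(seed), rf_tol = rf_tol,
                 rf_max_iter = as.integer(rf_max_iter),
                 canonical = canonical),
            class = "fpcrf_config")
}

#' Levy-flight step sizes (Mantegna sampler)
#'
#' Draws heavy-tailed steps whose magnitude follows the Levy-stable tail
#' `P(|s| > x) ~ x^(-lambda)`: `s = u / |v|^(1/lambda)` with
#' `u ~ N(0, sigma^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma = [Gamma(1+lambda) sin(pi lambda / 2) /
#' (Gamma((1+lambda)/2) lambda 2^((lambda-1)/2))]^(1/lambda)`.
#' Draws come from R's global RNG, so the sequence is reproducible under
#' `set.seed()`.
#'
#' @param lambda Tail exponent in (1, 3).
#' @param count Number of steps.
#' @return Numeric vector of length `count`.
#' @export
levy_step <- function(lambda = 1.5, count = 1L) {
  if (lambda <= 1 || lambda >= 3) stop("`lambda` must be in (1, 3)", call. = FALSE)
  count <- as.integer(count)
  if (count == 0L) return(numeric(0))
  sigma <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
              (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(count, sd = sigma)
  v <- stats::rnorm(count)
  u / abs(v)^(1 / lambda)
}

#' Global pollination move
#'
#' `y' = clip(y + theta * L * (y - B), 0, 1)` with an independent Levy
#' step `L` per coordinate (orientation flips to `(B - y)` when
#' `canonical = TRUE`). The best position `B` is a fixed point: a pollen
#' sitting at `B` never moves.
#'
#' @param y Current position in `[0, 1]^d`.
#' @param B Global best position.
#' @param theta Scaling factor.
#' @param lambda Levy exponent.
#' @param canonical Orientation flag (see [fpcrf_config()]).
#' @return Updated position, clipped to `[0, 1]`.
#' @export
global_pollination <- function(y, B, theta = 0.01, lambda = 1.5,
                               canonical = FALSE) {
  stopifnot(length(y) == length(B))
  L <- levy_step(lambda, length(y))
  dir <- if (canonical) B - y else y - B
  pmin(pmax(y + theta * L * dir, 0), 1)
}

#' Local pollination move
#'
#' `y' = clip(y + mu * (y_z - y_k), 0, 1)` with a single
#' `mu ~ Uniform(0, 1)` per update mixing two other population members.
#'
#' @param y Current position.
#' @param y_z,y_k Two other positions from the same population.
#' @param mu Optional fixed mixing coefficient (drawn uniformly when
#'   `NULL`).
#' @return Updated position, clipped to `[0, 1]`.
#' @export
local_pollination <- function(y, y_z, y_k, mu = NULL) {
  stopifnot(length(y) == length(y_z), length(y) == length(y_k))
  if (is.null(mu)) mu <- stats::runif(1)
  pmin(pmax(y + mu * (y_z - y_k), 0), 1)
}

#' Binarise a continuous position into a feature mask
#'
#' `mask_j = 1` iff `position_j >= tau`. If no coordinate clears the
#' threshold, the single largest coordinate is forced on (lowest index on
#' ties), so the mask is never empty.
#'
#' @param position Numeric vector in `[0, 1]`.
#' @param tau Threshold in (0, 1).
#' @return Logical vector of the same length.
#' @export
binarize <- function(position, tau = 0.5) {
  mask <- position >= tau
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# Stratified fold assignment: per class, shuffled then dealt round-robin.
# Consumes the global RNG; callers seed it.
make_folds <- function(labels, k) {
  k <- as.integer(k)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < k) {
      stop("class '", cl, "' has ", length(ix), " members, fewer than k = ",
           k, "; use a smaller k", call. = FALSE)
    }
    fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# Cross-validated 1-NN misclassification rate on a column subset, given a
# fixed fold assignment.
knn_cv_error <- function(values, labels, cols, fold) {
  wrong <- 0L
  for (f in sort(unique(fold))) {
    test <- fold == f
    pred <- class::knn(values[!test, cols, drop = FALSE],
                       values[test, cols, drop = FALSE],
                       cl = labels[!test], k = 1L)
    wrong <- wrong + sum(pred != labels[test])
  }
  wrong / length(labels)
}

#' Wrapper fitness: cross-validated 1-NN error of a feature mask
#'
#' Stratified k-fold cross-validated misclassification rate of a
#' 1-nearest-neighbour classifier (Euclidean distance) restricted to the
#' masked columns. Fold assignment is seeded from `config$seed`, so the
#' value is deterministic for a given configuration.
#'
#' @param mask Logical (or 0/1) vector selecting >= 1 column.
#' @param X A [feature_matrix()] with >= 2 classes.
#' @param config An [fpcrf_config()].
#' @return Error rate in `[0, 1]`.
#' @export
fitness <- function(mask, X, config = fpcrf_config()) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask selects no features", call. = FALSE)
  labels <- fm_labels(X)
  if (length(unique(labels)) < 2L) {
    stop("fitness needs at least two classes", call. = FALSE)
  }
  values <- fm_values(X)
  fold <- withr::with_seed(config$seed, make_folds(labels, config$folds))
  knn_cv_error(values, labels, which(mask), fold)
}

#' Regula falsi (false position) root finding
#'
#' Given a bracket with a sign change, iterates the secant-through-bracket
#' update `V = (r1 f(r2) - r2 f(r1)) / (f(r2) - f(r1))`, replacing the
#' endpoint whose value shares the sign of `f(V)`, until `|f(V)| <= tol`
#' or `max_iter` iterations. The returned approximation always lies inside
#' the initial bracket.
#'
#' @param f Scalar function.
#' @param r1,r2 Bracket endpoints with `f(r1) * f(r2) < 0`.
#' @param tol Tolerance on `|f|`.
#' @param max_iter Iteration cap.
#' @return List with `root`, `f_root`, `iterations` and the iterate
#'   `history`.
#' @export
regula_falsi <- function(f, r1, r2, tol = 1e-10, max_iter = 100L) {
  f1 <- f(r1); f2 <- f(r2)
  if (!is.finite(f1) || !is.finite(f2)) {
    stop("function not finite at the bracket endpoints", call. = FALSE)
  }
  if (f1 * f2 > 0) {
    stop("no sign change on the bracket [", r1, ", ", r2, "]", call. = FALSE)
  }
  history <- numeric(0)
  V <- r1; fV <- f1
  for (i in seq_len(max_iter)) {
    V <- (r1 * f2 - r2 * f1) / (f2 - f1)
    fV <- f(V)
    history <- c(history, V)
    if (abs(fV) <= tol) break
    if (fV * f1 < 0) { r2 <- V; f2 <- fV } else { r1 <- V; f1 <- fV }
  }
  list(root = V, f_root = fV, iterations = length(history), history = history)
}

# Comparator implementing the tie-break: lower fitness wins; on exact ties
# fewer selected features win, then the lexicographically smaller index set.
mask_better <- function(fit_new, mask_new, fit_old, mask_old) {
  if (fit_new < fit_old) return(TRUE)
  if (fit_new > fit_old) return(FALSE)
  n_new <- sum(mask_new); n_old <- sum(mask_old)
  if (n_new != n_old) return(n_new < n_old)
  i_new <- which(mask_new); i_old <- which(mask_old)
  d <- which(i_new != i_old)
  length(d) > 0L && i_new[d[1L]] < i_old[d[1L]]
}

#' Regula-falsi refinement of the binarisation threshold
#'
#' Roots the fitness-difference function
#' `f(tau) = fitness(binarize(B, tau)) - fitness(binarize(B, tau0))` over
#' the bracket `[min(B), max(B)]`. An 11-point coarse scan locates a sign
#' change for [regula_falsi()]; when none exists the scan's arg-min is
#' used. The final threshold is chosen among the scanned points, `tau0`
#' and the regula-falsi root by lowest fitness (fewest features on ties),
#' so the refined mask never has worse fitness than the mask at `tau0`.
#' A (near-)constant best vector degenerates to `Vn = tau0`.
#'
#' @param B Converged best position in `[0, 1]^d`.
#' @param X A [feature_matrix()].
#' @param config An [fpcrf_config()].
#' @param fit_fun Optional fitness function `mask -> error`; defaults to
#'   [fitness()] with `X` and `config`.
#' @return List with `Vn` (final threshold), `mask`, `fitness`, `bracket`
#'   and regula-falsi `history` (empty when the fallback was used).
#' @export
refine_threshold <- function(B, X, config = fpcrf_config(), fit_fun = NULL) {
  if (is.null(fit_fun)) fit_fun <- function(mask) fitness(mask, X, config)
  r1 <- min(B); r2 <- max(B)
  base_mask <- binarize(B, config$tau0)
  base_fit <- fit_fun(base_mask)
  if (r2 - r1 < 1e-12) {
    return(list(Vn = config$tau0, mask = base_mask, fitness = base_fit,
                bracket = c(r1, r2), history = numeric(0)))
  }
  eval_tau <- function(tau) {
    tau <- min(max(tau, 1e-9), 1 - 1e-9)
    fit_fun(binarize(B, tau))
  }
  grid <- seq(r1, r2, length.out = 11L)
  grid_fit <- vapply(grid, eval_tau, numeric(1))
  f_diff <- grid_fit - base_fit
  history <- numeric(0)
  candidates <- tibble::tibble(tau = c(grid, config$tau0),
                               fit = c(grid_fit, base_fit))
  sc <- which(f_diff[-length(f_diff)] * f_diff[-1L] < 0)
  if (length(sc)) {
    i <- sc[1L]
    rf <- regula_falsi(function(tau) eval_tau(tau) - base_fit,
                       grid[i], grid[i + 1L],
                       tol = config$rf_tol, max_iter = config$rf_max_iter)
    history <- rf$history
    candidates <- dplyr::bind_rows(
      candidates, tibble::tibble(tau = rf$root, fit = eval_tau(rf$root)))
  }
  best <- list(tau = config$tau0, fit = base_fit, mask = base_mask)
  for (i in seq_len(nrow(candidates))) {
    m <- binarize(B, min(max(candidates$tau[i], 1e-9), 1 - 1e-9))
    if (mask_better(candidates$fit[i], m, best$fit, best$mask)) {
      best <- list(tau = candidates$tau[i], fit = candidates$fit[i], mask = m)
    }
  }
  list(Vn = best$tau, mask = best$mask, fitness = best$fit,
       bracket = c(r1, r2), history = history)
}

#' Flower-pollination-controlled regula-falsi feature selection
#'
#' Evolves `pop` continuous positions in `[0, 1]^d` for exactly `iters`
#' iterations (no early stopping): each pollen takes a global
#' (Levy-flight, probability `p`) or local (uniform mixing) pollination
#' move, the move is kept only if the cross-validated 1-NN error of the
#' binarised mask improves (greedy acceptance), and the elitist best `B`
#' tracks the population. The final binarisation threshold is refined with
#' [refine_threshold()]. Fully deterministic for a given `config$seed`.
#'
#' @param X A [feature_matrix()] with >= 2 classes and >= 2 feature
#'   columns.
#' @param config An [fpcrf_config()].
#' @return A list of class `fpcrf_result`: `mask`, `selected` (column
#'   indices), `feature_names`, `Vn`, `trace` (best fitness per iteration,
#'   non-increasing), `fitness` (of the final mask), `baseline_fitness`
#'   (all features), `bracket`, `rf_history`, `best_position`, `config`.
#' @export
fpcrf_select <- function(X, config = fpcrf_config()) {
  labels <- fm_labels(X)
  values <- fm_values(X)
  d <- ncol(values)
  if (d < 2L) stop("need at least 2 feature columns", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }

  withr::with_seed(config$seed, {
    fold <- make_folds(labels, config$folds)
    fit_of <- function(mask) knn_cv_error(values, labels, which(mask), fold)

    pos <- matrix(stats::runif(config$pop * d), config$pop, d)
    fit <- numeric(config$pop)
    masks <- vector("list", config$pop)
    for (i in seq_len(config$pop)) {
      masks[[i]] <- binarize(pos[i, ], config$tau0)
      fit[i] <- fit_of(masks[[i]])
    }
    if (any(!is.finite(fit))) stop("non-finite fitness", call. = FALSE)
    best_i <- which.min(fit)
    B <- pos[best_i, ]; B_fit <- fit[best_i]; B_mask <- masks[[best_i]]

    trace <- numeric(config$iters)
    for (j in seq_len(config$iters)) {
      for (i in seq_len(config$pop)) {
        if (stats::runif(1) < config$p) {
          cand <- global_pollination(pos[i, ], B, config$theta,
                                     config$lambda, config$canonical)
        } else {
          zk <- sample(setdiff(seq_len(config$pop), i), 2L)
          cand <- local_pollination(pos[i, ], pos[zk[1L], ], pos[zk[2L], ])
        }
        cand_mask <- binarize(cand, config$tau0)
        cand_fit <- fit_of(cand_mask)
        if (mask_better(cand_fit, cand_mask, fit[i], masks[[i]])) {
          pos[i, ] <- cand; fit[i] <- cand_fit; masks[[i]] <- cand_mask
          if (mask_better(cand_fit, cand_mask, B_fit, B_mask)) {
            B <- cand; B_fit <- cand_fit; B_mask <- cand_mask
          }
        }
      }
      trace[j] <- B_fit
    }

    refined <- refine_threshold(B, X, config, fit_fun = fit_of)
    final_mask <- refined$mask
    structure(list(
      mask = final_mask,
      selected = which(final_mask),
      feature_names = colnames(values)[final_mask],
      Vn = refined$Vn,
      trace = trace,
      fitness = refined$fitness,
      baseline_fitness = fit_of(rep(TRUE, d)),
      bracket = refined$bracket,
      rf_history = refined$history,
      best_position = B,
      config = config
    ), class = "fpcrf_result")
  })
}

#' @export
print.fpcrf_result <- function(x, ...) {
  cat("FPcRF feature selection\n")
  cat("  selected:", length(x$selected), "of", length(x$mask), "features\n")
  cat("  final threshold Vn:", format(x$Vn, digits = 6), "\n")
  cat("  CV error:", format(x$fitness, digits = 4),
      "(all features:", format(x$baseline_fitness, digits = 4), ")\n")
  invisible(x)
}

#' Tidy an FPcRF result: one row per feature
#'
#' @param x An [fpcrf_select()] result.
#' @param ... Unused.
#' @return Tibble with `feature`, `position` (best pollen coordinate) and
#'   `selected`.
#' @export
tidy.fpcrf_result <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$mask),
                 position = x$best_position,
                 selected = x$mask)
}

#' @rdname tidy.fpcrf_result
#' @export
glance.fpcrf_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_features = length(x$mask),
                 Vn = x$Vn,
                 cv_error = x$fitness,
                 baseline_cv_error = x$baseline_fitness,
                 iterations = length(x$trace))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the best-fitness trace of an FPcRF run
#'
#' @param object An [fpcrf_select()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpcrf_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       best_cv_error = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$best_cv_error)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best CV error",
                  title = "FPcRF best-fitness trace") +
    ggplot2::theme_minimal()
}
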