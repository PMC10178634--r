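#' Enhancement parameters
#'
#' Parameters of the hybrid contrast-enhancement transform: a global
#' histogram-based remapping followed by local-statistics contrast
#' stretching
#' \deqn{G(x,y) = \frac{K \cdot gm}{\sigma(x,y)+\beta}\,(F(x,y) - c\,\mu(x,y)) + \mu(x,y)^a}
#' where `gm` is the global mean of the remapped image `F`, and
#' \eqn{\mu,\sigma} are windowed local mean and standard deviation.
#'
#' @param K Gain constant (> 0). Default 0.8.
#' @param beta Stabiliser added to the local standard deviation (> 0),
#'   keeping the stretch gain finite in flat regions. Default 1.
#' @param c Local-mean coefficient. Default 1 (classical adaptive contrast
#'   enhancement).
#' @param a Local-mean exponent. Default 1.
#' @param window Odd side length of the square window for local statistics.
#'   Default 7.
#' @param mu_term How the trailing local-mean term is applied: `"power"`
#'   (\eqn{\mu^a}, default) or `"multiply"` (\eqn{\mu \cdot a}).
#' @param fixed_range If `TRUE` the histogram remapping targets the full
#'   `[0, L - 1]` range instead of the observed min/max.
#' @return A list of class `enhance_params`.
#' @export
enhance_params <- function(K = 0.8, beta = 1.0, c = 1.0, a = 1.0,
                           window = 7L, mu_term = c("power", "multiply"),
                           fixed_range = FALSE) {
  mu_term <- match.arg(mu_term)
  window <- as.integer(window)
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(K = K, beta = beta, c = c, a = a, window = window,
                 mu_term = mu_term, fixed_range = fixed_range),
            class = "enhance_params")
}

#' Intensity histogram, pdf and cdf of a grayscale image
#'
#' Pixels are binned to the nearest of the `L` integer levels; the pdf is
#' the per-level pixel fraction and the cdf its cumulative sum.
#'
#' @param img A [grayscale_image()] or numeric matrix in `[0, L - 1]`.
#' @param L Level count (taken from the image attribute when present).
#' @return A list of class `intensity_histogram` with elements `counts`,
#'   `pdf`, `cdf` (each length `L`), `levels` (0..L-1) and `total`.
#' @export
intensity_histogram <- function(img, L = img_levels(img)) {
  m <- unclass(img)
  if (length(m) == 0L) stop("empty image", call. = FALSE)
  k <- pmin(pmax(as.integer(round(m)), 0L), L - 1L)
  counts <- tabulate(k + 1L, nbins = L)
  total <- length(m)
  pdf <- counts / total
  structure(list(counts = counts, pdf = pdf, cdf = cumsum(pdf),
                 levels = 0:(L - 1L), total = total),
            class = "intensity_histogram")
}

#' Histogram-based global remapping
#'
#' Maps each pixel at level \eqn{k} to
#' \eqn{F_k = \phi_0 + (\phi_{max} - \phi_0)\, cdf(k)} where
#' \eqn{\phi_0, \phi_{max}} are the observed minimum and maximum intensities
#' (or `0` and `L - 1` when `fixed_range = TRUE`). A constant image is
#' returned unchanged (the mapping is ill-posed for zero dynamic range).
#'
#' @param img Grayscale image the histogram was computed from.
#' @param hist An [intensity_histogram()] of `img`; computed when `NULL`.
#' @param fixed_range Use the full `[0, L - 1]` target range.
#' @return A [grayscale_image()] of the same size.
#' @export
histogram_transform <- function(img, hist = NULL, fixed_range = FALSE) {
  L <- img_levels(img)
  m <- unclass(img)
  if (is.null(hist)) hist <- intensity_histogram(m, L = L)
  lo <- if (fixed_range) 0 else min(m)
  hi <- if (fixed_range) L - 1 else max(m)
  if (hi <= lo) return(grayscale_image(m, L = L))
  k <- pmin(pmax(as.integer(round(m)), 0L), L - 1L)
  out <- lo + (hi - lo) * hist$cdf[k + 1L]
  dim(out) <- dim(m)
  grayscale_image(out, L = L)
}

# Reflect-padded index vector for a window radius r over n positions.
reflect_index <- function(n, r) {
  idx <- c(rev(seq_len(min(r, n - 1)) + 1L), seq_len(n),
           n - seq_len(min(r, n - 1)))
  if (r >= n) stop("window too large for image dimension", call. = FALSE)
  idx
}

#' Windowed local statistics and global mean
#'
#' Local mean and standard deviation over a square window centred at each
#' pixel, with reflect padding at the borders, plus the exact global mean.
#' The standard deviation uses the population formula (divide by the window
#' area).
#'
#' @param img Grayscale image or numeric matrix.
#' @param window Odd window side length.
#' @return List with matrices `mu` and `sigma` (same size as `img`) and
#'   scalar `gm`.
#' @export
local_stats <- function(img, window = 7L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  m <- unclass(img)
  M <- nrow(m); N <- ncol(m)
  r <- (window - 1L) %/% 2L
  p <- m[reflect_index(M, r), reflect_index(N, r), drop = FALSE]
  # box sums via a summed-area table on the padded image
  box_sum <- function(x) {
    s <- apply(x, 2L, cumsum)
    s <- t(apply(s, 1L, cumsum))
    s <- rbind(0, cbind(0, s))
    w <- window
    s[(1L:M) + w, (1L:N) + w] - s[(1L:M) + w, 1L:N] -
      s[1L:M, (1L:N) + w] + s[1L:M, 1L:N]
  }
  area <- window^2
  mu <- box_sum(p) / area
  ex2 <- box_sum(p^2) / area
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  list(mu = mu, sigma = sigma, gm = mean(m))
}

#' Local-statistics contrast stretching
#'
#' Applies \eqn{G = Q \cdot (F - c\,\mu) + \mu^a} with the stretch gain
#' \eqn{Q = K \cdot gm / (\sigma + \beta)}, then clips to `[0, L - 1]`.
#'
#' @param F Grayscale image (typically the output of
#'   [histogram_transform()]).
#' @param params An [enhance_params()] object.
#' @param Q_override Optional constant or matrix replacing the computed gain
#'   `Q`; with `Q_override = 1`, `c = 1`, `a = 1` the transform is the
#'   identity map (useful as an algebraic check).
#' @return A [grayscale_image()] with attribute `params`.
#' @export
contrast_stretch <- function(F, params = enhance_params(), Q_override = NULL) {
  stopifnot(inherits(params, "enhance_params"))
  L <- img_levels(F)
  m <- unclass(F)
  ls <- local_stats(m, window = params$window)
  Q <- if (is.null(Q_override)) {
    params$K * ls$gm / (ls$sigma + params$beta)
  } else {
    Q_override
  }
  mu_term <- switch(params$mu_term,
    power    = ls$mu^params$a,
    multiply = ls$mu * params$a
  )
  G <- Q * (m - params$c * ls$mu) + mu_term
  G <- pmin(pmax(G, 0), L - 1)
  out <- grayscale_image(G, L = L)
  attr(out, "params") <- params
  out
}

#' Hybrid contrast enhancement
#'
#' The full enhancement chain: grayscale conversion, intensity histogram,
#' histogram-based global remapping, then local-statistics contrast
#' stretching. Deterministic; no randomness anywhere in the chain.
#'
#' @param image Matrix or M x N x 3 array.
#' @param params An [enhance_params()] object.
#' @param L Intensity level count.
#' @return A [grayscale_image()] with attribute `params`.
#' @export
enhance <- function(image, params = enhance_params(), L = 256L) {
  g <- to_grayscale(image, L = L)
  h <- intensity_histogram(g)
  f <- histogram_transform(g, h, fixed_range = params$fixed_range)
  contrast_stretch(f, params = params)
}
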