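#' Geometric augmentation primitives
#'
#' The three augmentation operations: horizontal flip (mirror columns),
#' vertical flip (mirror rows) and counter-clockwise 90-degree rotation.
#' All are exact index permutations; applied to a matrix they satisfy
#' `flip_h(flip_h(x)) == x`, `flip_v(flip_v(x)) == x` and four `rot90`s
#' compose to the identity.
#'
#' @param img Numeric matrix.
#' @return The transformed matrix (attributes preserved where meaningful).
#' @name augment-ops
NULL

#' @rdname augment-ops
#' @export
flip_h <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' @rdname augment-ops
#' @export
flip_v <- function(img) img[rev(seq_len(nrow(img))), , drop = FALSE]

#' @rdname augment-ops
#' @export
rot90 <- function(img) t(img)[rev(seq_len(ncol(img))), , drop = FALSE]

aug_ops <- list(flip_h = flip_h, flip_v = flip_v, rot90 = rot90)

#' Apply a chain of augmentation operations
#'
#' @param img Numeric matrix.
#' @param chain Character vector of operation names (applied left to right),
#'   each one of `"flip_h"`, `"flip_v"`, `"rot90"`.
#' @return The transformed matrix.
#' @export
apply_chain <- function(img, chain) {
  for (op in chain) {
    f <- aug_ops[[op]]
    if (is.null(f)) stop("unknown operation: ", op, call. = FALSE)
    img <- f(img)
  }
  img
}

# Signature of a chain as a transform: the permutation it induces on an
# asymmetric probe grid. Used to deduplicate chains that are equal as
# transforms (the three ops generate the 8-element dihedral group, so only
# 7 non-identity transforms exist).
chain_signature <- function(chain) {
  probe <- matrix(seq_len(12L), nrow = 3L)
  paste(apply_chain(probe, chain), collapse = ",")
}

# Deduplicated enumeration of operation chains ordered by (length,
# lexicographic op order), keeping only the first chain realising each
# distinct non-identity transform. Returns a list of character vectors;
# always the 7 dihedral transforms.
distinct_chains <- function() {
  ops <- names(aug_ops)
  id_sig <- chain_signature(character())
  seen <- id_sig
  out <- list()
  len <- 1L
  while (length(out) < 7L) {
    grid <- expand.grid(rep(list(ops), len), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    # lexicographic in op order, first position most significant
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      chain <- unlist(grid[i, ], use.names = FALSE)
      sig <- chain_signature(chain)
      if (!sig %in% seen) {
        seen <- c(seen, sig)
        out[[length(out) + 1L]] <- chain
      }
    }
    len <- len + 1L
  }
  out
}

#' Class inventory
#'
#' Bookkeeping record for one image class: how many images exist and how
#' many the balancing step should produce.
#'
#' @param class Class name.
#' @param count Initial image count (>= 0).
#' @param target Target count after augmentation (>= `count`).
#' @param images Optional character vector of image references (defaults to
#'   `img_001` style names).
#' @return A one-row tibble of class `class_inventory`.
#' @export
class_inventory <- function(class, count, target, images = NULL) {
  count <- as.integer(count); target <- as.integer(target)
  if (count < 0L || target < 0L) stop("counts must be non-negative", call. = FALSE)
  if (target < count) stop("`target` must be >= `count`", call. = FALSE)
  if (is.null(images)) {
    images <- sprintf("%s_%03d", class, seq_len(count))
  } else if (length(images) != count) {
    stop("`images` must have length `count`", call. = FALSE)
  }
  out <- tibble::tibble(class = class, count = count, target = target,
                        images = list(images))
  class(out) <- c("class_inventory", class(out))
  out
}

#' Plan class-balancing augmentation
#'
#' Enumerates (source image, operation chain) items in deterministic rounds
#' until `target - count` items exist. Round 1 applies each single
#' operation to every source; later rounds use longer chains in
#' lexicographic order, skipping chains equal *as transforms* to earlier
#' ones. The three operations generate only 7 distinct non-identity
#' transforms, so once those are exhausted the enumeration cycles (the
#' `copy` column records the pass). The final round is truncated to the
#' exact target with a seeded shuffle; every source image is used before
#' any is reused.
#'
#' @param inventory A [class_inventory()].
#' @param seed Integer seed for the truncation shuffle.
#' @return A tibble of class `augmentation_plan` with columns `source`,
#'   `chain` (list of character vectors), `round` and `copy`, and
#'   attributes `class` and `target`.
#' @export
plan_augmentation <- function(inventory, seed = 0L) {
  stopifnot(inherits(inventory, "class_inventory"), nrow(inventory) == 1L)
  n0 <- inventory$count
  target <- inventory$target
  if (n0 < 1L) stop("cannot augment a class with zero images", call. = FALSE)
  sources <- inventory$images[[1L]]
  need <- target - n0

  chains <- distinct_chains()
  rounds <- split(seq_along(chains),
                  vapply(chains, length, integer(1)))  # round = chain length
  per_round <- lapply(rounds, function(ix) chains[ix])

  rows <- list(); made <- 0L; round_no <- 0L; copy <- 0L
  while (made < need) {
    for (rchains in per_round) {
      round_no <- round_no + 1L
      items <- tidyr::expand_grid(source = sources,
                                  chain_id = seq_along(rchains))
      items$chain <- rchains[items$chain_id]
      items$chain_id <- NULL
      items$round <- round_no
      items$copy <- copy
      remaining <- need - made
      if (nrow(items) > remaining) {
        keep <- withr::with_seed(seed, sample(nrow(items), remaining))
        items <- items[sort(keep), , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- items
      made <- made + nrow(items)
      if (made >= need) break
    }
    copy <- copy + 1L
  }
  plan <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(source = character(), chain = list(),
                   round = integer(), copy = integer())
  attr(plan, "class_name") <- inventory$class
  attr(plan, "target") <- target
  class(plan) <- c("augmentation_plan", class(plan))
  plan
}

#' Execute an augmentation plan
#'
#' Applies each planned operation chain to its source image and returns the
#' full class set (originals followed by generated images).
#'
#' @param plan An [plan_augmentation()] result.
#' @param images Named list of numeric matrices covering every source
#'   referenced by the plan.
#' @return A named list of matrices of length `target`; generated images
#'   are named `<source>.<round>.<i>`.
#' @export
execute_plan <- function(plan, images) {
  missing <- setdiff(unique(plan$source), names(images))
  if (length(missing)) {
    stop("missing source image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  generated <- purrr::imap(seq_len(nrow(plan)), function(i, ...) {
    apply_chain(images[[plan$source[i]]], plan$chain[[i]])
  })
  names(generated) <- sprintf("%s.r%d.%d", plan$source, plan$round,
                              seq_len(nrow(plan)))
  c(images, generated)
}

#' Total images across executed inventories
#'
#' @param inventories A list of [class_inventory()] rows (or a tibble built
#'   by binding them).
#' @return Integer sum of the target counts (0 for an empty list).
#' @export
dataset_totals <- function(inventories) {
  if (is.data.frame(inventories)) return(sum(inventories$target))
  sum(vapply(inventories, function(inv) sum(inv$target), numeric(1)))
}

#' Stratified train/test split
#'
#' Splits a labelled set per class: training receives `floor(ratio * n)`
#' items of each class, the remainder goes to testing. Seeded and
#' reproducible.
#'
#' @param data A data frame with a `class` column (one row per item).
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return The input tibble with an added `partition` column
#'   (`"train"`/`"test"`).
#' @export
split_train_test <- function(data, ratio = 0.5, seed = 0L) {
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  data <- tibble::as_tibble(data)
  partition <- character(nrow(data))
  withr::with_seed(seed, {
    for (cl in unique(data$class)) {
      ix <- which(data$class == cl)
      n_train <- floor(length(ix) * ratio)
      train_ix <- sample(ix, n_train)
      partition[train_ix] <- "train"
      partition[setdiff(ix, train_ix)] <- "test"
    }
  })
  dplyr::mutate(data, partition = partition)
}
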