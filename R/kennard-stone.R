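#' Kennard-Stone calibration/validation partitioning
#'
#' Deterministic max-min selection on Euclidean distances between sample
#' spectra: the pair at maximum distance seeds the training set, then the
#' candidate maximizing its minimum distance to the already-selected set is
#' added until the training size is reached. The remainder forms the test
#' set. Ties are broken toward the lowest sample index, making the split a
#' pure function of the input matrix.
#'
#' Distances are computed on whatever matrix is supplied — typically the
#' preprocessed fused spectra so that all fusion models share one split —
#' but any single block can be used instead.
#'
#' The training size is `floor(fraction * n)`: 80% of 196 samples gives
#' 156 training and 40 test samples.
#'
#' @param block a [spectra_block()] or numeric sample x channel matrix.
#' @param fraction target training proportion in `(0, 1)`, default 0.8.
#' @return object of class `split_index`: list with `train_ids`,
#'   `test_ids` (ordered by selection / original order), integer
#'   `train_idx`, `test_idx`, and `fraction`.
#' @examples
#' x <- matrix(c(0, 1, 2, 10), ncol = 1)
#' kennard_stone(x, fraction = 0.75)$train_idx  # 1 4 3
#' @export
kennard_stone <- function(block, fraction = 0.8) {
  x <- as_spectra_matrix(block)
  ids <- if (inherits(block, "spectra_block")) block$samples else
    rownames(x) %||% as.character(seq_len(nrow(x)))
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("'fraction' must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- floor(fraction * n + 1e-9)
  if (n_train < 2L) {
    stop("fraction ", fraction, " yields a training set of fewer than 2 of ",
         n, " samples", call. = FALSE)
  }
  d <- unname(as.matrix(stats::dist(x)))
  # seed: pair at global maximum distance, lowest indices on ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(c(best[1L, 1L], best[1L, 2L]))
  mind <- pmin(d[, sel[1L]], d[, sel[2L]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    # which.max returns the first (lowest) index on ties
    nxt <- as.integer(which.max(mind))
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  test <- setdiff(seq_len(n), sel)
  structure(list(train_ids = ids[sel], test_ids = ids[test],
                 train_idx = sel, test_idx = test, fraction = fraction),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("<split_index: %d train / %d test (fraction %.2f)>\n",
              length(x$train_idx), length(x$test_idx), x$fraction))
  invisible(x)
}

#' Write a split as a two-column CSV (sample id, partition)
#'
#' @param split a `split_index`.
#' @param path file path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_index"))
  df <- data.frame(sample = c(split$train_ids, split$test_ids),
                   partition = rep(c("train", "test"),
                                   c(length(split$train_ids),
                                     length(split$test_ids))),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
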