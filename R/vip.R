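#' Variable importance in projection (VIP)
#'
#' Computes per-channel VIP scores from a fitted NIPALS PLS model:
#' `VIP_j = sqrt( p * sum_a w_ja^2 * SSY_a / SSY_total )`, where `p` is the
#' channel count, `w_ja` the unit-norm weight of channel `j` on component
#' `a`, `SSY_a` the Y sum of squares explained by component `a`, and
#' `SSY_total` the sum over the fitted components. With unit-norm weight
#' columns the mean of the squared VIP scores is exactly 1, so a threshold
#' of 1 ("more important than average") is the conventional selection
#' cutoff.
#'
#' @param model a [fit_pls()] model with at least one latent variable.
#' @param threshold selection cutoff stored with the result (default 1).
#' @return object of class `vip_result`: `scores` (per channel),
#'   `threshold`, logical `mask` (`scores > threshold`), and `n_lv`.
#' @export
compute_vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls_model"))
  if (model$n_lv < 1L) stop("model has no latent variables", call. = FALSE)
  ssy <- model$ssy
  if (sum(ssy) <= 0) {
    stop("model explains no Y variance; VIP undefined", call. = FALSE)
  }
  p <- nrow(model$W)
  scores <- sqrt(p * as.numeric(model$W^2 %*% (ssy / sum(ssy))))
  structure(list(scores = scores, threshold = threshold,
                 mask = scores > threshold, n_lv = model$n_lv),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result: %d channels, %d above threshold %g>\n",
              length(x$scores), sum(x$mask), x$threshold))
  invisible(x)
}

#' Threshold-select channels from per-block VIP results
#'
#' Applies a strict `score > threshold` rule (configurable to `>=`) to the
#' VIP results of the two sensor blocks and reports the per-block and
#' total selected channel counts. A block in which nothing survives the
#' threshold is rejected.
#'
#' @param vip1,vip2 [compute_vip()] results for the first and second block.
#' @param threshold selection cutoff (default 1).
#' @param strict if `TRUE` (default) use `>`; otherwise `>=`.
#' @return list with logical masks `mask1`, `mask2`, the counts
#'   `n_selected1`, `n_selected2`, `n_selected_total`, and the rule used.
#' @export
select_variables <- function(vip1, vip2, threshold = 1, strict = TRUE) {
  stopifnot(inherits(vip1, "vip_result"), inherits(vip2, "vip_result"))
  pick <- function(v) if (strict) v$scores > threshold else
    v$scores >= threshold
  m1 <- pick(vip1); m2 <- pick(vip2)
  if (!any(m1) || !any(m2)) {
    empty <- c("block 1", "block 2")[c(!any(m1), !any(m2))]
    stop("no channels selected in ", paste(empty, collapse = " and "),
         " at threshold ", threshold,
         "; lower the threshold or use strict = FALSE", call. = FALSE)
  }
  list(mask1 = m1, mask2 = m2,
       n_selected1 = sum(m1), n_selected2 = sum(m2),
       n_selected_total = sum(m1) + sum(m2),
       threshold = threshold, strict = strict)
}

#' VIP-filtered sequential orthogonalized PLS
#'
#' The variable-selected fusion model: a plain PLS model is fitted per
#' block with a cross-validated component count, per-block VIP scores are
#' thresholded to masks, and an SOPLS model with a fresh cross-validated
#' `(a1, a2)` grid search is fitted on the reduced blocks. All selection
#' statistics are computed from the supplied (training) data only; apply
#' the returned masks to test blocks before prediction (or use
#' [predict.sf_vip_sopls()], which does so).
#'
#' @inheritParams fit_sopls
#' @param max_lv per-block component-count cap for the VIP models.
#' @param max_a1,max_a2 grid bounds for the reduced SOPLS model.
#' @param folds,seed cross-validation controls (shared by all stages).
#' @param threshold,strict VIP selection rule (see [select_variables()]).
#' @param a1,a2 optional fixed component counts overriding the grid search.
#' @return object of class `sf_vip_sopls`: the reduced `model`
#'   (`sopls_model`), `vip1`, `vip2`, `selection` masks and the `grid`
#'   search result (`NULL` if `a1`/`a2` were fixed).
#' @export
fit_sf_vip_sopls <- function(X1, X2, Y, max_lv = 10L, max_a1 = 10L,
                             max_a2 = 10L, folds = 10L, seed = 1L,
                             threshold = 1, strict = TRUE,
                             a1 = NULL, a2 = NULL) {
  X1 <- as_spectra_matrix(X1); X2 <- as_spectra_matrix(X2)
  cv1 <- select_lv(X1, Y, max_lv = max_lv, folds = folds, seed = seed)
  cv2 <- select_lv(X2, Y, max_lv = max_lv, folds = folds, seed = seed)
  m1 <- fit_pls(X1, Y, n_lv = cv1$n_lv)
  m2 <- fit_pls(X2, Y, n_lv = cv2$n_lv)
  v1 <- compute_vip(m1, threshold)
  v2 <- compute_vip(m2, threshold)
  sel <- select_variables(v1, v2, threshold = threshold, strict = strict)
  X1r <- X1[, sel$mask1, drop = FALSE]
  X2r <- X2[, sel$mask2, drop = FALSE]
  grid <- NULL
  if (is.null(a1) || is.null(a2)) {
    grid <- sopls_select_lv(X1r, X2r, Y, max_a1 = max_a1, max_a2 = max_a2,
                            folds = folds, seed = seed)
    a1 <- grid$a1; a2 <- grid$a2
  }
  model <- fit_sopls(X1r, X2r, Y, a1 = a1, a2 = a2)
  structure(list(model = model, vip1 = v1, vip2 = v2, selection = sel,
                 grid = grid, block_cv = list(cv1, cv2), seed = seed),
            class = "sf_vip_sopls")
}

#' @export
print.sf_vip_sopls <- function(x, ...) {
  cat(sprintf(paste0("<sf_vip_sopls: %d + %d selected channels, ",
                     "a1 = %d, a2 = %d>\n"),
              x$selection$n_selected1, x$selection$n_selected2,
              x$model$a1, x$model$a2))
  invisible(x)
}

#' @rdname fit_sf_vip_sopls
#' @param object a fitted `sf_vip_sopls`.
#' @param X1_new,X2_new full (unreduced) new blocks; the stored masks are
#'   applied before prediction.
#' @param ... unused.
#' @export
predict.sf_vip_sopls <- function(object, X1_new, X2_new, ...) {
  X1n <- as_spectra_matrix(X1_new)[, object$selection$mask1, drop = FALSE]
  X2n <- as_spectra_matrix(X2_new)[, object$selection$mask2, drop = FALSE]
  predict(object$model, X1n, X2n)
}

#' Export VIP scores and masks as CSV keyed by channel axis value
#'
#' @param vip a [compute_vip()] result.
#' @param axis per-channel axis values (defaults to channel index).
#' @param path file path.
#' @export
write_vip <- function(vip, path, axis = seq_along(vip$scores)) {
  stopifnot(inherits(vip, "vip_result"))
  utils::write.csv(data.frame(axis = axis, vip = vip$scores,
                              selected = vip$mask),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
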