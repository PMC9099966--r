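#' Sequential orthogonalized PLS (SOPLS) for two blocks
#'
#' Fits the two-block sequential model `Y = X1 B1 + X2 C2 + E`:
#'
#' 1. `Y` is fitted to the first block `X1` by PLS with `a1` components;
#' 2. the centered second block is orthogonalized against the first-stage
#'    score space, `X2orth = X2c - T1 (T1'T1)^- T1' X2c`;
#' 3. a second PLS with `a2` components predicts the stage-1 residuals
#'    from `X2orth`;
#' 4. the final prediction is the sum of the two stage predictions.
#'
#' Because each block enters only through its own PLS scores and the
#' orthogonalized remainder, predictions are invariant to rescaling either
#' block, and the second block's contribution is strictly incremental —
#' the information already captured by block 1 is projected out. By default
#' the MIR block is taken first and XRF second; pass the blocks in the
#' order you want.
#'
#' `a1 = 0` skips stage 1 (stage 2 then fits `Y` directly); `a2 = 0` makes
#' the model identical to a plain PLS on `X1`. Both zero is rejected.
#'
#' @param X1,X2 sample x channel matrices or [spectra_block()]s on the
#'   same samples.
#' @param Y response vector/matrix.
#' @param a1,a2 per-block latent-variable counts (nonnegative).
#' @param ortho_tol pseudo-inverse tolerance for the score projection.
#' @return object of class `sopls_model` with the two stage `pls_model`s,
#'   the orthogonalization operator `G`, centering vectors, and training
#'   `fitted` values.
#' @seealso [sopls_select_lv()] for cross-validated choice of `(a1, a2)`.
#' @export
fit_sopls <- function(X1, X2, Y, a1, a2, ortho_tol = 1e-10) {
  X1 <- as_spectra_matrix(X1); X2 <- as_spectra_matrix(X2)
  Y <- if (is.null(dim(Y))) matrix(as.numeric(Y), ncol = 1L) else as.matrix(Y)
  n <- nrow(Y)
  if (nrow(X1) != n || nrow(X2) != n) {
    stop("X1, X2 and Y must share the same samples", call. = FALSE)
  }
  check_scalar_number(a1, "a1", min = 0)
  check_scalar_number(a2, "a2", min = 0)
  if (a1 == 0 && a2 == 0) stop("a1 = a2 = 0 gives an empty model",
                               call. = FALSE)
  ym <- colMeans(Y)
  if (a1 > 0) {
    m1 <- fit_pls(X1, Y, n_lv = a1)
    a1 <- m1$n_lv
    T1 <- m1$T
    yhat1 <- m1$fitted
  } else {
    m1 <- NULL
    T1 <- matrix(0, n, 0L)
    yhat1 <- matrix(ym, n, ncol(Y), byrow = TRUE)
  }
  x2m <- colMeans(X2)
  X2c <- sweep(X2, 2L, x2m)
  G <- if (ncol(T1) > 0L) {
    pinv(crossprod(T1), tol = ortho_tol) %*% crossprod(T1, X2c)
  } else {
    matrix(0, 0L, ncol(X2))
  }
  X2orth <- X2c - T1 %*% G
  resid1 <- Y - yhat1
  if (a2 > 0) {
    # an orthogonalized block with no residual variance (e.g. X2 fully
    # explained by the stage-1 scores) degrades to a2 = 0
    m2 <- tryCatch(fit_pls(X2orth, resid1, n_lv = a2),
                   error = function(e) {
                     warning("second block has no usable variance after ",
                             "orthogonalization; a2 set to 0",
                             call. = FALSE)
                     NULL
                   })
    a2 <- if (is.null(m2)) 0L else m2$n_lv
    fitted <- if (is.null(m2)) yhat1 else yhat1 + m2$fitted
  } else {
    m2 <- NULL
    fitted <- yhat1
  }
  structure(list(block1_model = m1, block2_model = m2, G = G,
                 x2_center = x2m, y_center = ym,
                 a1 = as.integer(a1), a2 = as.integer(a2),
                 fitted = fitted, X2orth = X2orth, T1 = T1),
            class = "sopls_model")
}

#' @export
print.sopls_model <- function(x, ...) {
  cat(sprintf("<sopls_model: a1 = %d, a2 = %d>\n", x$a1, x$a2))
  invisible(x)
}

#' Predict from an SOPLS model
#'
#' Applies the stored centers and orthogonalization operator to the new
#' second block before the stage-2 prediction, then sums the two stage
#' predictions.
#'
#' @param object an `sopls_model`.
#' @param X1_new,X2_new new data with the training channel counts.
#' @param components if `TRUE`, return a list with `total`, `stage1` and
#'   `stage2` prediction matrices instead of just the total.
#' @param ... unused.
#' @export
predict.sopls_model <- function(object, X1_new, X2_new,
                                components = FALSE, ...) {
  X1n <- as_spectra_matrix(X1_new); X2n <- as_spectra_matrix(X2_new)
  if (ncol(X2n) != length(object$x2_center)) {
    stop("X2 channel count does not match training", call. = FALSE)
  }
  n <- nrow(X2n)
  q <- length(object$y_center)
  if (object$a1 > 0L) {
    yhat1 <- predict(object$block1_model, X1n)
    t1 <- pls_scores(object$block1_model, X1n)
  } else {
    yhat1 <- matrix(object$y_center, n, q, byrow = TRUE)
    t1 <- matrix(0, n, 0L)
  }
  yhat2 <- if (object$a2 > 0L) {
    X2o <- sweep(X2n, 2L, object$x2_center) - t1 %*% object$G
    predict(object$block2_model, X2o)
  } else {
    matrix(0, n, q)
  }
  total <- yhat1 + yhat2
  if (components) {
    list(total = total, stage1 = yhat1, stage2 = yhat2)
  } else {
    total
  }
}

#' Cross-validated (a1, a2) grid selection for SOPLS
#'
#' Exhaustive grid search over `a1 = 0..max_a1`, `a2 = 0..max_a2`
#' (excluding `(0, 0)`) minimizing the cross-validated RMSE, with the
#' orthogonalization operator, centers and both stage fits re-learned
#' inside each training fold. Ties are resolved toward smaller
#' `a1 + a2`, then smaller `a1`. Fold construction matches [select_lv()]
#' (contiguous blocks after a seeded shuffle), so a PLS model on block 1
#' alone and the `a2 = 0` row of the grid see identical folds.
#'
#' @inheritParams fit_sopls
#' @param max_a1,max_a2 grid bounds (capped by fold sizes).
#' @param folds number of CV folds.
#' @param seed fold-shuffle seed.
#' @param keep_pred if `TRUE`, also return the out-of-fold prediction
#'   array (`samples x (max_a1 + 1) x (max_a2 + 1)`, single response
#'   only), useful for auditing that fold models never see their own
#'   test samples.
#' @return list with chosen `a1`, `a2`, the `rmsecv` and `r2cv` matrices
#'   (rows `a1 = 0..max_a1`, columns `a2 = 0..max_a2`), `fold`, `seed`.
#' @export
sopls_select_lv <- function(X1, X2, Y, max_a1 = 10L, max_a2 = 10L,
                            folds = 10L, seed = 1L, keep_pred = FALSE) {
  X1 <- as_spectra_matrix(X1); X2 <- as_spectra_matrix(X2)
  Y <- if (is.null(dim(Y))) matrix(as.numeric(Y), ncol = 1L) else as.matrix(Y)
  n <- nrow(Y)
  fold <- make_folds(n, folds, seed)
  max_fold <- max(tabulate(fold, folds))
  cap <- n - max_fold - 1L
  max_a1 <- min(max_a1, cap, ncol(X1))
  max_a2 <- min(max_a2, cap, ncol(X2))
  if (max_a1 < 0L || max_a2 < 0L || (max_a1 == 0L && max_a2 == 0L)) {
    stop("grid bounds leave no admissible model", call. = FALSE)
  }
  sse <- matrix(0, max_a1 + 1L, max_a2 + 1L)
  cv_pred <- if (keep_pred && ncol(Y) == 1L) {
    array(NA_real_, c(n, max_a1 + 1L, max_a2 + 1L))
  } else NULL
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    Ytr <- Y[tr, , drop = FALSE]; Yte <- Y[te, , drop = FALSE]
    X1tr <- X1[tr, , drop = FALSE]; X1te <- X1[te, , drop = FALSE]
    X2tr <- X2[tr, , drop = FALSE]; X2te <- X2[te, , drop = FALSE]
    ym <- colMeans(Ytr)
    m1 <- if (max_a1 > 0L) fit_pls(X1tr, Ytr, n_lv = max_a1) else NULL
    x2m <- colMeans(X2tr)
    X2ctr <- sweep(X2tr, 2L, x2m)
    X2cte <- sweep(X2te, 2L, x2m)
    for (a1 in 0:max_a1) {
      a1_eff <- if (is.null(m1)) 0L else min(a1, m1$n_lv)
      if (a1_eff > 0L) {
        T1 <- m1$T[, seq_len(a1_eff), drop = FALSE]
        yhat1_tr <- predict(m1, X1tr, n_lv = a1_eff)
        yhat1_te <- predict(m1, X1te, n_lv = a1_eff)
        t1te <- pls_scores(m1, X1te, n_lv = a1_eff)
        G <- pinv(crossprod(T1)) %*% crossprod(T1, X2ctr)
        X2o_tr <- X2ctr - T1 %*% G
        X2o_te <- X2cte - t1te %*% G
      } else {
        yhat1_tr <- matrix(ym, nrow(X1tr), ncol(Y), byrow = TRUE)
        yhat1_te <- matrix(ym, nrow(X1te), ncol(Y), byrow = TRUE)
        X2o_tr <- X2ctr
        X2o_te <- X2cte
      }
      rtr <- Ytr - yhat1_tr
      m2 <- if (max_a2 > 0L) {
        tryCatch(suppressWarnings(fit_pls(X2o_tr, rtr, n_lv = max_a2)),
                 error = function(e) NULL)
      } else NULL
      for (a2 in 0:max_a2) {
        a2_eff <- if (is.null(m2)) 0L else min(a2, m2$n_lv)
        pred <- yhat1_te
        if (a2_eff > 0L) {
          pred <- pred + predict(m2, X2o_te, n_lv = a2_eff)
        }
        sse[a1 + 1L, a2 + 1L] <- sse[a1 + 1L, a2 + 1L] +
          sum((pred - Yte)^2)
        if (!is.null(cv_pred)) cv_pred[te, a1 + 1L, a2 + 1L] <- pred
      }
    }
  }
  sse[1L, 1L] <- Inf  # (0, 0) is not a model
  rmsecv <- sqrt(sse / (n * ncol(Y)))
  sstot <- sum(sweep(Y, 2L, colMeans(Y))^2)
  r2cv <- 1 - sse / sstot
  # argmin with ties -> smaller a1 + a2, then smaller a1
  cand <- which(rmsecv <= min(rmsecv) * (1 + 1e-12), arr.ind = TRUE)
  tot <- cand[, 1L] + cand[, 2L]
  cand <- cand[order(tot, cand[, 1L]), , drop = FALSE]
  a1 <- unname(cand[1L, 1L] - 1L); a2 <- unname(cand[1L, 2L] - 1L)
  dimnames(rmsecv) <- dimnames(r2cv) <-
    list(a1 = 0:max_a1, a2 = 0:max_a2)
  list(a1 = a1, a2 = a2, rmsecv = rmsecv, r2cv = r2cv,
       fold = fold, folds = folds, seed = seed, cv_pred = cv_pred)
}

#' Serialize an SOPLS model as JSON
#'
#' Same array container as [write_pls_model()], with block metadata.
#'
#' @param model an `sopls_model`.
#' @param path file path.
#' @export
write_sopls_model <- function(model, path) {
  stopifnot(inherits(model, "sopls_model"))
  strip <- function(m) if (is.null(m)) NULL else
    m[c("x_center", "y_center", "W", "T", "P", "U", "Q", "ssy", "n_lv",
        "center")]
  obj <- list(type = "sopls_model", a1 = model$a1, a2 = model$a2,
              y_center = model$y_center, x2_center = model$x2_center,
              G = model$G, block1 = strip(model$block1_model),
              block2 = strip(model$block2_model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
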