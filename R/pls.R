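#' NIPALS partial least squares regression
#'
#' Fits a PLS regression model by the NIPALS algorithm after mean-centering
#' `X` and `Y`. The predictor matrix is decomposed as `X = T P' + E` and
#' the response as `Y = U Q' + F`, with unit-norm weight columns `W` and
#' mutually orthogonal score columns `T`; each latent variable captures
#' maximal covariance between the (deflated) blocks. Channels are not
#' autoscaled: spectra share one unit, so only centering is applied
#' (configurable). NIPALS is used (rather than SIMPLS) because variable
#' importance in projection is defined on the per-component weights `W`.
#'
#' If the residual predictor matrix runs out of rank before `n_lv`
#' components, fitting stops early with a warning and `n_lv` is truncated.
#'
#' @param X numeric sample x channel matrix or [spectra_block()].
#' @param Y numeric response vector or sample x response matrix.
#' @param n_lv number of latent variables, at most `min(n - 1, p)`.
#' @param center logical; mean-center `X` and `Y` (default `TRUE`).
#' @param tol convergence / rank tolerance.
#' @return object of class `pls_model` with elements `x_center`,
#'   `y_center`, `W` (channel x LV weights, unit columns), `T` (scores),
#'   `P` (X-loadings), `U` (Y-scores), `Q` (Y-loadings, response x LV),
#'   `R` (projection weights `W (P'W)^-1`), `coefficients`, `fitted`,
#'   `ssy` (per-component explained Y sum of squares), `n_lv`.
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X %*% c(1, -1, 0, 0, 0) + rnorm(20, 0, 0.01)
#' m <- fit_pls(X, y, n_lv = 2)
#' head(predict(m, X))
#' @export
fit_pls <- function(X, Y, n_lv, center = TRUE, tol = 1e-12) {
  X <- as_spectra_matrix(X)
  if (nrow(X) == 1L && !is.null(dim(Y)) && nrow(Y) != 1L) {
    stop("X and Y sample counts differ", call. = FALSE)
  }
  Y <- if (is.null(dim(Y))) matrix(as.numeric(Y), ncol = 1L) else {
    Y <- as.matrix(Y); storage.mode(Y) <- "double"; Y
  }
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y sample counts differ", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("missing values not allowed", call. = FALSE)
  check_scalar_number(n_lv, "n_lv", min = 1)
  if (n_lv > min(n - 1L, p)) {
    stop("n_lv (", n_lv, ") exceeds min(n - 1, channels) = ",
         min(n - 1L, p), call. = FALSE)
  }
  n_lv <- as.integer(n_lv)
  xm <- if (center) colMeans(X) else rep(0, p)
  ym <- if (center) colMeans(Y) else rep(0, q)
  Xc <- sweep(X, 2L, xm)
  Yc <- sweep(Y, 2L, ym)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); U <- matrix(0, n, n_lv)
  Q <- matrix(0, q, n_lv); ssy <- numeric(n_lv)
  x_scale0 <- sum(Xc^2)
  A <- 0L
  for (a in seq_len(n_lv)) {
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    if (sum(u^2) <= tol * max(1, sum(Y^2))) break
    t_old <- rep(Inf, n)
    w <- t_vec <- NULL
    for (it in seq_len(200L)) {
      w <- crossprod(Xc, u)
      wn <- sqrt(sum(w^2))
      if (wn <= sqrt(tol * max(x_scale0, 1))) { w <- NULL; break }
      w <- w / wn
      t_vec <- as.numeric(Xc %*% w)
      tt <- sum(t_vec^2)
      if (tt <= tol * max(x_scale0, 1)) { w <- NULL; break }
      qv <- as.numeric(crossprod(Yc, t_vec)) / tt
      if (q == 1L) break
      u_new <- as.numeric(Yc %*% qv) / sum(qv^2)
      if (sum((t_vec - t_old)^2) <= tol * tt) { u <- u_new; break }
      t_old <- t_vec
      u <- u_new
    }
    if (is.null(w)) break
    tt <- sum(t_vec^2)
    qv <- as.numeric(crossprod(Yc, t_vec)) / tt
    pv <- as.numeric(crossprod(Xc, t_vec)) / tt
    Xc <- Xc - tcrossprod(t_vec, pv)
    Yc <- Yc - tcrossprod(t_vec, qv)
    A <- a
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t_vec; U[, a] <- u
    Q[, a] <- qv
    ssy[a] <- tt * sum(qv^2)
  }
  if (A == 0L) stop("X has no usable variance; cannot extract components",
                    call. = FALSE)
  if (A < n_lv) {
    warning("rank exhausted after ", A, " of ", n_lv,
            " requested latent variables; n_lv truncated", call. = FALSE)
  }
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; U <- U[, seq_len(A), drop = FALSE]
  Q <- Q[, seq_len(A), drop = FALSE]; ssy <- ssy[seq_len(A)]
  R <- W %*% solve(crossprod(P, W))  # P'W is upper triangular for NIPALS
  B <- R %*% t(Q)
  fitted <- sweep(sweep(X, 2L, xm) %*% B, 2L, ym, `+`)
  model <- structure(list(x_center = xm, y_center = ym,
                          W = W, T = Tm, P = P, U = U, Q = Q,
                          R = R, coefficients = B, fitted = fitted,
                          ssy = ssy, n_lv = A, center = center),
                     class = "pls_model")
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d latent variables, %d channels, %d response(s)>\n",
              x$n_lv, nrow(x$W), nrow(x$Q)))
  invisible(x)
}

pls_coefficients <- function(model, n_lv = model$n_lv) {
  a <- seq_len(n_lv)
  model$W[, a, drop = FALSE] %*%
    solve(crossprod(model$P[, a, drop = FALSE],
                    model$W[, a, drop = FALSE])) %*%
    t(model$Q[, a, drop = FALSE])
}

#' Predict from a PLS model
#'
#' Deterministic linear prediction applying the stored centering vectors.
#'
#' @param object a `pls_model`.
#' @param newdata sample x channel matrix or [spectra_block()] with the
#'   training channel count.
#' @param n_lv number of components to use (default: all fitted).
#' @param ... unused.
#' @return matrix of predictions (samples x responses).
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  Xn <- as_spectra_matrix(newdata)
  if (ncol(Xn) != length(object$x_center)) {
    stop("channel count (", ncol(Xn), ") does not match training (",
         length(object$x_center), ")", call. = FALSE)
  }
  check_scalar_number(n_lv, "n_lv", min = 0, max = object$n_lv)
  if (n_lv == 0L) {
    return(matrix(object$y_center, nrow(Xn), length(object$y_center),
                  byrow = TRUE))
  }
  B <- if (n_lv == object$n_lv) object$coefficients else
    pls_coefficients(object, n_lv)
  sweep(sweep(Xn, 2L, object$x_center) %*% B, 2L, object$y_center, `+`)
}

#' X-scores of new samples under a fitted PLS model
#'
#' @inheritParams predict.pls_model
#' @return samples x `n_lv` score matrix `(X - center) W (P'W)^-1`.
#' @export
pls_scores <- function(object, newdata, n_lv = object$n_lv) {
  Xn <- as_spectra_matrix(newdata)
  if (ncol(Xn) != length(object$x_center)) {
    stop("channel count does not match training", call. = FALSE)
  }
  sweep(Xn, 2L, object$x_center) %*% object$R[, seq_len(n_lv), drop = FALSE]
}

# Contiguous-block fold assignment after a seeded shuffle; returns an
# integer vector of fold labels per sample.
make_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("'folds' must be at least 2", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                       rep(0L, folds - n %% folds))
  if (any(sizes < 2L)) {
    stop("a fold would contain fewer than 2 samples", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(folds), times = sizes)
  fold
}

#' Cross-validated latent-variable selection
#'
#' k-fold cross-validation of [fit_pls()] over component counts
#' `1..max_lv`; the chosen count minimizes the cross-validated RMSE
#' (RMSECV), ties going to the smaller count. Folds are contiguous blocks
#' after a seeded shuffle, and all model statistics (centers, weights) are
#' learned inside each training fold only.
#'
#' @inheritParams fit_pls
#' @param max_lv largest component count searched (default 20, capped at
#'   what the fold sizes allow).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param keep_pred if `TRUE`, also return the out-of-fold prediction
#'   array (`samples x responses x components`).
#' @return object of class `cv_result`: `rmsecv` and `r2cv` per component
#'   count, chosen `n_lv`, `fold` assignment and `seed`.
#' @export
select_lv <- function(X, Y, max_lv = 20L, folds = 10L, seed = 1L,
                      keep_pred = FALSE) {
  X <- as_spectra_matrix(X)
  Y <- if (is.null(dim(Y))) matrix(as.numeric(Y), ncol = 1L) else as.matrix(Y)
  n <- nrow(X)
  fold <- make_folds(n, folds, seed)
  min_train <- min(tabulate(fold, folds))
  max_lv <- min(max_lv, n - max(tabulate(fold, folds)) - 1L, ncol(X))
  if (max_lv < 1L) stop("no admissible component count", call. = FALSE)
  preds <- array(NA_real_, c(n, ncol(Y), max_lv))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    m <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                 n_lv = max_lv)
    for (a in seq_len(max_lv)) {
      preds[te, , a] <- predict(m, X[te, , drop = FALSE],
                                n_lv = min(a, m$n_lv))
    }
  }
  rmsecv <- apply(preds, 3L, function(pp) sqrt(mean((pp - Y)^2)))
  sstot <- sum(sweep(Y, 2L, colMeans(Y))^2)
  r2cv <- apply(preds, 3L, function(pp) 1 - sum((pp - Y)^2) / sstot)
  chosen <- which.min(rmsecv)  # first minimum = fewest LVs on ties
  structure(list(rmsecv = rmsecv, r2cv = r2cv, n_lv = chosen,
                 fold = fold, folds = folds, seed = seed,
                 cv_pred = if (keep_pred) preds else NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: chosen n_lv = %d (RMSECV %.4g), %d folds>\n",
              x$n_lv, x$rmsecv[x$n_lv], x$folds))
  invisible(x)
}

#' Serialize / deserialize a PLS model as JSON
#'
#' Stores centers, weights, scores, loadings and the chosen component
#' count as plain JSON arrays.
#'
#' @param model a `pls_model`.
#' @param path file path.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(type = "pls_model", n_lv = model$n_lv, center = model$center,
              x_center = model$x_center, y_center = model$y_center,
              W = model$W, T = model$T, P = model$P, U = model$U,
              Q = model$Q, ssy = model$ssy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  }
  W <- as_mat(o$W); P <- as_mat(o$P); Q <- as_mat(o$Q)
  R <- W %*% solve(crossprod(P, W))
  structure(list(x_center = as.numeric(o$x_center),
                 y_center = as.numeric(o$y_center),
                 W = W, T = as_mat(o$T), P = P, U = as_mat(o$U), Q = Q,
                 R = R, coefficients = R %*% t(Q), fitted = NULL,
                 ssy = as.numeric(o$ssy), n_lv = as.integer(o$n_lv),
                 center = isTRUE(o$center)),
            class = "pls_model")
}
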