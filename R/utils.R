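# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never clobber
# the user's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Moore-Penrose pseudo-inverse with a relative singular-value tolerance.
pinv <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (length(A) == 0L) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d[1], .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Accept a spectra_block, matrix, data.frame or bare numeric vector
# (interpreted as a single spectrum) and return a numeric matrix.
as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_block")) return(x$values)
  if (is.null(dim(x))) return(matrix(as.numeric(x), nrow = 1L))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# Rebuild an object of the same shape as `template` with new channel values.
rewrap_spectra <- function(template, values) {
  if (inherits(template, "spectra_block")) {
    out <- template
    rownames(values) <- template$samples
    out$values <- values
    return(out)
  }
  if (is.null(dim(template))) return(drop(values))
  dimnames(values) <- dimnames(template)
  values
}

spectra_axis <- function(x) {
  if (inherits(x, "spectra_block")) return(x$axis)
  seq_len(ncol(as_spectra_matrix(x)))
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x),
         call. = FALSE)
  }
  invisible(x)
}
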