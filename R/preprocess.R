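#' Spectral preprocessing operators
#'
#' Row-wise (per-spectrum) pre-treatment operators used to correct scatter
#' and baseline artifacts before multivariate calibration. Every operator
#' accepts a [spectra_block()], a numeric matrix (rows = spectra), or a
#' bare numeric vector (one spectrum), and returns an object of the same
#' shape. Sample count and ordering are never changed.
#'
#' @name preprocessing
NULL

#' Moving-average smoothing
#'
#' Each channel is replaced by the mean over a centered window of odd size.
#' At the spectrum edges the window shrinks to the available neighbors
#' (mean over the in-range channels), so a constant spectrum is left
#' unchanged everywhere and `window = 1` is the identity.
#'
#' @param block spectra input (see [preprocessing]).
#' @param window odd window size, `>= 1` and at most the channel count.
#' @return smoothed spectra of the same shape.
#' @export
moving_average <- function(block, window = 5L) {
  x <- as_spectra_matrix(block)
  p <- ncol(x)
  check_scalar_number(window, "window", min = 1)
  if (window %% 2 == 0) stop("'window' must be odd", call. = FALSE)
  if (window > p) stop("'window' (", window, ") exceeds channel count (",
                       p, ")", call. = FALSE)
  h <- (window - 1L) / 2L
  lo <- pmax(seq_len(p) - h, 1L)
  hi <- pmin(seq_len(p) + h, p)
  out <- t(apply(x, 1L, function(row) {
    cs <- cumsum(c(0, row))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }))
  if (p == 1L) out <- matrix(out, ncol = 1L)
  rewrap_spectra(block, out)
}

#' Maximum normalization
#'
#' Divides each spectrum by its own maximum so that values lie within
#' unity (per-spectrum maximum becomes exactly 1). Idempotent.
#'
#' @inheritParams moving_average
#' @export
max_normalize <- function(block) {
  x <- as_spectra_matrix(block)
  mx <- apply(x, 1L, max)
  bad <- which(mx <= 0)
  if (length(bad)) {
    stop("non-positive spectrum maximum for sample(s): ",
         paste(rownames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  rewrap_spectra(block, x / mx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum individually to mean 0 and sample
#' standard deviation 1 (`n - 1` denominator). Invariant to affine
#' transformations `a + b * x` with `b > 0` of a spectrum, which is what
#' makes it a scatter correction.
#'
#' @inheritParams moving_average
#' @export
snv <- function(block) {
  x <- as_spectra_matrix(block)
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    stop("constant spectrum (zero variance) for sample(s): ",
         paste(rownames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  rewrap_spectra(block, (x - m) / s)
}

#' Multiplicative scatter correction (MSC)
#'
#' Fits an ordinary least-squares regression line of each spectrum on a
#' reference spectrum (`x ~ a + b * reference`) and returns
#' `(x - a) / b`. The reference defaults to the mean spectrum of the input
#' and, in a calibration setting, must be learned on the training set and
#' reused on test data (see [fit_recipe()]); a spectrum equal to an affine
#' distortion `a + b * reference` is mapped back to the reference exactly.
#'
#' @inheritParams moving_average
#' @param reference numeric reference spectrum; default mean spectrum of
#'   `block`. Must be non-constant.
#' @export
msc <- function(block, reference = NULL) {
  x <- as_spectra_matrix(block)
  if (is.null(reference)) reference <- colMeans(x)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(x)) {
    stop("reference length must equal channel count", call. = FALSE)
  }
  vr <- stats::var(reference)
  if (!is.finite(vr) || vr == 0) {
    stop("MSC reference must be non-constant", call. = FALSE)
  }
  rm_ <- mean(reference)
  rc <- reference - rm_  # centered, so sum(rc) == 0
  # OLS slope of x ~ a + b*ref, row-wise: cov(x, ref) / var(ref)
  b <- as.numeric(x %*% rc) / sum(rc^2)
  a <- rowMeans(x) - b * rm_
  bad <- which(b == 0 | !is.finite(b))
  if (length(bad)) {
    stop("zero MSC slope for sample(s): ",
         paste(rownames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  out <- (x - a) / b
  res <- rewrap_spectra(block, out)
  attr(res, "msc_reference") <- reference
  res
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing by the standard Savitzky-Golay
#' convolution (delegated to `signal::sgolayfilt`). A spectrum that is
#' exactly a polynomial of degree `<= polyorder` in the channel index is
#' reproduced unchanged.
#'
#' @inheritParams moving_average
#' @param window odd filter length, strictly greater than `polyorder`.
#' @param polyorder polynomial order (default 2).
#' @export
savitzky_golay <- function(block, window = 11L, polyorder = 2L) {
  x <- as_spectra_matrix(block)
  check_scalar_number(window, "window", min = 1)
  check_scalar_number(polyorder, "polyorder", min = 0)
  if (window %% 2 == 0) stop("'window' must be odd", call. = FALSE)
  if (window <= polyorder) {
    stop("'window' must exceed 'polyorder'", call. = FALSE)
  }
  if (window > ncol(x)) {
    stop("'window' (", window, ") exceeds channel count (", ncol(x), ")",
         call. = FALSE)
  }
  out <- t(apply(x, 1L, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window)
  }))
  if (ncol(x) == 1L) out <- matrix(out, ncol = 1L)
  rewrap_spectra(block, out)
}

#' Asymmetric least-squares baseline correction
#'
#' Estimates a slowly varying baseline under each spectrum by asymmetric
#' least squares (second-difference penalty with asymmetric residual
#' weights) and subtracts it. Intended for XRF continua: a pure smooth ramp
#' is removed almost entirely while narrow emission peaks are preserved.
#'
#' @inheritParams moving_average
#' @param smoothness penalty weight on the squared second differences of
#'   the baseline (larger = stiffer baseline), default `1e5`.
#' @param asymmetry weight given to residuals above the baseline, default
#'   `0.01`; points below the baseline get weight `1 - asymmetry`.
#' @param iterations number of reweighting iterations, default 10.
#' @export
baseline_correct <- function(block, smoothness = 1e5, asymmetry = 0.01,
                             iterations = 10L) {
  x <- as_spectra_matrix(block)
  if (any(!is.finite(x))) stop("non-finite values in spectra", call. = FALSE)
  check_scalar_number(smoothness, "smoothness", min = 0)
  check_scalar_number(asymmetry, "asymmetry", min = 0, max = 1)
  p <- ncol(x)
  if (p < 3L) stop("need at least 3 channels for baseline estimation",
                   call. = FALSE)
  D <- Matrix::diff(Matrix::Diagonal(p), differences = 2L)
  DTD <- smoothness * Matrix::crossprod(D)
  out <- x
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    w <- rep(1, p)
    z <- y
    for (it in seq_len(iterations)) {
      Wm <- Matrix::Diagonal(x = w)
      z <- as.numeric(Matrix::solve(Wm + DTD, w * y))
      w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
      if (all(w_new == w)) break
      w <- w_new
    }
    out[i, ] <- y - z
  }
  rewrap_spectra(block, out)
}

#' Compton normalization
#'
#' Divides each XRF spectrum by its integrated intensity (trapezoidal rule
#' over the energy axis) inside a scatter-region window, so the post-hoc
#' integral over that window equals 1. This corrects sample matrix effects
#' because the incoherent (Compton) scatter of the source line scales with
#' the bulk matrix. The default window 18-22 keV brackets the Rh K-line
#' scatter region of a Rh-anode instrument. Idempotent and invariant to
#' positive rescaling of a spectrum.
#'
#' @inheritParams moving_average
#' @param window length-2 energy interval in axis units (keV), default
#'   `c(18, 22)`; must lie within the axis range and contain at least two
#'   channels.
#' @export
compton_normalize <- function(block, window = c(18, 22)) {
  x <- as_spectra_matrix(block)
  axis <- spectra_axis(block)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("'window' must be an increasing interval", call. = FALSE)
  }
  if (window[1] < min(axis) || window[2] > max(axis)) {
    stop(sprintf("window [%s, %s] outside axis range [%s, %s]",
                 window[1], window[2], min(axis), max(axis)), call. = FALSE)
  }
  idx <- which(axis >= window[1] & axis <= window[2])
  if (length(idx) < 2L) {
    stop("window must contain at least two channels", call. = FALSE)
  }
  idx <- idx[order(axis[idx])]
  ax <- axis[idx]
  sub <- x[, idx, drop = FALSE]
  w <- diff(ax)
  integ <- as.numeric(sub[, -length(idx), drop = FALSE] %*% w +
                        sub[, -1L, drop = FALSE] %*% w) / 2
  bad <- which(integ <= 0)
  if (length(bad)) {
    stop("non-positive window integral for sample(s): ",
         paste(rownames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  rewrap_spectra(block, x / integ)
}

#' Drop channels inside an axis interval
#'
#' Removes the channels whose axis value falls inside `interval`
#' (inclusive). Used to excise detector artifacts such as the spurious
#' XRF peak near 2.5 keV; the default interval is 2.3-2.7 keV.
#'
#' @param block a [spectra_block()].
#' @param interval length-2 axis interval whose channels are removed.
#' @export
drop_channels <- function(block, interval = c(2.3, 2.7)) {
  stopifnot(inherits(block, "spectra_block"))
  keep <- !(block$axis >= min(interval) & block$axis <= max(interval))
  if (!any(keep)) stop("interval removes every channel", call. = FALSE)
  subset_channels(block, keep)
}

# ---- recipes -------------------------------------------------------------

op_registry <- function() {
  list(moving_average = moving_average,
       max_normalize = max_normalize,
       snv = snv,
       msc = msc,
       savitzky_golay = savitzky_golay,
       baseline_correct = baseline_correct,
       compton_normalize = compton_normalize,
       drop_channels = drop_channels)
}

#' Preprocessing recipes
#'
#' A recipe is an ordered list of operator steps applied to a spectra
#' block. `preprocess_spec()` builds and validates one; `recipe_preset()`
#' returns the per-sensor, per-attribute default recipes used for the soil
#' attributes: moving average (window 5) followed by maximum normalization
#' for pH/OC/Mg/MC, SNV for P, nothing further for K, and MSC for Ca; XRF
#' recipes are prefixed by baseline correction and Compton normalization.
#'
#' Statistics a step learns from data (the MSC reference) must come from
#' the training set only: [fit_recipe()] applies the steps to a training
#' block and freezes any learned state, and [apply_recipe()] with the
#' fitted recipe replays the frozen steps on new data.
#'
#' @param steps list of steps; each step is a list with element `op` (an
#'   operator name from the implemented set) and optional parameters.
#' @param sensor `"MIR"` or `"XRF"`.
#' @param attribute optional attribute name the recipe serves.
#' @return `preprocess_spec()` / `recipe_preset()` return a
#'   `preprocess_spec`; `fit_recipe()` returns a `fitted_recipe`;
#'   `apply_recipe()` returns the transformed block.
#' @examples
#' sp <- recipe_preset("MIR", "pH")
#' @export
preprocess_spec <- function(steps, sensor = c("MIR", "XRF"),
                            attribute = NULL) {
  sensor <- match.arg(sensor)
  known <- names(op_registry())
  for (st in steps) {
    if (is.null(st$op) || !st$op %in% known) {
      stop("unknown operator: '", st$op %||% "<missing>", "'; implemented: ",
           paste(known, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(steps = steps, sensor = sensor, attribute = attribute),
            class = "preprocess_spec")
}

#' @rdname preprocess_spec
#' @export
recipe_preset <- function(sensor = c("MIR", "XRF"),
                          attribute = c("pH", "OC", "P", "K", "Mg", "Ca",
                                        "MC")) {
  sensor <- match.arg(sensor)
  attribute <- match.arg(attribute)
  tail_step <- switch(attribute,
                      pH = , OC = , Mg = , MC = list(list(op = "max_normalize")),
                      P = list(list(op = "snv")),
                      K = list(),
                      Ca = list(list(op = "msc")))
  steps <- if (sensor == "MIR") {
    c(list(list(op = "moving_average", window = 5L)), tail_step)
  } else {
    c(list(list(op = "baseline_correct"),
           list(op = "compton_normalize"),
           list(op = "moving_average", window = 5L)), tail_step)
  }
  preprocess_spec(steps, sensor = sensor, attribute = attribute)
}

#' @export
print.preprocess_spec <- function(x, ...) {
  ops <- vapply(x$steps, function(s) s$op, character(1))
  cat(sprintf("<preprocess_spec [%s%s]: %s>\n", x$sensor,
              if (!is.null(x$attribute)) paste0("/", x$attribute) else "",
              if (length(ops)) paste(ops, collapse = " -> ") else "identity"))
  invisible(x)
}

apply_step <- function(block, step) {
  fn <- op_registry()[[step$op]]
  args <- step[setdiff(names(step), "op")]
  do.call(fn, c(list(block), args))
}

#' @rdname preprocess_spec
#' @param block spectra block the recipe is fitted to / applied on.
#' @param spec a `preprocess_spec`, or (for `apply_recipe()`) a
#'   `fitted_recipe` returned by `fit_recipe()`.
#' @export
fit_recipe <- function(spec, block) {
  stopifnot(inherits(spec, "preprocess_spec"))
  fitted_steps <- vector("list", length(spec$steps))
  cur <- block
  for (i in seq_along(spec$steps)) {
    st <- spec$steps[[i]]
    if (st$op == "msc" && is.null(st$reference)) {
      st$reference <- colMeans(as_spectra_matrix(cur))
    }
    cur <- apply_step(cur, st)
    fitted_steps[[i]] <- st
  }
  structure(list(steps = fitted_steps, sensor = spec$sensor,
                 attribute = spec$attribute, trained = TRUE),
            class = c("fitted_recipe", "preprocess_spec"))
}

#' @rdname preprocess_spec
#' @export
apply_recipe <- function(block, spec) {
  if (inherits(spec, "fitted_recipe")) {
    cur <- block
    for (st in spec$steps) cur <- apply_step(cur, st)
    return(cur)
  }
  stopifnot(inherits(spec, "preprocess_spec"))
  apply_recipe(block, fit_recipe(spec, block))
}

#' Serialize / deserialize a recipe as JSON
#'
#' Mirrors the arrow notation of a preprocessing chain as a JSON list of
#' steps, so recipes can be stored alongside model outputs.
#'
#' @param spec a `preprocess_spec`.
#' @param path file path.
#' @export
write_recipe <- function(spec, path) {
  stopifnot(inherits(spec, "preprocess_spec"))
  jsonlite::write_json(list(sensor = spec$sensor,
                            attribute = spec$attribute,
                            steps = spec$steps),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  preprocess_spec(obj$steps, sensor = obj$sensor,
                  attribute = obj$attribute)
}
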