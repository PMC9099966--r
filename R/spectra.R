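#' Spectra block container
#'
#' A `spectra_block` holds one sensor's sample-by-channel matrix together
#' with its physical channel axis (wavenumbers in cm^-1 for MIR, energies in
#' keV for XRF) and a block label. The MIR axis is conventionally stored
#' descending (4000 -> 650 cm^-1) and the XRF axis ascending; functions in
#' this package only ever assume strict monotonicity, not a direction.
#'
#' @param values numeric sample x channel matrix (no missing values).
#' @param axis numeric per-channel coordinate, strictly monotonic, length
#'   equal to `ncol(values)`.
#' @param samples character vector of unique sample ids; defaults to the
#'   row names of `values` or `s1, s2, ...`.
#' @param label block name, e.g. `"MIR"` or `"XRF"`.
#' @return an object of class `spectra_block` with fields `values`, `axis`,
#'   `samples`, `label` and (after [concatenate_blocks()]) `boundaries`.
#' @examples
#' b <- spectra_block(matrix(1:6, 2), axis = c(1, 2, 3), label = "toy")
#' n_channels(b)
#' @export
spectra_block <- function(values, axis, samples = NULL, label = "block") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) samples <- rownames(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  samples <- as.character(samples)
  if (length(samples) != nrow(values)) {
    stop("length of 'samples' must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  axis <- as.numeric(axis)
  if (length(axis) != ncol(values)) {
    stop("axis length (", length(axis), ") must equal channel count (",
         ncol(values), ")", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', channel %d (axis %s)",
                 samples[bad[1L]], bad[2L], format(axis[bad[2L]])),
         call. = FALSE)
  }
  if (length(axis) >= 2L) {
    d <- diff(axis)
    if (!(all(d > 0) || all(d < 0))) {
      stop("axis must be strictly monotonic", call. = FALSE)
    }
  }
  rownames(values) <- samples
  structure(list(values = values, axis = axis, samples = samples,
                 label = label, boundaries = NULL),
            class = "spectra_block")
}

#' @export
print.spectra_block <- function(x, ...) {
  cat(sprintf("<spectra_block '%s': %d samples x %d channels, axis %s..%s>\n",
              x$label, nrow(x$values), ncol(x$values),
              format(x$axis[1]), format(x$axis[length(x$axis)])))
  if (!is.null(x$boundaries)) {
    cat("  fused from:",
        paste(sprintf("%s (%d)", names(x$boundaries), x$boundaries),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname spectra_block
#' @param block a `spectra_block`.
#' @export
n_channels <- function(block) ncol(as_spectra_matrix(block))

#' @rdname spectra_block
#' @export
n_samples <- function(block) {
  if (inherits(block, "attribute_table")) return(nrow(block$values))
  nrow(as_spectra_matrix(block))
}

#' Attribute table container
#'
#' Per-sample response matrix for the modeled soil attributes. Sample ids
#' must match the paired spectra blocks exactly (same ids, same order).
#'
#' @param values numeric sample x attribute matrix with attribute names as
#'   column names.
#' @param samples character sample ids (default: row names).
#' @param units named character vector of per-attribute unit strings;
#'   defaults to the conventional units of the seven soil fertility
#'   attributes where the names match.
#' @return object of class `attribute_table`.
#' @export
attribute_table <- function(values, samples = NULL, units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("attribute columns must be named", call. = FALSE)
  }
  if (is.null(samples)) samples <- rownames(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at sample '%s', attribute '%s'",
                 samples[bad[1L]], colnames(values)[bad[2L]]), call. = FALSE)
  }
  default_units <- c(pH = "-", OC = "%", P = "mg/100 g", K = "mg/100 g",
                     Mg = "mg/100 g", Ca = "mg/100 g", MC = "%")
  if (is.null(units)) {
    units <- default_units[colnames(values)]
    units[is.na(units)] <- ""
    names(units) <- colnames(values)
  }
  if (nrow(values) > 0L) rownames(values) <- samples
  structure(list(values = values, samples = samples,
                 names = colnames(values), units = units),
            class = "attribute_table")
}

#' @export
print.attribute_table <- function(x, ...) {
  cat(sprintf("<attribute_table: %d samples x %d attributes (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Read / write spectra blocks as CSV
#'
#' The on-disk format is a plain comma-separated table with a mandatory
#' header row: first column `sample` holds sample ids, remaining column
#' names are the numeric axis values. Decimal separator is `.`. Reading
#' validates numeric content, unique ids and axis monotonicity; writing a
#' block and reading it back reproduces values up to 15 significant digits
#' of decimal text representation.
#'
#' @param path file path.
#' @param label block label to attach on read.
#' @return `read_spectra()` returns a [spectra_block()];
#'   `write_spectra()` invisibly returns `path`.
#' @export
read_spectra <- function(path, label = "block") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus at least one channel",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  raw <- df[-1L]
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      if (is.na(bad)) bad <- which(is.na(col))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad], bad, colnames(raw)[j]), call. = FALSE)
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop(sprintf("missing value at row %d (sample '%s'), column '%s'",
                   bad, ids[bad], colnames(raw)[j]), call. = FALSE)
    }
  }
  axis <- suppressWarnings(as.numeric(colnames(raw)))
  if (anyNA(axis)) {
    stop("header row must contain numeric axis values; offending column: '",
         colnames(raw)[which(is.na(axis))[1L]], "'", call. = FALSE)
  }
  spectra_block(as.matrix(raw), axis = axis, samples = ids, label = label)
}

#' @rdname read_spectra
#' @param block a `spectra_block` to write.
#' @export
write_spectra <- function(block, path) {
  stopifnot(inherits(block, "spectra_block"))
  df <- data.frame(sample = block$samples,
                   block$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample",
                    formatC(block$axis, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write attribute tables as CSV
#'
#' Same CSV dialect as [read_spectra()]: first column `sample`, remaining
#' columns one per attribute.
#'
#' @inheritParams read_spectra
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[-1L])
  if (!is.numeric(vals)) stop("attribute columns must be numeric", call. = FALSE)
  attribute_table(vals, samples = ids)
}

#' @rdname read_attributes
#' @param table an `attribute_table` to write.
#' @export
write_attributes <- function(table, path) {
  stopifnot(inherits(table, "attribute_table"))
  df <- data.frame(sample = table$samples, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concatenate two spectra blocks for low-level fusion
#'
#' Joins the channels of two blocks measured on the same samples into one
#' fused predictor block (e.g. 900 MIR channels + 2048 XRF channels =
#' 2948 fused variables). The physical axes of the two sensors are not
#' commensurable, so the fused block carries a plain channel-index axis and
#' records the per-block channel counts in `boundaries` so downstream
#' variable-importance reporting can be split back per sensor.
#'
#' @param block1,block2 [spectra_block()] objects with identical sample ids
#'   in identical order.
#' @param label label for the fused block.
#' @return a `spectra_block`; if one input has zero channels the other is
#'   returned unchanged.
#' @export
concatenate_blocks <- function(block1, block2,
                               label = paste(block1$label, block2$label,
                                             sep = "+")) {
  stopifnot(inherits(block1, "spectra_block"),
            inherits(block2, "spectra_block"))
  if (n_channels(block2) == 0L) return(block1)
  if (n_channels(block1) == 0L) return(block2)
  if (!identical(block1$samples, block2$samples)) {
    off <- union(setdiff(block1$samples, block2$samples),
                 setdiff(block2$samples, block1$samples))
    if (length(off) == 0L) off <- "(same ids, different order)"
    stop("sample ids do not match between blocks: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  values <- cbind(block1$values, block2$values)
  out <- spectra_block(values, axis = seq_len(ncol(values)),
                       samples = block1$samples, label = label)
  b1 <- if (is.null(block1$boundaries)) {
    stats::setNames(n_channels(block1), block1$label)
  } else block1$boundaries
  b2 <- if (is.null(block2$boundaries)) {
    stats::setNames(n_channels(block2), block2$label)
  } else block2$boundaries
  out$boundaries <- c(b1, b2)
  out$channel_axes <- c(
    if (is.null(block1$channel_axes)) stats::setNames(list(block1$axis), block1$label) else block1$channel_axes,
    if (is.null(block2$channel_axes)) stats::setNames(list(block2$axis), block2$label) else block2$channel_axes)
  out
}

#' @rdname concatenate_blocks
#' @param block a fused `spectra_block`.
#' @return `block_boundaries()` returns the named integer vector of
#'   per-sensor channel counts (a single entry for an unfused block).
#' @export
block_boundaries <- function(block) {
  stopifnot(inherits(block, "spectra_block"))
  if (is.null(block$boundaries)) {
    return(stats::setNames(n_channels(block), block$label))
  }
  block$boundaries
}

#' Subset channels of a block
#'
#' @param block a `spectra_block`.
#' @param keep logical or integer channel selector.
#' @return a `spectra_block` restricted to the kept channels.
#' @export
subset_channels <- function(block, keep) {
  stopifnot(inherits(block, "spectra_block"))
  vals <- block$values[, keep, drop = FALSE]
  spectra_block(vals, axis = block$axis[keep], samples = block$samples,
                label = block$label)
}
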