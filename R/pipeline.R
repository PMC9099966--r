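#' Configuration of a five-model comparison run
#'
#' Bundles everything [run_comparison()] needs: the data source (a
#' [synth_config()] or paths to MIR/XRF/attribute CSV files), the split
#' fraction, cross-validation controls, component-count caps, the VIP
#' threshold and a master seed from which all per-attribute sub-seeds are
#' derived deterministically.
#'
#' @param synth a [synth_config()], or `NULL` when reading from files.
#' @param mir_path,xrf_path,attr_path CSV paths (used when `synth` is
#'   `NULL`).
#' @param attributes attribute names to model (default: all available).
#' @param split_fraction Kennard-Stone training fraction (default 0.8).
#' @param folds CV folds (default 10).
#' @param max_lv component cap for single-block and concatenated PLS
#'   (default 15).
#' @param max_a1,max_a2 SOPLS grid bounds (default 8 each).
#' @param vip_threshold VIP selection cutoff (default 1).
#' @param seed master seed.
#' @param output_dir optional directory for report, masks, split, config
#'   and log files.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       mir_path = NULL, xrf_path = NULL, attr_path = NULL,
                       attributes = NULL,
                       split_fraction = 0.8, folds = 10L, max_lv = 15L,
                       max_a1 = 8L, max_a2 = 8L, vip_threshold = 1,
                       seed = 1L, output_dir = NULL) {
  if (is.null(synth) &&
      (is.null(mir_path) || is.null(xrf_path) || is.null(attr_path))) {
    stop("either 'synth' or all three input paths must be given",
         call. = FALSE)
  }
  check_scalar_number(split_fraction, "split_fraction")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("'split_fraction' must be in (0, 1)", call. = FALSE)
  }
  check_scalar_number(folds, "folds", min = 2)
  check_scalar_number(max_lv, "max_lv", min = 1)
  check_scalar_number(max_a1, "max_a1", min = 0)
  check_scalar_number(max_a2, "max_a2", min = 0)
  check_scalar_number(vip_threshold, "vip_threshold", min = 0)
  check_scalar_number(seed, "seed")
  structure(list(synth = synth, mir_path = mir_path, xrf_path = xrf_path,
                 attr_path = attr_path, attributes = attributes,
                 split_fraction = split_fraction, folds = as.integer(folds),
                 max_lv = as.integer(max_lv), max_a1 = as.integer(max_a1),
                 max_a2 = as.integer(max_a2),
                 vip_threshold = vip_threshold, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

model_roster <- function() {
  c("MIR-TPLS", "XRF-TPLS", "SF-PLS", "SF-SOPLS", "SF-VIP-SOPLS")
}

#' Run the five-model comparison
#'
#' End-to-end harness over one dataset: generate (or read) paired MIR/XRF
#' spectra and attributes; compute a single shared Kennard-Stone split on a
#' reference preprocessing of the fused spectra (the per-spectrum pH
#' recipes, which learn nothing from data); then, per attribute, apply the
#' per-sensor preprocessing recipe (training-set statistics frozen and
#' reused on the test set), and fit and evaluate five model families on
#' the same split: PLS on MIR alone, PLS on XRF alone, PLS on the
#' concatenated spectra, SOPLS (MIR first, XRF second), and VIP-filtered
#' SOPLS. Cross-validated metrics are reported on the training set and
#' prediction metrics on the held-out test set.
#'
#' The run is a deterministic function of the configuration: rerunning
#' with the same `run_config` reproduces the report bit-identically.
#'
#' @param config a [run_config()].
#' @return object of class `sf_comparison`: `report` (one row per
#'   attribute x model with R2cv, RMSECV, RPDcv, R2p, RMSEP, RPDp, RPIQp,
#'   chosen component counts and variable counts), `split`, `models`
#'   (nested per attribute), `dataset`, and the `config`. If
#'   `config$output_dir` is set, the report, split, per-attribute VIP
#'   masks, resolved configuration and a stage log are also written there.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (!is.null(config$synth)) {
    say("stage data: generating synthetic dataset (seed %d)",
        config$synth$seed)
    dataset <- generate_soil_data(config$synth)
    mir <- dataset$mir; xrf <- dataset$xrf; attrs <- dataset$attributes
  } else {
    say("stage data: reading %s / %s / %s", config$mir_path,
        config$xrf_path, config$attr_path)
    dataset <- NULL
    mir <- read_spectra(config$mir_path, label = "MIR")
    xrf <- read_spectra(config$xrf_path, label = "XRF")
    attrs <- read_attributes(config$attr_path)
    if (!identical(mir$samples, xrf$samples) ||
        !identical(mir$samples, attrs$samples)) {
      stop("sample ids differ across input tables", call. = FALSE)
    }
  }
  attributes <- config$attributes %||%
    intersect(c("pH", "OC", "P", "K", "Mg", "Ca", "MC"), attrs$names)
  if (length(attributes) == 0L) attributes <- attrs$names

  # shared split: reference preprocessing uses only per-spectrum operators
  say("stage split: Kennard-Stone at fraction %g", config$split_fraction)
  ref_mir <- apply_recipe(mir, recipe_preset("MIR", "pH"))
  ref_xrf <- apply_recipe(xrf, xrf_reference_recipe(xrf))
  fused_ref <- concatenate_blocks(ref_mir, ref_xrf)
  split <- kennard_stone(fused_ref, fraction = config$split_fraction)
  tr <- split$train_idx; te <- split$test_idx
  say("  train %d / test %d", length(tr), length(te))

  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    length(attributes)))
  report <- list(); models <- list()
  for (ai in seq_along(attributes)) {
    attr_name <- attributes[ai]
    seed_a <- sub_seeds[ai]
    say("stage model [%s]: preprocessing + five models (sub-seed %d)",
        attr_name, seed_a)
    y <- attrs$values[, attr_name]
    y_tr <- y[tr]; y_te <- y[te]

    prep <- preprocess_attribute(mir, xrf, attr_name, tr, te)
    res <- fit_five_models(prep, y_tr, y_te, config, seed_a)
    for (row in res$rows) {
      row$attribute <- attr_name
      report[[length(report) + 1L]] <- row
    }
    models[[attr_name]] <- res$models
    say("  chosen LVs: MIR %d, XRF %d, SF %d, SOPLS (%d, %d), VIP-SOPLS (%d, %d) on %d vars",
        res$models$mir$cv$n_lv, res$models$xrf$cv$n_lv,
        res$models$sf$cv$n_lv, res$models$sopls$grid$a1,
        res$models$sopls$grid$a2, res$models$vip$model$a1,
        res$models$vip$model$a2, res$models$vip$selection$n_selected_total)
  }

  report <- do.call(rbind, lapply(report, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  report <- report[, c("attribute", "model", "R2cv", "RMSECV", "RPDcv",
                       "R2p", "RMSEP", "RPDp", "RPIQp", "n_lv1", "n_lv2",
                       "n_train", "n_test", "variables")]
  rownames(report) <- NULL

  out <- structure(list(report = report, split = split, models = models,
                        dataset = dataset, config = config,
                        log = log_lines),
                   class = "sf_comparison")
  if (!is.null(config$output_dir)) write_comparison(out, config$output_dir)
  out
}

# XRF reference recipe with a Compton window adapted to the axis range, so
# small simulated axes (e.g. tests ending below 22 keV) remain valid.
xrf_reference_recipe <- function(xrf) {
  rng <- range(xrf$axis)
  win <- c(18, 22)
  if (win[1] < rng[1] || win[2] > rng[2]) {
    win <- rng[1] + c(0.6, 0.8) * diff(rng)
  }
  preprocess_spec(list(list(op = "baseline_correct"),
                       list(op = "compton_normalize", window = win),
                       list(op = "moving_average", window = 5L),
                       list(op = "max_normalize")),
                  sensor = "XRF", attribute = "reference")
}

# Fit recipes on the training partition, apply to train and test, and
# return the per-block and fused matrices.
preprocess_attribute <- function(mir, xrf, attr_name, tr, te) {
  mir_tr <- subset_samples(mir, tr); mir_te <- subset_samples(mir, te)
  xrf_tr <- subset_samples(xrf, tr); xrf_te <- subset_samples(xrf, te)
  spec_mir <- recipe_preset("MIR", attr_name)
  spec_xrf <- recipe_preset("XRF", attr_name)
  # adapt the Compton window if the simulated axis does not reach 22 keV
  rng <- range(xrf$axis)
  if (rng[2] < 22 || rng[1] > 18) {
    win <- rng[1] + c(0.6, 0.8) * diff(rng)
    spec_xrf$steps <- lapply(spec_xrf$steps, function(st) {
      if (st$op == "compton_normalize") st$window <- win
      st
    })
  }
  fit_m <- fit_recipe(spec_mir, mir_tr)
  fit_x <- fit_recipe(spec_xrf, xrf_tr)
  X1_tr <- apply_recipe(mir_tr, fit_m); X1_te <- apply_recipe(mir_te, fit_m)
  X2_tr <- apply_recipe(xrf_tr, fit_x); X2_te <- apply_recipe(xrf_te, fit_x)
  list(X1_tr = X1_tr$values, X1_te = X1_te$values,
       X2_tr = X2_tr$values, X2_te = X2_te$values,
       Xf_tr = cbind(X1_tr$values, X2_tr$values),
       Xf_te = cbind(X1_te$values, X2_te$values))
}

subset_samples <- function(block, idx) {
  spectra_block(block$values[idx, , drop = FALSE], axis = block$axis,
                samples = block$samples[idx], label = block$label)
}

eval_row <- function(model_name, y_tr, y_te, cv_rmse, cv_r2, pred_te,
                     n_lv1, n_lv2, variables) {
  list(model = model_name,
       R2cv = cv_r2, RMSECV = cv_rmse,
       RPDcv = stats::sd(y_tr) / cv_rmse,
       R2p = r_squared(y_te, pred_te), RMSEP = rmse(y_te, pred_te),
       RPDp = rpd(y_te, pred_te), RPIQp = rpiq(y_te, pred_te),
       n_lv1 = n_lv1, n_lv2 = n_lv2,
       n_train = length(y_tr), n_test = length(y_te),
       variables = variables)
}

fit_five_models <- function(prep, y_tr, y_te, config, seed_a) {
  rows <- list(); models <- list()

  tpls <- function(Xtr, Xte, name) {
    cv <- select_lv(Xtr, y_tr, max_lv = config$max_lv,
                    folds = config$folds, seed = seed_a)
    m <- fit_pls(Xtr, y_tr, n_lv = cv$n_lv)
    pred <- predict(m, Xte)
    list(row = eval_row(name, y_tr, y_te, cv$rmsecv[cv$n_lv],
                        cv$r2cv[cv$n_lv], pred, cv$n_lv, NA_integer_,
                        ncol(Xtr)),
         fit = list(cv = cv, model = m, pred = pred))
  }
  r <- tpls(prep$X1_tr, prep$X1_te, "MIR-TPLS")
  rows$mir <- r$row; models$mir <- r$fit
  r <- tpls(prep$X2_tr, prep$X2_te, "XRF-TPLS")
  rows$xrf <- r$row; models$xrf <- r$fit
  r <- tpls(prep$Xf_tr, prep$Xf_te, "SF-PLS")
  rows$sf <- r$row; models$sf <- r$fit

  grid <- sopls_select_lv(prep$X1_tr, prep$X2_tr, y_tr,
                          max_a1 = config$max_a1, max_a2 = config$max_a2,
                          folds = config$folds, seed = seed_a)
  ms <- fit_sopls(prep$X1_tr, prep$X2_tr, y_tr, a1 = grid$a1, a2 = grid$a2)
  pred <- predict(ms, prep$X1_te, prep$X2_te)
  rows$sopls <- eval_row("SF-SOPLS", y_tr, y_te,
                         grid$rmsecv[grid$a1 + 1L, grid$a2 + 1L],
                         grid$r2cv[grid$a1 + 1L, grid$a2 + 1L],
                         pred, grid$a1, grid$a2,
                         ncol(prep$X1_tr) + ncol(prep$X2_tr))
  models$sopls <- list(grid = grid, model = ms, pred = pred)

  mv <- fit_sf_vip_sopls(prep$X1_tr, prep$X2_tr, y_tr,
                         max_lv = config$max_lv, max_a1 = config$max_a1,
                         max_a2 = config$max_a2, folds = config$folds,
                         seed = seed_a, threshold = config$vip_threshold)
  pred <- predict(mv, prep$X1_te, prep$X2_te)
  rows$vip <- eval_row("SF-VIP-SOPLS", y_tr, y_te,
                       mv$grid$rmsecv[mv$model$a1 + 1L, mv$model$a2 + 1L],
                       mv$grid$r2cv[mv$model$a1 + 1L, mv$model$a2 + 1L],
                       pred, mv$model$a1, mv$model$a2,
                       mv$selection$n_selected_total)
  models$vip <- mv
  models$vip_pred <- pred

  list(rows = rows, models = models)
}

#' @export
print.sf_comparison <- function(x, ...) {
  cat(sprintf("<sf_comparison: %d attributes x %d models>\n",
              length(unique(x$report$attribute)),
              length(unique(x$report$model))))
  print(x$report, digits = 3)
  invisible(x)
}

write_comparison <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$report, file.path(dir, "eval_report.csv"),
                   row.names = FALSE)
  write_split(out$split, file.path(dir, "split.csv"))
  cfg <- out$config
  cfg$output_dir <- NULL
  jsonlite::write_json(
    list(config = unclass_deep(cfg),
         package_version = as.character(utils::packageVersion("specfusion"))),
    file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  for (attr_name in names(out$models)) {
    mv <- out$models[[attr_name]]$vip
    write_vip(mv$vip1, file.path(dir, sprintf("vip_%s_block1.csv",
                                              attr_name)))
    write_vip(mv$vip2, file.path(dir, sprintf("vip_%s_block2.csv",
                                              attr_name)))
  }
  writeLines(out$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Read back an evaluation report written by [run_comparison()]
#'
#' @param path CSV path.
#' @export
read_eval_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
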