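# End-to-end benchmark pipeline: structures -> charged conformers ->
# core alignment -> shared lattice -> fields -> column filter -> PLS ->
# internal / external validation, with optional region focusing.

.split_col <- function(model) {
  switch(model, comfa = "comfa_split", comfa_rf = "comfarf_split",
         comsia = "comsia_split")
}

#' Row subset of a field matrix
#' @param fm A `qsar_field_matrix`.
#' @param rows Row indices or names.
#' @return The subsetted `qsar_field_matrix` (mask and metadata shared).
#' @export
fm_subset <- function(fm, rows) {
  fm$values <- fm$values[rows, , drop = FALSE]
  fm
}

#' Grid-frame orientation of the aligned benchmark aggregate
#'
#' Runs the all-orientation search on the full aligned series (the
#' activity-weighted objective is the LOO q2 of the whole data set, the
#' convention of orienting before splitting) and returns the winning
#' orientation, reusable across model flavours via the `orientation`
#' argument of [run_benchmark_pipeline()].
#'
#' @param mols Embedded benchmark molecules.
#' @param bench Benchmark table.
#' @param config A [qsar_config()]; `config$alignment$aos_step` sets the
#'   Euler step.
#' @return A `qsar_orientation`.
#' @export
benchmark_orientation <- function(mols, bench = load_benchmark(),
                                  config = qsar_config()) {
  aligned <- align_benchmark(mols, bench, template_id = config$alignment$template_id)
  orientation_search(aligned, bench$pki,
                     step_degrees = config$alignment$aos_step,
                     config = config, method = "comfa")
}

# Iterated region focusing on the training block: each round derives
# sd x |coef| weights from a training fit, grid-searches the exponent by
# training LOO q2 and keeps the reweighted matrix only while it improves.
.focus_iterate <- function(fm, idx_train, y, config, ncomp) {
  fm_train <- fm_subset(fm, idx_train)
  q2_cur <- loo_q2(fm_train, y[idx_train], ncomp)$q2
  scan <- data.frame(round = 0L, exponent = NA_real_, q2 = q2_cur)
  exponent <- NA_real_
  for (round in seq_len(config$pls$focus_rounds)) {
    base_fit <- fit_pls(fm_train, y[idx_train], ncomp)
    contrib <- base_fit$column_sd * abs(base_fit$coefficients)
    w_base <- if (max(contrib) > 0) contrib / max(contrib) else contrib
    best_q <- -Inf; best_fm <- NULL; best_e <- NA_real_
    for (e in config$pls$focus_exponents) {
      w <- w_base^e
      f_all <- fm
      active <- which(f_all$mask)
      f_all$values[, active] <- sweep(f_all$values[, active, drop = FALSE],
                                      2, w, "*")
      f_all$focus_weights[active] <- f_all$focus_weights[active] * w
      q2_e <- loo_q2(fm_subset(f_all, idx_train), y[idx_train], ncomp)$q2
      if (q2_e > best_q) { best_q <- q2_e; best_fm <- f_all; best_e <- e }
    }
    scan <- rbind(scan, data.frame(round = round, exponent = best_e, q2 = best_q))
    if (best_q <= q2_cur) break
    q2_cur <- best_q
    exponent <- best_e
    fm <- best_fm
    fm_train <- fm_subset(fm, idx_train)
  }
  list(fm = fm, q2 = q2_cur, exponent = exponent, scan = scan)
}

.apply_orientation <- function(mols, orientation) {
  centroid <- colMeans(do.call(rbind, lapply(mols, mol_coords)))
  r <- orientation$rotation
  lapply(mols, function(m) {
    xyz <- mol_coords(m)
    mol_set_coords(m, sweep(sweep(xyz, 2, centroid) %*% t(r), 2, centroid, "+"))
  })
}

#' Run the full 3D-QSAR pipeline on the packaged benchmark
#'
#' Embeds the 41 inhibitors, aligns them on the conserved
#' benzenesulfonamide-pyrazole core of the most active compound, computes
#' the lattice fields for the requested model flavour, filters columns on
#' the training compounds, fits the latent-variable model and reports the
#' full statistics table: LOO q2, non-cross-validated r2, SEE, F,
#' RMSEC/RMSEP, predictive r2 on the published test and validation splits,
#' Golbraikh-Tropsha diagnostics, per-field fractions and contour sets.
#' For `model = "comfa_rf"` the lattice columns are re-weighted by region
#' focusing, the exponent chosen from `config$pls$focus_exponents` by LOO
#' q2 on the training set.
#'
#' @param model `"comfa"`, `"comfa_rf"` or `"comsia"` (selects both the
#'   field flavour and the published split assignment).
#' @param config A [qsar_config()].
#' @param bench Benchmark table ([load_benchmark()]).
#' @param mols Optional pre-embedded molecule list (skips embedding).
#' @param orientation Optional precomputed [benchmark_orientation()]; by
#'   default one is computed when `config$alignment$aos_step > 0`.
#' @return A `qsar_benchmark_fit` list with the fitted model, field
#'   matrix, statistics and contours.
#' @export
run_benchmark_pipeline <- function(model = c("comfa", "comfa_rf", "comsia"),
                                   config = qsar_config(),
                                   bench = load_benchmark(), mols = NULL,
                                   orientation = NULL) {
  model <- match.arg(model)
  method <- if (model == "comsia") "comsia" else "comfa"
  if (is.null(mols)) mols <- embed_benchmark(bench, seed = config$seeds$embed)
  aligned <- align_benchmark(mols, bench, template_id = config$alignment$template_id)

  split <- bench[[.split_col(model)]]
  idx_train <- which(split == "train")
  idx_test <- which(split == "test")
  idx_val <- which(split == "validation")
  y <- bench$pki

  ncomp <- config$pls$n_components
  prepare <- function(mset) {
    grid <- make_grid(mset, config$grid$spacing, config$grid$margin)
    fm <- compute_field_matrix(mset, grid, method = method, config = config)
    ft <- column_filter(fm_subset(fm, idx_train),
                        config$grid$column_filter_threshold)
    fm$mask <- ft$mask
    fm <- block_scale(fm, rows = idx_train)
    list(fm = fm, grid = grid)
  }

  if (is.null(orientation) && config$alignment$aos_step > 0) {
    # grid-frame orientation tuned by LOO q2 on the training compounds
    # only, so the scan never sees held-out activities
    orientation <- orientation_search(aligned[idx_train], y[idx_train],
                                      step_degrees = config$alignment$aos_step,
                                      config = config, method = method)
  }

  focus_exponent <- NA_real_
  focus_scan <- NULL
  if (model == "comfa_rf" && inherits(orientation, "qsar_orientation")) {
    # region focusing interacts with the lattice frame, so the frame is
    # chosen by the focused model's own internal validation: shortlist
    # the orientations with the best unfocused training q2, focus each,
    # keep the one whose focused q2 is highest
    k_short <- min(5L, nrow(orientation$scan))
    shortlist <- order(-orientation$scan$objective)[seq_len(k_short)]
    best <- NULL
    for (k in shortlist) {
      ori_k <- orientation
      ori_k$rotation <- orientation$rotations[[k]]
      cand_aligned <- .apply_orientation(aligned, ori_k)
      prep <- prepare(cand_aligned)
      foc <- .focus_iterate(prep$fm, idx_train, y, config, ncomp)
      if (is.null(best) || foc$q2 > best$foc$q2) {
        best <- list(ori = ori_k, aligned = cand_aligned, prep = prep, foc = foc)
      }
    }
    orientation <- best$ori
    aligned <- best$aligned
    grid <- best$prep$grid
    fm <- best$foc$fm
    focus_exponent <- best$foc$exponent
    focus_scan <- best$foc$scan
  } else {
    if (!is.null(orientation)) aligned <- .apply_orientation(aligned, orientation)
    prep <- prepare(aligned)
    grid <- prep$grid
    fm <- prep$fm
    if (model == "comfa_rf") {
      foc <- .focus_iterate(fm, idx_train, y, config, ncomp)
      fm <- foc$fm
      focus_exponent <- foc$exponent
      focus_scan <- foc$scan
    }
  }
  fm_train <- fm_subset(fm, idx_train)

  fit <- fit_pls(fm_train, y[idx_train], ncomp)
  cv <- loo_q2(fm_train, y[idx_train], ncomp)
  stats <- summary_statistics(fit, fm_train, y[idx_train])
  fractions <- field_fractions(fit)

  pred_test <- predict(fit, fm_subset(fm, idx_test))
  ext_test <- external_validate(pred_test, y[idx_test],
                                training_mean = mean(y[idx_train]))
  ext_val <- if (length(idx_val) >= 3L) {
    external_validate(predict(fit, fm_subset(fm, idx_val)), y[idx_val],
                      training_mean = mean(y[idx_train]))
  } else NULL

  contours <- extract_contours(fit, fm)

  structure(list(
    model = model, method = method, config = config,
    n_components = fit$n_components,
    q2 = cv$q2, rmsec = cv$rmsec, loo_predictions = cv$predictions,
    r2_ncv = stats$r2_ncv, see = stats$see, f_value = stats$f_value,
    rmsec_train = stats$rmsec_train,
    rmsep = ext_test$rmsep, r2_pred_test = ext_test$r2_pred,
    r2_pred_validation = if (!is.null(ext_val)) ext_val$r2_pred else NA_real_,
    gt = ext_test[c("gt_ratio", "gt_ratio_prime", "k", "k_prime", "gt_pass")],
    fractions = fractions, contours = contours, orientation = orientation,
    focus_exponent = focus_exponent, focus_scan = focus_scan,
    splits = list(train = idx_train, test = idx_test, validation = idx_val),
    fit = fit, field_matrix = fm, grid = grid, mols = aligned, y = y
  ), class = "qsar_benchmark_fit")
}

#' @export
print.qsar_benchmark_fit <- function(x, ...) {
  cat("<qsar_benchmark_fit> ", toupper(x$model), " (", x$n_components,
      " components)\n", sep = "")
  cat(sprintf("  q2 (LOO)          %.3f\n", x$q2))
  cat(sprintf("  r2 (ncv)          %.3f\n", x$r2_ncv))
  cat(sprintf("  SEE               %.3f\n", x$see))
  cat(sprintf("  F                 %.3f\n", x$f_value))
  cat(sprintf("  RMSEP (test)      %.3f\n", x$rmsep))
  cat(sprintf("  r2_pred (test)    %.3f\n", x$r2_pred_test))
  if (is.finite(x$r2_pred_validation)) {
    cat(sprintf("  r2_pred (valid.)  %.3f\n", x$r2_pred_validation))
  }
  if (is.finite(x$focus_exponent)) {
    cat(sprintf("  focus exponent    %.1f\n", x$focus_exponent))
  }
  cat("  field fractions   ",
      paste(sprintf("%s %.3f", names(x$fractions), x$fractions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Recompute the published external-validation arithmetic
#'
#' Runs [external_validate()] on the packaged published predicted /
#' experimental activities for the requested model's test or validation
#' split -- the desk-reproducible part of the published statistics table.
#'
#' @param model `"comfa"`, `"comfa_rf"` or `"comsia"`.
#' @param split `"test"` or `"validation"`.
#' @return The [external_validate()] statistics list.
#' @export
published_external_stats <- function(model = c("comfa", "comfa_rf", "comsia"),
                                     split = c("test", "validation")) {
  model <- match.arg(model); split <- match.arg(split)
  bench <- load_benchmark()
  preds <- load_published_predictions()
  stopifnot(identical(bench$compound_id, preds$compound_id))
  rows <- bench[[.split_col(model)]] == split
  pred_col <- paste0("pred_", sub("_", "", model))
  external_validate(preds[[pred_col]][rows], preds$pki[rows])
}
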