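# Partial least squares (PLS1, NIPALS) on lattice-field descriptors, with
# leave-one-out cross-validation, external (test/validation) statistics
# including the Golbraikh-Tropsha through-origin criteria, per-field
# contribution fractions and favoured/disfavoured contour extraction.

.as_x <- function(X) {
  if (inherits(X, "qsar_field_matrix")) field_values(X) else as.matrix(X)
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares for a single response on column-centred
#' (not variance-scaled) descriptors, the convention of lattice-field
#' QSAR.  Deterministic; component extraction stops early if the residual
#' covariance vanishes.
#'
#' @param X Descriptor matrix or `qsar_field_matrix` (active columns used).
#' @param y Activity vector.
#' @param n_components Number of latent variables (study setting: 3).
#' @return A `qsar_pls` model: weights, loadings, `coefficients` (in
#'   activity units per descriptor unit, over active columns), intercept,
#'   fitted values and column metadata when available.
#' @export
fit_pls <- function(X, y, n_components = 3L) {
  meta <- if (inherits(X, "qsar_field_matrix")) X$meta[X$mask, , drop = FALSE] else NULL
  X <- .as_x(X)
  n_components <- as.integer(n_components)
  if (ncol(X) == 0L) stop("no active descriptor columns to fit")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (sd(y) == 0) stop("zero-variance activity vector")
  if (n_components < 1L) stop("n_components must be >= 1")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  qv <- numeric(n_components)
  used <- 0L
  for (h in seq_len(n_components)) {
    wh <- crossprod(E, f)
    nw <- sqrt(sum(wh^2))
    if (nw < 1e-12) break
    wh <- wh / nw
    t_h <- E %*% wh
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    ph <- crossprod(E, t_h) / tt
    qh <- sum(f * t_h) / tt
    E <- E - t_h %*% t(ph)
    f <- f - qh * t_h
    W[, h] <- wh; P[, h] <- ph; qv[h] <- qh
    used <- h
  }
  if (used == 0L) stop("PLS extracted no components (degenerate descriptors)")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  beta <- W %*% solve(crossprod(P, W), qv)
  fitted <- as.vector(sweep(X, 2, x_center) %*% beta) + y_center
  structure(list(n_components = used, x_center = x_center, y_center = y_center,
                 x_weights = W, x_loadings = P, y_loadings = qv,
                 coefficients = as.vector(beta),
                 intercept = y_center - sum(x_center * beta),
                 fitted = fitted, column_sd = apply(X, 2, sd), meta = meta),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat("<qsar_pls> ", x$n_components, " component(s), ",
      length(x$coefficients), " descriptor columns\n", sep = "")
  invisible(x)
}

#' Predict activities from a fitted PLS model
#' @param object A `qsar_pls`.
#' @param newdata Matrix or `qsar_field_matrix` over the same active columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.qsar_pls <- function(object, newdata, ...) {
  X <- .as_x(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$coefficients))
  }
  as.vector(X %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validation
#'
#' Refits the full centring + PLS pipeline on every size n-1 subset and
#' predicts the held-out compound; the column filter mask is fixed once on
#' the full matrix, outside the loop.  `q2 = 1 - PRESS / sum((y - ybar)^2)`
#' with `ybar` the full-set mean.  The cross-validated RMSE
#' (`rmsec = sqrt(PRESS/n)`) is reported alongside.
#'
#' @inheritParams fit_pls
#' @return List: `q2`, `press`, `rmsec`, `predictions`.
#' @export
loo_q2 <- function(X, y, n_components = 3L) {
  X <- .as_x(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  if (n_components >= n - 1L) stop("n_components must be < n - 1 for LOO")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components)
    pred[i] <- predict(m, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  list(q2 = q2, press = press, rmsec = sqrt(press / n), predictions = pred)
}

#' Choose the number of latent variables
#'
#' Argmax of leave-one-out q2 over `1..max_components`; exact ties resolve
#' to the fewest components.
#'
#' @inheritParams fit_pls
#' @param max_components Upper bound of the scan.
#' @return Integer component count.
#' @export
select_components <- function(X, y, max_components = 6L) {
  stopifnot(max_components >= 1L)
  q2 <- vapply(seq_len(max_components), function(a) loo_q2(X, y, a)$q2, numeric(1))
  which.max(q2)
}

#' External validation statistics
#'
#' Test/validation-set predictivity: RMSEP, predictive r2 (squared Pearson
#' correlation of predicted vs observed) and the Golbraikh-Tropsha
#' through-origin diagnostics.  `R0^2` regresses observed on predicted
#' through the origin (slope `K`), `R0'^2` the reverse (slope `K'`);
#' the acceptance rule is `(R^2 - R0^2)/R^2 < 0.1` (either direction) and
#' `0.85 <= K <= 1.15` (either slope).
#'
#' @param predicted,observed Equal-length activity vectors (n >= 3).
#' @param training_mean Optional training-set mean; when given, the
#'   `q2_external` variant `1 - PRESS/sum((y - training_mean)^2)` is also
#'   reported.
#' @return List of statistics (`rmsep`, `r2_pred`, `r0sq`, `r0sq_prime`,
#'   `k`, `k_prime`, `gt_ratio`, `gt_ratio_prime`, `gt_pass`, optionally
#'   `q2_external`).
#' @export
external_validate <- function(predicted, observed, training_mean = NULL) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3L)
  if (sd(predicted) == 0 || sd(observed) == 0) {
    stop("zero variance in predicted or observed values")
  }
  rmsep <- sqrt(mean((observed - predicted)^2))
  r2 <- cor(predicted, observed)^2
  k <- sum(observed * predicted) / sum(predicted^2)
  k_prime <- sum(observed * predicted) / sum(observed^2)
  r0sq <- 1 - sum((observed - k * predicted)^2) / sum((observed - mean(observed))^2)
  r0sq_prime <- 1 - sum((predicted - k_prime * observed)^2) /
    sum((predicted - mean(predicted))^2)
  gt_ratio <- (r2 - r0sq) / r2
  gt_ratio_prime <- (r2 - r0sq_prime) / r2
  out <- list(rmsep = rmsep, r2_pred = r2, r0sq = r0sq, r0sq_prime = r0sq_prime,
              k = k, k_prime = k_prime, gt_ratio = gt_ratio,
              gt_ratio_prime = gt_ratio_prime,
              gt_pass = (gt_ratio < 0.1 || gt_ratio_prime < 0.1) &&
                ((k >= 0.85 && k <= 1.15) || (k_prime >= 0.85 && k_prime <= 1.15)))
  if (!is.null(training_mean)) {
    out$q2_external <- 1 - sum((observed - predicted)^2) /
      sum((observed - training_mean)^2)
  }
  out
}

#' Training-set summary statistics
#'
#' Non-cross-validated r2, standard error of estimate
#' `SEE = sqrt(RSS/(n - c - 1))` and Fisher ratio
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))` with `c` latent variables; the
#' plain training RMSE is reported as `rmsec_train`.  A perfect fit
#' returns `SEE = 0`, `F = Inf`.
#'
#' @param model Fitted `qsar_pls`.
#' @param X Training descriptors (matrix or `qsar_field_matrix`).
#' @param y Training activities.
#' @return List: `r2_ncv`, `see`, `f_value`, `rmsec_train`, `n`, `c`.
#' @export
summary_statistics <- function(model, X, y) {
  X <- .as_x(X)
  n <- nrow(X); cc <- model$n_components
  if (n <= cc + 1L) stop("need n > n_components + 1 for SEE/F")
  yhat <- predict(model, X)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  see <- sqrt(rss / (n - cc - 1))
  f <- if (rss < 1e-14) Inf else (r2 / cc) / ((1 - r2) / (n - cc - 1))
  list(r2_ncv = r2, see = see, f_value = f, rmsec_train = sqrt(rss / n),
       n = n, c = cc)
}

#' Per-field contribution fractions
#'
#' Share of each field kind in the model: `sum(sd_j * |coef_j|)` over that
#' kind's columns divided by the total.  Fractions sum to 1.
#'
#' @param model Fitted `qsar_pls` carrying column metadata (fitted on a
#'   `qsar_field_matrix`), or supply `kinds`.
#' @param kinds Optional character vector of per-column kinds.
#' @return Named numeric vector of fractions.
#' @export
field_fractions <- function(model, kinds = NULL) {
  if (is.null(kinds)) {
    if (is.null(model$meta)) stop("model carries no column metadata; pass `kinds`")
    kinds <- model$meta$kind
  }
  contrib <- model$column_sd * abs(model$coefficients)
  total <- sum(contrib)
  if (total == 0) {
    u <- sort(unique(kinds))
    return(setNames(rep(0, length(u)), u))
  }
  out <- tapply(contrib, kinds, sum) / total
  setNames(as.numeric(out), names(out))
}

#' Extract favoured / disfavoured contour point sets
#'
#' Ranks the active lattice columns of each field kind by their signed
#' contribution `sd_j * coef_j`; the favoured set is the smallest set of
#' positive-contribution points covering `favored_level` percent of the
#' total positive contribution, the disfavoured set the analogue on the
#' negative side at `disfavored_level` percent (the display convention:
#' 80% / 20%).
#'
#' @param model Fitted `qsar_pls` with column metadata.
#' @param fm The `qsar_field_matrix` the model was fitted on (supplies the
#'   lattice frame).
#' @param favored_level,disfavored_level Coverage percentages.
#' @return A `qsar_contours` object: per-kind `favored` / `disfavored`
#'   point tables (lattice indices, coordinates, contribution share),
#'   sorted by descending contribution.
#' @export
extract_contours <- function(model, fm, favored_level = 80, disfavored_level = 20) {
  stopifnot(inherits(fm, "qsar_field_matrix"))
  meta <- fm$meta[fm$mask, , drop = FALSE]
  if (nrow(meta) != length(model$coefficients)) {
    stop("model does not match the matrix's active columns")
  }
  contrib <- model$column_sd * model$coefficients
  sets <- list()
  pick <- function(vals, rows, cols, level) {
    if (!length(vals) || sum(vals) <= 0) {
      return(data.frame(column = integer(), ix = integer(), iy = integer(),
                        iz = integer(), x = numeric(), y = numeric(),
                        z = numeric(), contribution = numeric()))
    }
    ord <- order(vals, decreasing = TRUE)
    cum <- cumsum(vals[ord]) / sum(vals)
    keep <- ord[seq_len(which(cum >= level / 100 - 1e-12)[1])]
    r <- rows[keep, , drop = FALSE]
    data.frame(column = cols[keep], ix = r$ix, iy = r$iy, iz = r$iz,
               x = fm$grid$origin[1] + r$ix * fm$grid$spacing,
               y = fm$grid$origin[2] + r$iy * fm$grid$spacing,
               z = fm$grid$origin[3] + r$iz * fm$grid$spacing,
               contribution = vals[keep] / sum(vals))
  }
  for (kind in unique(meta$kind)) {
    sel <- meta$kind == kind
    pos <- which(sel & contrib > 0)
    neg <- which(sel & contrib < 0)
    sets[[kind]] <- list(
      favored = pick(contrib[pos], meta[pos, , drop = FALSE], pos, favored_level),
      disfavored = pick(-contrib[neg], meta[neg, , drop = FALSE], neg,
                        disfavored_level)
    )
  }
  structure(list(sets = sets,
                 levels = c(favored = favored_level, disfavored = disfavored_level)),
            class = "qsar_contours")
}

#' @export
print.qsar_contours <- function(x, ...) {
  for (kind in names(x$sets)) {
    cat(kind, ": ", nrow(x$sets[[kind]]$favored), " favoured / ",
        nrow(x$sets[[kind]]$disfavored), " disfavoured points\n", sep = "")
  }
  invisible(x)
}
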