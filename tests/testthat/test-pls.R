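test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(42)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  ols <- coef(lm(y ~ X))
  m <- fit_pls(X, y, 4)
  expect_equal(m$coefficients, unname(ols[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("rank-1 noiseless problem is solved by one component", {
  set.seed(7)
  t1 <- rnorm(12)
  X <- t1 %o% rnorm(5)
  y <- 2 * t1 + 1
  m <- fit_pls(X, y, 1)
  expect_equal(m$fitted, y, tolerance = 1e-9)
})

test_that("predictions are invariant to descriptor column order", {
  set.seed(13)
  X <- matrix(rnorm(80), 10, 8)
  y <- rnorm(10)
  perm <- sample(8)
  m1 <- fit_pls(X, y, 3)
  m2 <- fit_pls(X[, perm], y, 3)
  Xnew <- matrix(rnorm(24), 3, 8)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew[, perm]), tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_pls(X, rep(1, 5), 2), "zero-variance")
  expect_error(fit_pls(X[, 0], rnorm(5), 2), "no active")
  expect_error(fit_pls(X, rnorm(5), 0), ">= 1")
})

test_that("leave-one-out q2 equals an independently coded loop", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    X <- matrix(rnorm(72), 12, 6)
    y <- X[, 1] - 0.5 * X[, 4] + rnorm(12, 0, 0.3)
    got <- loo_q2(X, y, 2)
    # brute-force oracle, written independently of the implementation
    pred <- vapply(seq_len(12), function(i) {
      Xi <- X[-i, ]; yi <- y[-i]
      mu <- colMeans(Xi); ym <- mean(yi)
      E <- sweep(Xi, 2, mu); f <- yi - ym
      B <- matrix(0, 6, 2); P <- matrix(0, 6, 2); q <- numeric(2)
      for (h in 1:2) {
        w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
        tt <- E %*% w
        p <- crossprod(E, tt) / sum(tt^2)
        qq <- sum(f * tt) / sum(tt^2)
        E <- E - tt %*% t(p); f <- f - qq * tt
        B[, h] <- w; P[, h] <- p; q[h] <- qq
      }
      beta <- B %*% solve(crossprod(P, B), q)
      sum((X[i, ] - mu) * beta) + ym
    }, numeric(1))
    q2_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    expect_equal(got$q2, q2_oracle, tolerance = 1e-10)
    expect_equal(got$predictions, pred, tolerance = 1e-10)
  }
})

test_that("q2 honours its definitional identities", {
  set.seed(4)
  y <- rnorm(10, 7, 1)
  # perfect predictions give q2 = 1 by the defining formula
  expect_equal(1 - sum((y - y)^2) / sum((y - mean(y))^2), 1)
  # a mean-only predictor cannot exceed q2 = 0 under LOO
  pred_mean <- vapply(seq_along(y), function(i) mean(y[-i]), numeric(1))
  q2_mean <- 1 - sum((y - pred_mean)^2) / sum((y - mean(y))^2)
  expect_lte(q2_mean, 0)
  expect_error(loo_q2(matrix(rnorm(4), 2, 2), rnorm(2), 1), "at least 3")
  expect_error(loo_q2(matrix(rnorm(40), 10, 4), rnorm(10), 9), "< n - 1")
})

test_that("q2 is invariant to masked-out columns", {
  set.seed(21)
  mols <- fixture_aligned_mols()[as.character(21:28)]
  fm <- compute_field_matrix(mols, make_grid(mols, 2, 4), "comfa")
  fm <- column_filter(fm, 0.3)
  y <- fixture_benchmark()$pki[21:28]
  q_base <- loo_q2(fm, y, 2)$q2
  masked <- fm
  masked$values <- cbind(fm$values, matrix(rnorm(8 * 5), 8, 5))
  masked$meta <- rbind(fm$meta, fm$meta[1:5, ])
  masked$mask <- c(fm$mask, rep(FALSE, 5))
  masked$focus_weights <- c(fm$focus_weights, rep(1, 5))
  expect_equal(loo_q2(masked, y, 2)$q2, q_base, tolerance = 1e-12)
})

test_that("component selection maximises q2 with fewest-wins ties", {
  set.seed(5)
  # two clean latent factors
  t1 <- rnorm(20); t2 <- rnorm(20)
  X <- cbind(t1 %o% rnorm(4), t2 %o% rnorm(4))
  y <- t1 - t2 + rnorm(20, 0, 0.02)
  expect_equal(select_components(X, y, 4), 2L)
  expect_equal(select_components(X, y, 1), 1L)
})

test_that("external validation reproduces the published test statistics", {
  comfa_test <- published_external_stats("comfa", "test")
  expect_lt(abs(comfa_test$rmsep - 0.226), 0.0015)
  expect_lt(abs(comfa_test$r2_pred - 0.891), 0.0015)
  comfa_val <- published_external_stats("comfa", "validation")
  expect_lt(abs(comfa_val$r2_pred - 0.790), 0.0015)
  rf_test <- published_external_stats("comfa_rf", "test")
  expect_lt(abs(rf_test$rmsep - 0.319), 0.0015)
  expect_lt(abs(rf_test$r2_pred - 0.742), 0.0015)
  comsia_test <- published_external_stats("comsia", "test")
  expect_lt(abs(comsia_test$rmsep - 0.308), 0.0015)
  expect_lt(abs(comsia_test$r2_pred - 0.743), 0.0015)
})

test_that("external validation identities and error cases hold", {
  y <- c(6.2, 7.1, 7.9, 8.3, 6.8)
  perfect <- external_validate(y, y)
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$r2_pred, 1)
  expect_equal(perfect$k, 1); expect_equal(perfect$k_prime, 1)
  expect_equal(perfect$gt_ratio, 0, tolerance = 1e-12)
  expect_true(perfect$gt_pass)
  # affine rescaling of predictions keeps r2 but moves the slopes
  shifted <- external_validate(2 * y + 1, y)
  expect_equal(shifted$r2_pred, 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(shifted$k, 1)))
  expect_error(external_validate(rep(1, 5), y), "zero variance")
  expect_error(external_validate(y[1:2], y[1:2]), "length")
})

test_that("summary statistics follow the documented conventions", {
  # the convention must reproduce the published pairing of r2 and F
  f_expected <- (0.856 / 3) / ((1 - 0.856) / 22)
  expect_equal(f_expected, 43.6, tolerance = 0.1)

  set.seed(8)
  X <- matrix(rnorm(26 * 6), 26, 6)
  y <- X %*% rnorm(6) + rnorm(26, 0, 0.4)
  m <- fit_pls(X, y, 3)
  s <- summary_statistics(m, X, y)
  expect_equal(s$f_value,
               (s$r2_ncv / 3) / ((1 - s$r2_ncv) / (26 - 3 - 1)),
               tolerance = 1e-12)
  expect_equal(s$see, sqrt(sum((y - predict(m, X))^2) / 22), tolerance = 1e-12)

  # y-scrambling must degrade the fit
  set.seed(9)
  s_perm <- summary_statistics(fit_pls(X, sample(y), 3), X, sample(y))
  expect_lt(s_perm$r2_ncv, s$r2_ncv)

  # perfect fit guards
  yy <- X[, 1]
  mp <- fit_pls(X[, 1, drop = FALSE], yy, 1)
  sp <- summary_statistics(mp, X[, 1, drop = FALSE], yy)
  expect_equal(sp$see, 0, tolerance = 1e-7)
  expect_true(is.infinite(sp$f_value))
})

test_that("field fractions partition unity and respect symmetry", {
  set.seed(10)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  m <- fit_pls(X, y, 2)
  f1 <- field_fractions(m, kinds = rep("steric", 5))
  expect_equal(unname(f1), 1)
  # duplicated blocks of two kinds split exactly in half
  X2 <- cbind(X, X)
  m2 <- fit_pls(X2, y, 2)
  f2 <- field_fractions(m2, kinds = rep(c("steric", "electrostatic"), each = 5))
  expect_equal(sum(f2), 1, tolerance = 1e-9)
  expect_equal(unname(f2["steric"]), 0.5, tolerance = 1e-9)
  expect_error(field_fractions(m), "metadata")
})

test_that("contour extraction covers the requested contribution levels", {
  mols <- fixture_aligned_mols()[as.character(21:28)]
  fm <- compute_field_matrix(mols, make_grid(mols, 2, 4), "comfa")
  fm <- column_filter(fm, 0.3)
  y <- fixture_benchmark()$pki[21:28]
  fit <- fit_pls(fm, y, 2)
  co <- extract_contours(fit, fm, favored_level = 80, disfavored_level = 20)
  for (kind in names(co$sets)) {
    fav <- co$sets[[kind]]$favored
    dis <- co$sets[[kind]]$disfavored
    if (nrow(fav)) {
      expect_gte(sum(fav$contribution), 0.8 - 1e-9)
      expect_false(is.unsorted(rev(fav$contribution)))
    }
    if (nrow(fav) && nrow(dis)) {
      expect_equal(nrow(merge(fav[, c("ix", "iy", "iz")],
                              dis[, c("ix", "iy", "iz")])), 0)
    }
  }
  # all-zero coefficients give empty sets; a single positive column is the set
  fit0 <- fit
  fit0$coefficients[] <- 0
  co0 <- extract_contours(fit0, fm)
  expect_true(all(vapply(co0$sets, function(s) nrow(s$favored) == 0, logical(1))))
  fit1 <- fit0
  fit1$coefficients[7] <- 1
  co1 <- extract_contours(fit1, fm)
  kind7 <- fm$meta$kind[fm$mask][7]
  expect_equal(nrow(co1$sets[[kind7]]$favored), 1L)
  expect_equal(co1$sets[[kind7]]$favored$contribution, 1)
})
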