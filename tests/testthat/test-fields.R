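test_that("grid construction follows the outward-snapping rule", {
  atom <- toy_atom()
  g <- make_grid(atom, spacing = 2, margin = 4)
  expect_equal(g$shape, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))

  g0 <- make_grid(atom, spacing = 2, margin = 0)
  expect_equal(g0$shape, c(1L, 1L, 1L))

  mols <- fixture_aligned_mols()[1:4]
  g1 <- make_grid(mols, 2, 4)
  shifted <- lapply(mols, function(m) mol_set_coords(m, mol_coords(m) +
                                                       rep(c(3, -1, 2), each = nrow(m$atoms))))
  g2 <- make_grid(shifted, 2, 4)
  expect_equal(g2$shape, g1$shape)
  expect_equal(g2$origin - g1$origin, c(3, -1, 2), tolerance = 1e-9)
  expect_error(make_grid(list()), "empty")
})

test_that("energy fields decay, clip and hit the LJ minimum exactly", {
  atom <- toy_atom("C")   # neutral
  probe <- probe_spec("comfa")
  far <- make_grid(atom, spacing = 100, margin = 50)  # corners 50+ A away
  f <- comfa_fields(atom, far, probe)
  pts <- grid_points(far)
  faridx <- which(sqrt(rowSums(pts^2)) >= 50)
  expect_true(all(abs(f$steric[faridx]) < 1e-6))
  expect_true(all(abs(f$electrostatic[faridx]) < 1e-6))

  near <- make_grid(atom, spacing = 2, margin = 0)  # single point at the core
  fn <- comfa_fields(atom, near, probe)
  expect_identical(fn$steric, 30)
  expect_true(fn$excluded)

  # probe at the pair minimum distance -> exactly -eps of the combined pair
  rmin <- atom$atoms$vdw_radius + probe$vdw_radius
  eps <- sqrt(atom$atoms$eps * probe$eps)
  g1 <- structure(list(origin = c(0, 0, 0), spacing = 1, shape = c(1L, 1L, 1L),
                       margin = 0), class = "qsar_grid")
  fmin <- comfa_fields(toy_atom("C", x = rmin), g1, probe)
  expect_equal(fmin$steric, -eps, tolerance = 1e-10)
})

test_that("similarity fields obey the closed Gaussian form", {
  probe <- probe_spec("comsia")
  g1 <- structure(list(origin = c(0, 0, 0), spacing = 1, shape = c(1L, 1L, 1L),
                       margin = 0), class = "qsar_grid")
  on_point <- toy_atom("C", hbd = TRUE)
  f <- comsia_fields(on_point, g1, probe, alpha = 0.3)
  expect_equal(f$hbd, -1)                       # exp(0) = 1, W = 1
  at2 <- toy_atom("C", x = 2, hbd = TRUE)
  f2 <- comsia_fields(at2, g1, probe, alpha = 0.3)
  expect_equal(f2$hbd, -exp(-1.2), tolerance = 1e-12)
  expect_equal(f2$hbd, -0.3012, tolerance = 1e-4)

  # additivity: two coincident atoms double the field
  twin <- qsar_mol("twin", atoms = data.frame(element = c("C", "C"),
                                              x = c(2, 2), y = 0, z = 0,
                                              charge = 0, aromatic = FALSE,
                                              hbd = TRUE, hba = FALSE))
  ft <- comsia_fields(twin, g1, probe, alpha = 0.3)
  expect_equal(ft$hbd, 2 * f2$hbd, tolerance = 1e-12)

  # boundedness: |field| <= sum_i |W_ik| everywhere, on a real molecule
  mol <- fixture_aligned_mols()[["26"]]
  g <- make_grid(mol, 2, 4)
  fs <- comsia_fields(mol, g, probe)
  expect_lte(max(abs(fs$steric)), sum(abs(mol$atoms$vdw_radius^3)) + 1e-9)
  expect_lte(max(abs(fs$hbd)), sum(mol$atoms$hbd) + 1e-9)
  expect_true(all(is.finite(unlist(fs))))
})

test_that("fields are unchanged when molecule and lattice rotate together", {
  mol <- fixture_aligned_mols()[["26"]]
  g <- make_grid(mol, 2, 4)
  probe_c <- probe_spec("comfa"); probe_s <- probe_spec("comsia")
  orig_c <- comfa_fields(mol, g, probe_c)
  orig_s <- comsia_fields(mol, g, probe_s)
  th <- 0.7
  r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rmol <- mol_set_coords(mol, mol_coords(mol) %*% t(r))
  pts <- grid_points(g) %*% t(r)   # the jointly rotated lattice points
  idx <- seq(1, prod(g$shape), by = 53)
  for (p in idx) {
    if (orig_c$excluded[p]) next  # excluded points carry the grid-wide mean
    gp <- structure(list(origin = pts[p, ], spacing = 1, shape = c(1L, 1L, 1L),
                         margin = 0), class = "qsar_grid")
    fc <- comfa_fields(rmol, gp, probe_c)
    expect_equal(fc$steric, orig_c$steric[p], tolerance = 1e-8)
    expect_equal(fc$electrostatic, orig_c$electrostatic[p], tolerance = 1e-8)
    fs <- comsia_fields(rmol, gp, probe_s)
    expect_equal(fs$hbd, orig_s$hbd[p], tolerance = 1e-8)
  }
})

test_that("column filtering applies the max-minus-min rule", {
  fm <- structure(list(values = matrix(c(0, 0.2, 0, 0.5, 1, 1), 2, 3),
                       meta = data.frame(kind = "steric", ix = 0:2, iy = 0, iz = 0,
                                         point = 1:3, any_excluded = FALSE),
                       mask = rep(TRUE, 3), focus_weights = rep(1, 3),
                       grid = NULL, method = "comfa"),
                  class = "qsar_field_matrix")
  expect_equal(column_filter(fm, 0.3)$mask, c(FALSE, TRUE, FALSE))
  expect_equal(column_filter(fm, 0)$mask, rep(TRUE, 3))
  constant <- fm; constant$values[] <- 5
  expect_equal(column_filter(constant, 1e-9)$mask, rep(FALSE, 3))
  expect_error(column_filter(fm_subset(fm, 1), 0.3), ">= 2")
})

test_that("region focusing weights follow sd x |coef| and exponent rules", {
  set.seed(1)
  X <- matrix(rnorm(60), 10, 6)
  y <- X[, 2] * 2 + rnorm(10, 0, 0.01)
  fm <- structure(list(values = X,
                       meta = data.frame(kind = "steric", ix = 0:5, iy = 0, iz = 0,
                                         point = 1:6, any_excluded = FALSE),
                       mask = rep(TRUE, 6), focus_weights = rep(1, 6),
                       grid = NULL, method = "comfa"),
                  class = "qsar_field_matrix")
  fit <- fit_pls(fm, y, 2)
  unchanged <- region_focus(fm, fit, exponent = 0)
  expect_equal(unchanged$values, X)
  focused <- region_focus(fm, fit, exponent = 1)
  w <- fit$column_sd * abs(fit$coefficients)
  w <- w / max(w)
  expect_equal(focused$values, sweep(X, 2, w, "*"))
  expect_equal(which.max(focused$focus_weights), 2L)
  expect_error(region_focus(fm, fit, exponent = -1), ">= 0")

  # a column with zero PLS coefficient is removed by focusing
  fit0 <- fit
  fit0$coefficients[5] <- 0
  gone <- region_focus(fm, fit0, exponent = 1)
  expect_true(all(gone$values[, 5] == 0))
})

test_that("block scaling equalises pooled block variance without reordering", {
  mols <- fixture_aligned_mols()[c("21", "22", "25", "26")]
  fm <- compute_field_matrix(mols, make_grid(mols, 2, 4), "comfa")
  fm <- column_filter(fm, 0.3)
  sc <- block_scale(fm)
  for (kind in names(sc$block_scales)) {
    cols <- which(sc$mask & sc$meta$kind == kind)
    pooled <- sqrt(mean(apply(sc$values[, cols, drop = FALSE], 2, var)))
    expect_equal(pooled, 1, tolerance = 1e-9)
  }
})
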