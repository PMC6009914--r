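random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

test_that("self-alignment and rigid-copy alignment are exact", {
  mol <- fixture_benchmark_mols()[["26"]]
  n <- nrow(mol$atoms)
  self <- align_to_template(mol, mol, mapping = cbind(1:n, 1:n))
  expect_lt(self$align_rmsd, 1e-8)

  r <- random_rotation(7)
  moved <- mol_set_coords(mol, sweep(mol_coords(mol) %*% t(r), 2, c(3, -2, 5), "+"))
  back <- align_to_template(moved, mol, mapping = cbind(1:n, 1:n))
  expect_lt(back$align_rmsd, 1e-6)
  expect_equal(mol_coords(back), mol_coords(mol), tolerance = 1e-6)
})

test_that("hand-checked three-point translation case recovers -t", {
  p <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  q <- sweep(p, 2, c(1, 1, 1), "+")  # template = p translated by (1,1,1)
  fit <- kabsch_fit(q, p)            # move the translated copy back
  expect_equal(fit$translation, c(-1, -1, -1), tolerance = 1e-12)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("alignment RMSD is invariant to rigid pre-transformation", {
  mols <- fixture_benchmark_mols()
  mol <- mols[["3"]]; template <- mols[["26"]]
  map <- core_mapping("I", "VI")
  base <- align_to_template(mol, template, mapping = map)
  r <- random_rotation(11)
  pre <- mol_set_coords(mol, sweep(mol_coords(mol) %*% t(r), 2, c(-4, 2, 9), "+"))
  again <- align_to_template(pre, template, mapping = map)
  expect_equal(again$align_rmsd, base$align_rmsd, tolerance = 1e-8)
  expect_equal(mol_coords(again), mol_coords(base), tolerance = 1e-6)
})

test_that("substructure mapping finds the embedded smaller molecule", {
  benzene <- embed_and_minimize("c1ccccc1", seed = 2)
  toluene <- embed_and_minimize("Cc1ccccc1", seed = 2)
  map <- common_substructure_mapping(benzene, toluene)
  expect_equal(nrow(map), 6L)
  expect_true(all(toluene$atoms$element[map[, "template"]] == "C"))
  aligned <- align_to_template(benzene, toluene)
  expect_lt(aligned$align_rmsd, 0.2)
  # no common substructure
  methane <- embed_and_minimize("C", seed = 2)
  water <- embed_and_minimize("O", seed = 2)
  expect_error(align_to_template(methane, water), "common substructure")
})

test_that("orientation search returns identity under a rotation-invariant objective", {
  mols <- fixture_aligned_mols()[1:8]
  y <- fixture_benchmark()$pki[1:8]
  inv_objective <- function(mset) 1  # every orientation ties
  o <- orientation_search(mols, y, step_degrees = 90, objective = inv_objective,
                          reduce_lattice_symmetry = FALSE)
  expect_equal(o$rotation, diag(3), tolerance = 1e-12)
  expect_equal(o$objective_value, 1)
  expect_equal(nrow(o$scan), 24L)  # the proper rotations of the 90-degree net
  # the whole 90-degree net is one lattice-symmetry class
  o2 <- orientation_search(mols, y, step_degrees = 90, objective = inv_objective)
  expect_equal(nrow(o2$scan), 1L)
})

test_that("orientation search never scores below the input orientation", {
  mols <- fixture_aligned_mols()[1:8]
  y <- fixture_benchmark()$pki[1:8]
  # cheap orientation-sensitive objective: alignment of aggregate with axes
  objective <- function(mset) {
    xyz <- do.call(rbind, lapply(mset, mol_coords))
    -sum(abs(prcomp(xyz)$rotation[, 1] - c(1, 0, 0)))
  }
  identity_score <- objective(mols)
  o <- orientation_search(mols, y, step_degrees = 90, objective = objective)
  expect_gte(o$objective_value, identity_score)
})

test_that("orientation search validates its inputs", {
  mols <- fixture_aligned_mols()[1:8]
  expect_error(orientation_search(mols, rep(1, 8), step_degrees = 90),
               "zero variance")
  expect_error(orientation_search(mols[1:3], 1:3, step_degrees = 90),
               "at least 6")
  expect_error(orientation_search(mols, 1:8, step_degrees = 7), "divisor")
})
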