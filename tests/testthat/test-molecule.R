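test_that("methane embeds as a symmetric 5-atom molecule", {
  m <- embed_and_minimize("C", seed = 3)
  expect_equal(nrow(m$atoms), 5L)
  xyz <- mol_coords(m)
  dch <- sqrt(rowSums(sweep(xyz[2:5, ], 2, xyz[1, ])^2))
  expect_lt(diff(range(dch)), 1e-2)
})

test_that("embedding is deterministic for a fixed seed", {
  smi <- fixture_benchmark()$smiles[5]
  m1 <- embed_molecules(smi, seed = 11)[[1]]
  rm(list = paste0(smi, "#11"), envir = qsar3d:::.embed_cache)  # force re-run
  m2 <- embed_molecules(smi, seed = 11)[[1]]
  expect_identical(mol_coords(m1), mol_coords(m2))
  expect_identical(m1$atoms$charge, m2$atoms$charge)
})

test_that("template compound reproduces the published molecular weight", {
  b <- fixture_benchmark()
  m <- embed_and_minimize(b$smiles[26], seed = 1)
  expect_equal(mol_weight(m), 360.36, tolerance = 0.01)
})

test_that("Gasteiger charges respect symmetry, ordering and conservation", {
  m <- embed_and_minimize("C", seed = 1)
  qc <- m$atoms$charge[m$atoms$element == "C"]
  qh <- m$atoms$charge[m$atoms$element == "H"]
  expect_lt(qc, 0)
  expect_lt(diff(range(qh)), 1e-6)
  expect_silent(assign_partial_charges(m))

  sulfa <- embed_and_minimize("NS(=O)(=O)c1ccccc1", seed = 1)
  benzene <- embed_and_minimize("c1ccccc1", seed = 1)
  qn <- abs(sulfa$atoms$charge[sulfa$atoms$element == "N"][1])
  qcar <- max(abs(benzene$atoms$charge[benzene$atoms$element == "C"]))
  expect_gt(qn, qcar)

  for (smi in c("CCO", "c1ccncc1", "CC(N)=O")) {
    m <- embed_and_minimize(smi, seed = 2)
    expect_lt(abs(sum(m$atoms$charge)), 1e-3)
  }
})

test_that("charge assignment is invariant to atom relabelling", {
  a <- embed_and_minimize("CCO", seed = 5)
  b <- embed_and_minimize("OCC", seed = 5)
  key <- function(m) {
    g <- mol_graph(m)
    deg <- igraph::degree(g)
    ord <- order(m$atoms$element, deg, round(m$atoms$charge, 4))
    round(m$atoms$charge[ord], 4)
  }
  expect_equal(key(a), key(b))
})

test_that("unparameterised elements and bad SMILES raise errors", {
  expect_error(embed_and_minimize("not-a-smiles", seed = 1), "failed")
  atoms <- data.frame(element = "Xe", x = 0, y = 0, z = 0)
  expect_error(qsar_mol("x", atoms = atoms), "unparameterised")
})

test_that("SDF round-trip preserves coordinates, charges and flags", {
  mols <- fixture_benchmark_mols()[c("1", "26")]
  path <- tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_equal(length(back), 2L)
  expect_equal(mol_coords(back[[2]]), mol_coords(mols[[2]]), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(back[[2]]$atoms$charge, mols[[2]]$atoms$charge, tolerance = 1e-6)
  expect_equal(back[[2]]$atoms$hbd, mols[[2]]$atoms$hbd)
  expect_equal(back[[2]]$atoms$aromatic, mols[[2]]$atoms$aromatic)
})
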