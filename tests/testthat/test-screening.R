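test_that("descriptors match definitional and published values", {
  eth <- compute_descriptors("CCO")
  expect_equal(eth$hbd_count, 1L)
  expect_equal(eth$hba_count, 1L)
  expect_equal(eth$rotatable_bonds, 0L)  # terminal rotors excluded by rule
  expect_false(eth$has_primary_sulfonamide)

  c26 <- compute_descriptors(fixture_benchmark()$smiles[26])
  expect_equal(c26$mw, 360.36, tolerance = 0.01)
  expect_true(c26$has_primary_sulfonamide)

  aza <- compute_descriptors("CC(=O)Nc1nnc(s1)S(N)(=O)=O")  # acetazolamide
  expect_equal(aza$mw, 222.24, tolerance = 0.01)
  expect_true(aza$has_primary_sulfonamide)
})

test_that("rule-of-five filter evaluates all four rules without short-circuit", {
  base <- data.frame(mw = 427.5, logp = 2.105, hbd_count = 3L, hba_count = 8L,
                     tpsa = 100, rotatable_bonds = 5L,
                     has_primary_sulfonamide = TRUE)
  rep_ok <- lipinski_filter(base)
  expect_true(filter_pass(rep_ok))
  expect_equal(nrow(rep_ok), 4L)

  heavy <- base; heavy$mw <- 501
  rep_mw <- lipinski_filter(heavy)
  expect_false(filter_pass(rep_mw))
  expect_equal(rep_mw$pass, c(FALSE, TRUE, TRUE, TRUE))

  water <- compute_descriptors("O")
  expect_true(filter_pass(lipinski_filter(water)))
})

test_that("all 41 benchmark compounds pass the rule of five", {
  b <- fixture_benchmark()
  desc <- compute_descriptors(b$smiles)
  passes <- vapply(seq_len(nrow(desc)), function(i) {
    filter_pass(lipinski_filter(desc[i, ]))
  }, logical(1))
  expect_true(all(passes))
})

test_that("range filter applies inclusive bounds and flags unknown rows", {
  d <- data.frame(mw = 360.36, logp = 7.0)
  ranges <- data.frame(descriptor = c("mw", "logp"),
                       lower = c(130, -2), upper = c(725, 6.5))
  rep <- range_filter(d, ranges)
  expect_equal(rep$pass, c(TRUE, FALSE))
  expect_false(filter_pass(rep))
  # boundary is inclusive
  expect_true(filter_pass(range_filter(data.frame(mw = 725), ranges[1, ])))
  # empty table passes vacuously; unknown descriptor errors
  expect_true(filter_pass(range_filter(d, ranges[0, ])))
  expect_error(range_filter(d, data.frame(descriptor = "logbb",
                                          lower = -3, upper = 1.2)),
               "unknown descriptor")
})

test_that("feature detection finds the expected benzenesulfonamide features", {
  mol <- embed_and_minimize("NS(=O)(=O)c1ccccc1", seed = 4)
  f <- detect_features(mol)
  expect_true(any(f$kind == "HBD"))       # sulfonamide NH2
  expect_true(any(f$kind == "HBA"))       # SO2 oxygens
  expect_true(any(f$kind == "aromatic"))  # the ring
  expect_gte(sum(f$kind == "HBA"), 2L)
})

test_that("pharmacophore from two copies reproduces the molecule's features", {
  mol <- fixture_aligned_mols()[["26"]]
  model <- build_pharmacophore(list(mol, mol))
  own <- detect_features(mol)
  expect_lte(nrow(model$features), model$max_features)
  for (r in seq_len(nrow(model$features))) {
    same <- own[own$kind == model$features$kind[r], , drop = FALSE]
    d <- sqrt((same$x - model$features$x[r])^2 +
                (same$y - model$features$y[r])^2 +
                (same$z - model$features$z[r])^2)
    expect_lt(min(d), 1e-9)
  }
})

test_that("benchmark actives yield a donor/acceptor/aromatic pharmacophore", {
  actives <- fixture_aligned_mols()[as.character(c(12, 22, 25, 26))]
  model <- build_pharmacophore(actives)
  kinds <- model$features$kind
  expect_true(all(c("HBD", "HBA", "aromatic") %in% kinds))
  expect_gte(nrow(model$features), model$min_features_required)
  # every active matches its own common-feature model
  for (id in names(actives)) {
    m <- match_pharmacophore(actives[[id]], model)
    expect_true(m$pass, label = paste("compound", id))
    expect_gte(m$matched, 4L)
  }
})

test_that("pharmacophore matching honours tolerance and kind constraints", {
  feat <- data.frame(kind = c("HBD", "HBA", "aromatic", "hydrophobe"),
                     x = c(0, 3, 6, 9), y = 0, z = 0, tolerance = 1)
  model <- structure(list(features = feat, min_features_required = 2L,
                          max_features = 10L), class = "qsar_pharmacophore")
  # one donor exactly at tolerance distance: closed-ball convention matches
  mol <- toy_atom("O", x = 1, hbd = TRUE)
  res <- match_pharmacophore(mol, model)
  expect_equal(res$matched, 1L)
  # no acceptors available -> the HBA feature cannot be satisfied
  expect_false(res$pass)
  beyond <- match_pharmacophore(toy_atom("O", x = 1.0001, hbd = TRUE), model)
  expect_equal(beyond$matched, 0L)
})

test_that("pharmacophore JSON round-trips", {
  actives <- fixture_aligned_mols()[as.character(c(25, 26))]
  model <- build_pharmacophore(actives)
  path <- tempfile(fileext = ".json")
  write_pharmacophore_json(model, path)
  back <- read_pharmacophore_json(path)
  expect_equal(back$features$kind, model$features$kind)
  expect_equal(back$features$x, model$features$x, tolerance = 1e-12)
  expect_equal(back$min_features_required, model$min_features_required)
})

test_that("chemical-space selection finds twins and outliers", {
  set.seed(31)
  cloud <- matrix(rnorm(49 * 7), 49, 7)
  cloud[25, ] <- cloud[24, ]          # identical pair
  cloud[49, ] <- cloud[49, ] + 25     # extreme outlier
  rownames(cloud) <- sprintf("c%02d", 1:49)
  sel <- chemical_space_select(cloud, k_similar = 5, k_dissimilar = 5)
  expect_true(all(c("c24", "c25") %in% sel$similar[1:2]))
  expect_equal(sel$dissimilar[1], "c49")
  # similar set is tighter than the cloud at large
  d <- as.matrix(dist(sel$scores))
  sim_idx <- match(sel$similar, rownames(cloud))
  mean_sim <- mean(d[sim_idx, sim_idx][upper.tri(diag(5))])
  expect_lt(mean_sim, mean(d[upper.tri(d)]))
  expect_error(chemical_space_select(matrix(1, 20, 3), 5, 5), "constant")
})

test_that("filter funnel is monotone: adding a rule never grows the pass set", {
  b <- fixture_benchmark()
  desc <- compute_descriptors(b$smiles[seq(1, 41, by = 4)])
  ranges1 <- data.frame(descriptor = "mw", lower = 130, upper = 725)
  ranges2 <- rbind(ranges1,
                   data.frame(descriptor = "logp", lower = -2, upper = 2.2))
  pass1 <- vapply(seq_len(nrow(desc)), function(i)
    filter_pass(range_filter(desc[i, ], ranges1)), logical(1))
  pass2 <- vapply(seq_len(nrow(desc)), function(i)
    filter_pass(range_filter(desc[i, ], ranges2)), logical(1))
  expect_true(all(which(pass2) %in% which(pass1)))
})
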