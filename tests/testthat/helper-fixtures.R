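# Shared fixtures, built once per test run.  Embedding results are
# memoised inside the package, so repeated calls are cheap; these helpers
# just centralise the canonical seeds and sizes used across test files.

.fixtures <- new.env(parent = emptyenv())

fixture_benchmark <- function() {
  if (is.null(.fixtures$bench)) .fixtures$bench <- load_benchmark()
  .fixtures$bench
}

fixture_benchmark_mols <- function() {
  if (is.null(.fixtures$mols)) {
    .fixtures$mols <- embed_benchmark(fixture_benchmark(), seed = 1L)
  }
  .fixtures$mols
}

fixture_aligned_mols <- function() {
  if (is.null(.fixtures$aligned)) {
    .fixtures$aligned <- align_benchmark(fixture_benchmark_mols(),
                                         fixture_benchmark())
  }
  .fixtures$aligned
}

fixture_benchmark_fit <- function(model) {
  key <- paste0("fit_", model)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_benchmark_pipeline(model,
                                               mols = fixture_benchmark_mols())
  }
  .fixtures[[key]]
}

fixture_synthetic <- function(n = 20L, noise_sd = 0.1, seed = 1L, ...) {
  generate_synthetic(synthetic_spec(n_compounds = n, noise_sd = noise_sd,
                                    seed = seed, ...))
}

# a single atom as a minimal molecule, for closed-form field checks
toy_atom <- function(element = "C", x = 0, y = 0, z = 0, charge = 0,
                     hbd = FALSE, hba = FALSE) {
  qsar_mol(id = "toy", atoms = data.frame(element = element, x = x, y = y,
                                          z = z, charge = charge,
                                          aromatic = FALSE, hbd = hbd,
                                          hba = hba),
           net_charge = round(sum(charge)))
}
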