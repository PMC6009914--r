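# qsar3d

Lattice-field 3D-QSAR and pharmacophore screening for sulfonamide
carbonic anhydrase inhibitors.

Primary sulfonamides inhibit human carbonic anhydrase II (hCA II) by
anchoring to the active-site zinc; within a congeneric series, potency
differences reflect the steric, electrostatic and hydrogen-bonding
environment the varying substituents create.  `qsar3d` implements the
classical ligand-based machinery for quantifying that relationship:

* **fields** — every aligned molecule is probed on a shared regular
  lattice (2.0 Å spacing) by an sp³-carbon probe with +1 charge:
  steric Lennard-Jones energies `Σᵢ (Aᵢ/r¹² − Cᵢ/r⁶)` and Coulomb
  electrostatics `Σᵢ 332 qᵢ/(D(r)·r)`, clipped at ±30 kcal/mol
  (CoMFA-style), plus Gaussian similarity indices
  `−Σᵢ W_ik e^(−0.3 r²)` for steric, electrostatic, hydrophobic and
  H-bond donor/acceptor properties (CoMSIA-style);
* **regression** — NIPALS PLS1 with leave-one-out cross-validation
  (`q² = 1 − PRESS/Σ(yᵢ−ȳ)²`), 0.3 kcal/mol minimum-variation column
  filtering, all-orientation search of the grid frame, and iterated
  region focusing (`sd×|coef|`-based column reweighting);
* **validation** — r²/SEE/F, RMSEP, predictive r² and the
  Golbraikh–Tropsha through-origin criteria;
* **interpretation** — favoured/disfavoured contour point sets at the
  80%/20% contribution levels, exportable as PDB pseudo-atoms and
  OpenDX grids;
* **screening** — common-feature pharmacophores from aligned actives,
  greedy 3D feature matching, Lipinski rule-of-five, descriptor
  standard-range and PCA chemical-space filters.

The package ships the 41-compound diarylpyrazole-benzenesulfonamide
hCA II benchmark (activities in nM, per-model train/test/validation
splits, and the published per-compound predictions as a fixture), plus
a seeded synthetic generator that plants known field–activity signal
for property-based testing of the whole pipeline.

Conformer embedding and Gasteiger charges are delegated to RDKit via a
bundled Python helper (`python` with `rdkit` importable must be on the
PATH); everything else is R.

## Worked example

```r
library(qsar3d)

b <- load_benchmark()
head(b[, c("compound_id", "scaffold", "r1_name", "ki_nM", "pki", "comfa_split")], 3)
#>   compound_id scaffold r1_name ki_nM      pki comfa_split
#> 1           1        I  Phenyl   420 6.376751        test
#> 2           2        I Pyridyl    43 7.366532  validation
#> 3           3        I   Tolyl   176 6.754487  validation
```

The `pki` column is recomputed from Ki (−log₁₀ of the molar value), not
read from file.  External-validation arithmetic on the packaged
published predictions reproduces the published statistics:

```r
s <- published_external_stats("comfa", "test")
sprintf("RMSEP %.3f  r2_pred %.3f  K %.3f", s$rmsep, s$r2_pred, s$k)
#> "RMSEP 0.226  r2_pred 0.892  K 0.992"
```

RMSEP 0.226 is the root-mean-square error of the ten test-set
predictions; r²_pred is their squared Pearson correlation with the
measured pKi; K near 1 is the through-origin slope guarding against
chance correlation.

The full rebuild — embedding, core-constrained alignment, fields,
orientation search, PLS, focusing — runs in a few minutes:

```r
mols <- embed_benchmark(b, seed = 1)
fit <- run_benchmark_pipeline("comfa_rf", mols = mols)
fit
#> <qsar_benchmark_fit> COMFA_RF (3 components)
#>   q2 (LOO)          0.437
#>   r2 (ncv)          0.684
#>   SEE               0.460
#>   F                 18.001
#>   RMSEP (test)      0.519
#>   r2_pred (test)    0.488
#>   focus exponent    0.6
#>   field fractions   electrostatic 0.726, steric 0.274
```

Here q² is the leave-one-out cross-validated correlation coefficient of
the 3-latent-variable region-focused model on its 29 training
compounds; the focusing trajectory is in `fit$focus_scan` and the
contour sets in `fit$contours`.  See the methods vignette
(`vignettes/qsar3d-methods.Rmd`) for the model definitions, the design
decisions behind the preparation pipeline, and what these numbers can
and cannot be compared to.

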