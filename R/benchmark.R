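# The 41-compound diarylpyrazole-benzenesulfonamide hCA II benchmark.
#
# Every compound is a 1-(sulfamoylphenyl)-5-(R1)-pyrazole bearing one of
# eight 3-substituent/regiochemistry variants (scaffolds I-VIII).  The
# scaffold SMILES are written so that their leading heavy atoms enumerate
# the conserved benzenesulfonamide-pyrazole core in a fixed order
# (sulfonamide N, S, O, O, six benzene carbons, pyrazole N1, N2, C3, C4,
# C5); R1 and the 3-substituent follow.  That convention gives an
# index-based atom mapping of the shared core across the whole series,
# which the alignment step uses directly.  "%s" marks where the R1
# fragment is spliced in.
SCAFFOLD_SMILES <- c(
  I    = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(O)=O",
  II   = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(=O)OC",
  III  = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C#N",
  IV   = "NS(=O)(=O)c1cccc(c1)n1nc(cc1%s)C(N)=O",
  V    = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(C)=O",
  VI   = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(N)=O",
  VII  = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(NC)=O",
  VIII = "NS(=O)(=O)c1ccc(cc1)n1nc(cc1%s)C(=O)NN"
)

# 1-based heavy-atom indices (SMILES order) of the alignment anchors:
# sulfonamide N, S, both O, ipso-S carbon, ipso-N carbon, pyrazole
# N1/N2/C3/C4/C5.  Identical for all para scaffolds; scaffold IV differs
# only in the ipso-N position on the benzene ring.
CORE_ANCHOR_IDX <- list(
  para = c(1L, 2L, 3L, 4L, 5L, 8L, 11L, 12L, 13L, 14L, 15L),
  meta = c(1L, 2L, 3L, 4L, 5L, 9L, 11L, 12L, 13L, 14L, 15L)
)

# R1 fragments as printed in Table 1; positional isomers left unstated in
# the printed names default to the para (or 2-thienyl/4-pyridyl) isomer.
R1_FRAGMENTS <- c(
  "Phenyl"                   = "-c2ccccc2",
  "Pyridyl"                  = "-c2ccncc2",
  "Tolyl"                    = "-c2ccc(C)cc2",
  "Bromophenyl"              = "-c2ccc(Br)cc2",
  "4-Bromophenyl"            = "-c2ccc(Br)cc2",
  "Cyanophenyl"              = "-c2ccc(C#N)cc2",
  "4-Methoxyphenyl"          = "-c2ccc(OC)cc2",
  "3-Methoxyphenyl"          = "-c2cccc(OC)c2",
  "2-Methoxyphenyl"          = "-c2ccccc2OC",
  "1-Naphthalenyl"           = "-c2cccc3ccccc23",
  "2-Naphthalenyl"           = "-c2ccc3ccccc3c2",
  "6-Methoxy-2-naphthalenyl" = "-c2ccc3cc(OC)ccc3c2",
  "Biphenyl"                 = "-c2ccc(-c3ccccc3)cc2",
  "4-Chlorophenyl"           = "-c2ccc(Cl)cc2",
  "4-Fluorophenyl"           = "-c2ccc(F)cc2",
  "4-Nitrophenyl"            = "-c2ccc([N+](=O)[O-])cc2",
  "Thienyl"                  = "-c2cccs2"
)

#' Convert an inhibition constant to pKi
#'
#' pKi = -log10(Ki in molar); the input is in nanomolar as tabulated.
#'
#' @param ki_nM Positive inhibition constant(s) in nM.
#' @return pKi value(s).
#' @examples
#' ki_to_pki(420)  # 6.376751
#' @export
ki_to_pki <- function(ki_nM) {
  if (!is.numeric(ki_nM) || any(!is.finite(ki_nM)) || any(ki_nM <= 0)) {
    stop("Ki must be positive and finite (nM)")
  }
  -log10(ki_nM * 1e-9)
}

#' Compose the SMILES of a benchmark compound
#'
#' @param scaffold Scaffold label, one of `"I"`..`"VIII"`.
#' @param r1_name Substituent name as printed in the activity table.
#' @return A single SMILES string.
#' @export
benchmark_smiles <- function(scaffold, r1_name) {
  if (!scaffold %in% names(SCAFFOLD_SMILES)) {
    stop("unknown scaffold: ", scaffold)
  }
  frag <- R1_FRAGMENTS[[r1_name]]
  if (is.null(frag)) stop("unknown R1 substituent name: ", r1_name)
  sprintf(SCAFFOLD_SMILES[[scaffold]], frag)
}

#' Load the 41-compound hCA II benchmark
#'
#' Returns the packaged activity table with the published model-specific
#' train/test/validation splits, a composed SMILES per compound and pKi
#' recomputed from Ki (never read from file, to avoid propagating printed
#' rounding).
#'
#' @param path Optional path to an activity CSV in the packaged layout
#'   (default: the packaged benchmark).
#' @return A `data.frame` with one row per compound: `compound_id`,
#'   `scaffold`, `r1_name`, `ki_nM`, `pki`, `smiles`, and the
#'   `comfa_split` / `comfarf_split` / `comsia_split` columns with values
#'   in `train`/`test`/`validation`.
#' @export
load_benchmark <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "benchmark_activities.csv", package = "qsar3d")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("benchmark activity table not found: ", path)
  }
  d <- read_activity_csv(path)
  d$smiles <- mapply(benchmark_smiles, d$scaffold, d$r1_name, USE.NAMES = FALSE)
  rownames(d) <- NULL
  d
}

#' Published per-model predictions for the benchmark
#'
#' The printed experimental pKi and the per-model predicted pKi for all 41
#' compounds (plain CoMFA, region-focused CoMFA, CoMSIA), as a fixture for
#' external-validation arithmetic.
#'
#' @return `data.frame` with columns `compound_id`, `pki`, `pred_comfa`,
#'   `pred_comfarf`, `pred_comsia`.
#' @export
load_published_predictions <- function() {
  path <- system.file("extdata", "table3_predictions.csv", package = "qsar3d")
  if (!nzchar(path)) stop("packaged prediction table missing")
  read.csv(path)
}

#' Heavy-atom indices of the conserved core of a benchmark compound
#'
#' @param scaffold Scaffold label `"I"`..`"VIII"`.
#' @return Integer vector of 11 anchor atom indices (SMILES heavy-atom
#'   order) spanning the sulfonamide group, both ipso carbons and the
#'   pyrazole ring.
#' @export
core_anchor_indices <- function(scaffold) {
  if (identical(scaffold, "IV")) CORE_ANCHOR_IDX$meta else CORE_ANCHOR_IDX$para
}

#' Core atom mapping of a benchmark compound onto a para-scaffold template
#'
#' For para scaffolds the full 11-atom anchor set maps onto itself; for
#' the meta-sulfonamide scaffold IV only the benzenesulfonamide block
#' (N, S, O, O, ipso-S carbon) is geometrically compatible with a para
#' template and is used for constraint and superposition.
#'
#' @param scaffold Scaffold label of the compound.
#' @param template_scaffold Scaffold label of the template (must not be
#'   `"IV"`).
#' @return Two-column integer matrix `(compound_atom, template_atom)`.
#' @export
core_mapping <- function(scaffold, template_scaffold = "VI") {
  if (identical(template_scaffold, "IV")) {
    stop("the meta-sulfonamide scaffold cannot serve as series template")
  }
  if (identical(scaffold, "IV")) {
    cbind(1:5, 1:5)
  } else {
    cbind(CORE_ANCHOR_IDX$para, CORE_ANCHOR_IDX$para)
  }
}

# Heavy-atom count of a SMILES fragment (supports the benchmark's
# element inventory; bracket atoms count once).
.count_heavy <- function(s) {
  s <- gsub("\\[[^]]*\\]", "A", s)         # bracket atom -> one token
  s <- gsub("Cl|Br", "A", s)
  hits <- gregexpr("[ABCNOPSFIbcnops]", s)[[1]]
  sum(hits > 0)
}

# Atom index blocks of a benchmark-convention compound: 15 core atoms,
# then the R1 fragment, then the scaffold 3-substituent.
.atom_blocks <- function(scaffold, r1_frag) {
  n_r1 <- .count_heavy(r1_frag)
  n_x <- .count_heavy(sprintf(SCAFFOLD_SMILES[[scaffold]], "")) - 15L
  list(core = 1:15, r1 = seq(16L, 15L + n_r1),
       x = if (n_x > 0) seq(15L + n_r1 + 1L, 15L + n_r1 + n_x) else integer(0))
}

#' Embed the full benchmark as aligned-ready 3D molecules
#'
#' Hierarchically constrained series embedding (see [embed_series()]):
#' the template compound (26, the most active) is embedded freely; the
#' first compound of every other scaffold inherits the template's
#' conserved core; every further compound inherits its scaffold parent's
#' core-plus-3-substituent geometry and, when its R1 substituent occurred
#' earlier in the series, that first occurrence's R1 geometry.  The whole
#' series thus shares one conformation for every shared fragment, as a
#' series sketched from a single template would.
#'
#' @param bench Benchmark table from [load_benchmark()].
#' @param seed Embedding seed.
#' @param template_id Compound whose free conformer anchors the series.
#' @return List of `qsar_mol`, named by compound id.
#' @export
embed_benchmark <- function(bench = load_benchmark(), seed = 1L, template_id = 26L) {
  t_pos <- which(bench$compound_id == template_id)
  tmpl_scaffold <- bench$scaffold[t_pos]
  if (identical(tmpl_scaffold, "IV")) {
    stop("the meta-sulfonamide scaffold cannot serve as series template")
  }
  ord <- c(t_pos, setdiff(seq_len(nrow(bench)), t_pos))
  blocks <- Map(.atom_blocks, bench$scaffold, R1_FRAGMENTS[bench$r1_name])
  constraints <- vector("list", nrow(bench))
  for (k in seq_along(ord)) {
    c_pos <- ord[k]
    cl <- list()
    if (k > 1L) {
      sp_k <- match(bench$scaffold[c_pos], bench$scaffold[ord[seq_len(k - 1L)]])
      if (is.na(sp_k)) {
        # first of its scaffold: core onto the template
        cl <- c(cl, list(list(ref = 1L,
                              map = core_mapping(bench$scaffold[c_pos], tmpl_scaffold))))
      } else {
        p_pos <- ord[sp_k]
        bc <- blocks[[c_pos]]; bp <- blocks[[p_pos]]
        cl <- c(cl, list(list(ref = sp_k,
                              map = cbind(c(bc$core, bc$x), c(bp$core, bp$x)))))
      }
      if (!identical(bench$scaffold[c_pos], "IV")) {
        earlier <- ord[seq_len(k - 1L)]
        cand <- earlier[bench$r1_name[earlier] == bench$r1_name[c_pos] &
                          bench$scaffold[earlier] != "IV"]
        if (length(cand)) {
          rp_k <- match(cand[1L], ord)
          bc <- blocks[[c_pos]]; bp <- blocks[[cand[1L]]]
          cl <- c(cl, list(list(ref = rp_k, map = cbind(bc$r1, bp$r1))))
        }
      }
    }
    constraints[[c_pos]] <- cl
  }
  mols <- embed_series(bench$smiles[ord], constraints[ord], seed = seed,
                       ids = as.character(bench$compound_id[ord]))
  mols[as.character(bench$compound_id)]
}
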