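#' @importFrom stats sd prcomp var coef lm setNames rnorm runif cor dist
#'   predict quantile
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom tools md5sum
NULL

# Per-element nonbonded parameters (UFF, Rappe et al. 1992): vdW distance
# x_i = pairwise minimum-energy separation for the homodimer (Angstrom) and
# well depth D_i (kcal/mol).  Combined by Lorentz-Berthelot in the field
# engine.  r_covalent only steers bond perception for SDF input.
UFF_VDW <- data.frame(
  element = c("H",   "C",   "N",   "O",   "F",   "S",   "Cl",  "Br",  "I",   "P"),
  rmin    = c(2.886, 3.851, 3.660, 3.500, 3.364, 4.035, 3.947, 4.189, 4.500, 4.147),
  eps     = c(0.044, 0.105, 0.069, 0.060, 0.050, 0.274, 0.227, 0.251, 0.339, 0.305),
  stringsAsFactors = FALSE
)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403,
                 S = 32.06, Cl = 35.45, Br = 79.904, I = 126.90447, P = 30.973762)

#' Locate the Python interpreter used for conformer embedding
#'
#' The embedding helper requires a Python with RDKit importable.  The
#' interpreter defaults to `python` on the PATH and can be overridden with
#' `options(qsar3d.python = "/path/to/python")`.
#'
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  py <- getOption("qsar3d.python", Sys.which("python")[[1L]])
  if (!nzchar(py)) {
    stop("No 'python' interpreter found on PATH; set options(qsar3d.python=)")
  }
  py
}

.embed_cache <- new.env(parent = emptyenv())

#' Embed SMILES into charged 3D molecules
#'
#' Generates one explicit-hydrogen, force-field-minimised 3D conformer per
#' SMILES (ETKDG distance geometry seeded by `seed`, MMFF94 minimisation)
#' and assigns Gasteiger partial charges plus per-atom pharmacophoric flags
#' (aromatic, H-bond donor, H-bond acceptor).  Output is deterministic for a
#' fixed `seed`.  Embedding is delegated to RDKit through the bundled
#' `embed_molecules.py` helper; results are memoised per (SMILES, seed)
#' within the session.
#'
#' @param smiles Character vector of SMILES strings.
#' @param seed Integer random seed for distance-geometry embedding.
#' @param ids Optional identifiers (default: names of `smiles` or 1..n).
#' @return A list of `qsar_mol` objects (see [qsar_mol()]).
#' @export
embed_molecules <- function(smiles, seed = 1L, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  keys <- paste0(smiles, "#", as.integer(seed))
  todo <- !vapply(unname(keys), exists, logical(1), envir = .embed_cache,
                  USE.NAMES = FALSE)
  if (any(todo)) {
    reqs <- unname(lapply(which(todo), function(k) list(id = k, smiles = smiles[[k]])))
    res <- .run_embed_helper(reqs, seed)
    for (rec in res) {
      k <- rec$id
      if (!isTRUE(rec$ok)) {
        assign(keys[[k]], structure(list(error = rec$error, smiles = rec$smiles),
                                    class = "qsar_embed_error"), envir = .embed_cache)
      } else {
        assign(keys[[k]], .mol_from_record(rec, seed), envir = .embed_cache)
      }
    }
  }
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    hit <- get(keys[[k]], envir = .embed_cache)
    if (inherits(hit, "qsar_embed_error")) {
      stop("embedding failed for SMILES '", hit$smiles, "': ", hit$error)
    }
    hit$id <- ids[[k]]
    out[[k]] <- hit
  }
  names(out) <- ids
  out
}

.run_embed_helper <- function(payload, seed) {
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  helper <- system.file("python", "embed_molecules.py", package = "qsar3d")
  status <- system2(find_python(), c(shQuote(helper), "--seed", as.integer(seed),
                                     shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(outfile)) {
    stop("conformer embedding helper failed (exit status ", status, ")")
  }
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Embed a congeneric series with shared fragment geometry
#'
#' Embeds the molecules in order; a molecule with constraints inherits the
#' listed atom coordinates from earlier series members (the references)
#' and keeps them position-restrained through minimisation.  Chaining a
#' free template, per-scaffold parents and first-occurrence substituent
#' parents gives the whole series one geometry for every shared fragment
#' -- the preparation a lattice-field QSAR expects, where only genuinely
#' new atoms relax freely.
#'
#' @param smiles Character vector of SMILES, ordered so that every
#'   constraint reference precedes its dependants.
#' @param constraints List (one element per molecule) of constraint lists;
#'   each constraint is `list(ref = <index of an earlier molecule>,
#'   map = <two-column matrix (molecule_atom, reference_atom)>)` with
#'   1-based heavy-atom indices in SMILES order.  `list()` embeds freely.
#' @param seed Embedding seed.
#' @param ids Optional identifiers.
#' @return List of `qsar_mol` in input order.
#' @export
embed_series <- function(smiles, constraints, seed = 1L, ids = NULL) {
  stopifnot(length(constraints) == length(smiles))
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  # a molecule's conformer is fully determined by its SMILES, the seed
  # and the (recursively keyed) geometry it is constrained to, so each
  # molecule is cached individually across series calls
  keys <- character(length(smiles))
  for (k in seq_along(smiles)) {
    keys[k] <- config_hash(list(smiles[[k]], as.integer(seed),
                                lapply(constraints[[k]], function(con) {
                                  list(keys[[con$ref]], as.matrix(con$map))
                                })))
  }
  keys <- paste0("mol#", keys)
  miss <- which(!vapply(keys, exists, logical(1), envir = .embed_cache,
                        USE.NAMES = FALSE))
  if (length(miss)) {
    needed <- sort(unique(c(miss, unlist(lapply(miss, function(k) {
      vapply(constraints[[k]], `[[`, numeric(1), "ref")
    })))))
    series <- lapply(needed, function(k) {
      if (!k %in% miss) {   # cached reference: ship its geometry only
        mol <- get(keys[[k]], envir = .embed_cache)
        return(list(id = k, smiles = smiles[[k]],
                    fixed_atoms = list(x = mol$atoms$x, y = mol$atoms$y,
                                       z = mol$atoms$z)))
      }
      list(id = k, smiles = smiles[[k]],
           constraints = unname(lapply(constraints[[k]], function(con) {
             m <- as.matrix(con$map)
             list(ref = as.integer(con$ref),
                  map = unname(cbind(as.integer(m[, 1]) - 1L,
                                     as.integer(m[, 2]) - 1L)))
           })))
    })
    res <- .run_embed_helper(list(series = unname(series)), seed)
    for (rec in res) {
      if (!isTRUE(rec$ok)) {
        stop("embedding failed for SMILES '", rec$smiles, "': ", rec$error)
      }
      assign(keys[[rec$id]], .mol_from_record(rec, seed), envir = .embed_cache)
    }
  }
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    mol <- get(keys[[k]], envir = .embed_cache)
    mol$id <- ids[[k]]
    out[[k]] <- mol
  }
  names(out) <- ids
  out
}

#' Embed and minimise a single molecule
#'
#' Convenience wrapper around [embed_molecules()] for one SMILES.
#'
#' @inheritParams embed_molecules
#' @param id Identifier stored on the molecule.
#' @return A `qsar_mol`.
#' @export
embed_and_minimize <- function(smiles, seed = 1L, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  embed_molecules(smiles, seed = seed, ids = id)[[1L]]
}

.mol_from_record <- function(rec, seed) {
  at <- rec$atoms
  atoms <- data.frame(
    element = unlist(at$element), x = unlist(at$x), y = unlist(at$y),
    z = unlist(at$z), charge = unlist(at$charge),
    aromatic = unlist(at$aromatic) == 1L, hbd = unlist(at$hbd) == 1L,
    hba = unlist(at$hba) == 1L, stringsAsFactors = FALSE
  )
  bonds <- data.frame(i = unlist(rec$bonds$i), j = unlist(rec$bonds$j),
                      order = unlist(rec$bonds$order))
  qsar_mol(id = rec$id, smiles = rec$smiles, atoms = atoms, bonds = bonds,
           n_heavy = rec$n_heavy, net_charge = rec$net_charge, seed = seed)
}

#' Construct a 3D molecule object
#'
#' The container used throughout the field engine: an atom table (element,
#' coordinates in Angstrom, Gasteiger partial charge in elementary charges,
#' aromatic/donor/acceptor flags) plus a bond table.  Construction populates
#' the per-atom physicochemical property values needed for similarity-index
#' fields: vdW radius and well depth (UFF table), and a hydrophobic
#' contribution (+1 apolar carbon or halogen on carbon, -1 N/O, 0 otherwise).
#'
#' @param id Identifier.
#' @param smiles SMILES the molecule was built from (may be `NA`).
#' @param atoms `data.frame` with at least element/x/y/z; missing charge or
#'   flag columns are filled with zeros/`FALSE`.
#' @param bonds `data.frame` with columns i, j (1-based atom indices), order.
#' @param n_heavy Number of heavy atoms (leading block of `atoms`).
#' @param net_charge Integer net molecular charge.
#' @param seed Embedding seed recorded for provenance.
#' @return An object of class `qsar_mol`.
#' @export
qsar_mol <- function(id, smiles = NA_character_, atoms, bonds = NULL,
                     n_heavy = NULL, net_charge = 0L, seed = NA_integer_) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  for (col in c("charge")) if (is.null(atoms[[col]])) atoms[[col]] <- 0
  for (col in c("aromatic", "hbd", "hba")) if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  idx <- match(atoms$element, UFF_VDW$element)
  if (anyNA(idx)) {
    stop("unparameterised element(s): ",
         paste(unique(atoms$element[is.na(idx)]), collapse = ", "))
  }
  atoms$vdw_radius <- UFF_VDW$rmin[idx] / 2   # per-atom radius; pair rmin = r_i + r_j
  atoms$eps <- UFF_VDW$eps[idx]
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  if (is.null(n_heavy)) n_heavy <- sum(atoms$element != "H")
  atoms$w_hyd <- .hydrophobic_contrib(atoms, bonds)
  structure(list(id = id, smiles = smiles, atoms = atoms, bonds = bonds,
                 n_heavy = as.integer(n_heavy), net_charge = as.integer(net_charge),
                 seed = seed),
            class = "qsar_mol")
}

# Pinned hydrophobic atom contributions: +1 for carbon with no N/O
# neighbour and for halogens bound to carbon; -1 for N and O; 0 otherwise.
.hydrophobic_contrib <- function(atoms, bonds) {
  n <- nrow(atoms)
  w <- numeric(n)
  nbr <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      nbr[[bonds$i[k]]] <- c(nbr[[bonds$i[k]]], bonds$j[k])
      nbr[[bonds$j[k]]] <- c(nbr[[bonds$j[k]]], bonds$i[k])
    }
  }
  for (a in seq_len(n)) {
    el <- atoms$element[a]
    nb_el <- atoms$element[nbr[[a]]]
    if (el == "C" && !any(nb_el %in% c("N", "O"))) w[a] <- 1
    else if (el %in% c("F", "Cl", "Br", "I") && any(nb_el == "C")) w[a] <- 1
    else if (el %in% c("N", "O")) w[a] <- -1
  }
  w
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat("<qsar_mol> ", x$id, ": ", nrow(x$atoms), " atoms (",
      x$n_heavy, " heavy), net charge ", x$net_charge, "\n", sep = "")
  invisible(x)
}

#' Atom coordinates of a molecule
#' @param mol A `qsar_mol`.
#' @return Numeric matrix (atoms x 3).
#' @export
mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param mol A `qsar_mol`.
#' @param xyz Numeric matrix (atoms x 3).
#' @return The molecule with new coordinates.
#' @export
mol_set_coords <- function(mol, xyz) {
  stopifnot(nrow(xyz) == nrow(mol$atoms), ncol(xyz) == 3L)
  mol$atoms$x <- xyz[, 1L]; mol$atoms$y <- xyz[, 2L]; mol$atoms$z <- xyz[, 3L]
  mol
}

#' Molecular weight from standard atomic masses
#' @param mol A `qsar_mol`.
#' @return Molecular weight in Dalton.
#' @export
mol_weight <- function(mol) {
  sum(ATOMIC_MASS[mol$atoms$element])
}

#' Verify and return assigned partial charges
#'
#' Charges are assigned at embedding time (Gasteiger).  This accessor
#' enforces the conservation invariant: the sum of partial charges must
#' equal the net molecular charge within 1e-3.
#'
#' @param mol A `qsar_mol`.
#' @return The molecule, invisibly, after validation.
#' @export
assign_partial_charges <- function(mol) {
  total <- sum(mol$atoms$charge)
  if (abs(total - mol$net_charge) > 1e-3) {
    stop("partial charges sum to ", signif(total, 6), " but net charge is ",
         mol$net_charge)
  }
  invisible(mol)
}

#' Molecular graph of a molecule
#'
#' Undirected [igraph::graph] with one vertex per atom (element stored as
#' vertex attribute) and one edge per bond.  Used for substructure mapping
#' during alignment and for ring/cluster perception in feature detection.
#'
#' @param mol A `qsar_mol`.
#' @param heavy_only Drop hydrogens first.
#' @return An igraph object.
#' @export
mol_graph <- function(mol, heavy_only = FALSE) {
  atoms <- mol$atoms; bonds <- mol$bonds
  keep <- if (heavy_only) which(atoms$element != "H") else seq_len(nrow(atoms))
  remap <- match(seq_len(nrow(atoms)), keep)
  sel <- bonds$i %in% keep & bonds$j %in% keep
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(remap[bonds$i[sel]], remap[bonds$j[sel]]))
  }
  igraph::set_vertex_attr(g, "element", value = atoms$element[keep])
}
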