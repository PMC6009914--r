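# Rigid-body superposition and orientation search.
#
# Molecules are aligned by least-squares (Kabsch) superposition over an
# atom mapping of a shared substructure -- for the benchmark series the
# conserved benzenesulfonamide-pyrazole core, for arbitrary pairs a
# mapping found by labelled subgraph matching (igraph LAD).  The grid-frame
# orientation of the whole aligned aggregate can then be optimised by a
# systematic rotation scan scored by cross-validated q2.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `||R p + t - q||` over paired points.
#'
#' @param p Moving points (n x 3).
#' @param q Reference points (n x 3).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` after superposition.
#' @export
kabsch_fit <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3L, ncol(q) == 3L, nrow(p) >= 3L)
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  s <- svd(crossprod(pp, qq))            # H = P'Q
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- qc - as.vector(rot %*% pc)
  moved <- sweep(p %*% t(rot), 2, trans, "+")
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - q)^2))))
}

#' Map a common substructure between two molecules
#'
#' Labelled subgraph monomorphism (igraph, LAD algorithm) of the smaller
#' molecule's heavy-atom graph into the larger one, elements constraining
#' the candidate domains.  Among all embeddings the one giving the lowest
#' post-superposition RMSD is returned.
#'
#' @param mol,template `qsar_mol` objects.
#' @param max_maps Cap on embeddings evaluated geometrically.
#' @return Two-column integer matrix `(mol_idx, template_idx)`.
#' @export
common_substructure_mapping <- function(mol, template, max_maps = 100L) {
  g1 <- mol_graph(mol, heavy_only = TRUE)
  g2 <- mol_graph(template, heavy_only = TRUE)
  swap <- igraph::vcount(g1) > igraph::vcount(g2)
  pat <- if (swap) g2 else g1
  tgt <- if (swap) g1 else g2
  pel <- igraph::vertex_attr(pat, "element")
  tel <- igraph::vertex_attr(tgt, "element")
  domains <- lapply(pel, function(e) which(tel == e))
  if (any(!lengths(domains))) stop("no common substructure of >= 3 atoms")
  maps <- igraph::subgraph_isomorphisms(pattern = pat, target = tgt,
                                        method = "lad", induced = FALSE,
                                        domains = domains)
  if (!length(maps)) stop("no common substructure of >= 3 atoms")
  maps <- maps[seq_len(min(length(maps), max_maps))]
  cm <- mol_coords(mol); ct <- mol_coords(template)
  best <- NULL; best_rmsd <- Inf
  for (m in maps) {
    tgt_idx <- as.integer(m)
    mp <- if (swap) cbind(tgt_idx, seq_along(tgt_idx)) else cbind(seq_along(tgt_idx), tgt_idx)
    fit <- kabsch_fit(cm[mp[, 1], , drop = FALSE], ct[mp[, 2], , drop = FALSE])
    if (fit$rmsd < best_rmsd) { best_rmsd <- fit$rmsd; best <- mp }
  }
  colnames(best) <- c("mol", "template")
  best
}

#' Superimpose a molecule onto a template
#'
#' Rigidly transforms `mol` to minimise RMSD over the paired atoms; the
#' mapping defaults to the maximum labelled-subgraph embedding found by
#' [common_substructure_mapping()].  The achieved RMSD is stored on the
#' result as `$align_rmsd`.
#'
#' @param mol Molecule to move.
#' @param template Reference molecule.
#' @param mapping Optional explicit 2-column atom index matrix
#'   `(mol, template)`; must pair at least 3 atoms.
#' @return The transformed `qsar_mol`.
#' @export
align_to_template <- function(mol, template, mapping = NULL) {
  if (is.null(mapping)) mapping <- common_substructure_mapping(mol, template)
  mapping <- as.matrix(mapping)
  if (nrow(mapping) < 3L) stop("alignment needs a mapping of >= 3 atoms")
  cm <- mol_coords(mol); ct <- mol_coords(template)
  fit <- kabsch_fit(cm[mapping[, 1], , drop = FALSE],
                    ct[mapping[, 2], , drop = FALSE])
  out <- mol_set_coords(mol, sweep(cm %*% t(fit$rotation), 2, fit$translation, "+"))
  out$align_rmsd <- fit$rmsd
  out
}

#' Align the benchmark series onto its template compound
#'
#' Uses the index-based mapping of the conserved core (see
#' [core_anchor_indices()]) with compound 26 -- the most active -- as the
#' default template.
#'
#' @param mols Embedded benchmark molecules (named by compound id).
#' @param bench Benchmark table ([load_benchmark()]).
#' @param template_id Compound id of the template.
#' @return List of aligned `qsar_mol`.
#' @export
align_benchmark <- function(mols, bench = load_benchmark(), template_id = 26L) {
  tid <- as.character(template_id)
  if (!tid %in% names(mols)) stop("template compound ", tid, " not in molecule set")
  template <- mols[[tid]]
  tmpl_scaffold <- bench$scaffold[bench$compound_id == template_id]
  out <- mols
  for (k in seq_along(mols)) {
    cid <- as.integer(names(mols)[k])
    map <- core_mapping(bench$scaffold[bench$compound_id == cid], tmpl_scaffold)
    out[[k]] <- align_to_template(mols[[k]], template, mapping = map)
  }
  out
}

.rotation_angle <- function(r) {
  acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2)))
}

# The 24 proper rotations of the cubic lattice.
.octahedral_group <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    m <- matrix(0, 3, 3)
    m[cbind(1:3, p)] <- c(s1, s2, s3)
    if (abs(det(m) - 1) < 1e-9) out[[length(out) + 1L]] <- m
  }
  out
}

# Quotient a rotation list by the lattice symmetry group: orientations
# related by a whole-lattice rotation sample the same field values up to
# column permutation, so cross-validation scores them identically; one
# representative (the smallest rotation angle) per class suffices.
.lattice_symmetry_reduce <- function(rots) {
  octa <- .octahedral_group()
  classes <- new.env(parent = emptyenv())
  for (r in rots) {
    keys <- vapply(octa, function(q) paste(round(q %*% r, 6), collapse = ","),
                   character(1))
    key <- min(keys)
    cur <- classes[[key]]
    if (is.null(cur) || .rotation_angle(r) < .rotation_angle(cur)) {
      classes[[key]] <- r
    }
  }
  out <- as.list(classes)
  names(out) <- NULL
  out[order(vapply(out, .rotation_angle, numeric(1)))]
}

# Proper rotations on a ZYZ Euler lattice, deduplicated, ordered by
# rotation angle (identity first) so scan ties resolve to the smallest
# rotation.
.euler_rotations <- function(step_degrees) {
  if (step_degrees <= 0 || 360 %% step_degrees != 0) {
    stop("step must be a positive divisor of 360")
  }
  ang <- seq(0, 360 - step_degrees, by = step_degrees) * pi / 180
  beta <- ang[ang <= pi + 1e-12]
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  seen <- new.env(parent = emptyenv())
  rots <- list()
  for (a in ang) for (b in beta) for (g in ang) {
    r <- rz(a) %*% ry(b) %*% rz(g)
    key <- paste(round(r, 6), collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      rots[[length(rots) + 1L]] <- r
    }
  }
  rots[order(vapply(rots, .rotation_angle, numeric(1)))]
}

#' Systematic orientation search of the aligned aggregate
#'
#' Scans a deduplicated Euler-angle lattice of proper rotations applied to
#' the whole aligned molecule set about its aggregate centroid; for each
#' orientation the lattice, fields and column filter are recomputed and
#' the model is scored by leave-one-out q2.  The identity is always part
#' of the scan, so the best objective never falls below the input
#' orientation's; ties resolve to the smallest rotation angle.
#'
#' @param mols Aligned molecules.
#' @param y Activity vector (one value per molecule).
#' @param step_degrees Euler lattice step; must divide 360.
#' @param config [qsar_config()] controlling grid/field/PLS settings.
#' @param method Field flavour passed to the objective.
#' @param objective Optional override: `function(mols) -> numeric` scored
#'   in place of the default field + LOO-q2 objective.
#' @param reduce_lattice_symmetry Drop orientations equivalent up to a
#'   whole-lattice (90-degree net) rotation, which the cross-validated
#'   objective cannot distinguish (default `TRUE`; cuts the scan roughly
#'   24-fold).
#' @return List of class `qsar_orientation`: `rotation`, `translation`,
#'   `objective_value`, and the full `scan` table.
#' @export
orientation_search <- function(mols, y, step_degrees = 30, config = qsar_config(),
                               method = c("comfa", "comsia"), objective = NULL,
                               reduce_lattice_symmetry = TRUE) {
  method <- match.arg(method)
  if (length(mols) < 6L) stop("orientation search needs at least 6 molecules")
  if (!is.null(y) && (length(unique(y)) < 2L || sd(y) == 0)) {
    stop("activity vector has zero variance")
  }
  rots <- .euler_rotations(step_degrees)
  if (reduce_lattice_symmetry) rots <- .lattice_symmetry_reduce(rots)
  centroid <- colMeans(do.call(rbind, lapply(mols, mol_coords)))
  if (is.null(objective)) {
    objective <- function(mset) {
      grid <- make_grid(mset, spacing = config$grid$spacing, margin = config$grid$margin)
      fm <- compute_field_matrix(mset, grid, method = method, config = config)
      fm <- column_filter(fm, threshold = config$grid$column_filter_threshold)
      loo_q2(fm, y, n_components = config$pls$n_components)$q2
    }
  }
  score <- numeric(length(rots))
  for (k in seq_along(rots)) {
    r <- rots[[k]]
    rotated <- lapply(mols, function(m) {
      xyz <- mol_coords(m)
      mol_set_coords(m, sweep(sweep(xyz, 2, centroid) %*% t(r), 2, centroid, "+"))
    })
    score[k] <- objective(rotated)
  }
  best <- which.max(score)   # first maximum = smallest rotation angle
  r <- rots[[best]]
  structure(list(rotation = r,
                 translation = centroid - as.vector(r %*% centroid),
                 objective_value = score[best],
                 scan = data.frame(orientation = seq_along(rots), objective = score),
                 rotations = rots),
            class = "qsar_orientation")
}
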