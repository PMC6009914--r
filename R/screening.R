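# Virtual-screening funnel: 2D descriptors and rule filters (Lipinski
# rule of five, descriptor standard ranges), common-feature pharmacophore
# construction and matching on aligned 3D molecules, and PCA chemical-space
# similar/dissimilar selection.

.desc_cache <- new.env(parent = emptyenv())

#' Compute screening descriptors
#'
#' Molecular weight (standard atomic masses), Wildman-Crippen
#' atomic-contribution logP and Ertl fragment-contribution TPSA; H-bond
#' donors counted as N-H/O-H hydrogens and acceptors as N + O atoms (the
#' rule-of-five conventions); rotatable bonds by the strict
#' single-non-ring-bond rule with terminal rotors excluded; plus a
#' substructure flag for an unsubstituted primary sulfonamide
#' (S(=O)(=O)NH2).  Computed by the bundled RDKit helper and memoised per
#' SMILES within the session; vectorised over the input.
#'
#' @param x A character vector of SMILES, a single `qsar_mol`, or a list
#'   of `qsar_mol`.
#' @return A `data.frame`, one row per molecule: `mw`, `logp`,
#'   `hbd_count`, `hba_count`, `tpsa`, `rotatable_bonds`,
#'   `has_primary_sulfonamide`.
#' @export
compute_descriptors <- function(x) {
  if (inherits(x, "qsar_mol")) x <- list(x)
  smiles <- if (is.list(x)) vapply(x, function(m) m$smiles, character(1)) else x
  stopifnot(is.character(smiles), length(smiles) >= 1L, !anyNA(smiles))
  todo <- unique(smiles[!vapply(smiles, exists, logical(1),
                                envir = .desc_cache, USE.NAMES = FALSE)])
  if (length(todo)) {
    reqs <- unname(lapply(seq_along(todo),
                          function(k) list(id = k, smiles = todo[[k]])))
    infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    jsonlite::write_json(reqs, infile, auto_unbox = TRUE, digits = NA)
    helper <- system.file("python", "embed_molecules.py", package = "qsar3d")
    status <- system2(find_python(), c(shQuote(helper), "--descriptors",
                                       shQuote(infile), shQuote(outfile)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(outfile)) {
      stop("descriptor helper failed (exit status ", status, ")")
    }
    res <- jsonlite::read_json(outfile, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    for (rec in res) {
      if (!isTRUE(rec$ok)) {
        stop("descriptor computation failed for SMILES '", rec$smiles, "': ",
             rec$error)
      }
      assign(rec$smiles, data.frame(
        mw = rec$mw, logp = rec$logp, hbd_count = as.integer(rec$hbd),
        hba_count = as.integer(rec$hba), tpsa = rec$tpsa,
        rotatable_bonds = as.integer(rec$rotatable_bonds),
        has_primary_sulfonamide = isTRUE(rec$primary_sulfonamide)
      ), envir = .desc_cache)
    }
  }
  out <- do.call(rbind, lapply(smiles, get, envir = .desc_cache))
  rownames(out) <- NULL
  out
}

.filter_report <- function(rule, value, threshold, pass) {
  out <- data.frame(rule = rule, value = value, threshold = threshold, pass = pass,
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- all(pass)
  class(out) <- c("qsar_filter_report", "data.frame")
  out
}

#' Overall outcome of a filter report
#' @param report A filter report.
#' @return Logical: all rules passed.
#' @export
filter_pass <- function(report) {
  isTRUE(attr(report, "overall"))
}

#' Lipinski rule-of-five filter
#'
#' The four drug-likeness rules: MW < 500 Da, logP <= 5, H-bond donors
#' <= 5, H-bond acceptors (N + O) <= 10.  All rules are evaluated (no
#' short-circuit) and reported individually.
#'
#' @param d Descriptor row from [compute_descriptors()].
#' @return A `qsar_filter_report` with one row per rule; see
#'   [filter_pass()] for the conjunction.
#' @export
lipinski_filter <- function(d) {
  .filter_report(
    rule = c("mw_lt_500", "logp_le_5", "hbd_le_5", "hba_le_10"),
    value = c(d$mw, d$logp, d$hbd_count, d$hba_count),
    threshold = c(500, 5, 5, 10),
    pass = c(d$mw < 500, d$logp <= 5, d$hbd_count <= 5, d$hba_count <= 10)
  )
}

#' Load the packaged descriptor standard ranges
#'
#' The shipped table covers the locally computable descriptors (MW, logP)
#' with the drug-likeness standard ranges used in the screening funnel;
#' users may extend it with further columns of the same layout.
#'
#' @return `data.frame` with `descriptor`, `lower`, `upper`.
#' @export
default_descriptor_ranges <- function() {
  read.csv(system.file("extdata", "descriptor_ranges.csv", package = "qsar3d"))
}

#' Descriptor standard-range filter
#'
#' Inclusive interval check for every descriptor present in both the
#' descriptor vector and the ranges table.  An empty table passes
#' vacuously; a range row naming an unknown descriptor is a
#' configuration error.
#'
#' @param d Descriptor row from [compute_descriptors()] (or any named
#'   one-row data.frame of numeric descriptors).
#' @param ranges Ranges table as in [default_descriptor_ranges()].
#' @return A `qsar_filter_report`.
#' @export
range_filter <- function(d, ranges = default_descriptor_ranges()) {
  if (!nrow(ranges)) {
    return(.filter_report(character(0), numeric(0), character(0), logical(0)))
  }
  unknown <- setdiff(ranges$descriptor, names(d))
  if (length(unknown)) {
    stop("ranges table names unknown descriptor(s): ", paste(unknown, collapse = ", "))
  }
  vals <- vapply(ranges$descriptor, function(k) as.numeric(d[[k]]), numeric(1))
  .filter_report(
    rule = paste0(ranges$descriptor, "_in_range"),
    value = vals,
    threshold = paste0("[", ranges$lower, ", ", ranges$upper, "]"),
    pass = vals >= ranges$lower & vals <= ranges$upper
  )
}

#' Detect pharmacophoric features of a 3D molecule
#'
#' Pinned substructure rules: one donor feature per N/O bearing hydrogen,
#' one acceptor feature per N/O with an available lone pair, one aromatic
#' feature per 5- or 6-membered aromatic ring (centroid), one hydrophobe
#' per connected cluster of >= 3 apolar carbons / aryl halogens
#' (centroid).
#'
#' @param mol A `qsar_mol` (aligned if features feed a model frame).
#' @return `data.frame`: `kind`, `x`, `y`, `z`.
#' @export
detect_features <- function(mol) {
  atoms <- mol$atoms
  xyz <- mol_coords(mol)
  feats <- list()
  add <- function(kind, pts) {
    if (length(pts) == 0) return(invisible())
    pts <- matrix(pts, ncol = 3)
    feats[[length(feats) + 1L]] <<- data.frame(kind = kind, x = pts[, 1],
                                               y = pts[, 2], z = pts[, 3])
  }
  add("HBD", xyz[which(atoms$hbd), , drop = FALSE])
  add("HBA", xyz[which(atoms$hba), , drop = FALSE])
  g <- mol_graph(mol)
  arom <- which(atoms$aromatic)
  if (length(arom) >= 5L) {
    sub <- igraph::induced_subgraph(g, arom)
    for (members in .small_rings(sub)) {
      add("aromatic", colMeans(xyz[arom[members], , drop = FALSE]))
    }
  }
  hyd <- which(atoms$w_hyd > 0 & atoms$element != "H")
  if (length(hyd) >= 3L) {
    sub <- igraph::induced_subgraph(g, hyd)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      members <- hyd[comp$membership == k]
      if (length(members) >= 3L) {
        add("hydrophobe", colMeans(xyz[members, , drop = FALSE]))
      }
    }
  }
  if (!length(feats)) {
    return(data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric()))
  }
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

# Minimal 5-/6-membered rings of a graph: for every edge, the shortest
# cycle through it (edge removed, shortest remaining path between its
# ends), deduplicated -- sufficient ring perception for aromatic systems.
.small_rings <- function(g, sizes = c(5L, 6L)) {
  rings <- list()
  seen <- character(0)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    gm <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(gm, from = u, to = v))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) %in% sizes) {
      key <- paste(sort(path), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- sort(path)
      }
    }
  }
  rings
}

#' Build a common-feature pharmacophore from aligned actives
#'
#' Features are detected per molecule, then features of the same kind are
#' clustered across molecules within `merge_radius`; only clusters
#' represented in every active survive (common features).  Feature centres
#' are cluster centroids; if more than `max_features` clusters survive the
#' tightest (smallest spread) are kept.
#'
#' @param actives List of aligned `qsar_mol` (>= 2).
#' @param merge_radius Cross-molecule feature merge radius, Angstrom.
#' @param min_features,max_features Model size bounds (study settings 4 / 10).
#' @param tolerance Match radius stored on every feature, Angstrom.
#' @return A `qsar_pharmacophore`: `features` (kind, centre, tolerance),
#'   `min_features_required`, `max_features`.
#' @export
build_pharmacophore <- function(actives, merge_radius = 1.5, min_features = 4L,
                                max_features = 10L, tolerance = 1.0) {
  stopifnot(length(actives) >= 2L)
  feat <- lapply(actives, detect_features)
  seeds <- feat[[1L]]
  clusters <- list()
  for (s in seq_len(nrow(seeds))) {
    kind <- seeds$kind[s]
    members <- matrix(as.numeric(seeds[s, c("x", "y", "z")]), ncol = 3)
    ok <- TRUE
    for (m in feat[-1L]) {
      cand <- m[m$kind == kind, , drop = FALSE]
      if (!nrow(cand)) { ok <- FALSE; break }
      d <- sqrt((cand$x - members[1, 1])^2 + (cand$y - members[1, 2])^2 +
                  (cand$z - members[1, 3])^2)
      if (min(d) > merge_radius) { ok <- FALSE; break }
      best <- which.min(d)
      members <- rbind(members, as.numeric(cand[best, c("x", "y", "z")]))
    }
    if (ok) {
      centre <- colMeans(members)
      spread <- if (nrow(members) > 1) {
        mean(sqrt(rowSums(sweep(members, 2, centre)^2)))
      } else 0
      clusters[[length(clusters) + 1L]] <-
        list(kind = kind, centre = centre, spread = spread)
    }
  }
  if (length(clusters) < min_features) {
    stop("only ", length(clusters), " common feature cluster(s) found; ",
         "need >= ", min_features, " -- consider a larger merge radius")
  }
  if (length(clusters) > max_features) {
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "spread"))]
    clusters <- clusters[seq_len(max_features)]
  }
  features <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(kind = cl$kind, x = cl$centre[1], y = cl$centre[2],
               z = cl$centre[3], tolerance = tolerance)
  }))
  rownames(features) <- NULL
  structure(list(features = features,
                 min_features_required = as.integer(min_features),
                 max_features = as.integer(max_features)),
            class = "qsar_pharmacophore")
}

#' @export
print.qsar_pharmacophore <- function(x, ...) {
  cat("<qsar_pharmacophore> ", nrow(x$features), " features (",
      paste(sprintf("%s:%d", names(table(x$features$kind)),
                    as.integer(table(x$features$kind))), collapse = ", "),
      "), match threshold ", x$min_features_required, "\n", sep = "")
  invisible(x)
}

#' Match a molecule against a pharmacophore model
#'
#' Greedy nearest-first one-to-one assignment of the molecule's detected
#' features to model features of the same kind within each feature's
#' tolerance (closed ball: a feature exactly at tolerance distance
#' matches).  The molecule must already sit in the model's frame.
#'
#' @param mol Aligned `qsar_mol`.
#' @param model A `qsar_pharmacophore`.
#' @return List: `pass` (matched >= required minimum), `matched` count,
#'   `mapping` table of assignments with distances.
#' @export
match_pharmacophore <- function(mol, model) {
  mf <- detect_features(mol)
  pf <- model$features
  pairs <- NULL
  for (i in seq_len(nrow(mf))) {
    same <- which(pf$kind == mf$kind[i])
    if (!length(same)) next
    d <- sqrt((pf$x[same] - mf$x[i])^2 + (pf$y[same] - mf$y[i])^2 +
                (pf$z[same] - mf$z[i])^2)
    ok <- d <= pf$tolerance[same] + 1e-12
    if (any(ok)) {
      pairs <- rbind(pairs, data.frame(mol_feature = i, model_feature = same[ok],
                                       distance = d[ok]))
    }
  }
  mapping <- data.frame(mol_feature = integer(), model_feature = integer(),
                        distance = numeric())
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$distance), , drop = FALSE]
    used_m <- used_p <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      if (pairs$mol_feature[r] %in% used_m || pairs$model_feature[r] %in% used_p) next
      mapping <- rbind(mapping, pairs[r, ])
      used_m <- c(used_m, pairs$mol_feature[r])
      used_p <- c(used_p, pairs$model_feature[r])
    }
  }
  list(pass = nrow(mapping) >= model$min_features_required,
       matched = nrow(mapping), mapping = mapping)
}

#' Serialise / load a pharmacophore model as JSON
#' @param model A `qsar_pharmacophore`.
#' @param path Output path.
#' @return `path` (write) or the model (read).
#' @export
write_pharmacophore_json <- function(model, path) {
  jsonlite::write_json(list(features = model$features,
                            min_features_required = model$min_features_required,
                            max_features = model$max_features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pharmacophore_json
#' @export
read_pharmacophore_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = as.data.frame(x$features),
                 min_features_required = as.integer(x$min_features_required),
                 max_features = as.integer(x$max_features)),
            class = "qsar_pharmacophore")
}

#' Chemical-space similar / dissimilar selection
#'
#' Standardises the descriptor matrix, projects onto the first two
#' principal axes and returns (i) the members of the `k_similar` smallest
#' pairwise distances (deduplicated, in increasing distance order) and
#' (ii) the `k_dissimilar` rows farthest from the score-space centroid.
#' Ties break by row id.
#'
#' @param descriptors Numeric matrix or data.frame (rows = compounds).
#' @param k_similar,k_dissimilar Selection sizes.
#' @return List: `similar` ids, `dissimilar` ids, `scores` (n x 2).
#' @export
chemical_space_select <- function(descriptors, k_similar = 5L, k_dissimilar = 5L) {
  X <- as.matrix(descriptors)
  n <- nrow(X)
  if (n < k_similar + k_dissimilar) stop("not enough rows for the requested selection")
  keep <- apply(X, 2, sd) > 0
  if (!any(keep)) stop("constant descriptor matrix: no principal axes")
  Xs <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))
  dm <- as.matrix(dist(scores))
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  ord <- order(dm[ut], ut[, 1], ut[, 2])
  similar <- character(0)
  for (r in ord) {
    similar <- union(similar, ids[c(ut[r, 1], ut[r, 2])])
    if (length(similar) >= k_similar) break
  }
  similar <- head(similar, k_similar)
  centroid_d <- sqrt(rowSums(scale(scores, center = TRUE, scale = FALSE)^2))
  dis_ord <- order(-centroid_d, seq_len(n))
  list(similar = similar, dissimilar = ids[head(dis_ord, k_dissimilar)],
       scores = scores)
}
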